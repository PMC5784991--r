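test_that("family rows parse with brackets, aliases and empty offspring", {
  ped <- parse_family_table(table2_fixture())
  fam <- ped$families

  # backcross family with four offspring, bracket groups ignored
  f1b <- fam[fam$family_id == "1b", ]
  expect_equal(f1b$n_offspring, 4L)
  expect_equal(f1b$cross_type, "backcross")
  expect_setequal(f1b$offspring[[1]], c("aAA109", "aAA110", "aAF95", "aAF96"))

  # "aAF46" (parent mention) and the 1a offspring are one individual
  expect_equal(sum(ped$individuals$canonical_id == "aAF46"), 1L)
  expect_equal(
    ped$individuals$family_of_birth[ped$individuals$canonical_id == "aAF46"],
    "1a"
  )
  # multi-alias mentions merge: aAF96 and aAF96/103 are one worm
  al <- ped$individuals$aliases[ped$individuals$canonical_id == "aAF96"][[1]]
  expect_setequal(al, c("96", "103"))

  # families recorded with no offspring ("---")
  expect_equal(fam$n_offspring[fam$family_id == "2c"], 0L)
  expect_equal(fam$generation_recorded[fam$family_id == "2c"], "F3")

  # alias numbers shared across different genotypes are flagged, not fatal
  expect_true(any(grepl("96", ped$flags$detail)))
  expect_true(any(grepl("141", ped$flags$detail)))
  expect_error(parse_family_table(table2_fixture(), strict = TRUE),
               class = "hw_integrity_error")
})

test_that("malformed tables raise located input errors", {
  expect_error(
    parse_family_table("family_id\tparent1\tparent2\toffspring\n1a\taAA1\tfXX2\tF1: ---\n"),
    regexp = "1a", class = "hw_input_error"
  )
  expect_error(
    parse_family_table("family_id\tparent1\n1a\taAA1\n"),
    class = "hw_input_error"
  )
})

test_that("hybrid census reproduces the family-table counts", {
  res <- run_census(table2_fixture())
  cen <- res$census
  expect_equal(cen$n_aAF, 26L)
  expect_equal(cen$n_fFA, 4L)
  org <- cen$origins
  expect_equal(org$n[org$genotype == "aAF" & org$cross_type == "interspecific"], 18L)
  expect_equal(org$n[org$genotype == "aAF" & org$cross_type == "backcross"], 8L)
  expect_equal(org$n[org$genotype == "fFA" & org$cross_type == "backcross"], 4L)
  # no fFA among F1 offspring of interspecific pairs
  expect_equal(cen$asymmetry$n_fFA_from_interspecific_F1, 0L)
  # class totals equal the sum over cross types
  sums <- tapply(org$n, org$genotype, sum)
  expect_equal(unname(sums[["aAF"]]), cen$n_aAF)
  expect_equal(unname(sums[["fFA"]]), cen$n_fFA)
})

test_that("census totals are invariant to row order and alias formatting", {
  lines <- readLines(table2_fixture())
  base <- hybrid_census(parse_family_table(table2_fixture()))
  # reversed family order (parents then appear after their families of birth)
  rev_txt <- paste(c(lines[1], rev(lines[-1])), collapse = "\n")
  cen_rev <- hybrid_census(parse_family_table(rev_txt))
  expect_equal(cen_rev$n_aAF, base$n_aAF)
  expect_equal(cen_rev$n_fFA, base$n_fFA)
  expect_equal(cen_rev$origins, base$origins)
  # alias formatting: mentioning a worm by any one of its numbers is the same worm
  txt2 <- sub("aAF96/103", "aAF96", paste(lines, collapse = "\n"), fixed = TRUE)
  cen2 <- hybrid_census(parse_family_table(txt2))
  expect_equal(cen2$n_aAF, base$n_aAF)
})

test_that("every fixture offspring is explained by the gamete model", {
  res <- run_census(table2_fixture())
  expect_equal(res$consistency$n_unexplained, 0L)
  expect_gt(res$consistency$n_explained, 0L)
  # an impossible offspring is reported, not swallowed
  bad <- paste(
    "family_id\tparent1\tparent2\toffspring",
    "x1\taAA1\taAA2\tF1: fFA3",
    sep = "\n"
  )
  rep_bad <- pedigree_consistency(parse_family_table(bad))
  expect_equal(rep_bad$n_unexplained, 1L)
  expect_equal(rep_bad$unexplained, "fFA3")
  # empty pedigree gives an empty report
  empty <- parse_family_table("family_id\tparent1\tparent2\toffspring\n")
  expect_equal(nrow(pedigree_consistency(empty)$report), 0L)
})

test_that("generation labels propagate from founders with overrides", {
  ped <- generation_labels(parse_family_table(table2_fixture()))
  ind <- ped$individuals
  gen <- setNames(ind$generation, ind$canonical_id)
  expect_equal(unname(gen["aAA25"]), "P")
  expect_equal(unname(gen["aAF46"]), "F1")
  # structural depth: chain P -> F1 -> F2 through family 4
  expect_equal(unname(gen["aAF68"]), "F1")
  expect_equal(unname(gen["fFA149"]), "F2")

  # the study's relabelling convention: the pure-species F1 couple of family
  # 1c is marked parental so its offspring count as F1
  expect_equal(unname(gen["aAF76"]), "F2")
  ped2 <- generation_labels(
    parse_family_table(table2_fixture()),
    overrides = c(aAA62 = "P", fFF61 = "P")
  )
  gen2 <- setNames(ped2$individuals$generation, ped2$individuals$canonical_id)
  expect_equal(unname(gen2["aAF76"]), "F1")

  # a hypothetical F3 offspring of family 4c sits at depth 3 once the 1c
  # relabelling is applied (aAF86 descends through family 1d)
  txt <- paste(
    c(readLines(table2_fixture()),
      "4e\tfFA149/194\taAF86/141\tF3: fFA300"),
    collapse = "\n"
  )
  ped3 <- generation_labels(parse_family_table(txt),
                            overrides = c(aAA62 = "P", fFF61 = "P"))
  gen3 <- setNames(ped3$individuals$generation, ped3$individuals$canonical_id)
  expect_equal(unname(gen3["fFA300"]), "F3")
})

test_that("cyclic pedigrees are rejected", {
  cyc <- paste(
    "family_id\tparent1\tparent2\toffspring",
    "c1\taAA1\taAA2\tF1: aAA3",
    "c2\taAA3\taAA4\tF1: aAA1",
    sep = "\n"
  )
  expect_error(generation_labels(parse_family_table(cyc)),
               class = "hw_integrity_error")
})
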