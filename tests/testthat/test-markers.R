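test_that("polymorphic-site discovery matches a naive column scan", {
  # no variation
  expect_equal(find_polymorphic_sites("ACGT", "ACGT"), integer(0))
  # single substitution
  expect_equal(find_polymorphic_sites("ACGT", "ACTT"), 3L)
  # gaps and N never create polymorphism
  expect_equal(find_polymorphic_sites(c("AC-T", "ACNT"), "ACGT"), integer(0))

  # planted panel: 9 polymorphic columns, recovered exactly
  set.seed(101)
  refs <- generate_reference_panel(seq_gen_params(), seed = 101)
  got <- find_polymorphic_sites(refs$s28_refs_a, refs$s28_refs_f)
  expect_equal(got, refs$truth$polymorphic_columns)
  scan <- oracle_scan_columns(refs$s28_refs_a$seq, refs$s28_refs_f$seq)
  expect_equal(got, scan$polymorphic)
})

test_that("diagnostic sites are the fixed between-species differences", {
  ds <- find_diagnostic_sites("ACGT", "ACTT")
  expect_equal(ds$column, 3L)
  expect_equal(ds$allele_a, "G")
  expect_equal(ds$allele_f, "T")

  # within-species polymorphism disqualifies a column
  ds2 <- find_diagnostic_sites(c("ACGT", "ACCT"), "ACTT")
  expect_false(3L %in% ds2$column)

  # 9 planted polymorphisms of which exactly 7 are fixed-different
  refs <- generate_reference_panel(seq_gen_params(), seed = 7)
  ds3 <- find_diagnostic_sites(refs$s28_refs_a, refs$s28_refs_f)
  expect_equal(nrow(ds3), 7L)
  expect_equal(ds3, refs$truth$diagnostic)
  scan <- oracle_scan_columns(refs$s28_refs_a$seq, refs$s28_refs_f$seq)
  expect_equal(ds3$column, scan$diagnostic)
})

test_that("diagnostic sites are a subset of polymorphic sites on random panels", {
  set.seed(33)
  for (i in 1:20) {
    refs_a <- random_alignment(3, 40, ids = sprintf("a%d", 1:3))
    refs_f <- random_alignment(3, 40, ids = sprintf("f%d", 1:3))
    panel <- build_marker_panel(refs_a, refs_f)
    expect_true(all(panel$diagnostic_sites$column %in% panel$polymorphic_sites))
  }
})

test_that("alignment errors are reported", {
  expect_error(find_polymorphic_sites("ACGT", "ACG"), class = "hw_input_error")
  expect_error(
    find_polymorphic_sites(character(0), "ACGT"),
    class = "hw_input_error"
  )
})

test_that("nuclear genotype calling scores diagnostic sites correctly", {
  refs <- generate_reference_panel(seq_gen_params(), seed = 5)
  panel <- build_marker_panel(refs$s28_refs_a, refs$s28_refs_f)
  a_seq <- refs$truth$s28_allele_a
  f_seq <- refs$truth$s28_allele_f

  # pure species match all sites of their allele
  expect_equal(call_nuclear(a_seq, panel)$genotype, "AA")
  expect_equal(call_nuclear(f_seq, panel)$genotype, "FF")

  # heterozygote: the two-base ambiguity code at all 7 sites
  het <- simulate_individual_sequences("aAF", refs)$s28
  cn <- call_nuclear(het, panel)
  expect_equal(cn$genotype, "AF")
  expect_equal(cn$n_het, 7L)
  expect_equal(cn$n_resolved, 7L)

  # het at 5 sites, N at the other 2: still AF under the 80%-of-resolved rule
  chars <- strsplit(het, "")[[1]]
  chars[panel$diagnostic_sites$column[1:2]] <- "N"
  cn5 <- call_nuclear(paste(chars, collapse = ""), panel)
  expect_equal(cn5$genotype, "AF")
  expect_equal(cn5$n_het, 5L)
  expect_equal(cn5$n_resolved, 5L)

  # mixed hom-A / hom-F without ambiguity codes: chimera flag, not AF
  chars <- strsplit(a_seq, "")[[1]]
  cols <- panel$diagnostic_sites$column
  chars[cols[1:3]] <- panel$diagnostic_sites$allele_f[1:3]
  expect_equal(call_nuclear(paste(chars, collapse = ""), panel)$genotype, "ambiguous")

  # zero resolved sites: warning plus ambiguous, not an error
  chars <- strsplit(a_seq, "")[[1]]
  chars[cols] <- "N"
  expect_warning(
    cz <- call_nuclear(paste(chars, collapse = ""), panel),
    "ambiguous"
  )
  expect_equal(cz$genotype, "ambiguous")
  expect_equal(cz$n_resolved, 0L)
})

test_that("every reference sequence calls as its own species", {
  refs <- generate_reference_panel(seq_gen_params(), seed = 11)
  panel <- build_marker_panel(refs$s28_refs_a, refs$s28_refs_f)
  for (i in seq_len(nrow(panel$refs_a))) {
    expect_equal(call_nuclear(panel$refs_a[i, ], panel)$genotype, "AA")
  }
  for (i in seq_len(nrow(panel$refs_f))) {
    expect_equal(call_nuclear(panel$refs_f[i, ], panel)$genotype, "FF")
  }
})

test_that("genotype codes compose with maternal-first orientation", {
  expect_equal(compose_genotype("a", "AA"), "aAA")
  expect_equal(compose_genotype("a", "AF"), "aAF")
  expect_equal(compose_genotype("f", "AF"), "fFA")
  expect_equal(compose_genotype("f2", "FF"), "f2FF")
  expect_error(compose_genotype("ambiguous", "AA"), class = "hw_integrity_error")
  expect_error(compose_genotype("a", "ambiguous"), class = "hw_integrity_error")
  expect_error(compose_genotype("x", "AA"), class = "hw_input_error")
})

test_that("genotype code parsing round-trips and rejects junk", {
  codes <- all_genotype_codes()
  expect_length(codes, 12L)
  g <- parse_genotype_code(codes)
  expect_equal(paste0(g$mito, g$allele_maternal, g$allele_paternal), codes)
  expect_error(parse_genotype_code("aAX"), class = "hw_input_error")
  lab <- parse_individual_label("fFA143/159/191")
  expect_equal(lab$genotype, "fFA")
  expect_equal(lab$aliases[[1]], c("143", "159", "191"))
})
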