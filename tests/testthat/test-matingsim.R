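test_that("generator plants exactly the configured site structure", {
  refs <- generate_reference_panel(seq_gen_params(), seed = 3)
  expect_equal(length(refs$truth$polymorphic_columns), 9L)
  expect_equal(nrow(refs$truth$diagnostic), 7L)
  expect_equal(nrow(find_diagnostic_sites(refs$s28_refs_a, refs$s28_refs_f)), 7L)

  # zero within-clade noise: planted divergence recovered exactly
  refs0 <- generate_reference_panel(
    seq_gen_params(div_af = 0.15, within_rate = 0), seed = 3
  )
  coi <- refs0$coi_refs
  expect_equal(
    group_p_distance(coi[coi$clade == "a", ], coi[coi$clade == "f", ]),
    refs0$truth$div_af_planted
  )
  expect_equal(refs0$truth$div_af_planted, 0.15)

  # infeasible parameters rejected
  expect_error(seq_gen_params(n_diagnostic = 10, n_polymorphic = 9),
               class = "hw_input_error")
  expect_error(seq_gen_params(n_polymorphic = 500, s28_length = 400,
                              n_diagnostic = 7),
               class = "hw_input_error")
})

test_that("detector recovers planted counts over random generator draws", {
  set.seed(47)
  for (i in 1:25) {
    n_poly <- sample(4:12, 1)
    n_diag <- sample(2:n_poly, 1)
    params <- seq_gen_params(
      coi_length = 200, s28_length = 120,
      n_polymorphic = n_poly, n_diagnostic = n_diag,
      div_af = runif(1, 0.08, 0.2), div_ff2 = runif(1, 0.08, 0.2),
      within_rate = 0, n_refs_coi = 3, n_refs_28s = 4
    )
    refs <- generate_reference_panel(params)
    expect_equal(
      find_polymorphic_sites(refs$s28_refs_a, refs$s28_refs_f),
      refs$truth$polymorphic_columns
    )
    expect_equal(
      find_diagnostic_sites(refs$s28_refs_a, refs$s28_refs_f),
      refs$truth$diagnostic
    )
  }
})

test_that("simulated pairs respect the reproductive parameters", {
  p0 <- sim_params(
    sterility_prob = c(intra_andrei = 0, intra_fetida = 0, interspecific = 0,
                       backcross = 0, hybrid_hybrid = 0)
  )
  set.seed(1)
  sim <- simulate_pair("aAA", "aAA", p0, weeks = 4)
  expect_gt(nrow(sim$offspring), 0)
  expect_true(all(sim$offspring$code == "aAA"))
  expect_true(all(!sim$cocoons$sterile))

  # forced direction: full hybridization, no viable fFA
  p1 <- sim_params(
    h_a = 1, h_f = 1, fFA_F1_viability = 0,
    sterility_prob = c(intra_andrei = 0, intra_fetida = 0, interspecific = 0,
                       backcross = 0, hybrid_hybrid = 0)
  )
  set.seed(2)
  sim1 <- simulate_pair("aAA", "fFF", p1, weeks = 4)
  expect_gt(nrow(sim1$offspring), 0)
  expect_true(all(sim1$offspring$code == "aAF"))

  # hybrid-hybrid pairs: plenty of cocoons, no hatchlings
  p2 <- sim_params(hybrid_pair_fertility = 0)
  set.seed(3)
  sim2 <- simulate_pair("aAF", "aAF", p2, weeks = 6)
  expect_gt(nrow(sim2$cocoons), 0)
  expect_equal(nrow(sim2$offspring), 0L)
  expect_equal(sum(sim2$cocoons$n_hatchlings), 0L)
})

test_that("simulated offspring are always enumerable offspring codes", {
  p <- sim_params(h_a = 0.5, h_f = 0.5, fFA_F1_viability = 1,
                  hybrid_pair_fertility = 1)
  pairs <- list(c("aAA", "fFF"), c("aAF", "aAA"), c("aAF", "fFF"),
                c("aAF", "fFA"), c("fFF", "fFF"), c("f2FF", "fFF"))
  set.seed(11)
  for (gts in pairs) {
    sim <- simulate_pair(gts[1], gts[2], p, weeks = 5)
    if (!nrow(sim$offspring)) next
    allowed <- union(
      union(offspring_codes(gts[1], mode = "self"),
            offspring_codes(gts[2], mode = "self")),
      union(offspring_codes(gts[1], gts[2], mode = "cross"),
            offspring_codes(gts[2], gts[1], mode = "cross"))
    )
    expect_true(all(sim$offspring$code %in% allowed))
    # per-offspring: mito always matches the laying worm
    mo <- parse_genotype_code(sim$offspring$code)$mito
    expect_equal(mo, parse_genotype_code(gts)$mito[sim$offspring$mother])
  }
})

test_that("experiments are reproducible under a fixed seed", {
  p <- sim_params(seed = 99)
  s1 <- simulate_experiment(table1_design(), p)
  s2 <- simulate_experiment(table1_design(), p)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$offspring, s2$offspring)
  # all-zero rates give an all-zero table
  pz <- sim_params(
    cocoon_rate = c(intra_andrei = 0, intra_fetida = 0, interspecific = 0,
                    backcross = 0, hybrid_hybrid = 0),
    seed = 1
  )
  sz <- simulate_experiment(table1_design(), pz)
  expect_true(all(sz$summary$cocoons_per_worm_week == 0))
  expect_true(all(sz$summary$hatchlings_per_worm_week == 0))
  expect_equal(nrow(sz$offspring), 0L)
})

test_that("simulated pedigrees parse and pass the consistency check", {
  p <- sim_params(seed = 123, h_a = 0.5, h_f = 0.5)
  sim <- simulate_experiment(table1_design(), p)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree_tsv(sim$pedigree, tf)
  ped <- parse_family_table(tf)
  expect_equal(nrow(ped$families), sum(table1_design()$n_pairs))
  rep <- pedigree_consistency(ped)
  expect_equal(rep$n_unexplained, 0L)
})

test_that("hybridization-rate estimation is the binomial MLE with exact CI", {
  est <- estimate_hybridization_rate(c(rep("aAF", 2), rep("aAA", 8)), "a")
  expect_equal(est$h_hat, 0.2)
  expect_equal(est$n_offspring, 10L)
  ci <- stats::binom.test(2, 10)$conf.int
  expect_equal(c(est$ci_low, est$ci_high), as.numeric(ci))
  expect_true(est$ci_low <= est$h_hat && est$h_hat <= est$ci_high)
  # f line counts fFA vs fFF only
  estf <- estimate_hybridization_rate(c("fFA", "fFF", "fFF", "aAF"), "f")
  expect_equal(estf$n_offspring, 3L)
  expect_equal(estf$h_hat, 1 / 3)
  expect_error(estimate_hybridization_rate(character(0), "a"),
               class = "hw_input_error")
  # tidy/glance accessors
  td <- tidy(est)
  expect_equal(td$estimate, 0.2)
  expect_equal(glance(est)$n_offspring, 10L)
})

test_that("the estimator recovers the simulated hybridization rate", {
  set.seed(77)
  p <- sim_params(h_a = 0.3)
  kids <- simulate_offspring("aAA", "fFF", 4000, p)
  est <- estimate_hybridization_rate(kids$code, "a")
  # binomial SE at n = 4000 is ~0.0072; allow 4 SE
  expect_lt(abs(est$h_hat - 0.3), 0.03)
  expect_true(est$ci_low < 0.3 && 0.3 < est$ci_high)
  # the cross-fertilized fraction is what the rate measures
  expect_equal(mean(kids$mode == "cross"), mean(kids$code == "aAF"))
})

test_that("viability correction de-biases the f-line estimate", {
  set.seed(88)
  h <- 0.4; v <- 0.5
  n <- 5000
  hyb <- rbinom(1, n, h)
  kept <- rbinom(1, hyb, v)
  codes <- c(rep("fFA", kept), rep("fFF", n - hyb))
  est <- estimate_hybridization_rate(codes, "f", viability = v)
  expect_lt(abs(est$h_hat - h), 0.04)
})
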