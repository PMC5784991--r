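# Forward simulator standing in for the wet-lab breeding experiment:
# synthetic reference panels with planted diagnostic sites and clade
# divergences, and multi-week cocoon/hatchling simulation for worm pairs
# under calibrated reproductive rates with asymmetric hybridization.

#' Parameters for the synthetic sequence generator
#'
#' Defaults emulate the study system: a 28S alignment with 9 polymorphic
#' sites of which 7 are species-diagnostic (the two non-diagnostic columns
#' segregate within a species, one planted in each), and COI haplogroups with
#' between-clade uncorrected p-distances 0.150 (a vs f) and 0.114 (f vs f2).
#' With the default 412 bp 28S alignment the 7 fixed differences give a
#' between-species 28S p-distance of 7/412 = 0.017.
#'
#' @param coi_length,s28_length Aligned lengths in bp.
#' @param n_polymorphic,n_diagnostic Planted 28S site counts.
#' @param div_af,div_ff2 Planted COI between-clade p-distances.
#' @param within_rate Per-site within-clade COI mutation probability applied
#'   independently to each reference copy (0 gives exact planted distances).
#' @param n_refs_coi References per COI clade.
#' @param n_refs_28s References per species for 28S (at least 2, so the
#'   within-species polymorphic columns can segregate).
#' @param seed Optional RNG seed.
#' @return A list of class `seq_gen_params`.
#' @export
seq_gen_params <- function(coi_length = 600, s28_length = 412,
                           n_polymorphic = 9, n_diagnostic = 7,
                           div_af = 0.150, div_ff2 = 0.114,
                           within_rate = 0.001,
                           n_refs_coi = 6, n_refs_28s = 6,
                           seed = NULL) {
  p <- as.list(environment())
  if (p$n_diagnostic > p$n_polymorphic) {
    abort_input("n_diagnostic cannot exceed n_polymorphic")
  }
  if (p$n_polymorphic > p$s28_length) {
    abort_input("n_polymorphic cannot exceed the 28S alignment length")
  }
  if (p$div_af < 0 || p$div_af > 1 || p$div_ff2 < 0 || p$div_ff2 > 1) {
    abort_input("divergences must be in [0, 1]")
  }
  if (round(p$div_af * p$coi_length) + round(p$div_ff2 * p$coi_length) > p$coi_length) {
    abort_input("planted COI divergences exceed the alignment length")
  }
  if (p$n_refs_28s < 2 && p$n_polymorphic > p$n_diagnostic) {
    abort_input("n_refs_28s must be >= 2 to segregate within-species polymorphic sites")
  }
  structure(p, class = "seq_gen_params")
}

random_seq <- function(n) paste(sample(UNAMBIGUOUS, n, replace = TRUE), collapse = "")

mutate_at_sites <- function(chars, sites) {
  for (i in sites) {
    chars[i] <- sample(setdiff(UNAMBIGUOUS, chars[i]), 1)
  }
  chars
}

add_within_noise <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  mutate_at_sites(chars, hit)
}

#' Generate a synthetic reference panel with planted truth
#'
#' Builds COI reference sets for the three haplogroups (`a`, `f`, `f2`) at the
#' planted between-clade divergences (the `a` and `f2` difference sets are
#' disjoint, so all between-clade distances stay well above typical linkage
#' thresholds) and 28S reference sets for the two species with the planted
#' polymorphic/diagnostic column structure. The returned truth record allows
#' round-trip tests of the detectors against the generator.
#'
#' @param params A [seq_gen_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return A list of class `ref_panel_sim` with `coi_refs` (tibble `id`,
#'   `seq`, `clade`), `s28_refs_a`, `s28_refs_f` (tibbles `id`, `seq`), and
#'   `truth` (planted columns, alleles, consensus sequences and realized
#'   divergences).
#' @export
generate_reference_panel <- function(params = seq_gen_params(), seed = NULL) {
  stopifnot(inherits(params, "seq_gen_params"))
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)

  # COI: clade f consensus is the ancestor; a and f2 diverge at disjoint sites
  Lc <- params$coi_length
  f_cons <- strsplit(random_seq(Lc), "")[[1]]
  m_af <- round(params$div_af * Lc)
  m_ff2 <- round(params$div_ff2 * Lc)
  sites_a <- sample(Lc, m_af)
  sites_f2 <- sample(setdiff(seq_len(Lc), sites_a), m_ff2)
  a_cons <- mutate_at_sites(f_cons, sites_a)
  f2_cons <- mutate_at_sites(f_cons, sites_f2)
  consensus <- list(a = a_cons, f = f_cons, f2 = f2_cons)
  coi_refs <- imap(consensus, function(cons, clade) {
    tibble(
      id = sprintf("%s_ref%d", clade, seq_len(params$n_refs_coi)),
      seq = map_chr(seq_len(params$n_refs_coi), function(i) {
        paste(add_within_noise(cons, params$within_rate), collapse = "")
      }),
      clade = clade
    )
  }) |> list_rbind()

  # 28S: allele A is the ancestor; allele F differs at the diagnostic columns;
  # the remaining planted columns segregate within one species each,
  # alternating species (one per species at the 9-vs-7 defaults).
  Ls <- params$s28_length
  a_allele <- strsplit(random_seq(Ls), "")[[1]]
  poly_cols <- sort(sample(Ls, params$n_polymorphic))
  diag_cols <- sort(sample(poly_cols, params$n_diagnostic))
  within_cols <- setdiff(poly_cols, diag_cols)
  f_allele <- mutate_at_sites(a_allele, diag_cols)
  within_species <- rep(c("A", "F"), length.out = length(within_cols))
  make_refs <- function(allele, species, prefix) {
    n <- params$n_refs_28s
    seqs <- map_chr(seq_len(n), function(i) {
      chars <- allele
      for (k in seq_along(within_cols)) {
        # first half of this species' refs carry the alternative base
        if (within_species[k] == species && i <= floor(n / 2)) {
          chars[within_cols[k]] <- alt_base(allele[within_cols[k]], k)
        }
      }
      paste(chars, collapse = "")
    })
    tibble(id = sprintf("%s_28s_ref%d", prefix, seq_len(n)), seq = seqs)
  }
  # deterministic alternative base per within-species column
  alt_base <- function(base, k) setdiff(UNAMBIGUOUS, base)[(k - 1) %% 3 + 1]
  s28_refs_a <- make_refs(a_allele, "A", "a")
  s28_refs_f <- make_refs(f_allele, "F", "f")

  truth <- list(
    polymorphic_columns = poly_cols,
    diagnostic = tibble(
      column = diag_cols,
      allele_a = a_allele[diag_cols],
      allele_f = f_allele[diag_cols]
    ),
    within_species_columns = tibble(column = within_cols, species = within_species),
    div_af_planted = m_af / Lc,
    div_ff2_planted = m_ff2 / Lc,
    coi_consensus = map(consensus, paste, collapse = ""),
    s28_allele_a = paste(a_allele, collapse = ""),
    s28_allele_f = paste(f_allele, collapse = "")
  )
  structure(
    list(
      coi_refs = coi_refs,
      s28_refs_a = s28_refs_a,
      s28_refs_f = s28_refs_f,
      truth = truth,
      params = params
    ),
    class = "ref_panel_sim"
  )
}

#' Synthesize marker sequences for individuals of known genotype
#'
#' COI follows the maternal clade consensus; the 28S sequence of a nuclear
#' heterozygote is the Sanger-style consensus of its two allele sequences,
#' with the two-base IUPAC ambiguity code at every column where the alleles
#' differ.
#'
#' @param codes Character vector of genotype codes (one individual each).
#' @param refs A [generate_reference_panel()] object.
#' @param noise Per-site mutation probability applied to the COI sequence
#'   (default 0 for exact truth recovery).
#' @param id_prefix Prefix for generated individual ids.
#' @return A tibble with `id`, `genotype_true`, `coi`, `s28`.
#' @export
simulate_individual_sequences <- function(codes, refs, noise = 0,
                                          id_prefix = "ind") {
  stopifnot(inherits(refs, "ref_panel_sim"))
  g <- parse_genotype_code(codes)
  allele_seq <- list(
    A = strsplit(refs$truth$s28_allele_a, "")[[1]],
    F = strsplit(refs$truth$s28_allele_f, "")[[1]]
  )
  tibble(
    id = sprintf("%s%03d_%s", id_prefix, seq_along(codes), codes),
    genotype_true = codes,
    coi = map_chr(g$mito, function(cl) {
      chars <- strsplit(refs$truth$coi_consensus[[cl]], "")[[1]]
      paste(add_within_noise(chars, noise), collapse = "")
    }),
    s28 = map2(g$allele_maternal, g$allele_paternal, function(m, p) {
      sm <- allele_seq[[m]]
      sp <- allele_seq[[p]]
      out <- sm
      diff <- which(sm != sp)
      if (length(diff)) out[diff] <- iupac_pair_code(sm[diff], sp[diff])
      paste(out, collapse = "")
    }) |> unlist()
  )
}

#' Reproductive and mating parameters for the pair simulator
#'
#' Rate defaults transcribe the study's calibration for the three measured
#' arms (cocoons per worm per week 2.9 / 3.4 / 4.3 and sterile-cocoon
#' fractions 0.07 / 0.48 / 0.77 for Ea+Ea, Ef+Ef and Ea+Ef pairs); hatchling
#' means per viable cocoon are derived from the same table. Backcross and
#' hybrid-hybrid arms were not measured there: backcrosses reuse the Ef+Ef
#' rates and hybrid-hybrid pairs the interspecific cocoon rate, with
#' `hybrid_pair_fertility = 0` encoding that such pairs produced cocoons but
#' no hatchlings. `fFA_F1_viability = 0` encodes the observed asymmetry (no
#' fFA hybrids among F1 of interspecific pairs); both switches are
#' user-overridable since the observations are censored, not proven absolute.
#'
#' @param cocoon_rate,sterility_prob,hatchlings_per_viable_cocoon Named
#'   numeric vectors keyed by pair class (`intra_andrei`, `intra_fetida`,
#'   `interspecific`, `backcross`, `hybrid_hybrid`). Hatchling means are the
#'   means of the zero-truncated Poisson hatch-count distribution (>= 1).
#' @param h_a Probability that an `aA` ovum of a paired worm is
#'   cross-fertilized by partner sperm (hybridization rate); otherwise it is
#'   self-fertilized, facilitated by the partner.
#' @param h_f Same for `fF` (and `f2F`) ova.
#' @param fFA_F1_viability Retention probability of `fFA` offspring of
#'   interspecific pairs.
#' @param hybrid_pair_fertility Probability that a non-sterile cocoon of a
#'   hybrid-hybrid pair yields hatchlings.
#' @param weeks Observation weeks per pair.
#' @param exclude_incompatible Ovum policy passed to [ova_of()].
#' @param seed Optional RNG seed used by [simulate_experiment()].
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(cocoon_rate = c(intra_andrei = 2.9, intra_fetida = 3.4,
                                       interspecific = 4.3, backcross = 3.4,
                                       hybrid_hybrid = 4.3),
                       sterility_prob = c(intra_andrei = 0.07, intra_fetida = 0.48,
                                          interspecific = 0.77, backcross = 0.48,
                                          hybrid_hybrid = 0.77),
                       hatchlings_per_viable_cocoon = c(
                         intra_andrei = 2.08, intra_fetida = 1.58,
                         interspecific = 1.01, backcross = 1.58,
                         hybrid_hybrid = 1.01),
                       h_a = 0.3, h_f = 0.3,
                       fFA_F1_viability = 0,
                       hybrid_pair_fertility = 0,
                       weeks = 2,
                       exclude_incompatible = TRUE,
                       seed = NULL) {
  p <- as.list(environment())
  probs <- c(p$sterility_prob, p$h_a, p$h_f, p$fFA_F1_viability,
             p$hybrid_pair_fertility)
  if (any(probs < 0 | probs > 1)) abort_input("probabilities must be in [0, 1]")
  if (any(p$cocoon_rate < 0)) abort_input("cocoon rates must be >= 0")
  if (any(p$hatchlings_per_viable_cocoon < 1)) {
    abort_input("hatchlings_per_viable_cocoon means must be >= 1 (zero-truncated)")
  }
  classes <- c("intra_andrei", "intra_fetida", "interspecific", "backcross",
               "hybrid_hybrid")
  for (nm in c("cocoon_rate", "sterility_prob", "hatchlings_per_viable_cocoon")) {
    if (!all(classes %in% names(p[[nm]]))) {
      abort_input(sprintf("%s must be named with all pair classes", nm))
    }
  }
  structure(p, class = "sim_params")
}

# Pair class keys the rate tables: intraspecific pairs split by species.
pair_class <- function(gt1, gt2) {
  ct <- classify_cross_type(gt1, gt2)
  if (ct != "intraspecific") return(ct)
  if (parse_genotype_code(gt1)$allele_maternal == "A") "intra_andrei" else "intra_fetida"
}

# Zero-truncated Poisson with a given mean: solve for lambda, sample by
# inversion restricted to (P(0), 1].
ztp_lambda <- function(mean) {
  if (mean < 1) abort_input("zero-truncated Poisson mean must be >= 1")
  if (mean < 1 + 1e-9) return(1e-9)
  uniroot(function(l) l / (1 - exp(-l)) - mean,
          lower = 1e-9, upper = max(10, 2 * mean))$root
}

ztp_sample <- function(n, mean) {
  if (n == 0) return(integer(0))
  lambda <- ztp_lambda(mean)
  pmax(1L, qpois(runif(n, dpois(0, lambda), 1), lambda))
}

#' Draw offspring genotypes for one maternal line
#'
#' Vectorized genotype draw for `n` offspring hatched from the mother's ova
#' in a pair: each ovum is cross-fertilized by partner sperm with the
#' ovum-clade-specific hybridization rate (`h_a` or `h_f`), otherwise
#' self-fertilized (facilitated by the partner); ovum and sperm types are
#' drawn uniformly among the gamete types of the relevant parent. This is
#' the per-hatchling model inside [simulate_pair()], exposed for estimator
#' studies at controlled offspring counts.
#'
#' @param mother_gt,father_gt Parental genotype codes (mother = ovum parent).
#' @param n Number of offspring.
#' @param params A [sim_params()] object.
#' @return A tibble with `code` and `mode` (`"cross"` or
#'   `"facilitated_self"`).
#' @export
#' @examples
#' set.seed(1)
#' table(simulate_offspring("aAA", "fFF", 20, sim_params(h_a = 0.3))$code)
simulate_offspring <- function(mother_gt, father_gt, n, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  parse_genotype_code(c(mother_gt, father_gt))
  draw_offspring_codes(mother_gt, father_gt, n, params)
}

draw_offspring_codes <- function(mother_gt, father_gt, n, params) {
  if (n == 0) {
    return(tibble(code = character(), mode = character()))
  }
  ova <- ova_of(mother_gt, params$exclude_incompatible)
  if (!length(ova)) ova <- ova_of(mother_gt, exclude_incompatible = FALSE)
  clade <- parse_genotype_code(mother_gt)$mito
  h <- if (clade == "a") params$h_a else params$h_f
  cross <- runif(n) < h
  ovum <- ova[sample.int(length(ova), n, replace = TRUE)]
  sp_self <- sperm_of(mother_gt)
  sp_cross <- sperm_of(father_gt)
  sperm <- ifelse(
    cross,
    sp_cross[sample.int(length(sp_cross), n, replace = TRUE)],
    sp_self[sample.int(length(sp_self), n, replace = TRUE)]
  )
  tibble(
    code = combine_gametes(ovum, sperm),
    mode = ifelse(cross, "cross", "facilitated_self")
  )
}

#' Simulate cocoon production and offspring of one worm pair
#'
#' Each week each worm lays a Poisson number of cocoons (rate keyed by the
#' pair class); each cocoon is sterile with the class's sterility
#' probability; non-sterile cocoons of hybrid-hybrid pairs yield hatchlings
#' only with probability `hybrid_pair_fertility`; productive cocoons yield a
#' zero-truncated Poisson number of hatchlings. Each hatchling's genotype is
#' drawn through the gamete model, cross-fertilized with probability
#' `h_a`/`h_f` (by ovum clade) and otherwise self-fertilized (facilitated by
#' the partner). `fFA` offspring of interspecific pairs are retained with
#' probability `fFA_F1_viability`.
#'
#' @param gt1,gt2 Parental genotype codes.
#' @param params A [sim_params()] object.
#' @param weeks Number of weeks (default `params$weeks`).
#' @return A list with `cocoons` (tibble `worm`, `week`, `cocoon`, `sterile`,
#'   `n_hatchlings`) and `offspring` (tibble `mother`, `week`, `cocoon`,
#'   `code`, `mode`), plus the pair metadata `gt` and `class`.
#' @export
simulate_pair <- function(gt1, gt2, params = sim_params(), weeks = params$weeks) {
  stopifnot(inherits(params, "sim_params"))
  gts <- c(gt1, gt2)
  parse_genotype_code(gts)
  cls <- pair_class(gt1, gt2)
  ct <- classify_cross_type(gt1, gt2)
  rate <- params$cocoon_rate[[cls]]
  p_sterile <- params$sterility_prob[[cls]]
  hatch_mean <- params$hatchlings_per_viable_cocoon[[cls]]

  slots <- expand_grid(worm = 1:2, week = seq_len(weeks))
  slots$n_cocoons <- rpois(nrow(slots), rate)
  cocoons <- tibble(
    worm = rep(slots$worm, slots$n_cocoons),
    week = rep(slots$week, slots$n_cocoons)
  ) |>
    group_by(.data$worm, .data$week) |>
    mutate(cocoon = row_number()) |>
    ungroup()
  n_coc <- nrow(cocoons)
  if (n_coc == 0) {
    return(list(
      gt = gts, class = cls,
      cocoons = tibble(worm = integer(), week = integer(), cocoon = integer(),
                       sterile = logical(), n_hatchlings = integer()),
      offspring = tibble(mother = integer(), week = integer(), cocoon = integer(),
                         code = character(), mode = character())
    ))
  }
  cocoons$sterile <- rbinom(n_coc, 1, p_sterile) == 1
  productive <- !cocoons$sterile
  if (cls == "hybrid_hybrid") {
    productive <- productive & rbinom(n_coc, 1, params$hybrid_pair_fertility) == 1
  }
  cocoons$n_hatchlings <- 0L
  cocoons$n_hatchlings[productive] <- ztp_sample(sum(productive), hatch_mean)

  offspring <- map(1:2, function(w) {
    rows <- cocoons |> filter(.data$worm == w, .data$n_hatchlings > 0)
    if (!nrow(rows)) return(NULL)
    kids <- draw_offspring_codes(gts[w], gts[3 - w], sum(rows$n_hatchlings), params)
    bind_cols(
      tibble(
        mother = w,
        week = rep(rows$week, rows$n_hatchlings),
        cocoon = rep(rows$cocoon, rows$n_hatchlings)
      ),
      kids
    )
  }) |> list_rbind()
  if (is.null(offspring) || !nrow(offspring)) {
    offspring <- tibble(mother = integer(), week = integer(), cocoon = integer(),
                        code = character(), mode = character())
  } else if (ct == "interspecific" && params$fFA_F1_viability < 1) {
    drop <- offspring$code == "fFA" &
      runif(nrow(offspring)) >= params$fFA_F1_viability
    if (any(drop)) {
      # removed embryos vanish before observation; hatch counts shrink with them
      lost <- offspring[drop, ] |>
        count(.data$mother, .data$week, .data$cocoon, name = "lost")
      for (i in seq_len(nrow(lost))) {
        sel <- cocoons$worm == lost$mother[i] & cocoons$week == lost$week[i] &
          cocoons$cocoon == lost$cocoon[i]
        cocoons$n_hatchlings[sel] <- cocoons$n_hatchlings[sel] - lost$lost[i]
      }
      offspring <- offspring[!drop, ]
    }
  }
  list(gt = gts, class = cls, cocoons = cocoons, offspring = offspring)
}

#' The study's three-arm pairing design
#'
#' Four intraspecific pairs of each species and seven interspecific pairs,
#' observed for two weeks.
#'
#' @return A design tibble for [simulate_experiment()].
#' @export
table1_design <- function() {
  tibble(
    arm = c("Ea+Ea", "Ef+Ef", "Ea+Ef"),
    gt1 = c("aAA", "fFF", "aAA"),
    gt2 = c("aAA", "fFF", "fFF"),
    n_pairs = c(4L, 4L, 7L),
    weeks = c(2L, 2L, 2L)
  )
}

#' Simulate a multi-arm mating experiment
#'
#' Runs [simulate_pair()] for every pair of every design arm and summarises
#' each arm with the five statistics of the study's reproduction table:
#' pairs with cocoons, cocoons per worm per week, hatchlings per worm per
#' week, pairs without offspring, and the percentage of sterile cocoons
#' (cocoons failing the per-cocoon sterility draw). Also emits a pedigree of
#' all pairs and their offspring in the family-table dialect.
#'
#' @param design A tibble with columns `arm`, `gt1`, `gt2`, `n_pairs`,
#'   `weeks` (default [table1_design()]).
#' @param params A [sim_params()] object; `params$seed`, when set, seeds the
#'   run for exact reproducibility.
#' @return An object of class `mating_sim`: list with `summary` (one row per
#'   arm), `pedigree` (family-table tibble: `family_id`, `parent1`,
#'   `parent2`, `offspring`), `offspring` (all offspring records with arm and
#'   pair), `design`, `params`.
#' @export
simulate_experiment <- function(design = table1_design(), params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  needed <- c("arm", "gt1", "gt2", "n_pairs", "weeks")
  if (!all(needed %in% names(design))) {
    abort_input(sprintf("design must have columns %s", paste(needed, collapse = ", ")))
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  next_num <- function(k = 1L) {
    out <- counter$n + seq_len(k)
    counter$n <- counter$n + k
    out
  }

  arms <- pmap(design, function(arm, gt1, gt2, n_pairs, weeks) {
    pairs <- map(seq_len(n_pairs), function(j) {
      sim <- simulate_pair(gt1, gt2, params, weeks)
      par_ids <- paste0(c(gt1, gt2), next_num(2))
      kid_ids <- if (nrow(sim$offspring)) {
        paste0(sim$offspring$code, next_num(nrow(sim$offspring)))
      } else {
        character(0)
      }
      list(
        sim = sim, arm = arm, pair = j,
        pedigree_row = tibble(
          family_id = sprintf("%s_p%d", gsub("[^A-Za-z0-9]", "", arm), j),
          parent1 = par_ids[1], parent2 = par_ids[2],
          offspring = if (length(kid_ids)) {
            paste0("F1: ", paste(kid_ids, collapse = "; "))
          } else {
            "F1: ---"
          }
        )
      )
    })
    n_worms <- 2 * n_pairs
    coc <- map(pairs, ~ .x$sim$cocoons) |> list_rbind()
    off <- map(pairs, function(p) {
      if (nrow(p$sim$offspring)) {
        p$sim$offspring |> mutate(arm = p$arm, pair = p$pair, .before = 1)
      } else {
        NULL
      }
    }) |> list_rbind()
    per_pair_off <- map_int(pairs, ~ nrow(.x$sim$offspring))
    per_pair_coc <- map_int(pairs, ~ nrow(.x$sim$cocoons))
    list(
      summary = tibble(
        arm = arm, gt1 = gt1, gt2 = gt2, n_pairs = n_pairs, weeks = weeks,
        pairs_with_cocoons = sum(per_pair_coc > 0),
        cocoons_per_worm_week = nrow(coc) / (n_worms * weeks),
        hatchlings_per_worm_week = sum(coc$n_hatchlings) / (n_worms * weeks),
        pairs_without_offspring = sum(per_pair_off == 0),
        pct_sterile = if (nrow(coc)) 100 * mean(coc$sterile) else NA_real_
      ),
      pedigree = map(pairs, ~ .x$pedigree_row) |> list_rbind(),
      offspring = off
    )
  })

  structure(
    list(
      summary = map(arms, ~ .x$summary) |> list_rbind(),
      pedigree = map(arms, ~ .x$pedigree) |> list_rbind(),
      offspring = {
        off <- map(arms, ~ .x$offspring)
        off <- off[!map_lgl(off, is.null)]
        if (length(off)) list_rbind(off) else
          tibble(arm = character(), pair = integer(), mother = integer(),
                 week = integer(), cocoon = integer(), code = character(),
                 mode = character())
      },
      design = design,
      params = params
    ),
    class = "mating_sim"
  )
}

#' @export
print.mating_sim <- function(x, ...) {
  cat(sprintf(
    "<mating_sim> %d arm(s), %d offspring\n",
    nrow(x$summary), nrow(x$offspring)
  ))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.mating_sim <- function(x, ...) x$summary

#' @export
glance.mating_sim <- function(x, ...) {
  tibble(
    n_arms = nrow(x$summary),
    n_pairs = sum(x$summary$n_pairs),
    n_offspring = nrow(x$offspring),
    n_hybrids = sum(parse_genotype_code(x$offspring$code)$hybrid)
  )
}

#' Write a simulated pedigree in the family-table dialect
#'
#' @param pedigree The `pedigree` tibble of a [simulate_experiment()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  readr::write_tsv(pedigree, path, progress = FALSE)
  invisible(path)
}
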