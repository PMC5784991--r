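# Pipeline surface: whole-file genotyping, census and scenario reports,
# simulation runs with on-disk artifacts, and reference-set serialization.
# Machine outputs are CSV/TSV/JSON with deterministic column order; a thin
# command-line dispatcher over these functions ships in inst/scripts.

#' Serialize a reference set (28S panel + COI clade references) to JSON
#'
#' @param panel A [build_marker_panel()] object for the 28S locus.
#' @param clade_refs COI references as a tibble with `id`, `seq`, `clade`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_reference_json <- function(panel, clade_refs, path) {
  stopifnot(inherits(panel, "marker_panel"))
  clade_refs <- as_alignment(clade_refs)
  if (!"clade" %in% names(clade_refs)) {
    abort_input("clade_refs must have a 'clade' column")
  }
  obj <- list(
    s28 = list(
      locus = panel$locus,
      refs_a = setNames(as.list(panel$refs_a$seq), panel$refs_a$id),
      refs_f = setNames(as.list(panel$refs_f$seq), panel$refs_f$id),
      polymorphic_sites = panel$polymorphic_sites,
      diagnostic_sites = panel$diagnostic_sites
    ),
    coi = list(
      clades = map(
        split(clade_refs, clade_refs$clade),
        function(tbl) setNames(as.list(tbl$seq), tbl$id)
      )
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a reference set from JSON
#'
#' The 28S panel's polymorphic and diagnostic sites are re-discovered from
#' the stored references and checked against the serialized site lists.
#'
#' @param path JSON path written by [write_reference_json()].
#' @return A list with `panel` (a `marker_panel`) and `clade_refs` (tibble
#'   `id`, `seq`, `clade`).
#' @export
read_reference_json <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("reference JSON not found: %s", path))
  obj <- jsonlite::read_json(path)
  to_tbl <- function(x) tibble(id = names(x), seq = unname(unlist(x)))
  panel <- build_marker_panel(
    to_tbl(obj$s28$refs_a), to_tbl(obj$s28$refs_f),
    locus = obj$s28$locus %||% "28S"
  )
  stored <- unlist(obj$s28$polymorphic_sites)
  if (!is.null(stored) && !identical(as.integer(stored), panel$polymorphic_sites)) {
    abort_integrity("stored polymorphic sites disagree with the stored references")
  }
  clade_refs <- imap(obj$coi$clades, function(x, clade) {
    to_tbl(x) |> mutate(clade = clade)
  }) |> list_rbind()
  list(panel = panel, clade_refs = clade_refs)
}

#' Genotype individuals from paired COI and 28S FASTA files
#'
#' Joins the two loci on exact sequence id, calls the mitochondrial
#' haplogroup and the nuclear genotype for every individual, and composes
#' genotype codes where both calls are unambiguous. Individuals present in
#' only one locus are emitted with partial calls and a flag.
#'
#' @param coi_fasta,s28_fasta Paths to aligned FASTA files (each aligned to
#'   its reference coordinates).
#' @param reference A list with `panel` and `clade_refs` (as returned by
#'   [read_reference_json()]), or a path to a reference JSON.
#' @param out Optional CSV output path.
#' @param het_fraction,min_het Passed to [call_nuclear()].
#' @param margin_threshold Passed to [call_mito()].
#' @return A tibble with one row per individual: `id`, `mito_clade`,
#'   `mito_margin`, `nuclear_genotype`, `n_het`, `n_resolved`,
#'   `genotype_code`, `flags`.
#' @export
run_genotyping <- function(coi_fasta, s28_fasta, reference, out = NULL,
                           het_fraction = 0.8, min_het = 2,
                           margin_threshold = 0.02) {
  if (is.character(reference)) reference <- read_reference_json(reference)
  panel <- reference$panel
  clade_refs <- reference$clade_refs
  coi <- read_alignment(coi_fasta)
  s28 <- read_alignment(s28_fasta)
  for (locus in list(list(tbl = coi, name = "COI"), list(tbl = s28, name = "28S"))) {
    dup <- unique(locus$tbl$id[duplicated(locus$tbl$id)])
    if (length(dup)) {
      abort_input(sprintf(
        "duplicate ids within the %s locus: %s", locus$name,
        paste(dup, collapse = ", ")
      ))
    }
  }
  ids <- union(coi$id, s28$id)
  rows <- map(ids, function(i) {
    flags <- character(0)
    mito <- NULL
    nuc <- NULL
    if (i %in% coi$id) {
      mito <- call_mito(coi[coi$id == i, ], clade_refs, margin_threshold)
      if (mito$clade == "ambiguous") flags <- c(flags, "ambiguous_mito")
    } else {
      flags <- c(flags, "missing_coi")
    }
    if (i %in% s28$id) {
      nuc <- suppressWarnings(
        call_nuclear(s28[s28$id == i, ], panel, het_fraction, min_het)
      )
      if (nuc$genotype == "ambiguous") flags <- c(flags, "ambiguous_nuclear")
    } else {
      flags <- c(flags, "missing_28s")
    }
    code <- if (!is.null(mito) && !is.null(nuc) &&
                mito$clade != "ambiguous" && nuc$genotype != "ambiguous") {
      compose_genotype(mito, nuc)
    } else {
      NA_character_
    }
    tibble(
      id = i,
      mito_clade = if (is.null(mito)) NA_character_ else mito$clade,
      mito_margin = if (is.null(mito)) NA_real_ else mito$margin,
      nuclear_genotype = if (is.null(nuc)) NA_character_ else nuc$genotype,
      n_het = if (is.null(nuc)) NA_integer_ else as.integer(nuc$n_het),
      n_resolved = if (is.null(nuc)) NA_integer_ else as.integer(nuc$n_resolved),
      genotype_code = code,
      flags = paste(flags, collapse = ";")
    )
  }) |> list_rbind()
  if (!is.null(out)) readr::write_csv(rows, out, progress = FALSE)
  rows
}

#' Parse a family table and compute its census and consistency report
#'
#' @param pedigree_tsv Path to (or text of) a family-table TSV.
#' @param out_json Optional path for the census + consistency JSON.
#' @param out_csv Optional path for the flat individuals CSV (`canonical_id`,
#'   `genotype`, `generation`, `family_of_birth`, `origin_cross_type`).
#' @param exclude_incompatible Passed to [pedigree_consistency()].
#' @return A list with `pedigree`, `census` (a [hybrid_census()]), and
#'   `consistency` (a [pedigree_consistency()] report).
#' @export
run_census <- function(pedigree_tsv, out_json = NULL, out_csv = NULL,
                       exclude_incompatible = TRUE) {
  ped <- parse_family_table(pedigree_tsv)
  census <- hybrid_census(ped)
  consistency <- pedigree_consistency(ped, exclude_incompatible)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(
        n_aAF = census$n_aAF,
        n_fFA = census$n_fFA,
        totals = census$totals,
        origins = census$origins,
        by_generation = census$by_generation,
        asymmetry = as.list(census$asymmetry),
        consistency = as.list(glance(consistency)),
        flags = ped$flags
      ),
      out_json, auto_unbox = TRUE, pretty = TRUE
    )
  }
  if (!is.null(out_csv)) {
    fam <- ped$families |> select("family_id", "cross_type")
    ped$individuals |>
      mutate(aliases = map_chr(.data$aliases, paste, collapse = "/")) |>
      left_join(fam, by = c(family_of_birth = "family_id")) |>
      select("canonical_id", "genotype", generation = "generation_recorded",
             "family_of_birth", origin_cross_type = "cross_type") |>
      readr::write_csv(out_csv, progress = FALSE)
  }
  list(pedigree = ped, census = census, consistency = consistency)
}

#' Write per-offspring fertilization-scenario reports
#'
#' One JSON object per offspring (JSON lines) with the array of explaining
#' scenarios, plus an optional summary TSV.
#'
#' @param pedigree_tsv Path to (or text of) a family-table TSV.
#' @param out_jsonl Optional JSON-lines output path.
#' @param out_tsv Optional summary TSV path.
#' @param exclude_incompatible Passed to [pedigree_consistency()].
#' @return The consistency report, invisibly.
#' @export
run_scenarios <- function(pedigree_tsv, out_jsonl = NULL, out_tsv = NULL,
                          exclude_incompatible = TRUE) {
  ped <- parse_family_table(pedigree_tsv)
  rep <- pedigree_consistency(ped, exclude_incompatible)
  if (!is.null(out_jsonl)) {
    lines <- pmap(rep$report, function(family_id, offspring_id, offspring_code,
                                       n_scenarios, modes, scenarios) {
      jsonlite::toJSON(
        list(
          family_id = family_id, offspring_id = offspring_id,
          offspring_code = offspring_code, n_scenarios = n_scenarios,
          scenarios = scenarios
        ),
        auto_unbox = TRUE
      )
    })
    writeLines(unlist(lines), out_jsonl)
  }
  if (!is.null(out_tsv)) {
    readr::write_tsv(tidy(rep), out_tsv, progress = FALSE)
  }
  invisible(rep)
}

#' Read a simulation configuration from YAML
#'
#' The file may set `seed`, override any [sim_params()] field under `params`
#' (rate tables are merged entrywise over the defaults), any
#' [seq_gen_params()] field under `seq_gen`, and replace the pairing design
#' under `design` (a list of records with `arm`, `gt1`, `gt2`, `n_pairs`,
#' `weeks`). Unknown keys are an error.
#'
#' @param path YAML path.
#' @return A list with `params`, `seq_gen`, `design`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path) %||% list()
  known <- c("seed", "params", "seq_gen", "design")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort_input(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  defaults <- sim_params()
  par_over <- cfg$params %||% list()
  bad <- setdiff(names(par_over), names(defaults))
  if (length(bad)) {
    abort_input(sprintf("unknown params key(s): %s", paste(bad, collapse = ", ")))
  }
  args <- list()
  for (nm in setdiff(names(defaults), "seed")) {
    val <- defaults[[nm]]
    if (nm %in% names(par_over)) {
      ov <- par_over[[nm]]
      if (is.list(ov) || !is.null(names(ov))) {
        ov <- unlist(ov)
        val[names(ov)] <- ov
      } else {
        val <- ov
      }
    }
    args[[nm]] <- val
  }
  args$seed <- cfg$seed %||% defaults$seed
  params <- do.call(sim_params, args)
  sg_over <- cfg$seq_gen %||% list()
  seq_gen <- do.call(seq_gen_params, sg_over)
  design <- if (!is.null(cfg$design)) {
    map(cfg$design, as_tibble) |> list_rbind()
  } else {
    table1_design()
  }
  list(params = params, seq_gen = seq_gen, design = design)
}

#' Run a configured mating simulation and write its artifacts
#'
#' Writes `summary.csv` (the per-arm reproduction table), `pedigree.tsv`
#' (family-table dialect), reference FASTA files (`refs_coi.fasta`,
#' `refs_28s.fasta`), marker sequences of all simulated offspring
#' (`offspring_coi.fasta`, `offspring_28s.fasta`), and `manifest.json`
#' echoing the seed and parameters.
#'
#' @param config Path to a YAML configuration, or a list as returned by
#'   [read_sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [simulate_experiment()] result, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  if (is.character(config)) config <- read_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_input(sprintf("cannot create %s", out_dir))
  sim <- simulate_experiment(config$design, config$params)
  refs <- generate_reference_panel(config$seq_gen)
  readr::write_csv(sim$summary, file.path(out_dir, "summary.csv"), progress = FALSE)
  write_pedigree_tsv(sim$pedigree, file.path(out_dir, "pedigree.tsv"))
  write_fasta(refs$coi_refs[c("id", "seq")], file.path(out_dir, "refs_coi.fasta"))
  write_fasta(
    bind_rows(refs$s28_refs_a, refs$s28_refs_f),
    file.path(out_dir, "refs_28s.fasta")
  )
  if (nrow(sim$offspring)) {
    ind <- simulate_individual_sequences(sim$offspring$code, refs)
    write_fasta(tibble(id = ind$id, seq = ind$coi),
                file.path(out_dir, "offspring_coi.fasta"))
    write_fasta(tibble(id = ind$id, seq = ind$s28),
                file.path(out_dir, "offspring_28s.fasta"))
  }
  manifest <- list(
    seed = config$params$seed,
    params = config$params[setdiff(names(config$params), "seed")],
    seq_gen = unclass(config$seq_gen),
    design = config$design,
    files = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sim)
}
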