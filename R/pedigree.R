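# Family-table pedigrees. The input dialect mirrors the study's family table:
# one TSV row per family with columns family_id, parent1, parent2, offspring;
# the offspring cell is a ';'-separated list of individual labels, optionally
# prefixed with a recorded generation ("F2:"), with square-bracket groups
# recording box-mates (housing only — stripped and ignored for counting) and
# "---" marking a family with no offspring.

#' Parse a family table into a pedigree
#'
#' Individuals are deduplicated by their numeric alias sets: two mentions with
#' the same genotype and overlapping alias numbers are one worm (repeated
#' tail-tip sampling gives one worm several numbers, so `aAF96` and
#' `aAF96/103` are the same individual). Mentions sharing a number but
#' differing in genotype are kept distinct and flagged (e.g. `aAA96` vs
#' `aAF96/103`); with `strict = TRUE` such collisions raise an integrity
#' error instead. Parents not seen as earlier offspring are created as
#' founders.
#'
#' @param x Path to a TSV file, or a character scalar containing TSV text
#'   (detected by an embedded newline).
#' @param strict Treat alias-number collisions across genotypes as integrity
#'   errors (default `FALSE`: flag only).
#' @return An object of class `pedigree`: list with
#'   * `families`: tibble `family_id`, `parent1`, `parent2` (canonical ids),
#'     `cross_type`, `generation_recorded`, `offspring` (list-column of
#'     canonical ids), `n_offspring`;
#'   * `individuals`: tibble `canonical_id`, `genotype`, `aliases`
#'     (list-column), `family_of_birth`, `generation_recorded`;
#'   * `flags`: tibble of parse-level findings (`flag`, `detail`).
#' @export
parse_family_table <- function(x, strict = FALSE) {
  txt <- if (length(x) == 1 && !str_detect(x, "\n") ) {
    if (!file.exists(x)) abort_input(sprintf("family table not found: %s", x))
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  raw <- readr::read_tsv(I(txt), col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("family_id", "parent1", "parent2", "offspring")
  if (!all(needed %in% names(raw))) {
    abort_input(sprintf(
      "family table must have columns %s", paste(needed, collapse = ", ")
    ))
  }

  # individual registry built row by row
  reg <- list()  # canonical_id -> list(genotype, aliases, family_of_birth, generation_recorded)
  flags <- list()
  canon <- function(genotype, aliases) {
    paste0(genotype, if (length(aliases)) min(as.integer(aliases)) else "")
  }
  # find an existing individual matching genotype + overlapping aliases
  match_ind <- function(genotype, aliases) {
    for (cid in names(reg)) {
      r <- reg[[cid]]
      if (length(intersect(aliases, r$aliases)) > 0) {
        if (r$genotype == genotype) return(cid)
        msg <- sprintf(
          "alias number(s) %s shared by %s and genotype %s",
          paste(intersect(aliases, r$aliases), collapse = "/"), cid, genotype
        )
        if (strict) abort_integrity(paste("alias conflict:", msg))
        flags[[length(flags) + 1]] <<- tibble(flag = "alias_collision", detail = msg)
      }
    }
    NULL
  }
  register <- function(label, row_ctx, family_of_birth = NA_character_,
                       generation = NA_character_) {
    p <- withCallingHandlers(
      parse_individual_label(label),
      error = function(e) {
        abort_input(sprintf("row %s: %s", row_ctx, conditionMessage(e)))
      }
    )
    cid <- match_ind(p$genotype, p$aliases[[1]])
    if (is.null(cid)) {
      cid <- canon(p$genotype, p$aliases[[1]])
      if (cid %in% names(reg)) {
        abort_integrity(sprintf("row %s: duplicate canonical id %s", row_ctx, cid))
      }
      reg[[cid]] <<- list(
        genotype = p$genotype, aliases = p$aliases[[1]],
        family_of_birth = family_of_birth, generation_recorded = generation
      )
    } else {
      reg[[cid]]$aliases <<- union(reg[[cid]]$aliases, p$aliases[[1]])
      if (!is.na(family_of_birth)) {
        if (!is.na(reg[[cid]]$family_of_birth) &&
            reg[[cid]]$family_of_birth != family_of_birth) {
          abort_integrity(sprintf(
            "individual %s recorded as offspring of two families (%s, %s)",
            cid, reg[[cid]]$family_of_birth, family_of_birth
          ))
        }
        reg[[cid]]$family_of_birth <<- family_of_birth
        reg[[cid]]$generation_recorded <<- generation
      }
    }
    cid
  }

  row_list <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) row_list[[i]] <- local({
    row <- raw[i, ]
    ctx <- sprintf("%d (family %s)", i, row$family_id)
    p1 <- register(str_trim(row$parent1), ctx)
    p2 <- register(str_trim(row$parent2), ctx)
    cell <- row$offspring %||% ""
    cell <- if (is.na(cell)) "" else str_trim(cell)
    gen <- str_match(cell, "^(P|F[0-9]+)\\s*:")[, 2]
    cell <- str_remove(cell, "^(P|F[0-9]+)\\s*:")
    cell <- str_replace_all(cell, "[\\[\\]]", "")  # box-mate brackets: housing only
    labels <- str_trim(str_split(cell, ";")[[1]])
    labels <- labels[labels != "" & labels != "---"]
    kids <- vapply(labels, register, character(1), row_ctx = ctx,
                   family_of_birth = row$family_id, generation = gen)
    tibble(
      family_id = row$family_id,
      parent1 = p1, parent2 = p2,
      cross_type = classify_cross_type(reg[[p1]]$genotype, reg[[p2]]$genotype),
      generation_recorded = gen,
      offspring = list(unname(kids)),
      n_offspring = length(kids)
    )
  })
  fam_rows <- list_rbind(row_list)

  individuals <- imap(reg, function(r, cid) {
    tibble(
      canonical_id = cid, genotype = r$genotype,
      aliases = list(r$aliases),
      family_of_birth = r$family_of_birth,
      generation_recorded = r$generation_recorded
    )
  }) |> list_rbind()

  structure(
    list(
      families = fam_rows,
      individuals = individuals,
      flags = if (length(flags)) list_rbind(flags) else
        tibble(flag = character(), detail = character())
    ),
    class = "pedigree"
  )
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf(
    "<pedigree> %d families, %d individuals (%d hybrids); %d flag(s)\n",
    nrow(x$families), nrow(x$individuals),
    sum(parse_genotype_code(x$individuals$genotype)$hybrid),
    nrow(x$flags)
  ))
  invisible(x)
}

#' Compute structural generation labels
#'
#' Founders (individuals with no family of birth) are the parental generation
#' `P`; every other individual gets `F(1 + max(parent generations))`. An
#' override map can pin individuals to a generation before propagation —
#' the study relabelled one pure-species F1 couple as parental so that their
#' offspring count as F1, and the same convention applies to any family whose
#' parents are pure species.
#'
#' @param pedigree A [parse_family_table()] object.
#' @param overrides Named character vector mapping canonical ids to labels,
#'   e.g. `c(aAA62 = "P", fFF61 = "P")`.
#' @return The pedigree with an added `generation` column on `individuals`.
#' @export
generation_labels <- function(pedigree, overrides = NULL) {
  stopifnot(inherits(pedigree, "pedigree"))
  ind <- pedigree$individuals
  fam <- pedigree$families
  parents_of <- setNames(
    map(fam$family_id, ~ c(fam$parent1[fam$family_id == .x],
                           fam$parent2[fam$family_id == .x])),
    fam$family_id
  )
  dangling <- setdiff(c(fam$parent1, fam$parent2), ind$canonical_id)
  if (length(dangling)) {
    abort_integrity(sprintf(
      "dangling parent reference(s): %s", paste(dangling, collapse = ", ")
    ))
  }
  lab_to_num <- function(lab) ifelse(lab == "P", 0L, as.integer(str_remove(lab, "^F")))
  gen <- setNames(rep(NA_integer_, nrow(ind)), ind$canonical_id)
  gen[is.na(ind$family_of_birth)] <- 0L
  if (!is.null(overrides)) gen[names(overrides)] <- lab_to_num(unname(overrides))
  fixed <- !is.na(gen)
  for (iter in seq_len(nrow(ind) + 1)) {
    changed <- FALSE
    for (cid in ind$canonical_id[!fixed]) {
      fob <- ind$family_of_birth[ind$canonical_id == cid]
      if (is.na(fob)) next
      pg <- gen[parents_of[[fob]]]
      if (all(!is.na(pg))) {
        val <- max(pg) + 1L
        if (is.na(gen[cid]) || gen[cid] != val) {
          gen[cid] <- val
          changed <- TRUE
        }
      }
    }
    if (!changed) break
    if (iter > nrow(ind)) {
      abort_integrity("cycle detected in pedigree: generations do not stabilise")
    }
  }
  if (any(is.na(gen))) {
    abort_integrity(sprintf(
      "cycle detected in pedigree near: %s",
      paste(names(gen)[is.na(gen)], collapse = ", ")
    ))
  }
  pedigree$individuals$generation <- ifelse(gen == 0L, "P", paste0("F", gen))
  pedigree
}

#' Check every offspring against the gamete model
#'
#' Runs [explain_offspring()] for each offspring against its family's parents
#' and reports the explaining scenarios; offspring with no scenario are
#' flagged as inconsistent with the pedigree (an empty scenario list is a
#' finding, not an error).
#'
#' @param pedigree A [parse_family_table()] object.
#' @param exclude_incompatible Passed to [explain_offspring()].
#' @return An object of class `pedigree_report`: list with `report` (tibble
#'   `family_id`, `offspring_id`, `offspring_code`, `n_scenarios`, `modes`,
#'   `scenarios` list-column), `n_explained`, `n_unexplained`, `unexplained`
#'   (ids).
#' @export
pedigree_consistency <- function(pedigree, exclude_incompatible = TRUE) {
  stopifnot(inherits(pedigree, "pedigree"))
  ind <- pedigree$individuals
  gt_of <- setNames(ind$genotype, ind$canonical_id)
  dangling <- setdiff(c(pedigree$families$parent1, pedigree$families$parent2),
                      names(gt_of))
  if (length(dangling)) {
    abort_integrity(sprintf(
      "dangling parent reference(s): %s", paste(dangling, collapse = ", ")
    ))
  }
  rows <- pmap(pedigree$families, function(family_id, parent1, parent2,
                                           offspring, ...) {
    if (!length(offspring)) return(NULL)
    parents <- setNames(gt_of[c(parent1, parent2)], c(parent1, parent2))
    map(offspring, function(kid) {
      scen <- explain_offspring(parents, gt_of[[kid]], exclude_incompatible)
      tibble(
        family_id = family_id,
        offspring_id = kid,
        offspring_code = gt_of[[kid]],
        n_scenarios = nrow(scen),
        modes = paste(sort(unique(scen$mode)), collapse = "+"),
        scenarios = list(scen)
      )
    }) |> list_rbind()
  }) |> list_rbind()
  if (is.null(rows)) {
    rows <- tibble(
      family_id = character(), offspring_id = character(),
      offspring_code = character(), n_scenarios = integer(),
      modes = character(), scenarios = list()
    )
  }
  structure(
    list(
      report = rows,
      n_explained = sum(rows$n_scenarios > 0),
      n_unexplained = sum(rows$n_scenarios == 0),
      unexplained = rows$offspring_id[rows$n_scenarios == 0]
    ),
    class = "pedigree_report"
  )
}

#' @export
print.pedigree_report <- function(x, ...) {
  cat(sprintf(
    "<pedigree_report> %d offspring checked: %d explained, %d unexplained\n",
    nrow(x$report), x$n_explained, x$n_unexplained
  ))
  if (x$n_unexplained > 0) {
    cat("  unexplained:", paste(x$unexplained, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Census of hybrid offspring in a pedigree
#'
#' Counts distinct heterozygous individuals (as offspring of their family of
#' birth), grouped by genotype class and by the cross type of that family,
#' with per-generation counts (recorded generations) and an asymmetry
#' summary. Founders never count as offspring. Pure-genotype counts reflect
#' only the individuals present in the table, which typically records just
#' the close relatives of hybrids.
#'
#' @param pedigree A [parse_family_table()] object.
#' @return An object of class `hybrid_census`: list with `n_aAF`, `n_fFA`,
#'   `totals` (tibble `genotype`, `n` over all offspring genotypes),
#'   `origins` (tibble `genotype`, `cross_type`, `n` for hybrid classes),
#'   `by_generation` (tibble `genotype`, `generation`, `n`), and `asymmetry`
#'   (one-row tibble with the aAF/fFA contrast).
#' @export
hybrid_census <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  fam <- pedigree$families
  born <- pedigree$individuals |>
    filter(!is.na(.data$family_of_birth)) |>
    left_join(
      fam |> select("family_id", "cross_type"),
      by = c(family_of_birth = "family_id")
    ) |>
    mutate(hybrid = parse_genotype_code(.data$genotype)$hybrid)
  totals <- born |> count(genotype = .data$genotype, name = "n")
  hyb <- born |> filter(.data$hybrid)
  origins <- hyb |>
    count(genotype = .data$genotype, cross_type = .data$cross_type, name = "n") |>
    arrange(.data$genotype, .data$cross_type)
  by_generation <- hyb |>
    count(genotype = .data$genotype, generation = .data$generation_recorded,
          name = "n") |>
    arrange(.data$genotype, .data$generation)
  n_aAF <- sum(hyb$genotype == "aAF")
  n_fFA <- sum(hyb$genotype == "fFA")
  asymmetry <- tibble(
    n_aAF = n_aAF,
    n_fFA = n_fFA,
    n_fFA_from_interspecific_F1 = sum(
      hyb$genotype == "fFA" & hyb$cross_type == "interspecific" &
        hyb$generation_recorded %in% "F1"
    ),
    ratio_aAF_fFA = ifelse(n_fFA > 0, n_aAF / n_fFA, Inf)
  )
  structure(
    list(
      n_aAF = n_aAF, n_fFA = n_fFA,
      totals = totals, origins = origins,
      by_generation = by_generation, asymmetry = asymmetry
    ),
    class = "hybrid_census"
  )
}

#' @export
print.hybrid_census <- function(x, ...) {
  cat(sprintf("<hybrid_census> %d aAF, %d fFA hybrids\n", x$n_aAF, x$n_fFA))
  if (nrow(x$origins)) {
    o <- x$origins
    cat(paste0(
      "  ", o$genotype, " from ", o$cross_type, ": ", o$n, collapse = "\n"
    ), "\n")
  }
  invisible(x)
}

#' @export
tidy.hybrid_census <- function(x, ...) x$origins

#' @export
glance.hybrid_census <- function(x, ...) x$asymmetry

#' @export
tidy.pedigree_report <- function(x, ...) {
  x$report |> select(-"scenarios")
}

#' @export
glance.pedigree_report <- function(x, ...) {
  tibble(
    n_offspring = nrow(x$report),
    n_explained = x$n_explained,
    n_unexplained = x$n_unexplained
  )
}
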