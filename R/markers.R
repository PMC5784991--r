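# Species-diagnostic site discovery and nuclear genotype calling on 28S
# alignments. A diagnostic site is an alignment column fixed for one base in
# all E. andrei references and for a different base in all E. fetida
# references; heterozygous hybrids show the two-base IUPAC ambiguity code
# there in a Sanger consensus.

#' Find polymorphic columns in a pooled reference alignment
#'
#' A column is polymorphic when the pooled references (both species together)
#' carry at least two distinct unambiguous bases there; gaps, `N` and IUPAC
#' ambiguity codes are ignored for the comparison.
#'
#' @param refs_a,refs_f Reference alignments (tibbles with `id`/`seq`, or
#'   character vectors) for *E. andrei* (`A`) and *E. fetida* (`F`). All
#'   sequences must share one aligned length.
#' @return Sorted integer vector of 1-based column indices.
#' @export
#' @examples
#' find_polymorphic_sites("ACGT", "ACTT")
find_polymorphic_sites <- function(refs_a, refs_f) {
  refs_a <- as_alignment(refs_a)
  refs_f <- as_alignment(refs_f)
  pooled <- bind_rows(refs_a, refs_f)
  check_alignment(pooled)
  m <- seq_matrix(pooled)
  poly <- apply(m, 2, function(col) {
    bases <- unique(col[col %in% UNAMBIGUOUS])
    length(bases) >= 2
  })
  which(poly)
}

#' Find species-diagnostic sites
#'
#' The subset of polymorphic columns where every `A` reference carries one
#' unambiguous base and every `F` reference carries a different unambiguous
#' base; these fixed differences assign alleles to species.
#'
#' @inheritParams find_polymorphic_sites
#' @return A tibble with one row per diagnostic site: `column` (1-based),
#'   `allele_a`, `allele_f`.
#' @export
#' @examples
#' find_diagnostic_sites("ACGT", "ACTT")
find_diagnostic_sites <- function(refs_a, refs_f) {
  refs_a <- as_alignment(refs_a)
  refs_f <- as_alignment(refs_f)
  check_alignment(bind_rows(refs_a, refs_f))
  ma <- seq_matrix(refs_a)
  mf <- seq_matrix(refs_f)
  fixed_base <- function(col) {
    bases <- unique(col)
    if (length(bases) == 1 && bases %in% UNAMBIGUOUS) bases else NA_character_
  }
  fa <- apply(ma, 2, fixed_base)
  ff <- apply(mf, 2, fixed_base)
  keep <- !is.na(fa) & !is.na(ff) & fa != ff
  tibble(column = which(keep), allele_a = fa[keep], allele_f = ff[keep])
}

#' Build a marker panel from species reference alignments
#'
#' Bundles the references with their discovered polymorphic and diagnostic
#' sites. Diagnostic sites are always a subset of polymorphic sites.
#'
#' @inheritParams find_polymorphic_sites
#' @param locus Locus label, `"28S"` (default) or `"COI"`.
#' @return An object of class `marker_panel`: a list with `locus`, `refs_a`,
#'   `refs_f`, `polymorphic_sites` (integer columns) and `diagnostic_sites`
#'   (tibble as returned by [find_diagnostic_sites()]).
#' @export
build_marker_panel <- function(refs_a, refs_f, locus = "28S") {
  refs_a <- as_alignment(refs_a)
  refs_f <- as_alignment(refs_f)
  check_alignment(bind_rows(refs_a, refs_f))
  panel <- structure(
    list(
      locus = locus,
      refs_a = refs_a,
      refs_f = refs_f,
      polymorphic_sites = find_polymorphic_sites(refs_a, refs_f),
      diagnostic_sites = find_diagnostic_sites(refs_a, refs_f)
    ),
    class = "marker_panel"
  )
  stopifnot(all(panel$diagnostic_sites$column %in% panel$polymorphic_sites))
  panel
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf(
    "<marker_panel> locus %s: %d A refs, %d F refs, %d bp aligned\n",
    x$locus, nrow(x$refs_a), nrow(x$refs_f), nchar(x$refs_a$seq[1])
  ))
  cat(sprintf(
    "  %d polymorphic sites, %d diagnostic: columns %s\n",
    length(x$polymorphic_sites), nrow(x$diagnostic_sites),
    paste(x$diagnostic_sites$column, collapse = ", ")
  ))
  invisible(x)
}

#' Call a diploid nuclear genotype at the panel's diagnostic sites
#'
#' Each diagnostic column of the query is scored `homA` (base equals the `A`
#' allele), `homF` (equals the `F` allele), `het` (the exact two-base IUPAC
#' ambiguity code covering both alleles, as in a Sanger consensus of a
#' heterozygote), or `unresolved` (gap, `N`, or any other residue). The
#' genotype is `AA` when all resolved sites are `homA`, `FF` when all are
#' `homF`, `AF` when the fraction of `het` among resolved sites is at least
#' `het_fraction` and at least `min_het` sites are `het`; anything else —
#' including mixed homozygous patterns, which suggest chimerism or
#' contamination — is `ambiguous`.
#'
#' @param query A single aligned sequence (one-row tibble or character scalar)
#'   in the panel's coordinates.
#' @param panel A [build_marker_panel()] object.
#' @param het_fraction Minimum fraction of resolved diagnostic sites scored
#'   `het` to call `AF` (default 0.8, tolerating one miscalled peak among 7).
#' @param min_het Minimum number of `het` sites for an `AF` call (default 2).
#' @return An object of class `nuclear_call`: list with `genotype`
#'   (`"AA"`, `"FF"`, `"AF"`, or `"ambiguous"`), `per_site` (tibble `column`,
#'   `base`, `score`), `n_het`, `n_resolved`.
#' @export
call_nuclear <- function(query, panel, het_fraction = 0.8, min_het = 2) {
  stopifnot(inherits(panel, "marker_panel"))
  query <- as_alignment(query, check_aligned = FALSE)
  if (nrow(query) != 1) abort_input("call_nuclear() takes a single query sequence")
  if (nchar(query$seq) != nchar(panel$refs_a$seq[1])) {
    abort_input("query is not aligned to panel coordinates")
  }
  ds <- panel$diagnostic_sites
  bases <- strsplit(query$seq, "", fixed = TRUE)[[1]][ds$column]
  het_code <- iupac_pair_code(ds$allele_a, ds$allele_f)
  score <- case_when(
    bases == ds$allele_a ~ "homA",
    bases == ds$allele_f ~ "homF",
    bases == het_code ~ "het",
    .default = "unresolved"
  )
  n_res <- sum(score != "unresolved")
  n_het <- sum(score == "het")
  genotype <- if (n_res == 0) {
    warn(sprintf("no resolved diagnostic sites for %s; genotype is ambiguous", query$id))
    "ambiguous"
  } else if (all(score[score != "unresolved"] == "homA")) {
    "AA"
  } else if (all(score[score != "unresolved"] == "homF")) {
    "FF"
  } else if (n_het / n_res >= het_fraction && n_het >= min_het) {
    "AF"
  } else {
    "ambiguous"
  }
  structure(
    list(
      id = query$id,
      genotype = genotype,
      per_site = tibble(column = ds$column, base = bases, score = score),
      n_het = n_het,
      n_resolved = n_res
    ),
    class = "nuclear_call"
  )
}

#' @export
print.nuclear_call <- function(x, ...) {
  cat(sprintf(
    "<nuclear_call> %s: %s (%d het / %d resolved sites)\n",
    x$id, x$genotype, x$n_het, x$n_resolved
  ))
  invisible(x)
}

#' Compose a four-letter genotype code from mitochondrial and nuclear calls
#'
#' The label is the lowercase maternal clade followed by the two nuclear
#' alleles with the maternal allele first: a heterozygote with an `a`
#' mitochondrial lineage is written `aAF` (its maternal nuclear allele must
#' have come from an `aA` ovum), while one with an `f`/`f2` lineage is `fFA`.
#'
#' @param mito A [call_mito()] result, or a clade string (`"a"`, `"f"`, `"f2"`).
#' @param nuclear A [call_nuclear()] result, or a genotype string (`"AA"`,
#'   `"FF"`, `"AF"`).
#' @return The genotype code as a character scalar, e.g. `"aAF"`.
#' @export
#' @examples
#' compose_genotype("f", "AF")  # maternal-first orientation: "fFA"
compose_genotype <- function(mito, nuclear) {
  clade <- if (inherits(mito, "mito_call")) mito$clade else mito
  nuc <- if (inherits(nuclear, "nuclear_call")) nuclear$genotype else nuclear
  if (identical(clade, "ambiguous")) {
    abort_integrity("cannot compose genotype: mitochondrial call is ambiguous")
  }
  if (identical(nuc, "ambiguous")) {
    abort_integrity("cannot compose genotype: nuclear call is ambiguous")
  }
  if (!clade %in% MITO_CLADES) abort_input(sprintf("unknown mito clade '%s'", clade))
  if (!nuc %in% c("AA", "FF", "AF", "FA")) {
    abort_input(sprintf("unknown nuclear genotype '%s'", nuc))
  }
  ordered <- if (nuc %in% c("AF", "FA")) {
    if (clade == "a") "AF" else "FA"
  } else {
    nuc
  }
  paste0(clade, ordered)
}
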