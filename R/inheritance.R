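# Gamete-inheritance model for simultaneous hermaphrodites. Ova carry the
# mitochondrial clade (maternal, uniparental) plus one nuclear allele; sperm
# carry one nuclear allele and no mitochondria. Offspring genotype = ovum
# clade + ovum allele + sperm allele, maternal allele written first.
# A paired worm can self-fertilize ("facilitated" self-fertilization, enabled
# by copulation and sperm mixing) or cross-fertilize with its partner's sperm.

#' Enumerate the ovum types a genotype can produce
#'
#' A homozygote makes one ovum type; a heterozygote segregates both alleles.
#' Ova whose nuclear allele belongs to the other species than the
#' mitochondrial clade (`aF`, `fA`) are considered incompatible and are
#' excluded under the default policy; they can be retained by setting
#' `exclude_incompatible = FALSE`.
#'
#' @param gt A genotype code, e.g. `"aAF"`.
#' @param exclude_incompatible Drop mito/nuclear-mismatched ova (default `TRUE`).
#' @return Character vector of ovum types like `"aA"`, sorted.
#' @export
#' @examples
#' ova_of("aAF")                              # "aA" (the aF ovum is excluded)
#' ova_of("aAF", exclude_incompatible = FALSE)
ova_of <- function(gt, exclude_incompatible = TRUE) {
  g <- parse_genotype_code(gt)
  alleles <- unique(c(g$allele_maternal, g$allele_paternal))
  ova <- paste0(g$mito, alleles)
  if (exclude_incompatible) {
    ova <- ova[alleles == mito_species(g$mito)]
  }
  sort(unique(ova))
}

#' Enumerate the sperm types a genotype can produce
#'
#' @param gt A genotype code.
#' @return Character vector of nuclear alleles (`"A"`, `"F"`), sorted.
#' @export
#' @examples
#' sperm_of("aAF")
sperm_of <- function(gt) {
  g <- parse_genotype_code(gt)
  sort(unique(c(g$allele_maternal, g$allele_paternal)))
}

# ovum like "aA"/"f2F" + sperm allele -> offspring code
combine_gametes <- function(ovum, sperm_allele) {
  paste0(ovum, sperm_allele)
}

#' Possible offspring genotypes of a mating
#'
#' All combinations of the mother's ova with the sperm source's sperm, mapped
#' to maternal-first genotype codes. Under `mode = "self"` the sperm come from
#' the mother herself (`father_gt` must equal `mother_gt` if given); under
#' `mode = "cross"` they come from the partner.
#'
#' @param mother_gt Genotype code of the ovum parent.
#' @param father_gt Genotype code of the sperm parent.
#' @param mode `"self"` or `"cross"`.
#' @param exclude_incompatible Passed to [ova_of()].
#' @return Sorted character vector of offspring genotype codes.
#' @export
#' @examples
#' offspring_codes("aAA", "fFF", mode = "cross")  # "aAF"
#' offspring_codes("aAF", "aAF", mode = "self")   # "aAA" "aAF"
offspring_codes <- function(mother_gt, father_gt = mother_gt,
                            mode = c("self", "cross"),
                            exclude_incompatible = TRUE) {
  mode <- match.arg(mode)
  if (mode == "self" && !identical(mother_gt, father_gt)) {
    abort_input("mode = 'self' requires father_gt identical to mother_gt")
  }
  ova <- ova_of(mother_gt, exclude_incompatible)
  sperm <- sperm_of(father_gt)
  sort(unique(as.vector(outer(ova, sperm, combine_gametes))))
}

#' Classify the cross type of a parent pair
#'
#' Based on nuclear genotypes: two nuclear homozygotes of the same species are
#' an intraspecific pair, of different species interspecific; one heterozygote
#' with a homozygote is a backcross; two heterozygotes a hybrid-hybrid pair.
#'
#' @param gt1,gt2 Parent genotype codes.
#' @return One of `"intraspecific"`, `"interspecific"`, `"backcross"`,
#'   `"hybrid_hybrid"`.
#' @export
#' @examples
#' classify_cross_type("aAA", "fFF")
#' classify_cross_type("aAF", "fFF")
classify_cross_type <- function(gt1, gt2) {
  g <- parse_genotype_code(c(gt1, gt2))
  n_hybrid <- sum(g$hybrid)
  if (n_hybrid == 2) return("hybrid_hybrid")
  if (n_hybrid == 1) return("backcross")
  if (g$allele_maternal[1] == g$allele_maternal[2]) "intraspecific" else "interspecific"
}

#' Fertilization scenarios explaining an observed offspring
#'
#' Enumerates every way a pair could have produced the observed genotype: each
#' parent as the ovum source, fertilized either by its own sperm (labelled
#' `facilitated_self`, since selfing in a paired worm is taken to be enabled
#' by the partner) or by the partner's sperm (`cross`). An empty result means
#' the offspring is inconsistent with the pair — a finding, not an error.
#'
#' @param parents Character vector of the two parental genotype codes,
#'   optionally named with individual ids.
#' @param offspring_gt Observed offspring genotype code.
#' @param exclude_incompatible Passed to [ova_of()].
#' @return A tibble with one row per scenario: `mode`, `ovum_parent`,
#'   `sperm_parent`, `ovum`, `sperm`, `offspring_code`.
#' @export
#' @examples
#' explain_offspring(c("aAF", "aAA"), "aAF")
explain_offspring <- function(parents, offspring_gt, exclude_incompatible = TRUE) {
  if (length(parents) != 2) abort_input("explain_offspring() needs exactly two parents")
  parse_genotype_code(offspring_gt)  # validate
  ids <- names(parents) %||% parents
  scen <- expand_grid(ovum_idx = 1:2, sperm_idx = 1:2) |>
    pmap(function(ovum_idx, sperm_idx) {
      ova <- ova_of(parents[ovum_idx], exclude_incompatible)
      sperm <- sperm_of(parents[sperm_idx])
      expand_grid(ovum = ova, sperm = sperm) |>
        mutate(
          mode = if (ovum_idx == sperm_idx) "facilitated_self" else "cross",
          ovum_parent = ids[ovum_idx],
          sperm_parent = ids[sperm_idx],
          offspring_code = combine_gametes(.data$ovum, .data$sperm)
        )
    }) |>
    list_rbind() |>
    filter(.data$offspring_code == offspring_gt) |>
    select("mode", "ovum_parent", "sperm_parent", "ovum", "sperm", "offspring_code")
  scen
}
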