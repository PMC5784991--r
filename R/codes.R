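# Genotype codes: lowercase maternal mitochondrial clade (a, f, f2) followed by
# the two nuclear 28S alleles (A or F), maternal allele written first, e.g.
# "aAA" (E. andrei), "fFF" (E. fetida), "aAF"/"fFA" (hybrids), "f2FF".

MITO_CLADES <- c("a", "f", "f2")
NUC_ALLELES <- c("A", "F")

#' All syntactically valid genotype codes
#'
#' Every combination of a mitochondrial clade (`a`, `f`, `f2`) with an ordered
#' pair of nuclear alleles (`A`/`F`, maternal first): 12 codes in total. Only a
#' subset is observed in real crosses (e.g. `aFF` requires an incompatible
#' `aF` ovum), but the full space is needed when enumerating scenarios.
#'
#' @return A character vector of 12 genotype codes.
#' @export
#' @examples
#' all_genotype_codes()
all_genotype_codes <- function() {
  out <- expand_grid(mito = MITO_CLADES, m = NUC_ALLELES, p = NUC_ALLELES)
  paste0(out$mito, out$m, out$p)
}

#' Parse genotype codes into their marker components
#'
#' @param code Character vector of genotype codes such as `"aAF"` or `"f2FF"`.
#' @return A tibble with one row per code: `code`, `mito` (maternal clade),
#'   `allele_maternal`, `allele_paternal`, and logical `hybrid` (heterozygous
#'   nuclear genotype).
#' @export
#' @examples
#' parse_genotype_code(c("aAF", "fFA", "f2FF"))
parse_genotype_code <- function(code) {
  m <- str_match(code, "^(f2|a|f)([AF])([AF])$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort_input(sprintf(
      "invalid genotype code(s): %s",
      paste(unique(code[bad]), collapse = ", ")
    ))
  }
  tibble(
    code = code,
    mito = m[, 2],
    allele_maternal = m[, 3],
    allele_paternal = m[, 4],
    hybrid = m[, 3] != m[, 4]
  )
}

is_valid_genotype_code <- function(code) {
  str_detect(code, "^(f2|a|f)[AF][AF]$")
}

# Species of a nuclear allele: A belongs to E. andrei, F to E. fetida; the
# mito clades a vs f/f2 map the same way.
mito_species <- function(mito) ifelse(mito == "a", "A", "F")

#' Parse an individual label bearing numeric aliases
#'
#' Individuals in family tables carry a genotype code plus one or more numeric
#' codes separated by `/` (repeated tail-tip sampling of the same worm gives it
#' several numbers, e.g. `"fFA143/159/191"`).
#'
#' @param label Character vector of labels like `"aAF96/103"`.
#' @return A tibble with `label`, `genotype`, and a list-column `aliases` of
#'   character vectors of numeric codes (empty if the label has none).
#' @export
#' @examples
#' parse_individual_label("aAF96/103")
parse_individual_label <- function(label) {
  m <- str_match(label, "^(f2[AF][AF]|[af][AF][AF])([0-9]+(?:/[0-9]+)*)?$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort_input(sprintf(
      "unparseable individual label(s): %s",
      paste(unique(label[bad]), collapse = ", ")
    ))
  }
  aliases <- map(m[, 3], function(x) {
    if (is.na(x)) character(0) else str_split(x, "/")[[1]]
  })
  tibble(label = label, genotype = m[, 2], aliases = aliases)
}
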