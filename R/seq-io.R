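# Alignment I/O. Aligned sequences are carried as tibbles with columns `id`
# and `seq` (uppercase residues over A/C/G/T, IUPAC ambiguity codes, '-', 'N');
# FASTA reading/writing goes through Biostrings.

#' Read an aligned FASTA file into a tibble
#'
#' Records are uppercased on read. All sequences must share one aligned length.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @param check_aligned Require equal sequence lengths (default `TRUE`).
#' @return A tibble with columns `id` and `seq`.
#' @export
read_alignment <- function(path, check_aligned = TRUE) {
  if (!file.exists(path)) abort_input(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  tbl <- tibble(
    id = str_trim(str_remove(names(ss), "\\s.*$")),
    seq = unname(toupper(as.character(ss)))
  )
  if (nrow(tbl) == 0) abort_input(sprintf("no sequences in %s", path))
  if (check_aligned) check_alignment(tbl)
  tbl
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_alignment(seqs, check_aligned = FALSE)
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Accept a tibble/data.frame (id, seq), a named character vector, or a bare
# character vector; normalise to the tibble form with uppercase residues.
as_alignment <- function(x, check_aligned = TRUE) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    x <- tibble(id = ids, seq = unname(x))
  } else if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x))) {
      abort_input("sequence table must have columns 'id' and 'seq'")
    }
    x <- as_tibble(x)
  } else {
    abort_input("sequences must be a data frame with id/seq or a character vector")
  }
  if (nrow(x) == 0) abort_input("empty sequence set")
  x$seq <- toupper(x$seq)
  if (check_aligned) check_alignment(x)
  x
}

check_alignment <- function(tbl) {
  len <- unique(nchar(tbl$seq))
  if (length(len) > 1) {
    abort_input(sprintf(
      "sequences are not aligned: lengths %s", paste(len, collapse = ", ")
    ))
  }
  invisible(tbl)
}

# Alignment as a character matrix: rows = sequences (named by id), columns =
# 1-based alignment positions.
seq_matrix <- function(tbl) {
  tbl <- as_alignment(tbl)
  m <- matrix(
    unlist(strsplit(tbl$seq, "", fixed = TRUE)),
    nrow = nrow(tbl), byrow = TRUE,
    dimnames = list(tbl$id, NULL)
  )
  m
}

UNAMBIGUOUS <- c("A", "C", "G", "T")

# IUPAC two-base ambiguity code for an unordered base pair, e.g. {A,G} -> "R".
iupac_pair_code <- function(b1, b2) {
  unname(Biostrings::mergeIUPACLetters(paste0(b1, b2)))
}
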