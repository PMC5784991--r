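# Uncorrected p-distances and single-linkage threshold clustering of COI
# haplotypes, plus haplogroup (a / f / f2) assignment by nearest reference
# clade. Gaps, N and ambiguity codes are removed pairwise, never globally.

#' Uncorrected p-distance between two aligned sequences
#'
#' The proportion of mismatching columns among columns where both sequences
#' carry an unambiguous base (`A`/`C`/`G`/`T`); columns with a gap, `N`, or an
#' IUPAC ambiguity code in either sequence are excluded for that pair only
#' (pairwise deletion). Symmetric and bounded by \[0, 1\].
#'
#' @param s1,s2 Aligned sequences of equal length (character scalars or
#'   one-row `id`/`seq` tibbles).
#' @return The p-distance as a numeric scalar.
#' @export
#' @examples
#' p_distance("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTATTT")
p_distance <- function(s1, s2) {
  s1 <- as_alignment(s1, check_aligned = FALSE)
  s2 <- as_alignment(s2, check_aligned = FALSE)
  if (nrow(s1) != 1 || nrow(s2) != 1) abort_input("p_distance() compares two single sequences")
  if (nchar(s1$seq) != nchar(s2$seq)) abort_input("sequences have unequal aligned lengths")
  b1 <- strsplit(s1$seq, "", fixed = TRUE)[[1]]
  b2 <- strsplit(s2$seq, "", fixed = TRUE)[[1]]
  ok <- b1 %in% UNAMBIGUOUS & b2 %in% UNAMBIGUOUS
  if (!any(ok)) {
    abort_input("p-distance undefined: no columns with unambiguous bases in both sequences")
  }
  sum(b1[ok] != b2[ok]) / sum(ok)
}

#' All pairwise p-distances of an alignment
#'
#' @param seqs An aligned sequence set (tibble with `id`/`seq` or named
#'   character vector).
#' @return A symmetric numeric matrix with sequence ids as dimnames.
#' @export
p_distance_matrix <- function(seqs) {
  seqs <- as_alignment(seqs)
  m <- seq_matrix(seqs)
  ok <- matrix(m %in% UNAMBIGUOUS, nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  if (n == 1) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) {
        abort_input(sprintf(
          "p-distance undefined between '%s' and '%s': no comparable columns",
          seqs$id[i], seqs$id[j]
        ))
      }
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    }
  }
  d
}

#' Mean between-group p-distance
#'
#' Arithmetic mean of all between-group pairwise p-distances (every sequence
#' of `group_x` against every sequence of `group_y`).
#'
#' @param group_x,group_y Aligned sequence sets.
#' @return Numeric scalar.
#' @export
group_p_distance <- function(group_x, group_y) {
  gx <- as_alignment(group_x)
  gy <- as_alignment(group_y)
  d <- map_dbl(seq_len(nrow(gx)), function(i) {
    mean(map_dbl(seq_len(nrow(gy)), function(j) p_distance(gx[i, ], gy[j, ])))
  })
  mean(d)
}

#' Single-linkage clustering of sequences at a p-distance threshold
#'
#' Agglomerates sequences so that two share a cluster exactly when they are
#' connected by a chain of pairwise p-distances strictly below
#' `link_threshold` (single linkage cut at the threshold). Cluster numbering
#' is deterministic: clusters are ordered by their lexicographically smallest
#' member id.
#'
#' @param seqs An aligned sequence set.
#' @param link_threshold Linking distance (default 0.05, which separates the
#'   `a`, `f` and `f2` COI haplogroups whose divergences exceed 0.11).
#' @return A tibble with `id` and integer `cluster`.
#' @export
cluster_sequences <- function(seqs, link_threshold = 0.05) {
  seqs <- as_alignment(seqs)
  n <- nrow(seqs)
  d <- p_distance_matrix(seqs)
  # union-find over edges d < threshold
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (d[i, j] < link_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- map_int(seq_len(n), find)
  # number clusters by lexicographically smallest member id
  members <- split(seqs$id, roots)
  ord <- order(map_chr(members, ~ min(.x)))
  renum <- setNames(seq_along(ord), names(members)[ord])
  tibble(id = seqs$id, cluster = unname(renum[as.character(roots)]))
}

#' Assign a mitochondrial haplogroup by nearest reference clade
#'
#' The query is assigned to the clade with the smallest mean p-distance to its
#' reference sequences. The call is `ambiguous` when the margin between the
#' best and second-best clade means is below `margin_threshold`.
#'
#' @param query A single aligned COI sequence.
#' @param clade_refs Reference sequences with clade labels: a tibble with
#'   columns `id`, `seq`, `clade`, or a named list of sequence sets keyed by
#'   clade.
#' @param margin_threshold Minimum best-vs-second-best margin (default 0.02).
#' @return An object of class `mito_call`: list with `clade` (`"a"`, `"f"`,
#'   `"f2"` or `"ambiguous"`), `best_clade`, `mean_dist_to_best`, `margin`,
#'   and `per_clade` (tibble `clade`, `mean_dist`).
#' @export
call_mito <- function(query, clade_refs, margin_threshold = 0.02) {
  query <- as_alignment(query, check_aligned = FALSE)
  if (nrow(query) != 1) abort_input("call_mito() takes a single query sequence")
  if (is.data.frame(clade_refs)) {
    if (!"clade" %in% names(clade_refs)) {
      abort_input("clade_refs table must have a 'clade' column")
    }
    clade_refs <- split(clade_refs[c("id", "seq")], clade_refs$clade)
  }
  if (length(clade_refs) < 1) abort_input("clade_refs must contain at least one clade")
  per_clade <- tibble(
    clade = names(clade_refs),
    mean_dist = map_dbl(clade_refs, function(refs) {
      refs <- as_alignment(refs)
      mean(map_dbl(seq_len(nrow(refs)), ~ p_distance(query, refs[.x, ])))
    })
  ) |>
    arrange(.data$mean_dist, .data$clade)
  per_clade$mean_dist <- unname(per_clade$mean_dist)
  best <- per_clade$clade[1]
  margin <- if (nrow(per_clade) > 1) per_clade$mean_dist[2] - per_clade$mean_dist[1] else Inf
  clade <- if (margin < margin_threshold) "ambiguous" else best
  structure(
    list(
      id = query$id,
      clade = clade,
      best_clade = best,
      mean_dist_to_best = per_clade$mean_dist[1],
      margin = margin,
      per_clade = per_clade
    ),
    class = "mito_call"
  )
}

#' @export
print.mito_call <- function(x, ...) {
  cat(sprintf(
    "<mito_call> %s: %s (mean dist %.4f, margin %.4f)\n",
    x$id, x$clade, x$mean_dist_to_best, x$margin
  ))
  invisible(x)
}
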