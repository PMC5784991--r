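# Independent brute-force oracles used to cross-check the implementation.

# Count fertilization scenarios by direct string manipulation of the codes
# (no package gamete functions): every (ovum parent, ovum allele, sperm
# parent, sperm allele) tuple whose resulting code matches.
oracle_count_scenarios <- function(parents, offspring, exclude_incompatible = TRUE) {
  split_code <- function(code) {
    mito <- regmatches(code, regexpr("^(f2|a|f)", code))
    alleles <- strsplit(substring(code, nchar(mito) + 1), "")[[1]]
    list(mito = mito, alleles = alleles)
  }
  n <- 0L
  for (op in 1:2) {
    mo <- split_code(parents[op])
    for (oa in unique(mo$alleles)) {
      if (exclude_incompatible) {
        species <- if (mo$mito == "a") "A" else "F"
        if (oa != species) next
      }
      for (sp in 1:2) {
        fa <- split_code(parents[sp])
        for (sa in unique(fa$alleles)) {
          if (paste0(mo$mito, oa, sa) == offspring) n <- n + 1L
        }
      }
    }
  }
  n
}

# Connected components of the graph with edges p-distance < threshold,
# computed by Warshall transitive closure on the adjacency matrix.
oracle_components <- function(dist_matrix, threshold) {
  n <- nrow(dist_matrix)
  adj <- dist_matrix < threshold
  diag(adj) <- TRUE
  for (k in seq_len(n)) {
    adj <- adj | (outer(adj[, k], adj[k, ], "&"))
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[adj[i, ]] <- next_id
    }
  }
  comp
}

# Naive per-column scan for polymorphic / fixed-difference columns, written
# against character vectors only.
oracle_scan_columns <- function(seqs_a, seqs_f) {
  split1 <- function(s) strsplit(s, "", fixed = TRUE)
  ca <- do.call(rbind, split1(seqs_a))
  cf <- do.call(rbind, split1(seqs_f))
  all_m <- rbind(ca, cf)
  bases <- c("A", "C", "G", "T")
  poly <- which(apply(all_m, 2, function(col) {
    length(unique(col[col %in% bases])) >= 2
  }))
  diag <- which(vapply(seq_len(ncol(all_m)), function(j) {
    ua <- unique(ca[, j]); uf <- unique(cf[, j])
    length(ua) == 1 && length(uf) == 1 &&
      ua %in% bases && uf %in% bases && ua != uf
  }, logical(1)))
  list(polymorphic = poly, diagnostic = diag)
}

# Small helper: a random ungapped alignment as a tibble.
random_alignment <- function(n, len, ids = sprintf("s%02d", seq_len(n))) {
  tibble::tibble(
    id = ids,
    seq = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  )
}

table2_fixture <- function() {
  system.file("extdata", "table2_families.tsv", package = "hybridworms")
}
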