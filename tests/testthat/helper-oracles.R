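# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package
# internals: plain dynamic programming and direct counting.

# Smith-Waterman local alignment score with affine gaps (Gotoh), floored at
# 0 (the empty alignment is allowed). A gap of length k costs open + k * ext.
oracle_local_score <- function(a, b, submat = sweetR::blosum62_matrix(),
                               open = 11, ext = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in x (moving along y)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in y
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[x[i - 1], y[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Global (Needleman-Wunsch) affine-gap score, terminal gaps charged.
oracle_global_score <- function(a, b, submat = sweetR::blosum62_matrix(),
                                open = 10, ext = 0.5) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(-Inf, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) E[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) F[i, 1] <- -(open + (i - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) +
        submat[x[i - 1], y[j - 1]]
      E[i, j] <- max(M[i, j - 1] - open - ext, E[i, j - 1] - ext,
                     F[i, j - 1] - open - ext)
      F[i, j] <- max(M[i - 1, j] - open - ext, F[i - 1, j] - ext,
                     E[i - 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

# Mutual information (nats) by direct contingency-table counting.
oracle_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  unname(s)
}

# Connected components by union-find over an edge list of accession pairs.
oracle_components <- function(nodes, edges_a, edges_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(v) {
    while (parent[[v]] != v) v <- parent[[v]]
    v
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}

# Per-position window-mean hydropathy candidates (full windows only).
oracle_tmh_candidates <- function(sequence, window, threshold) {
  kd <- sweetR::KD_HYDROPATHY[strsplit(sequence, "")[[1]]]
  kd[is.na(kd)] <- 0
  n <- length(kd); half <- (window - 1) / 2
  cand <- rep(FALSE, n)
  for (p in (half + 1):(n - half)) {
    cand[p] <- mean(kd[(p - half):(p + half)]) >= threshold
  }
  cand
}

random_aa_seq <- function(n) {
  paste(sample(sweetR::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Canonical bipartition keys of an unrooted tree (smaller side, sorted;
# ties by first label), computed through ape's clade enumeration.
tree_bipartitions_keyset <- function(tree) {
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(p) {
    s <- sort(tree$tip.label[p])
    o <- sort(setdiff(tree$tip.label, s))
    if (length(o) &&
        (length(o) < length(s) ||
         (length(o) == length(s) && o[1] < s[1]))) s <- o
    paste(s, collapse = "|")
  }, character(1))
  unique(keys[vapply(keys, nchar, integer(1)) > 0])
}
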