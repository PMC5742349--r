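# Distance-based neighbour-joining trees with column-resampling bootstrap
# support. Trees are ape "phylo" objects; Newick I/O goes through ape.

#' Pairwise distances from an MSA
#'
#' p-distance (1 - fraction identical over columns where both rows are
#' ungapped) or its Poisson correction \code{-ln(identity)}. Saturated or
#' undefined pairs are capped at \code{max_distance}.
#'
#' @param msa an \code{msa} object.
#' @param model \code{"p"} or \code{"poisson"}.
#' @param max_distance cap for saturated pairs (default 10).
#' @return Symmetric distance matrix with accession dimnames.
#' @export
msa_distances <- function(msa, model = c("p", "poisson"), max_distance = 10) {
  model <- match.arg(model)
  mat <- msa_matrix(msa)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(msa$accessions, msa$accessions))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(both)) { D[i, j] <- D[j, i] <- max_distance; next }
    id <- mean(mat[i, both] == mat[j, both])
    d <- if (model == "p") 1 - id else if (id <= exp(-max_distance))
      max_distance else -log(id)
    D[i, j] <- D[j, i] <- min(d, max_distance)
  }
  D
}

#' Neighbour-joining tree
#'
#' Canonical NJ on a symmetric distance matrix with the Q criterion. Ties in
#' Q are broken by the lexicographically smallest pair of clade labels (the
#' smallest leaf accession inside each clade). Negative branch lengths are
#' clamped to 0 with the deficit shifted to the sibling edge (itself floored
#' at 0).
#'
#' @param d symmetric distance matrix with accession dimnames (>= 3 taxa,
#'   finite entries).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
nj_tree <- function(d) {
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("non-finite distances")
  labels <- rownames(d)
  stopifnot(!is.null(labels), identical(labels, colnames(d)))

  n_internal <- n - 2L
  edge <- matrix(0L, 0L, 2L)
  edge_len <- numeric(0)
  next_internal <- n + 1L
  # active node ids (leaves 1..n, internal n+1..) and their clade label
  act_id <- seq_len(n)
  act_lab <- labels
  D <- d

  add_edge <- function(parent, child, len) {
    edge <<- rbind(edge, c(parent, child))
    edge_len <<- c(edge_len, max(len, 0))
  }

  while (length(act_id) > 3L) {
    N <- length(act_id)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(act_lab[ij[1L]], act_lab[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- max(lj + li, 0); li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    u <- next_internal
    next_internal <- next_internal + 1L
    add_edge(u, act_id[i], li)
    add_edge(u, act_id[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    new_lab <- min(act_lab[c(i, j)])
    act_id <- c(act_id[keep], u)
    act_lab <- c(act_lab[keep], new_lab)
    rownames(D) <- colnames(D) <- NULL
  }
  # final star join of the last three nodes (three-point formulas)
  u <- next_internal
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(u, act_id[1L], l1)
  add_edge(u, act_id[2L], l2)
  add_edge(u, act_id[3L], l3)

  # renumber internal nodes: ape wants the "root" (basal trifurcation) first
  ids <- c(seq_len(n), u, setdiff(sort(unique(edge[edge > n])), u))
  remap <- integer(max(ids))
  remap[seq_len(n)] <- seq_len(n)
  internals <- c(u, setdiff(sort(unique(edge[edge > n]), decreasing = TRUE), u))
  remap[internals] <- n + seq_along(internals)
  tree <- structure(list(
    edge = matrix(remap[edge], ncol = 2L),
    edge.length = edge_len,
    tip.label = labels,
    Nnode = n_internal), class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

# Canonical keys for the non-trivial bipartitions (internal edges) of an
# unrooted tree: the sorted accession set on the side containing the
# alphabetically first tip.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  anchor <- min(tree$tip.label)
  keys <- vapply(parts, function(p) {
    s <- tree$tip.label[p]
    if (!(anchor %in% s)) s <- setdiff(tree$tip.label, s)
    if (length(s) == n || length(s) == n - 1L) return(NA_character_)
    paste(sort(s), collapse = "|")
  }, character(1))
  stats::setNames(keys, seq_along(parts) + n)  # node id -> key
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement \code{n_replicates} times (seeded),
#' recomputes distances and NJ per replicate, and reports for each internal
#' bipartition of the point tree the percentage of replicate trees containing
#' it. Supports are attached as internal node labels, so the Newick output
#' carries them.
#'
#' @param msa an \code{msa} object.
#' @param n_replicates number of bootstrap replicates (at least 10).
#' @param seed integer seed.
#' @param model distance model passed to \code{\link{msa_distances}}.
#' @return The point-estimate \code{phylo} tree with \code{node.label}
#'   holding supports (0-100; empty for the basal node) and a
#'   \code{data.frame} attribute \code{"supports"} with the bipartition
#'   keys and supports.
#' @export
bootstrap_nj <- function(msa, n_replicates = 100L, seed = 1L, model = "p") {
  if (n_replicates < 10L) stop("n_replicates must be at least 10")
  point <- nj_tree(msa_distances(msa, model))
  keys <- tree_bipartitions(point)
  counts <- stats::setNames(numeric(length(keys)), keys)
  mat <- msa_matrix(msa)
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    rep_msa <- msa_object(msa$accessions,
                          apply(mat[, cols, drop = FALSE], 1L, paste,
                                collapse = ""))
    rep_tree <- nj_tree(msa_distances(rep_msa, model))
    rep_keys <- tree_bipartitions(rep_tree)
    hit <- names(counts) %in% rep_keys[!is.na(rep_keys)]
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_replicates
  node_label <- character(point$Nnode)
  for (i in seq_along(keys)) {
    node_label[i] <- if (is.na(keys[i])) "" else
      format(round(support[i], 1), trim = TRUE)
  }
  point$node.label <- node_label
  attr(point, "supports") <- data.frame(
    bipartition = unname(keys), support = unname(support),
    stringsAsFactors = FALSE)[!is.na(keys), , drop = FALSE]
  point
}

#' Support of the bipartition separating two groups
#'
#' Looks up the bootstrap support of the internal edge that splits the given
#' accession set from the rest of the tree (NA when the point tree does not
#' contain that bipartition).
#'
#' @param tree result of \code{\link{bootstrap_nj}}.
#' @param group character vector of accessions on one side.
#' @return Support percentage in [0, 100], or NA.
#' @export
split_support <- function(tree, group) {
  sup <- attr(tree, "supports")
  anchor <- min(tree$tip.label)
  s <- sort(group)
  if (!(anchor %in% s)) s <- sort(setdiff(tree$tip.label, group))
  key <- paste(s, collapse = "|")
  hit <- match(key, sup$bipartition)
  if (is.na(hit)) NA_real_ else sup$support[hit]
}
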