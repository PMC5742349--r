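# Column-pair mutual information with a shuffle-null z-score, significance
# thresholding, the three-class edge colouring, cumulative MI per position,
# and structure-based proximity MI.

# Pairwise-complete residue vectors for two MSA columns (rows gapped in
# either column are dropped).
complete_pair <- function(mat, a, b) {
  ok <- mat[, a] != "-" & mat[, b] != "-"
  list(x = mat[ok, a], y = mat[ok, b], w = ok)
}

mi_from_counts <- function(x, y, w = NULL, pseudocount = 0) {
  lev_x <- sort(unique(x)); lev_y <- sort(unique(y))
  if (is.null(w)) w <- rep(1, length(x))
  joint <- matrix(0, length(lev_x), length(lev_y),
                  dimnames = list(lev_x, lev_y))
  for (i in seq_along(x)) joint[x[i], y[i]] <- joint[x[i], y[i]] + w[i]
  joint <- joint + pseudocount
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Mutual information between MSA column pairs
#'
#' For each requested pair of columns, computes
#' \code{MI = sum p(x, y) ln[p(x, y) / (p(x) p(y))]} (nats) over weighted,
#' optionally pseudocounted joint frequencies of the pairwise-complete rows
#' (rows gapped in either column are excluded). Pairs where either column
#' has fewer than \code{min_effective_rows} ungapped entries are skipped.
#'
#' @param msa an \code{msa} object (at least 2 columns).
#' @param columns columns to consider (default: all); MI is computed for all
#'   unordered pairs of these.
#' @param pseudocount added to every joint count cell (default 0).
#' @param weighting sequence weighting as in
#'   \code{\link{conservation_profile}}.
#' @param min_effective_rows minimum ungapped rows per column (default 5).
#' @return \code{data.frame}: \code{col_a}, \code{col_b}
#'   (\code{col_a < col_b}), \code{mi_nats}, \code{mi_bits}.
#' @export
column_mi <- function(msa, columns = NULL, pseudocount = 0,
                      weighting = "none", min_effective_rows = 5L) {
  mat <- msa_matrix(msa)
  if (ncol(mat) < 2L) stop("MSA must have at least 2 columns")
  if (is.null(columns)) columns <- seq_len(ncol(mat))
  columns <- sort(unique(as.integer(columns)))
  w <- as.numeric(msa_weights(mat, weighting))
  nongap <- colSums(mat[, columns, drop = FALSE] != "-")
  usable <- columns[nongap >= min_effective_rows]
  skipped <- setdiff(columns, usable)
  if (length(skipped)) {
    message("skipping ", length(skipped),
            " column(s) with fewer than ", min_effective_rows,
            " ungapped rows")
  }
  if (length(usable) < 2L) {
    return(data.frame(col_a = integer(0), col_b = integer(0),
                      mi_nats = numeric(0), mi_bits = numeric(0)))
  }
  pairs <- utils::combn(usable, 2L)
  mi <- vapply(seq_len(ncol(pairs)), function(k) {
    ok <- mat[, pairs[1L, k]] != "-" & mat[, pairs[2L, k]] != "-"
    if (sum(ok) < min_effective_rows) return(NA_real_)
    mi_from_counts(mat[ok, pairs[1L, k]], mat[ok, pairs[2L, k]], w[ok],
                   pseudocount)
  }, numeric(1))
  out <- data.frame(col_a = pairs[1L, ], col_b = pairs[2L, ],
                    mi_nats = mi, mi_bits = mi / log(2))
  out[!is.na(out$mi_nats), , drop = FALSE]
}

#' Shuffle-null z-scores for MI pairs
#'
#' For each pair, a null distribution is built from \code{n_shuffles}
#' independent row permutations of the second column (the permutation
#' breaks the pairing while preserving both marginals);
#' \code{mi_z = (mi - null_mean) / null_sd}, with the null standard
#' deviation floored at 1e-12. Seeded, so identical seeds give identical
#' z-scores.
#'
#' @param pairs output of \code{\link{column_mi}}.
#' @param msa the \code{msa} the pairs came from.
#' @param n_shuffles number of permutations (at least 20; default 100).
#' @param seed integer seed.
#' @param pseudocount,weighting as in \code{\link{column_mi}}.
#' @return \code{pairs} with columns \code{mi_z}, \code{null_mean},
#'   \code{null_sd} appended.
#' @export
mi_zscores <- function(pairs, msa, n_shuffles = 100L, seed = 1L,
                       pseudocount = 0, weighting = "none") {
  if (n_shuffles < 20L) stop("n_shuffles must be at least 20")
  mat <- msa_matrix(msa)
  w <- as.numeric(msa_weights(mat, weighting))
  set.seed(seed)
  null_mean <- numeric(nrow(pairs)); null_sd <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ok <- mat[, pairs$col_a[k]] != "-" & mat[, pairs$col_b[k]] != "-"
    x <- mat[ok, pairs$col_a[k]]; y <- mat[ok, pairs$col_b[k]]
    wk <- w[ok]
    null <- vapply(seq_len(n_shuffles), function(s) {
      mi_from_counts(x, y[sample.int(length(y))], wk, pseudocount)
    }, numeric(1))
    null_mean[k] <- mean(null)
    null_sd[k] <- max(stats::sd(null), 1e-12)
  }
  pairs$null_mean <- null_mean
  pairs$null_sd <- null_sd
  pairs$mi_z <- (pairs$mi_nats - null_mean) / null_sd
  pairs
}

#' Three-class colouring of significant MI edges
#'
#' Ranks significant pairs by raw MI (descending; ties broken by
#' \code{(col_a, col_b)} order): the top 5\% are \code{red} (count by
#' ceiling), scores down to the 70th percentile are \code{black} (count by
#' floor, 25\% of edges), and the remaining ~70\% are \code{gray}.
#'
#' @param significant \code{data.frame} of significant pairs with
#'   \code{col_a}, \code{col_b}, \code{mi_nats}.
#' @return The input with an \code{edge_class} column
#'   (\code{red}/\code{black}/\code{gray}).
#' @export
classify_mi_edges <- function(significant) {
  n <- nrow(significant)
  if (n < 1L) stop("need at least one significant pair")
  ord <- order(-significant$mi_nats, significant$col_a, significant$col_b)
  n_red <- ceiling(0.05 * n)
  n_black <- min(floor(0.25 * n), n - n_red)
  cls <- rep("gray", n)
  cls[ord[seq_len(n_red)]] <- "red"
  if (n_black > 0L) cls[ord[n_red + seq_len(n_black)]] <- "black"
  significant$edge_class <- cls
  significant
}

#' Cumulative MI per column
#'
#' \code{cMI(c)} is the sum of raw MI over the significant pairs containing
#' column c; columns in no significant pair score 0.
#'
#' @param significant significant pair \code{data.frame}.
#' @param n_columns total number of MSA columns.
#' @return Numeric vector of length \code{n_columns}.
#' @export
cumulative_mi <- function(significant, n_columns) {
  cmi <- numeric(n_columns)
  for (k in seq_len(nrow(significant))) {
    a <- significant$col_a[k]; b <- significant$col_b[k]
    cmi[a] <- cmi[a] + significant$mi_nats[k]
    cmi[b] <- cmi[b] + significant$mi_nats[k]
  }
  cmi
}

#' Significant MI network
#'
#' Convenience wrapper: MI for all column pairs, shuffle z-scores,
#' significance at \code{mi_threshold}, edge classes and cumulative MI.
#'
#' @inheritParams column_mi
#' @inheritParams mi_zscores
#' @param mi_threshold z-score significance threshold (default 6.5).
#' @return List of class \code{mi_network}: \code{pairs} (all scored pairs),
#'   \code{significant} (classed edges), \code{cmi} (per column).
#' @export
mi_network <- function(msa, columns = NULL, mi_threshold = 6.5,
                       n_shuffles = 100L, seed = 1L, pseudocount = 0,
                       weighting = "none") {
  pairs <- column_mi(msa, columns, pseudocount, weighting)
  pairs <- mi_zscores(pairs, msa, n_shuffles, seed, pseudocount, weighting)
  sig <- pairs[pairs$mi_z > mi_threshold, , drop = FALSE]
  rownames(sig) <- NULL
  if (nrow(sig) > 0L) sig <- classify_mi_edges(sig)
  structure(list(pairs = pairs, significant = sig,
                 cmi = cumulative_mi(sig, msa$n_columns),
                 mi_threshold = mi_threshold),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat("MI network:", nrow(x$pairs), "scored pairs,", nrow(x$significant),
      sprintf("significant (z > %g)\n", x$mi_threshold))
  if (nrow(x$significant) > 0L) print(table(x$significant$edge_class))
  invisible(x)
}

#' Read alpha-carbon coordinates from a PDB file
#'
#' Parses a PDB-format file with bio3d and returns one representative-atom
#' coordinate per residue.
#'
#' @param pdb_file path to a PDB-format file.
#' @param atom representative atom name (default \code{"CA"}).
#' @param chain optional chain identifier.
#' @return \code{data.frame}: \code{residue}, \code{x}, \code{y}, \code{z}.
#' @export
read_ca_coords <- function(pdb_file, atom = "CA", chain = NULL) {
  pdb <- bio3d::read.pdb(pdb_file)
  a <- pdb$atom
  sel <- a$elety == atom
  if (!is.null(chain)) sel <- sel & a$chain == chain
  a <- a[sel, , drop = FALSE]
  a <- a[!duplicated(a$resno), , drop = FALSE]
  data.frame(residue = a$resno, x = a$x, y = a$y, z = a$z)
}

#' Proximity MI from structure coordinates
#'
#' \code{pMI(r)} is the mean cumulative MI over residues whose
#' representative atoms lie within \code{radius_angstrom} of residue r
#' (r itself excluded); residues with no neighbour score 0. MSA columns are
#' translated to residue numbers through the reference map; mapped residues
#' absent from the coordinate table are skipped with a message.
#'
#' @param cmi per-column cumulative MI vector.
#' @param coords coordinate \code{data.frame} (\code{residue}, \code{x},
#'   \code{y}, \code{z}), e.g. from \code{\link{read_ca_coords}}.
#' @param reference_map a \code{\link{map_reference}} result.
#' @param radius_angstrom neighbourhood radius (default 5).
#' @return \code{data.frame}: \code{residue}, \code{cmi}, \code{pmi}.
#' @export
proximity_mi <- function(cmi, coords, reference_map, radius_angstrom = 5) {
  cols <- as.integer(names(reference_map$column_to_residue))
  res <- unname(reference_map$column_to_residue)
  have <- res %in% coords$residue
  if (any(!have)) {
    message("skipping ", sum(!have),
            " mapped residue(s) absent from the coordinate table")
  }
  res <- res[have]
  cmi_res <- setNames(cmi[cols[have]], res)
  xyz <- as.matrix(coords[match(res, coords$residue), c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  pmi <- vapply(seq_along(res), function(i) {
    nb <- which(d[i, ] <= radius_angstrom & seq_along(res) != i)
    if (!length(nb)) 0 else mean(cmi_res[nb])
  }, numeric(1))
  data.frame(residue = res, cmi = unname(cmi_res), pmi = pmi)
}
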