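# Progressive multiple alignment (k-mer distances -> UPGMA guide tree ->
# profile-profile global alignment), per-column conservation normalised so
# the top column scores 100, sequence-logo information matrices, and
# reference-coordinate mapping.

#' Construct an MSA object from aligned rows
#'
#' @param accessions character vector of sequence identifiers.
#' @param rows equal-length aligned strings over the amino-acid alphabet
#'   plus \code{"-"}.
#' @return List of class \code{msa} with \code{accessions}, \code{rows},
#'   \code{n_columns}.
#' @export
msa_object <- function(accessions, rows) {
  stopifnot(length(accessions) == length(rows),
            length(unique(nchar(rows))) == 1L)
  structure(list(accessions = as.character(accessions),
                 rows = as.character(rows),
                 n_columns = nchar(rows[1L])),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", length(x$rows), "sequences x", x$n_columns, "columns\n")
  invisible(x)
}

# Character matrix view of an MSA (rows = sequences).
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

# 21 x ncol profile (20 residues + gap) of column frequencies.
msa_profile <- function(mat) {
  symbols <- c(AA_ALPHABET, "-")
  apply(mat, 2L, function(col) {
    tabulate(factor(col, levels = symbols), nbins = 21L) / length(col)
  })
}

# k-mer distance between two plain sequences: 1 - Jaccard index of their
# distinct k-mer sets.
kmer_distance <- function(seq_a, seq_b, k = 3L) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  a <- km(seq_a); b <- km(seq_b)
  1 - length(intersect(a, b)) / length(union(a, b))
}

# Align two sub-alignments (lists with $rows, $accessions) by
# profile-profile global alignment. Column-vs-column scores are expected
# substitution scores under the column frequency profiles (gaps score 0).
merge_alignments <- function(a, b, submat, gap_open, gap_extend) {
  fa <- msa_profile(do.call(rbind, strsplit(a$rows, "", fixed = TRUE)))
  fb <- msa_profile(do.call(rbind, strsplit(b$rows, "", fixed = TRUE)))
  S <- t(fa[1:20, , drop = FALSE]) %*% submat %*% fb[1:20, , drop = FALSE]
  res <- gotoh_profile_align(S, gap_open, gap_extend)
  path <- res$path
  idx_a <- integer(length(path)); idx_b <- integer(length(path))
  ia <- 0L; ib <- 0L
  for (p in seq_along(path)) {
    if (path[p] != 3L) ia <- ia + 1L
    if (path[p] != 2L) ib <- ib + 1L
    idx_a[p] <- if (path[p] != 3L) ia else NA_integer_
    idx_b[p] <- if (path[p] != 2L) ib else NA_integer_
  }
  expand <- function(rows, idx) {
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out <- matrix("-", nrow = nrow(mat), ncol = length(idx))
    out[, !is.na(idx)] <- mat[, idx[!is.na(idx)], drop = FALSE]
    apply(out, 1L, paste, collapse = "")
  }
  list(accessions = c(a$accessions, b$accessions),
       rows = c(expand(a$rows, idx_a), expand(b$rows, idx_b)),
       score = res$score)
}

#' Progressive multiple sequence alignment
#'
#' Pairwise k-mer distances feed a UPGMA guide tree; sub-alignments are
#' merged bottom-up by profile-profile global alignment with affine gaps
#' (BLOSUM62, open 10, extend 0.5 by default). Sequences are processed in
#' accession order so guide-tree ties resolve deterministically, and
#' ungapping any output row reproduces its input sequence exactly.
#'
#' @param records protein record \code{data.frame}.
#' @param gap_open,gap_extend affine gap penalties (a gap of length k costs
#'   \code{gap_open + k * gap_extend}).
#' @param submat substitution matrix (default BLOSUM62).
#' @param k k-mer length for guide-tree distances.
#' @return An \code{msa} object (input order of accessions preserved).
#' @export
align_msa <- function(records, gap_open = 10, gap_extend = 0.5,
                      submat = blosum62_matrix(), k = 3L) {
  n <- nrow(records)
  if (n < 1L) stop("no records to align")
  if (n == 1L) {
    warning("single sequence: returning a trivial one-row MSA")
    return(msa_object(records$accession, records$sequence))
  }
  ord <- order(records$accession, method = "radix")
  rec <- records[ord, , drop = FALSE]
  if (n == 2L) {
    merged <- merge_alignments(
      list(accessions = rec$accession[1L], rows = rec$sequence[1L]),
      list(accessions = rec$accession[2L], rows = rec$sequence[2L]),
      submat, gap_open, gap_extend)
  } else {
    D <- matrix(0, n, n)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- kmer_distance(rec$sequence[i], rec$sequence[j], k)
    }
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", n - 1L)
    leaf <- function(i) list(accessions = rec$accession[i],
                             rows = rec$sequence[i])
    for (s in seq_len(n - 1L)) {
      pick <- function(x) if (x < 0L) leaf(-x) else nodes[[x]]
      nodes[[s]] <- merge_alignments(pick(hc$merge[s, 1L]),
                                     pick(hc$merge[s, 2L]),
                                     submat, gap_open, gap_extend)
    }
    merged <- nodes[[n - 1L]]
  }
  keep <- match(records$accession, merged$accessions)
  msa_object(merged$accessions[keep], merged$rows[keep])
}

#' Global pairwise alignment score
#'
#' Score of the optimal global (Needleman-Wunsch, affine-gap) alignment of
#' two sequences under the progressive aligner's scoring scheme; exposed for
#' direct use and cross-checking.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @inheritParams align_msa
#' @return Numeric alignment score.
#' @export
global_alignment_score <- function(seq_a, seq_b, gap_open = 10,
                                   gap_extend = 0.5,
                                   submat = blosum62_matrix()) {
  merged <- merge_alignments(list(accessions = "a", rows = seq_a),
                             list(accessions = "b", rows = seq_b),
                             submat, gap_open, gap_extend)
  merged$score
}

# Sequence weights: uniform, or inverse cluster size after single-linkage
# clustering of rows at >= 62% pairwise identity (identity over columns
# where both rows are ungapped).
msa_weights <- function(mat, weighting = c("none", "identity_cluster")) {
  weighting <- match.arg(weighting)
  n <- nrow(mat)
  if (weighting == "none" || n == 1L) return(rep(1, n))
  sim <- matrix(FALSE, n, n)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    id <- if (any(both)) mean(mat[i, both] == mat[j, both]) else 0
    sim[i, j] <- sim[j, i] <- id >= 0.62
  }
  g <- igraph::graph_from_adjacency_matrix(sim, mode = "undirected")
  memb <- igraph::components(g)$membership
  1 / table(memb)[as.character(memb)]
}

#' Per-column conservation profile
#'
#' Raw conservation of column c is the weighted sum over ungapped row pairs
#' of the min-max-normalised substitution score,
#' \code{raw(c) = sum_{i<j} w_i w_j s_norm(a_i, a_j)}. Relative scores put
#' the best column at exactly 100 (\code{100 * raw / max raw}); columns with
#' more than 50\% gaps are excluded from the normalising maximum (still
#' scored) so alignment artifacts cannot claim the anchor.
#'
#' @param msa an \code{msa} object.
#' @param weighting \code{"none"} (uniform) or \code{"identity_cluster"}
#'   (inverse cluster size at 62\% identity).
#' @param submat substitution matrix used for the normalised pair score.
#' @return \code{data.frame} of class \code{conservation_profile}: per column
#'   \code{raw_score}, \code{relative_score}, \code{gap_fraction},
#'   \code{information_bits}, plus a \code{frequencies} attribute
#'   (20 x n_columns matrix of non-gap residue frequencies).
#' @export
conservation_profile <- function(msa, weighting = "none",
                                 submat = blosum62_matrix()) {
  mat <- msa_matrix(msa)
  sn <- normalize_submat(submat)
  w <- as.numeric(msa_weights(mat, weighting))
  nc <- ncol(mat)
  raw <- numeric(nc); gapf <- numeric(nc)
  freqs <- matrix(0, nrow = 20L, ncol = nc, dimnames = list(AA_ALPHABET, NULL))
  for (c in seq_len(nc)) {
    col <- mat[, c]
    ok <- col != "-"
    gapf[c] <- 1 - mean(ok)
    if (!any(ok)) next
    cnt <- tapply(w[ok], factor(col[ok], levels = AA_ALPHABET), sum,
                  default = 0)
    freqs[, c] <- cnt / sum(cnt)
    # sum_{i<j} w_i w_j s(a_i, a_j)
    #   = (cnt' S cnt - sum_x (sum_i w_i^2 [a_i = x]) s(x, x)) / 2
    w2 <- tapply(w[ok]^2, factor(col[ok], levels = AA_ALPHABET), sum,
                 default = 0)
    raw[c] <- as.numeric(t(cnt) %*% sn %*% cnt - sum(w2 * diag(sn))) / 2
  }
  eligible <- raw[gapf <= 0.5]
  mx <- if (length(eligible) && max(eligible) > 0) max(eligible) else NA_real_
  relative <- if (is.na(mx)) rep(0, nc) else 100 * raw / mx
  lm <- logo_matrix(msa)
  out <- data.frame(column = seq_len(nc), raw_score = raw,
                    relative_score = relative, gap_fraction = gapf,
                    information_bits = lm$information_bits)
  attr(out, "frequencies") <- freqs
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Sequence-logo information matrix
#'
#' Column information content in bits, \code{log2(20) - H(c)} with H the
#' Shannon entropy of the non-gap residue frequencies (no small-sample
#' correction), and per-residue letter heights
#' \code{height(a, c) = f_a(c) * information_bits(c)}.
#'
#' @param msa an \code{msa} object.
#' @return List with \code{information_bits} (per column) and \code{heights}
#'   (20 x n_columns matrix).
#' @export
logo_matrix <- function(msa) {
  mat <- msa_matrix(msa)
  nc <- ncol(mat)
  bits <- numeric(nc)
  heights <- matrix(0, nrow = 20L, ncol = nc,
                    dimnames = list(AA_ALPHABET, NULL))
  for (c in seq_len(nc)) {
    col <- mat[, c]
    col <- col[col != "-"]
    if (!length(col)) next
    f <- tabulate(factor(col, levels = AA_ALPHABET), nbins = 20L) / length(col)
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    bits[c] <- log2(20) - h
    heights[, c] <- f * bits[c]
  }
  list(information_bits = bits, heights = heights)
}

#' Map MSA columns to reference residue numbers
#'
#' @param msa an \code{msa} object.
#' @param reference_accession accession of the reference row.
#' @return List of class \code{reference_map}: \code{column_to_residue}
#'   (named integer vector over mapped columns), \code{residue_to_column}
#'   (inverse), \code{reference}.
#' @export
map_reference <- function(msa, reference_accession) {
  i <- match(reference_accession, msa$accessions)
  if (is.na(i)) stop("reference accession absent from MSA: ",
                     reference_accession)
  chars <- seq_chars(msa$rows[i])
  ungapped <- chars != "-"
  cols <- which(ungapped)
  res <- cumsum(ungapped)[ungapped]
  structure(list(
    reference = reference_accession,
    column_to_residue = setNames(as.integer(res), cols),
    residue_to_column = setNames(as.integer(cols), res)
  ), class = "reference_map")
}

#' Write an MSA as aligned FASTA
#' @param msa an \code{msa} object.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_msa_fasta <- function(msa, file) {
  aa <- Biostrings::AAStringSet(msa$rows)
  names(aa) <- msa$accessions
  Biostrings::writeXStringSet(aa, file, width = 60L)
  invisible(file)
}

#' Read an aligned FASTA into an MSA object
#' @param file aligned FASTA path.
#' @return An \code{msa} object.
#' @export
read_msa_fasta <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  msa_object(sub("\\s.*$", "", names(aa)), toupper(as.character(aa)))
}
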