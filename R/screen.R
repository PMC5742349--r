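# Screening stage: dedupe at 100% identity, fragment removal, PQ-loop motif
# detection, and a sliding-window Kyte-Doolittle transmembrane-helix
# predictor with an at-least-3-TMH filter.

#' Remove byte-identical sequences
#'
#' Among identical sequences the record with the lexicographically smallest
#' accession is retained; every removed record is reported together with its
#' retained representative.
#'
#' @param records protein record \code{data.frame}.
#' @return List with \code{kept} (records) and \code{removed}
#'   (\code{data.frame} with columns \code{removed}, \code{representative}).
#' @export
dedupe_records <- function(records) {
  if (anyDuplicated(records$accession)) {
    stop("duplicate accession in input")
  }
  ord <- order(records$accession, method = "radix")
  rec <- records[ord, , drop = FALSE]
  rep_acc <- tapply(rec$accession, rec$sequence, function(a) a[1L])
  representative <- unname(rep_acc[rec$sequence])
  is_rep <- rec$accession == representative
  removed <- data.frame(removed = rec$accession[!is_rep],
                        representative = representative[!is_rep],
                        stringsAsFactors = FALSE)
  kept <- rec[is_rep, , drop = FALSE]
  # restore original input order for the kept set
  kept <- kept[order(match(kept$accession, records$accession)), , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Predict transmembrane helices by windowed hydropathy
#'
#' Transparent stand-in for an HMM topology predictor: a position is a helix
#' candidate iff the mean Kyte-Doolittle hydropathy of the length-\code{window}
#' window centred on it is at least \code{threshold} (only full windows are
#' evaluated). Maximal candidate runs separated by fewer than
#' \code{merge_gap} positions are merged, and runs of at least
#' \code{min_helix_len} become helices.
#'
#' @param sequence amino-acid string (X scores 0).
#' @param window odd window length (default 19).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @param min_helix_len minimum helix run length (default 15).
#' @param merge_gap runs closer than this many positions are merged
#'   (default 3).
#' @return List of class \code{tmh_topology} with \code{helices}
#'   (matrix of 1-based inclusive \code{start}, \code{end}) and \code{count}.
#' @export
predict_tmh <- function(sequence, window = 19L, threshold = 1.6,
                        min_helix_len = 15L, merge_gap = 3L) {
  stopifnot(window %% 2L == 1L, window > 0L, min_helix_len > 0L,
            merge_gap >= 0L)
  check_sequence(sequence)
  chars <- seq_chars(sequence)
  n <- length(chars)
  empty <- structure(list(helices = cbind(start = integer(0), end = integer(0)),
                          count = 0L), class = "tmh_topology")
  if (n < window) return(empty)
  kd <- KD_HYDROPATHY[chars]
  kd[is.na(kd)] <- 0  # X
  half <- (window - 1L) %/% 2L
  means <- as.numeric(stats::filter(kd, rep(1 / window, window), sides = 2))
  centre <- (half + 1L):(n - half)
  cand <- rep(FALSE, n)
  cand[centre] <- means[centre] >= threshold
  runs <- rle(cand)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- cbind(start = starts[runs$values], end = ends[runs$values])
  if (nrow(seg) == 0L) return(empty)
  # merge runs separated by < merge_gap
  merged <- seg[1L, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (i in 2L:nrow(seg)) {
      if (seg[i, "start"] - merged[nrow(merged), "end"] - 1L < merge_gap) {
        merged[nrow(merged), "end"] <- seg[i, "end"]
      } else {
        merged <- rbind(merged, seg[i, , drop = FALSE])
      }
    }
  }
  keep <- (merged[, "end"] - merged[, "start"] + 1L) >= min_helix_len
  helices <- merged[keep, , drop = FALSE]
  structure(list(helices = helices, count = nrow(helices)),
            class = "tmh_topology")
}

#' @export
print.tmh_topology <- function(x, ...) {
  cat("TMH topology:", x$count, "helices\n")
  if (x$count > 0L) {
    cat(paste(sprintf("  TMH%d: %d-%d", seq_len(x$count),
                      x$helices[, "start"], x$helices[, "end"]),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Locate the PQ-loop motif near the first helix
#'
#' Scans the first predicted helix, extended by \code{flank} residues on each
#' side, for the first \code{P} followed by \code{Q} (\code{strict_PQ}) or
#' for the first \code{P} alone (\code{relaxed_P}; glutamine is conserved
#' only in the 3-TMH SemiSWEETs, so the relaxed mode captures SWEETs whose Q
#' has drifted).
#'
#' @param sequence amino-acid string.
#' @param topology \code{tmh_topology} computed from \code{sequence}.
#' @param mode \code{"strict_PQ"} or \code{"relaxed_P"}.
#' @param flank extension of the first helix on each side (default 10).
#' @return 1-based position of the motif P, or \code{NA_integer_} if absent
#'   (including when no helix was predicted).
#' @export
find_pq_motif <- function(sequence, topology, mode = c("strict_PQ", "relaxed_P"),
                          flank = 10L) {
  mode <- match.arg(mode)
  if (topology$count == 0L) return(NA_integer_)
  chars <- seq_chars(sequence)
  lo <- max(1L, topology$helices[1L, "start"] - flank)
  hi <- min(length(chars), topology$helices[1L, "end"] + flank)
  for (i in lo:hi) {
    if (chars[i] == "P") {
      if (mode == "relaxed_P") return(i)
      if (i < length(chars) && chars[i + 1L] == "Q") return(i)
    }
  }
  NA_integer_
}

#' Screen protein records
#'
#' Applies the four filters in fixed order: 100\%-identity dedupe, fragment
#' removal (length below \code{fragment_max_fraction} of the median input
#' length), PQ-loop motif presence, and a minimum predicted-TMH count.
#' Each removed record carries exactly the first failing reason.
#'
#' @param records protein record \code{data.frame}.
#' @param min_tmh minimum number of predicted helices (default 3).
#' @param fragment_max_fraction fragment cutoff as a fraction of the median
#'   input length (default 0.5).
#' @param motif_mode passed to \code{\link{find_pq_motif}}.
#' @param tmh_params list of arguments for \code{\link{predict_tmh}}.
#' @param motif_flank passed to \code{\link{find_pq_motif}}.
#' @return List of class \code{screen_report}: \code{report} (per-record
#'   \code{passed}, \code{tmh_count}, \code{pq_hit}, \code{removal_reason}),
#'   \code{passed} (the surviving records) and \code{counts} (records removed
#'   per reason).
#' @export
screen_records <- function(records, min_tmh = 3L, fragment_max_fraction = 0.5,
                           motif_mode = "strict_PQ", tmh_params = list(),
                           motif_flank = 10L) {
  if (is.null(records) || nrow(records) == 0L) stop("empty input record set")
  dd <- dedupe_records(records)
  reason <- setNames(rep("none", nrow(records)), records$accession)
  reason[dd$removed$removed] <- "duplicate"

  len <- nchar(records$sequence)
  med <- stats::median(len)
  is_frag <- len < fragment_max_fraction * med
  frag <- reason == "none" & is_frag
  reason[frag] <- "fragment"

  tmh_count <- rep(NA_integer_, nrow(records))
  pq_hit <- rep(NA_integer_, nrow(records))
  for (i in seq_len(nrow(records))) {
    if (reason[i] != "none") next
    topo <- do.call(predict_tmh, c(list(records$sequence[i]), tmh_params))
    tmh_count[i] <- topo$count
    pq_hit[i] <- find_pq_motif(records$sequence[i], topo, motif_mode,
                               flank = motif_flank)
    if (is.na(pq_hit[i])) {
      reason[i] <- "no_motif"
    } else if (topo$count < min_tmh) {
      reason[i] <- "too_few_tmh"
    }
  }
  report <- data.frame(accession = records$accession,
                       passed = reason == "none",
                       tmh_count = tmh_count, pq_hit = pq_hit,
                       removal_reason = unname(reason),
                       stringsAsFactors = FALSE)
  counts <- table(factor(reason, levels = c("duplicate", "fragment",
                                            "no_motif", "too_few_tmh", "none")))
  structure(list(report = report,
                 passed = records[report$passed, , drop = FALSE],
                 counts = counts),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screen report:", nrow(x$report), "records,", sum(x$report$passed),
      "passed\n")
  print(x$counts)
  invisible(x)
}
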