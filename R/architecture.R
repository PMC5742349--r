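# Repeat-unit architecture: TMH-count classification into
# SemiSWEET / SWEET / extraSWEET / superSWEET, decomposition into 3-TMH
# repeat units plus single-helix linkers, and duplication/fusion evidence
# from unit-vs-reference local alignment.

#' Default architecture class bins
#'
#' 3-4 TMHs: SemiSWEET; 6-7: SWEET; 14-15: extraSWEET (the 14- and 15-TMH
#' proteins reported in grape and wild rice); 18 or more: superSWEET (the
#' oomycete 18/23/25-TMH fusions); everything else: atypical.
#' @export
default_arch_bins <- function() {
  list(semiSWEET = c(3L, 4L), SWEET = c(6L, 7L), extraSWEET = c(14L, 15L),
       superSWEET_min = 18L)
}

#' Classify a protein by predicted TMH count
#'
#' @param tmh_count number of predicted transmembrane helices.
#' @param bins class bins as produced by \code{\link{default_arch_bins}}.
#' @return One of \code{"semiSWEET"}, \code{"SWEET"}, \code{"extraSWEET"},
#'   \code{"superSWEET"}, \code{"atypical"}.
#' @export
classify_architecture <- function(tmh_count, bins = default_arch_bins()) {
  stopifnot(tmh_count >= 0L)
  fixed <- c(bins$semiSWEET, bins$SWEET, bins$extraSWEET)
  if (anyDuplicated(fixed) || any(fixed >= bins$superSWEET_min)) {
    stop("overlapping architecture bins in config")
  }
  if (tmh_count %in% bins$semiSWEET) return("semiSWEET")
  if (tmh_count %in% bins$SWEET) return("SWEET")
  if (tmh_count %in% bins$extraSWEET) return("extraSWEET")
  if (tmh_count >= bins$superSWEET_min) return("superSWEET")
  "atypical"
}

# Canonical helix-ordinal plans (triplet = 3 helices, linker = 1):
# 3 -> [t]; 4 -> [t,l]; 7 -> [t,l,t]; 15 -> [t,l,t,l,t,l,t].
# Other counts: greedy 7-helix chunks [t,l,t] while >= 7 helices remain,
# then 6 -> [t,t], 5 -> [t] + 2 unresolved, 4 -> [t,l], 3 -> [t],
# 1-2 -> unresolved.
unit_plan_for_count <- function(tmh_count) {
  canonical <- list(`3` = c("t"), `4` = c("t", "l"),
                    `7` = c("t", "l", "t"),
                    `15` = c("t", "l", "t", "l", "t", "l", "t"))
  key <- as.character(tmh_count)
  if (!is.null(canonical[[key]])) return(canonical[[key]])
  plan <- character(0)
  rem <- tmh_count
  while (rem >= 7L) {
    plan <- c(plan, "t", "l", "t")
    rem <- rem - 7L
  }
  plan <- c(plan, switch(as.character(rem),
                         "0" = character(0),
                         "1" = "u1", "2" = "u2",
                         "3" = "t", "4" = c("t", "l"),
                         "5" = c("t", "u2"), "6" = c("t", "t")))
  plan
}

#' Decompose a topology into repeat units
#'
#' Assigns helix ordinals to 3-TMH triplet units, single-helix linkers, and
#' (for non-canonical counts) trailing unresolved helices, then cuts the
#' sequence at the midpoints of the loops between consecutive units so each
#' unit carries its flanking loop context. Spans partition 1..nchar(sequence).
#'
#' @param topology \code{tmh_topology} for the sequence.
#' @param sequence the amino-acid string the topology was computed from.
#' @return \code{data.frame} with columns \code{unit_type} (\code{triplet},
#'   \code{linker} or \code{unresolved}), \code{tmh_first}, \code{tmh_last}
#'   (helix ordinals), \code{start}, \code{end} (1-based inclusive residue
#'   spans).
#' @export
decompose_units <- function(topology, sequence) {
  if (topology$count == 0L) stop("cannot decompose a topology with 0 helices")
  plan <- unit_plan_for_count(topology$count)
  sizes <- c(t = 3L, l = 1L, u1 = 1L, u2 = 2L)[plan]
  types <- c(t = "triplet", l = "linker", u1 = "unresolved",
             u2 = "unresolved")[plan]
  last <- cumsum(sizes)
  first <- last - sizes + 1L
  n <- length(plan)
  L <- nchar(sequence)
  starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    starts[i] <- if (i == 1L) 1L else ends[i - 1L] + 1L
    if (i == n) {
      ends[i] <- L
    } else {
      helix_end <- topology$helices[last[i], "end"]
      next_start <- topology$helices[first[i + 1L], "start"]
      ends[i] <- (helix_end + next_start) %/% 2L
    }
  }
  data.frame(unit_type = unname(types), tmh_first = unname(first),
             tmh_last = unname(last), start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Score duplication/fusion evidence for repeat units
#'
#' Aligns each triplet unit's subsequence locally against every reference
#' sequence and reports the best hit by bitscore, with identity and e-value.
#' Units whose best identity reaches \code{fusion_identity_threshold} are
#' flagged as fusion evidence (the repeated units of multi-unit proteins
#' align at high identity to stand-alone SWEET/SemiSWEET references).
#'
#' @param units decomposition from \code{\link{decompose_units}}.
#' @param sequence the full protein sequence.
#' @param references protein record \code{data.frame} of reference
#'   SWEET/SemiSWEET sequences.
#' @param params \code{\link{similarity_params}}.
#' @param fusion_identity_threshold percent identity flag threshold
#'   (default 70).
#' @return \code{data.frame}: \code{unit_index}, \code{unit_type},
#'   \code{best_reference_accession}, \code{percent_identity},
#'   \code{bitscore}, \code{evalue}, \code{fusion_evidence}.
#' @export
detect_fusion <- function(units, sequence, references,
                          params = similarity_params(),
                          fusion_identity_threshold = 70) {
  if (is.null(references) || nrow(references) == 0L) {
    stop("empty reference set")
  }
  triplets <- which(units$unit_type == "triplet")
  if (length(triplets) == 0L) stop("no triplet units to score")
  db <- sum(nchar(references$sequence))
  out <- NULL
  for (i in triplets) {
    sub <- substr(sequence, units$start[i], units$end[i])
    best <- NULL
    for (j in seq_len(nrow(references))) {
      e <- pairwise_similarity(list(accession = "unit", sequence = sub),
                               references[j, ], params, db_residues = db)
      e$reference <- references$accession[j]
      if (is.null(best) || e$bitscore > best$bitscore) best <- e
    }
    out <- rbind(out, data.frame(
      unit_index = i, unit_type = "triplet",
      best_reference_accession = best$reference,
      percent_identity = best$percent_identity,
      bitscore = best$bitscore, evalue = best$evalue,
      fusion_evidence = best$percent_identity >= fusion_identity_threshold,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Architecture call for one record
#'
#' Convenience wrapper: predicts the topology, classifies the TMH count and
#' decomposes units in one step.
#'
#' @param sequence amino-acid string.
#' @param bins class bins (see \code{\link{default_arch_bins}}).
#' @param tmh_params list of arguments for \code{\link{predict_tmh}}.
#' @return List of class \code{arch_call}: \code{tmh_count},
#'   \code{arch_class}, \code{topology}, \code{units} (NULL when no helix).
#' @export
architecture_call <- function(sequence, bins = default_arch_bins(),
                              tmh_params = list()) {
  topo <- do.call(predict_tmh, c(list(sequence), tmh_params))
  cls <- classify_architecture(topo$count, bins)
  units <- if (topo$count > 0L) decompose_units(topo, sequence) else NULL
  structure(list(tmh_count = topo$count, arch_class = cls,
                 topology = topo, units = units),
            class = "arch_call")
}

#' @export
print.arch_call <- function(x, ...) {
  cat("Architecture:", x$arch_class, sprintf("(%d TMHs)\n", x$tmh_count))
  if (!is.null(x$units)) {
    cat(" ", paste(sprintf("%d-%d:%s", x$units$start, x$units$end,
                           x$units$unit_type), collapse = " "), "\n")
  }
  invisible(x)
}
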