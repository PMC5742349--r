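# Synthetic SWEET/SemiSWEET family generator with planted truth.
#
# Families are built from 3-TMH repeat units: three hydrophobic blocks
# (drawn from {I,V}, Kyte-Doolittle 4.5/4.2) separated by hydrophilic loops
# (drawn from {D,E,N,Q}, all -3.5), with a Pro-Gln (PQ-loop) dipeptide
# planted in the loop preceding the first block. Restricting each region to
# residues of a single hydropathy level makes the window-averaged
# hydropathy profile a deterministic two-level step function, so the
# helix predictor recovers the planted topology exactly at any
# substitution rate; substitutions are resampled within the same set.

BLOCK_ALPHABET <- c("I", "V")
LOOP_ALPHABET  <- c("D", "E", "N", "Q")

#' Build one 3-TMH unit template
#'
#' A unit is \code{loop + block + loop + block + loop + block}: three
#' hydrophobic blocks separated by hydrophilic loops, with the PQ-loop
#' dipeptide planted near the end of the leading loop (immediately upstream
#' of the first helix).
#'
#' @param unit_id identifier string.
#' @param block_len length of each hydrophobic block (default 21).
#' @param loop_len length of each hydrophilic loop (default 12).
#' @return A list of class \code{unit_template} with fields \code{unit_id},
#'   \code{sequence}, \code{pq_position} (1-based index of the planted P) and
#'   \code{block_spans} (3 x 2 matrix of block start/end).
#' @export
unit_template <- function(unit_id, block_len = 21L, loop_len = 12L) {
  stopifnot(block_len >= 15L, loop_len >= 4L)
  piece <- function(n, alpha) paste(sample(alpha, n, replace = TRUE), collapse = "")
  loops <- replicate(3L, piece(loop_len, LOOP_ALPHABET))
  blocks <- replicate(3L, piece(block_len, BLOCK_ALPHABET))
  pq_position <- loop_len - 2L
  substr(loops[1L], pq_position, pq_position + 1L) <- "PQ"
  sequence <- paste0(loops[1L], blocks[1L], loops[2L], blocks[2L],
                     loops[3L], blocks[3L])
  starts <- loop_len + 1L + (0:2) * (block_len + loop_len)
  structure(list(
    unit_id = unit_id,
    sequence = sequence,
    pq_position = pq_position,
    block_spans = cbind(start = starts, end = starts + block_len - 1L)
  ), class = "unit_template")
}

#' Draw a set of random unit templates
#'
#' @param n number of templates.
#' @param seed optional integer seed for reproducible template draws.
#' @inheritParams unit_template
#' @return List of \code{unit_template} objects with ids \code{"U1"}, ...
#' @export
random_unit_templates <- function(n, seed = NULL, block_len = 21L, loop_len = 12L) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i)
    unit_template(paste0("U", i), block_len = block_len, loop_len = loop_len))
}

#' Describe an evolution scenario for the family generator
#'
#' @param n_families number of independent families.
#' @param seqs_per_family full-length sequences generated per family.
#' @param architecture_per_family TMH counts, one per family, each one of
#'   3, 7, 15 or 25 (recycled).
#' @param substitution_rate per-site substitution probability per sequence.
#' @param n_invariant number of planted invariant loop columns per family,
#'   written as Asp/Asn so that the planted conservation signal is the
#'   strongest the sum-of-pairs score can produce. The PQ-loop dipeptide is
#'   also never mutated but is tracked separately as \code{pq_positions},
#'   not in \code{invariant_columns}.
#' @param n_covarying number of planted covarying column pairs per family.
#' @param covary_states matrix of allowed joint states for covarying pairs
#'   (rows = allowed (state A, state B) combinations over the loop alphabet).
#' @param fragment_rate fraction of full-length records truncated to 20-45\%
#'   of their length.
#' @param duplicate_rate fraction of records re-emitted as byte-identical
#'   copies under fresh accessions.
#' @param seed integer seed driving the single pseudo-random stream.
#' @return A list of class \code{evolution_scenario}.
#' @export
evolution_scenario <- function(n_families = 2L, seqs_per_family = 20L,
                               architecture_per_family = 7L,
                               substitution_rate = 0.1,
                               n_invariant = 10L, n_covarying = 2L,
                               covary_states = rbind(c("D", "E"), c("E", "D"),
                                                     c("N", "Q"), c("Q", "N")),
                               fragment_rate = 0, duplicate_rate = 0,
                               seed = 1L) {
  arch <- rep_len(as.integer(architecture_per_family), n_families)
  if (!all(arch %in% c(3L, 7L, 15L, 25L))) {
    stop("architecture_per_family must be one of 3, 7, 15, 25 TMHs")
  }
  for (r in c(substitution_rate, fragment_rate, duplicate_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  stopifnot(all(covary_states %in% LOOP_ALPHABET))
  structure(list(
    n_families = as.integer(n_families),
    seqs_per_family = as.integer(seqs_per_family),
    architecture_per_family = arch,
    substitution_rate = substitution_rate,
    n_invariant = as.integer(n_invariant),
    n_covarying = as.integer(n_covarying),
    covary_states = covary_states,
    fragment_rate = fragment_rate,
    duplicate_rate = duplicate_rate,
    seed = as.integer(seed)
  ), class = "evolution_scenario")
}

# Piece plan for a TMH count: "unit" entries are 3-TMH repeats, "linker"
# entries single helices. 3 = [u]; 7 = [u,l,u]; 15 = [u,l,u,l,u,l,u];
# 25 = [u,l,u] x3 + [u,l] (three SWEET-like 7-TMH halves plus a 4-TMH tail).
tmh_plan <- function(tmh_count) {
  switch(as.character(tmh_count),
    "3"  = c("unit"),
    "7"  = c("unit", "linker", "unit"),
    "15" = c("unit", "linker", "unit", "linker", "unit", "linker", "unit"),
    "25" = c(rep(c("unit", "linker", "unit"), 3L), "unit", "linker"),
    stop("no generation plan for ", tmh_count, " TMHs"))
}

arch_class_for_count <- function(tmh_count) {
  classify_architecture(tmh_count)
}

# Build one family ancestor from templates; returns sequence, block spans,
# per-unit spans (midpoint rule), pq positions, loop positions.
build_ancestor <- function(plan, templates, block_len, loop_len) {
  seqs <- character(0)
  blocks <- NULL
  piece_blocks <- list()  # block indices per piece
  pq_positions <- integer(0)
  offset <- 0L
  u <- 0L
  for (p in plan) {
    if (p == "unit") {
      u <- u + 1L
      tpl <- templates[[(u - 1L) %% length(templates) + 1L]]
      seqs <- c(seqs, tpl$sequence)
      b <- tpl$block_spans + offset
      pq_positions <- c(pq_positions, tpl$pq_position + offset)
      offset <- offset + nchar(tpl$sequence)
    } else {
      linker <- paste0(
        paste(sample(LOOP_ALPHABET, loop_len, replace = TRUE), collapse = ""),
        paste(sample(BLOCK_ALPHABET, block_len, replace = TRUE), collapse = ""))
      seqs <- c(seqs, linker)
      b <- cbind(start = offset + loop_len + 1L,
                 end = offset + loop_len + block_len)
      offset <- offset + nchar(linker)
    }
    piece_blocks[[length(piece_blocks) + 1L]] <-
      nrow2(blocks) + seq_len(nrow(b))
    blocks <- rbind(blocks, b)
  }
  tail_loop <- paste(sample(LOOP_ALPHABET, loop_len, replace = TRUE),
                     collapse = "")
  sequence <- paste0(paste(seqs, collapse = ""), tail_loop)
  units <- unit_spans_from_blocks(blocks, plan, piece_blocks, nchar(sequence))
  chars <- seq_chars(sequence)
  in_block <- logical(nchar(sequence))
  for (i in seq_len(nrow(blocks))) in_block[blocks[i, 1]:blocks[i, 2]] <- TRUE
  loop_positions <- which(!in_block & chars %in% LOOP_ALPHABET)
  list(sequence = sequence, blocks = blocks, units = units,
       pq_positions = pq_positions, loop_positions = loop_positions)
}

nrow2 <- function(x) if (is.null(x)) 0L else nrow(x)

# Midpoint-rule spans for an ordered list of pieces over known block spans.
unit_spans_from_blocks <- function(blocks, plan, piece_blocks, seq_len_total) {
  n <- length(plan)
  starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    first_b <- blocks[piece_blocks[[i]][1L], ]
    last_b <- blocks[piece_blocks[[i]][length(piece_blocks[[i]])], ]
    starts[i] <- if (i == 1L) 1L else ends[i - 1L] + 1L
    if (i == n) {
      ends[i] <- seq_len_total
    } else {
      next_b <- blocks[piece_blocks[[i + 1L]][1L], ]
      ends[i] <- (last_b["end"] + next_b["start"]) %/% 2L
    }
  }
  data.frame(
    unit_type = ifelse(plan == "unit", "triplet", "linker"),
    tmh_first = vapply(piece_blocks, function(ix) ix[1L], integer(1)),
    tmh_last = vapply(piece_blocks, function(ix) ix[length(ix)], integer(1)),
    start = starts, end = ends, stringsAsFactors = FALSE)
}

# One mutated descendant of an ancestor. Substitutions resample within the
# residue's hydropathy set; invariant positions are skipped; covarying pairs
# switch jointly to a random allowed state combination.
mutate_sequence <- function(chars, rate, mutable, covary, covary_states) {
  out <- chars
  if (rate > 0) {
    hit <- mutable[stats::runif(length(mutable)) < rate]
    for (p in hit) {
      alpha <- if (out[p] %in% BLOCK_ALPHABET) BLOCK_ALPHABET else LOOP_ALPHABET
      out[p] <- sample(alpha, 1L)
    }
    q <- min(1, 2 * rate)
    for (pair in covary) {
      if (stats::runif(1) < q) {
        row <- covary_states[sample(nrow(covary_states), 1L), ]
        out[pair[1L]] <- row[1L]
        out[pair[2L]] <- row[2L]
      }
    }
  }
  out
}

#' Generate synthetic protein families with planted truth
#'
#' Runs the documented generation process: per family, an ancestor is
#' assembled from unit templates according to its TMH plan, descendants are
#' drawn by per-site substitution (invariant columns skipped, covarying
#' pairs switched jointly), and fragments plus exact duplicates are injected.
#' The single RNG stream is seeded from \code{scenario$seed}, so identical
#' inputs give byte-identical outputs.
#'
#' @param scenario an \code{\link{evolution_scenario}}.
#' @param templates list of \code{\link{unit_template}} objects shared by
#'   all families (related families), or \code{NULL} to draw a fresh
#'   template set per family from the seeded stream (unrelated families).
#' @param family_prefix accession prefix (default \code{"F"}); set a
#'   different prefix when merging several generated sets.
#' @return A list of class \code{family_set} with elements:
#'   \describe{
#'     \item{records}{protein record \code{data.frame} (FASTA-ready).}
#'     \item{truth}{list with \code{sequences} (per-record truth rows:
#'       family, architecture class, TMH count, unit spans, fragment and
#'       duplicate flags) and \code{families} (per-family ancestor, true
#'       block topology, unit spans, invariant columns, covarying pairs).}
#'   }
#' @export
generate_families <- function(scenario, templates = NULL,
                              family_prefix = "F") {
  stopifnot(inherits(scenario, "evolution_scenario"))
  if (!is.null(templates)) {
    if (length(templates) == 0L) stop("at least one unit template is required")
    stopifnot(all(vapply(templates, inherits, logical(1), "unit_template")))
  }
  set.seed(scenario$seed)
  tpl0 <- if (is.null(templates)) unit_template("probe") else templates[[1L]]
  block_len <- diff(tpl0$block_spans[1L, ]) + 1L
  loop_len <- tpl0$block_spans[1L, "start"] - 1L

  taxa <- rep_len(c("green_plants", "bacteria", "oomycota", "metazoa", "fungi"),
                  scenario$n_families)
  records <- NULL
  seq_truth <- NULL
  fam_truth <- vector("list", scenario$n_families)

  for (f in seq_len(scenario$n_families)) {
    plan <- tmh_plan(scenario$architecture_per_family[f])
    fam_templates <- if (is.null(templates)) {
      random_unit_templates(2L, block_len = block_len, loop_len = loop_len)
    } else templates
    anc <- build_ancestor(plan, fam_templates, block_len, loop_len)
    tmh_count <- nrow(anc$blocks)
    arch_class <- classify_architecture(tmh_count)

    # Planted covarying pairs and invariant columns live in loop positions;
    # the PQ dipeptide positions are invariant by construction.
    pq_cols <- sort(c(anc$pq_positions, anc$pq_positions + 1L))
    avail <- setdiff(anc$loop_positions, pq_cols)
    covary <- list()
    if (scenario$n_covarying > 0L) {
      picked <- sample(avail, 2L * scenario$n_covarying)
      covary <- lapply(seq_len(scenario$n_covarying), function(i)
        sort(picked[c(2L * i - 1L, 2L * i)]))
      avail <- setdiff(avail, picked)
    }
    planted_inv <- sort(sample(avail, min(scenario$n_invariant,
                                          length(avail))))
    chars <- seq_chars(anc$sequence)
    # Planted invariant sites take the loop residues with the largest
    # substitution-matrix self-score (Asp/Asn), so that a truly invariant
    # column outranks any nearly conserved background column under the
    # sum-of-pairs conservation score; this keeps the planted truth
    # identifiable by the statistic that is supposed to recover it.
    chars[planted_inv] <- sample(c("D", "N"), length(planted_inv),
                                 replace = TRUE)
    # Set covarying pairs to their first allowed state in the ancestor.
    for (pair in covary) {
      chars[pair[1L]] <- scenario$covary_states[1L, 1L]
      chars[pair[2L]] <- scenario$covary_states[1L, 2L]
    }
    mutable <- setdiff(seq_along(chars),
                       c(planted_inv, pq_cols, unlist(covary)))
    fam_truth[[f]] <- list(
      family = f, ancestor = paste(chars, collapse = ""),
      tmh_count = tmh_count, arch_class = arch_class,
      blocks = anc$blocks, units = anc$units,
      invariant_columns = planted_inv, covarying_pairs = covary,
      pq_positions = anc$pq_positions)

    for (i in seq_len(scenario$seqs_per_family)) {
      mut <- mutate_sequence(chars, scenario$substitution_rate, mutable,
                             covary, scenario$covary_states)
      acc <- sprintf("%s%02dS%03d", family_prefix, f, i)
      records <- rbind(records, data.frame(
        accession = acc,
        description = sprintf("synthetic %s family %d", arch_class, f),
        taxon_group = taxa[f],
        sequence = paste(mut, collapse = ""),
        stringsAsFactors = FALSE))
      seq_truth <- rbind(seq_truth, data.frame(
        accession = acc, family = f, arch_class = arch_class,
        tmh_count = tmh_count,
        unit_spans = format_unit_spans(anc$units),
        is_fragment = FALSE, duplicate_of = "",
        stringsAsFactors = FALSE))
    }
  }

  n_core <- nrow(records)
  n_frag <- round(scenario$fragment_rate * n_core)
  if (n_frag > 0L) {
    idx <- sample(n_core, n_frag)
    for (j in idx) {
      full <- records$sequence[j]
      frac <- stats::runif(1, 0.20, 0.45)
      len <- max(1L, floor(frac * nchar(full)))
      start <- sample(nchar(full) - len + 1L, 1L)
      records$sequence[j] <- substr(full, start, start + len - 1L)
      seq_truth$is_fragment[j] <- TRUE
      seq_truth$unit_spans[j] <- ""
    }
  }

  n_dup <- round(scenario$duplicate_rate * n_core)
  if (n_dup > 0L) {
    src <- sample(which(!seq_truth$is_fragment), n_dup, replace = n_dup >
                    sum(!seq_truth$is_fragment))
    for (k in seq_len(n_dup)) {
      j <- src[k]
      acc <- sprintf("%s_DUP%02d", records$accession[j], k)
      records <- rbind(records, transform(records[j, ], accession = acc))
      row <- seq_truth[j, ]
      row$accession <- acc
      row$duplicate_of <- records$accession[j]
      seq_truth <- rbind(seq_truth, row)
    }
  }
  rownames(records) <- rownames(seq_truth) <- NULL

  structure(list(records = records,
                 truth = list(sequences = seq_truth, families = fam_truth),
                 scenario = scenario),
            class = "family_set")
}

format_unit_spans <- function(units) {
  paste(sprintf("%d-%d:%s", units$start, units$end, units$unit_type),
        collapse = ";")
}

#' @export
print.family_set <- function(x, ...) {
  cat("Synthetic family set:", nrow(x$records), "records,",
      x$scenario$n_families, "families\n")
  cat("  architectures:",
      paste(x$scenario$architecture_per_family, collapse = ", "), "TMHs\n")
  cat("  substitution rate:", x$scenario$substitution_rate,
      " fragments:", sum(x$truth$sequences$is_fragment),
      " duplicates:", sum(nzchar(x$truth$sequences$duplicate_of)), "\n")
  invisible(x)
}

#' Write a family set to disk
#'
#' Emits the FASTA (60-column wrap), the metadata TSV and the two truth
#' tables (per-sequence and per-family).
#'
#' @param fam a \code{family_set}.
#' @param dir output directory (created if missing).
#' @return Named vector of the written paths, invisibly.
#' @export
write_family_set <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "families.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    sequence_truth = file.path(dir, "sequence_truth.tsv"),
    family_truth = file.path(dir, "family_truth.tsv"))
  write_protein_fasta(fam$records, paths[["fasta"]])
  write_metadata_tsv(fam$records, paths[["metadata"]])
  write_tsv(fam$truth$sequences, paths[["sequence_truth"]])
  fam_rows <- do.call(rbind, lapply(fam$truth$families, function(ft)
    data.frame(family = ft$family, tmh_count = ft$tmh_count,
               arch_class = ft$arch_class,
               invariant_columns = paste(ft$invariant_columns, collapse = ","),
               covarying_pairs = paste(vapply(ft$covarying_pairs,
                 function(p) paste(p, collapse = "-"), character(1)),
                 collapse = ";"),
               stringsAsFactors = FALSE)))
  write_tsv(fam_rows, paths[["family_truth"]])
  invisible(paths)
}
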