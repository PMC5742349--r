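# Sequence similarity network: all-vs-all local alignment with
# Karlin-Altschul statistics, e-value thresholding, connected-component
# clustering and cluster labelling with taxonomic composition.

#' Scoring and statistics parameters for pairwise similarity
#'
#' @param substitution_matrix symmetric integer substitution matrix
#'   (default BLOSUM62).
#' @param gap_open,gap_extend positive gap penalties; a gap of length k
#'   costs \code{gap_open + k * gap_extend}.
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters for the gapped
#'   score distribution (defaults are the standard gapped BLOSUM62 11/1
#'   values, lambda = 0.267, K = 0.041).
#' @return List of class \code{similarity_params}.
#' @export
similarity_params <- function(substitution_matrix = blosum62_matrix(),
                              gap_open = 11, gap_extend = 1,
                              karlin_lambda = 0.267, karlin_k = 0.041) {
  stopifnot(isSymmetric(unname(substitution_matrix)),
            gap_open > 0, gap_extend > 0, karlin_lambda > 0, karlin_k > 0)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k),
            class = "similarity_params")
}

# Optimal local alignment (Smith-Waterman) of two sequences under params.
# Returns score (floored at 0, i.e. the empty local alignment is allowed),
# identities and alignment length.
local_alignment <- function(seq_a, seq_b, params) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = FALSE)
  score <- Biostrings::score(aln)
  if (score <= 0) {
    return(list(raw_score = 0, identities = 0L, alignment_length = 0L))
  }
  list(raw_score = score,
       identities = Biostrings::nmatch(aln),
       alignment_length = Biostrings::nchar(aln))
}

karlin_bitscore <- function(raw_score, params) {
  (params$karlin_lambda * raw_score - log(params$karlin_k)) / log(2)
}

#' Pairwise similarity edge between two records
#'
#' Exact Smith-Waterman local alignment with Karlin-Altschul statistics:
#' \code{bitscore = (lambda * raw - ln K) / ln 2} and
#' \code{evalue = m * n * 2^-bitscore}, where m is the query length and n
#' the total residue count of the search database.
#'
#' The pair is canonically oriented (the record with the smaller accession
#' is the query), so the result is identical in all fields whichever order
#' the two records are passed in.
#'
#' @param record_a,record_b single-row protein records (or lists with
#'   \code{accession} and \code{sequence}).
#' @param params \code{\link{similarity_params}}.
#' @param db_residues database size n for the e-value (default: length of
#'   the subject sequence).
#' @return One-row \code{data.frame}: \code{id_a}, \code{id_b} (sorted so
#'   \code{id_a < id_b}), \code{raw_score}, \code{bitscore}, \code{evalue},
#'   \code{percent_identity}, \code{alignment_length}.
#' @export
pairwise_similarity <- function(record_a, record_b,
                                params = similarity_params(),
                                db_residues = NULL) {
  check_sequence(record_a$sequence); check_sequence(record_b$sequence)
  if (record_b$accession < record_a$accession) {
    tmp <- record_a; record_a <- record_b; record_b <- tmp
  }
  if (is.null(db_residues)) db_residues <- nchar(record_b$sequence)
  aln <- local_alignment(record_a$sequence, record_b$sequence, params)
  bits <- karlin_bitscore(aln$raw_score, params)
  evalue <- nchar(record_a$sequence) * db_residues * 2^(-bits)
  pid <- if (aln$alignment_length > 0L) {
    100 * aln$identities / aln$alignment_length
  } else 0
  ids <- c(record_a$accession, record_b$accession)
  data.frame(id_a = ids[1L], id_b = ids[2L],
             raw_score = aln$raw_score, bitscore = bits, evalue = evalue,
             percent_identity = pid,
             alignment_length = aln$alignment_length,
             stringsAsFactors = FALSE)
}

#' Build a protein sequence similarity network
#'
#' All-vs-all local alignment; an edge is kept iff its e-value is at most
#' \code{evalue_cutoff}. Clusters are the connected components of the
#' kept-edge graph (singletons allowed). E-values use the query length times
#' the total residue count of the record set as the search space.
#'
#' @param records protein record \code{data.frame} (at least 2 rows).
#' @param params \code{\link{similarity_params}}.
#' @param evalue_cutoff e-value threshold (default 1e-55).
#' @return List of class \code{ssn_graph}: \code{records}, \code{edges}
#'   (kept edges), \code{all_edges}, \code{clusters} (list of accession
#'   sets), \code{membership} (accession -> cluster index), \code{labels}
#'   (filled by \code{\link{label_clusters}}).
#' @export
build_ssn <- function(records, params = similarity_params(),
                      evalue_cutoff = 1e-55) {
  if (nrow(records) < 2L) stop("need at least 2 records")
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be > 0")
  db <- sum(nchar(records$sequence))
  pairs <- utils::combn(nrow(records), 2L)
  edges <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    pairwise_similarity(records[i, ], records[j, ], params, db_residues = db)
  }))
  kept <- edges[edges$evalue <= evalue_cutoff, , drop = FALSE]
  rownames(kept) <- NULL
  g <- igraph::graph_from_data_frame(
    kept[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = records$accession,
                          taxon_group = records$taxon_group))
  comp <- igraph::components(g)
  membership <- comp$membership[records$accession]
  clusters <- split(records$accession, membership)
  names(clusters) <- NULL
  structure(list(records = records, edges = kept, all_edges = edges,
                 clusters = clusters,
                 membership = setNames(as.integer(membership),
                                       records$accession),
                 evalue_cutoff = evalue_cutoff,
                 labels = NULL, composition = NULL),
            class = "ssn_graph")
}

#' Label large clusters and report taxonomic composition
#'
#' Clusters with at least \code{min_cluster_size} members get labels
#' 1, 2, ... by decreasing size (ties broken by smallest member accession);
#' smaller clusters stay unlabelled. Per labelled cluster the fraction of
#' members in each taxonomic group is reported (fractions sum to 1).
#'
#' @param graph an \code{ssn_graph}.
#' @param min_cluster_size labelling threshold (default 10).
#' @return The graph with \code{labels} (cluster index -> label) and
#'   \code{composition} (data.frame label x taxon_group fractions) filled in.
#' @export
label_clusters <- function(graph, min_cluster_size = 10L) {
  if (min_cluster_size < 1L) stop("min_cluster_size must be >= 1")
  sizes <- lengths(graph$clusters)
  smallest <- vapply(graph$clusters, function(a) min(a), character(1))
  big <- which(sizes >= min_cluster_size)
  ord <- big[order(-sizes[big], smallest[big], method = "radix")]
  labels <- setNames(seq_along(ord), ord)  # cluster index -> label
  composition <- NULL
  tax <- setNames(graph$records$taxon_group, graph$records$accession)
  for (k in seq_along(ord)) {
    members <- graph$clusters[[ord[k]]]
    frac <- table(factor(tax[members], levels = TAXON_GROUPS)) / length(members)
    composition <- rbind(composition,
                         data.frame(label = k, size = length(members),
                                    t(as.matrix(frac)), check.names = FALSE))
  }
  graph$labels <- labels
  graph$composition <- composition
  graph
}

#' @export
print.ssn_graph <- function(x, ...) {
  cat("SSN:", nrow(x$records), "nodes,", nrow(x$edges),
      sprintf("edges (e-value <= %g),", x$evalue_cutoff),
      length(x$clusters), "clusters\n")
  if (!is.null(x$labels)) {
    cat("  labelled clusters:", length(x$labels), "\n")
  }
  invisible(x)
}

#' Write an SSN to disk
#'
#' Emits the kept-edge list as TSV, the cluster membership TSV, and the
#' graph as GraphML with \code{taxon_group} as a node attribute.
#'
#' @param graph an \code{ssn_graph}.
#' @param dir output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_ssn <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "ssn_edges.tsv"),
             clusters = file.path(dir, "ssn_clusters.tsv"),
             graphml = file.path(dir, "ssn.graphml"))
  write_tsv(graph$edges[, c("id_a", "id_b", "bitscore", "evalue",
                            "percent_identity")], paths[["edges"]])
  lab <- rep(NA_integer_, length(graph$membership))
  if (!is.null(graph$labels)) {
    lab <- unname(graph$labels[as.character(graph$membership)])
  }
  write_tsv(data.frame(accession = names(graph$membership),
                       cluster = unname(graph$membership), label = lab),
            paths[["clusters"]])
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("id_a", "id_b", "bitscore", "evalue")],
    directed = FALSE,
    vertices = data.frame(name = graph$records$accession,
                          taxon_group = graph$records$taxon_group))
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  invisible(paths)
}
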