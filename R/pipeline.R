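# End-to-end orchestration: one validated config drives the stages
# screen -> ssn -> architecture -> msa_profile -> coevolution -> phylo
# (energetics independent), with a JSON run report for provenance, plus the
# packaged mutation-outcome table and its summary operation.

#' Default pipeline configuration
#'
#' Nested named list with one entry per stage; every key is validated, and
#' unknown keys are rejected by \code{\link{run_pipeline}}.
#'
#' @return Named list of stage parameter lists.
#' @export
default_config <- function() {
  list(
    input = list(fasta = NULL, metadata = NULL, out_dir = "pipeline_out"),
    stages = list(screen = TRUE, ssn = TRUE, architecture = TRUE,
                  msa_profile = TRUE, coevolution = TRUE, phylo = TRUE,
                  energetics = FALSE),
    screen = list(min_tmh = 3, fragment_max_fraction = 0.5,
                  motif_mode = "strict_PQ"),
    ssn = list(evalue_cutoff = 1e-55, min_cluster_size = 10),
    architecture = list(fusion_identity = 70, references_fasta = NULL),
    msa_profile = list(reference = NULL, weighting = "none"),
    coevolution = list(mi_threshold = 6.5, n_shuffles = 100, seed = 7,
                       max_columns = 150),
    phylo = list(n_replicates = 100, seed = 7, model = "p"),
    energetics = list(table = NULL, gamma = 0.0054, beta = 0.92, tds = 0)
  )
}

# Recursively overlay user values on the defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    } else user[[k]]
  }
  defaults
}

#' Validate a pipeline config against the defaults
#'
#' @param config partial config (nested named list); missing keys take their
#'   defaults, unknown keys raise an error naming the key.
#' @return The completed config.
#' @export
validate_config <- function(config = list()) {
  merge_config(default_config(), config)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in fixed order on the input FASTA (each stage
#' consuming the screen survivors), writes every stage's tables under
#' \code{out_dir}, and returns (and writes) a JSON run report recording the
#' full config, per-stage parameters, output paths and row counts. With a
#' fixed config the run is deterministic.
#'
#' @param config nested config list (see \code{\link{default_config}});
#'   \code{input$fasta} is required when any sequence stage is enabled.
#' @param records optionally, protein records passed directly instead of
#'   \code{input$fasta}.
#' @return The run report (list), invisibly; also written as
#'   \code{report.json} in \code{out_dir}.
#' @export
run_pipeline <- function(config = list(), records = NULL) {
  cfg <- validate_config(config)
  out_dir <- cfg$input$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("sweetR")),
                 config = cfg, seed = cfg$coevolution$seed,
                 stages = list(), outputs = list())
  log_stage <- function(name, params, outputs, rows) {
    message("[", name, "] ", rows, " rows")
    report$stages[[name]] <<- list(params = params, rows = rows)
    report$outputs[[name]] <<- outputs
  }
  seq_stages <- c("screen", "ssn", "architecture", "msa_profile",
                  "coevolution", "phylo")
  any_seq <- any(unlist(cfg$stages[seq_stages]))
  if (any_seq) {
    if (is.null(records)) {
      if (is.null(cfg$input$fasta)) stop("input$fasta is required")
      records <- read_protein_fasta(cfg$input$fasta, cfg$input$metadata)
    }
  }

  passed <- records
  if (isTRUE(cfg$stages$screen)) {
    scr <- screen_records(records, min_tmh = cfg$screen$min_tmh,
                          fragment_max_fraction =
                            cfg$screen$fragment_max_fraction,
                          motif_mode = cfg$screen$motif_mode)
    passed <- scr$passed
    f <- file.path(out_dir, "screen_report.tsv")
    write_tsv(scr$report, f)
    ff <- file.path(out_dir, "screened.fasta")
    write_protein_fasta(passed, ff)
    log_stage("screen", cfg$screen, c(f, ff), nrow(scr$report))
  }
  if (isTRUE(cfg$stages$ssn)) {
    if (nrow(passed) < 2L) stop("ssn stage needs at least 2 screened records")
    graph <- build_ssn(passed, evalue_cutoff = cfg$ssn$evalue_cutoff)
    graph <- label_clusters(graph, cfg$ssn$min_cluster_size)
    paths <- write_ssn(graph, out_dir)
    log_stage("ssn", cfg$ssn, unname(paths), nrow(graph$edges))
  }
  if (isTRUE(cfg$stages$architecture)) {
    calls <- lapply(passed$sequence, architecture_call)
    arch <- data.frame(
      accession = passed$accession,
      tmh_count = vapply(calls, `[[`, integer(1), "tmh_count"),
      arch_class = vapply(calls, `[[`, character(1), "arch_class"),
      unit_spans = vapply(calls, function(x)
        if (is.null(x$units)) "" else format_unit_spans(x$units),
        character(1)),
      stringsAsFactors = FALSE)
    f <- file.path(out_dir, "architecture.tsv")
    write_tsv(arch, f)
    log_stage("architecture", cfg$architecture, f, nrow(arch))
  }
  msa <- NULL
  if (isTRUE(cfg$stages$msa_profile)) {
    msa <- align_msa(passed)
    cons <- conservation_profile(msa, weighting = cfg$msa_profile$weighting)
    if (!is.null(cfg$msa_profile$reference)) {
      rmap <- map_reference(msa, cfg$msa_profile$reference)
      ref_pos <- rep(NA_integer_, msa$n_columns)
      ref_pos[as.integer(names(rmap$column_to_residue))] <-
        rmap$column_to_residue
      cons$ref_position <- ref_pos
    }
    fa <- file.path(out_dir, "alignment.fasta")
    write_msa_fasta(msa, fa)
    f <- file.path(out_dir, "conservation.tsv")
    write_tsv(as.data.frame(cons), f)
    log_stage("msa_profile", cfg$msa_profile, c(fa, f), nrow(cons))
  }
  if (isTRUE(cfg$stages$coevolution)) {
    if (is.null(msa)) msa <- align_msa(passed)
    cols <- seq_len(min(msa$n_columns, cfg$coevolution$max_columns))
    net <- mi_network(msa, columns = cols,
                      mi_threshold = cfg$coevolution$mi_threshold,
                      n_shuffles = cfg$coevolution$n_shuffles,
                      seed = cfg$coevolution$seed)
    f <- file.path(out_dir, "mi_pairs.tsv")
    write_tsv(net$significant, f)
    f2 <- file.path(out_dir, "cmi.tsv")
    write_tsv(data.frame(column = seq_along(net$cmi), cmi = net$cmi), f2)
    log_stage("coevolution", cfg$coevolution, c(f, f2),
              nrow(net$significant))
  }
  if (isTRUE(cfg$stages$phylo)) {
    if (is.null(msa)) msa <- align_msa(passed)
    tree <- bootstrap_nj(msa, n_replicates = cfg$phylo$n_replicates,
                         seed = cfg$phylo$seed, model = cfg$phylo$model)
    f <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, f)
    log_stage("phylo", cfg$phylo, f, length(tree$tip.label))
  }
  if (isTRUE(cfg$stages$energetics)) {
    if (is.null(cfg$energetics$table)) stop("energetics stage needs a table")
    comp <- read_energy_table(cfg$energetics$table)
    rows <- energy_favorability(
      combine_energy(comp, gamma = cfg$energetics$gamma,
                     beta = cfg$energetics$beta, tds = cfg$energetics$tds))
    f <- file.path(out_dir, "energy_decomposition.tsv")
    write_tsv(rows, f)
    log_stage("energetics", cfg$energetics, f, nrow(rows))
  }
  check_report_schema(report)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(report)
}

# Validate the run report against the packaged schema (required keys).
check_report_schema <- function(report) {
  schema <- jsonlite::read_json(system.file("extdata",
                                            "run_report_schema.json",
                                            package = "sweetR"))
  miss <- setdiff(unlist(schema$required), names(report))
  if (length(miss)) stop("run report missing required field(s): ",
                         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Load the packaged mutation-outcome table
#'
#' The 19 experimentally characterised highly conserved SWEET residues with
#' their relative conservation values, OsSWEET2b/AtSWEET1 positions,
#' substitutions tested and impact on glucose transport activity
#' (\code{Abolish}, \code{Reduce} or \code{No effect}).
#'
#' @return \code{data.frame} with 19 rows.
#' @export
load_mutation_table <- function() {
  read_tsv(system.file("extdata", "mutation_outcomes.tsv",
                       package = "sweetR"))
}

#' Load the packaged residue-region annotation
#'
#' Structural region labels (extrafacial gate, substrate binding pocket,
#' intrafacial gate) for the conserved AtSWEET1 residues; used only to label
#' outputs.
#'
#' @return \code{data.frame} with columns \code{region}, \code{residue_at},
#'   \code{amino_acid}.
#' @export
load_residue_regions <- function() {
  read_tsv(system.file("extdata", "residue_regions.tsv", package = "sweetR"))
}

#' Summarise mutation outcomes by impact
#'
#' @param rows mutation table (default: the packaged fixture).
#' @param impact_filter one of \code{"Abolish"}, \code{"Reduce"},
#'   \code{"No effect"}.
#' @return List with \code{count} and \code{residues} (AtSWEET1 labels like
#'   \code{"S54"}).
#' @export
summarize_mutation_table <- function(rows = load_mutation_table(),
                                     impact_filter) {
  allowed <- c("Abolish", "Reduce", "No effect")
  if (!impact_filter %in% allowed) {
    stop("unknown impact label: ", impact_filter)
  }
  hit <- rows[rows$impact == impact_filter, , drop = FALSE]
  list(count = nrow(hit),
       residues = paste0(hit$residue_at, hit$position_at))
}
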