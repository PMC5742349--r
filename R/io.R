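# FASTA and metadata I/O, backed by Biostrings.

#' Read protein records from FASTA (plus optional metadata TSV)
#'
#' @param fasta_file path to a FASTA file of amino-acid sequences.
#' @param metadata_file optional TSV with columns \code{accession} and
#'   \code{taxon_group}; records without a metadata row get
#'   \code{taxon_group = "unknown"}.
#' @return A protein record \code{data.frame} (see \code{\link{protein_records}}).
#' @export
read_protein_fasta <- function(fasta_file, metadata_file = NULL) {
  aa <- Biostrings::readAAStringSet(fasta_file)
  full <- names(aa)
  accession <- sub("\\s.*$", "", full)
  description <- sub("^\\S+\\s*", "", full)
  rec <- protein_records(accession, toupper(as.character(aa)),
                         description = description)
  if (!is.null(metadata_file)) {
    meta <- utils::read.delim(metadata_file, stringsAsFactors = FALSE)
    stopifnot(all(c("accession", "taxon_group") %in% names(meta)))
    idx <- match(rec$accession, meta$accession)
    hit <- !is.na(idx)
    rec$taxon_group[hit] <- meta$taxon_group[idx[hit]]
  }
  rec
}

#' Write protein records to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param records protein record \code{data.frame}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_protein_fasta <- function(records, file) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- ifelse(nzchar(records$description),
                      paste(records$accession, records$description),
                      records$accession)
  Biostrings::writeXStringSet(aa, file, width = 60L)
  invisible(file)
}

#' Write record metadata as TSV
#' @param records protein record \code{data.frame}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_metadata_tsv <- function(records, file) {
  utils::write.table(records[, c("accession", "taxon_group")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Shared TSV writer with fixed conventions (header, no quoting).
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_tsv <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
}
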