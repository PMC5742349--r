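# Amino-acid constants shared across modules.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, in alphabetical order.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices used by the sliding-window transmembrane
#' helix predictor. Positive values are hydrophobic.
#' @export
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# BLOSUM62 restricted to the 20 standard residues, taken from Biostrings.
blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  storage.mode(m) <- "integer"
  m
})

#' Substitution matrix accessor
#'
#' Returns the BLOSUM62 substitution matrix restricted to the 20 standard
#' amino acids (symmetric integer matrix).
#' @return A 20 x 20 integer matrix with residue dimnames.
#' @export
blosum62_matrix <- function() blosum62

# Min-max normalization of a substitution matrix to [0, 1]; used by the
# column-conservation score.
normalize_submat <- function(mat = blosum62_matrix()) {
  (mat - min(mat)) / (max(mat) - min(mat))
}

#' Validate a protein sequence string
#'
#' @param sequence character scalar, uppercase amino acids.
#' @param allow_x allow the ambiguity code X.
#' @return The sequence, invisibly; errors on invalid characters.
#' @keywords internal
check_sequence <- function(sequence, allow_x = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  ok <- c(AA_ALPHABET, if (allow_x) "X")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), ok)
  if (length(bad)) {
    stop("sequence contains invalid characters: ", paste(bad, collapse = ", "))
  }
  invisible(sequence)
}

# Split a sequence into a character vector of residues.
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

#' Taxonomic groups recognised in record metadata
#' @export
TAXON_GROUPS <- c("green_plants", "chlorophyta", "other_algae", "oomycota",
                  "metazoa", "fungi", "protista", "bacteria", "archaea",
                  "unknown")

#' Construct a set of protein records
#'
#' A protein record set is a plain \code{data.frame} with columns
#' \code{accession}, \code{description}, \code{taxon_group} and
#' \code{sequence}. Accessions must be unique; sequences are uppercase
#' strings over the 20 standard residues (plus \code{X}).
#'
#' @param accession character vector of unique identifiers.
#' @param sequence character vector of sequences.
#' @param taxon_group taxonomic group per record (see \code{TAXON_GROUPS}).
#' @param description free-text description per record.
#' @return A \code{data.frame} of protein records.
#' @export
protein_records <- function(accession, sequence,
                            taxon_group = "unknown", description = "") {
  stopifnot(length(accession) == length(sequence))
  if (anyDuplicated(accession)) {
    stop("duplicate accession in input: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  }
  taxon_group <- rep_len(as.character(taxon_group), length(accession))
  bad_tax <- setdiff(unique(taxon_group), TAXON_GROUPS)
  if (length(bad_tax)) stop("unknown taxon_group: ", paste(bad_tax, collapse = ", "))
  invisible(lapply(sequence, check_sequence))
  data.frame(
    accession = as.character(accession),
    description = rep_len(as.character(description), length(accession)),
    taxon_group = taxon_group,
    sequence = as.character(sequence),
    stringsAsFactors = FALSE
  )
}
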