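# Readers and writers for the plain-text dialects the pipeline consumes.

#' Read a protein sequence from a FASTA file
#'
#' @param file path to a FASTA file; the first record is used.
#' @return upper-case one-letter sequence string.
#' @export
read_sequence <- function(file) {
  seqs <- seqinr::read.fasta(file, seqtype = "AA", as.string = TRUE)
  if (length(seqs) == 0) abort("empty FASTA file", "hdx_invalid_parameters")
  toupper(as.character(seqs[[1]]))
}

#' Read a long-format decay table
#'
#' Expects tab- or comma-separated columns `residue`, `replicate`,
#' `time_min`, `volume`.
#'
#' @param file path.
#' @return data.frame.
#' @export
read_decay_table <- function(file) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  utils::read.table(file, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}

#' Read a CD unfolding table
#'
#' Expects columns `conc_M`, `theta_mrd`.
#'
#' @param file path.
#' @return data.frame.
#' @export
read_unfolding_table <- function(file) read_decay_table(file)

#' Write a data frame as TSV
#'
#' @param x data.frame.
#' @param file path.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", row.names = FALSE, quote = FALSE)
}
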