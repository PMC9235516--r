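#' Read sequences from a FASTA file
#'
#' Standard multi-record FASTA via Biostrings; sequences are upper-cased.
#'
#' @param path FASTA file path.
#' @param id optional record id; by default all records are returned.
#' @return A named character vector of nucleotide strings.
#' @export
read_fasta <- function(path, id = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  if (!is.null(id)) {
    if (!id %in% names(out)) {
      stop("record '", id, "' not found in ", path, call. = FALSE)
    }
    out <- out[id]
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of nucleotide strings, or a list of
#'   [kmer_seq] objects carrying source strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs)) {
    seqs <- vapply(seqs, function(s) {
      s <- as_kmer_seq(s, "seqs[[i]]")
      if (is.null(s$source)) {
        stop("kmer_seq without a source string cannot be written as FASTA",
             call. = FALSE)
      }
      s$source
    }, character(1))
  }
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' @param x data frame or tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
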