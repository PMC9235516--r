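#' Construct a k-mer sequence from an ordered vector of k-mers
#'
#' A `kmer_seq` is an ordered sequence of `L` length-`k` strings over
#' `{A,C,G,T}`.  Most objects are built from a nucleotide string with
#' [kmerize()], in which case consecutive k-mers overlap by `k - 1`
#' characters; generators for structured layouts may instead supply the
#' k-mers directly (no underlying contiguous string), which the estimator and
#' all bias machinery support because they depend only on k-mer identity.
#'
#' @param kmers character vector of k-mers, all of the same length.
#' @param source optional originating nucleotide string.
#' @return An object of class `kmer_seq` with fields `kmers`, `k`, `L`,
#'   `duplicate_free` and `source`.
#' @seealso [kmerize()]
#' @export
kmer_seq <- function(kmers, source = NULL) {
  if (!is.character(kmers) || length(kmers) < 1) {
    stop("`kmers` must be a non-empty character vector", call. = FALSE)
  }
  k <- nchar(kmers[1])
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (any(nchar(kmers) != k)) {
    stop("all k-mers must have the same length", call. = FALSE)
  }
  structure(
    list(
      kmers = kmers,
      k = as.integer(k),
      L = length(kmers),
      duplicate_free = !anyDuplicated(kmers),
      source = source
    ),
    class = "kmer_seq"
  )
}

#' Split a nucleotide string into its ordered k-mers
#'
#' Positions are 0-based: `A_0` is the first k-mer and `A_{L-1}` the last,
#' with `L = nchar(seq) - k + 1`.
#'
#' @param seq a single nucleotide string over `{A,C,G,T}`.
#' @param k k-mer size (integer >= 2).
#' @return A [kmer_seq] with `source = seq`.
#' @examples
#' kmerize("ACGT", 2)$kmers # "AC" "CG" "GT"
#' @export
kmerize <- function(seq, k) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq)) {
    stop("`seq` must be a single string", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 2) stop("k must be an integer >= 2", call. = FALSE)
  n <- nchar(seq)
  if (n < k) stop("sequence is shorter than k", call. = FALSE)
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains characters outside {A,C,G,T}; ",
         "ambiguity codes such as N are not sketchable", call. = FALSE)
  }
  L <- n - k + 1
  kmer_seq(substring(seq, seq_len(L), seq_len(L) + k - 1L), source = seq)
}

is_kmer_seq <- function(x) inherits(x, "kmer_seq")

as_kmer_seq <- function(x, arg = "x") {
  if (!is_kmer_seq(x)) {
    stop("`", arg, "` must be a kmer_seq (see kmerize())", call. = FALSE)
  }
  x
}

check_same_k <- function(A, B) {
  if (A$k != B$k) {
    stop("A and B have different k-mer sizes (", A$k, " vs ", B$k, ")",
         call. = FALSE)
  }
  invisible(A$k)
}

#' @export
print.kmer_seq <- function(x, ...) {
  cat(sprintf(
    "<kmer_seq> L = %d k-mers, k = %d, %s%s\n", x$L, x$k,
    if (x$duplicate_free) "duplicate-free" else "with duplicate k-mers",
    if (is.null(x$source)) " (no source string)" else ""
  ))
  shown <- utils::head(x$kmers, 6)
  cat("  ", paste(shown, collapse = " "),
      if (x$L > 6) "..." else "", "\n", sep = "")
  invisible(x)
}
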