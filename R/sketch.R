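#' Hash k-mers to the unit interval
#'
#' Deterministic seeded hashing standing in for the idealized hash that maps
#' every k-mer to an independent uniform value in `[0, 1)`.  The value at a
#' position depends only on the k-mer content and the seed, so equal k-mers
#' in different sequences always receive equal values, and changing the seed
#' decorrelates the values (a *hash replicate*).  64-bit mixing makes
#' collisions among realistic k-mer sets vanishingly unlikely.
#'
#' @param x a [kmer_seq] or character vector of k-mers.
#' @param seed integer hash seed.
#' @return Numeric vector of values in `[0, 1)`, one per k-mer.
#' @export
hash_kmers <- function(x, seed = 1) {
  kmers <- if (is_kmer_seq(x)) x$kmers else x
  if (!is.character(kmers)) stop("`x` must be a kmer_seq or character vector",
                                 call. = FALSE)
  hash_kmers_cpp(kmers, as.double(seed))
}

#' Derive a reproducible list of hash seeds from a master seed
#'
#' Counter-mode derivation: the i-th seed is a 53-bit mix of
#' `master_seed` and `i`, so the full seed list is reproducible from
#' `master_seed` alone.
#'
#' @param master_seed integer master seed.
#' @param n number of seeds.
#' @return Numeric vector of `n` integer-valued seeds.
#' @export
derive_hash_seeds <- function(master_seed, n) {
  derive_seeds_cpp(as.double(master_seed), as.integer(n))
}

#' Minimizer sketch of a k-mer sequence
#'
#' Position `p` is selected iff it attains the minimum hash value in at least
#' one window of `w` consecutive positions; the sketch is the set of k-mers at
#' the selected positions.  Ties (possible only through hash collisions) are
#' broken toward the smaller position; the underlying theory assumes a
#' collision-free real-valued hash.
#'
#' @param ks a [kmer_seq] with `L >= w`.
#' @param w window size in k-mers (>= 1); `w = 1` selects every position.
#' @param seed hash seed, ignored when `hashes` is given.
#' @param hashes optional pre-computed hash values (length `L`).
#' @return An object of class `minimizer_sketch`: `positions` (0-based,
#'   sorted), `members` (the distinct selected k-mers), `kmers`, `hashes`,
#'   `w`, `L`, `k`.
#' @export
minimizer_sketch <- function(ks, w, seed = 1, hashes = NULL) {
  ks <- as_kmer_seq(ks, "ks")
  w <- as.integer(w)
  if (is.na(w) || w < 1) stop("w must be an integer >= 1", call. = FALSE)
  if (ks$L < w) stop("sequence has fewer than w k-mers", call. = FALSE)
  if (!ks$duplicate_free) {
    warning("sequence is not duplicate-free; sketch uses set semantics ",
            "and theoretical guarantees do not apply", call. = FALSE)
  }
  if (is.null(hashes)) hashes <- hash_kmers(ks, seed)
  if (length(hashes) != ks$L) stop("hashes must have length L", call. = FALSE)
  pos <- minimizer_positions_cpp(as.numeric(hashes), w)
  structure(
    list(
      positions = pos,
      members = unique(ks$kmers[pos + 1L]),
      kmers = ks$kmers[pos + 1L],
      hashes = hashes[pos + 1L],
      w = w, L = ks$L, k = ks$k
    ),
    class = "minimizer_sketch"
  )
}

#' @export
print.minimizer_sketch <- function(x, ...) {
  cat(sprintf(
    "<minimizer_sketch> %d selected positions of L = %d (w = %d, k = %d)\n",
    length(x$positions), x$L, x$w, x$k
  ))
  invisible(x)
}

#' Tabulate a minimizer sketch
#'
#' @param ms a `minimizer_sketch`.
#' @return A tibble with columns `position` (0-based), `kmer`, `hash_value`,
#'   suitable for TSV export.
#' @export
sketch_table <- function(ms) {
  stopifnot(inherits(ms, "minimizer_sketch"))
  tibble::tibble(position = ms$positions, kmer = ms$kmers,
                 hash_value = ms$hashes)
}

#' Charged index of a position
#'
#' Every minimizer is attributed to ("charges") exactly one window: `p`
#' charges index `i` (the window starting at `i + 1`) iff
#' `i` lies in `[max(-1, p - w), min(p - 1, L - w - 1)]`, `a_p` is the minimum
#' of the hash values over `[i + 1, i + w]`, and either `i = max(-1, p - w)`
#' or `a_i < a_p`.  A position charges an index iff it is a minimizer, and the
#' charged index is then unique — this is what makes minimizer events
#' decomposable into disjoint sign patterns.
#'
#' @param p 0-based position in `[0, L - 1]`.
#' @param hashes numeric vector of hash values (length `L`).
#' @param w window size (>= 1).
#' @return The charged index in `[-1, L - w - 1]`, or `NA` if `p` is not a
#'   minimizer.
#' @export
charges <- function(p, hashes, w) {
  p <- as.integer(p)
  L <- length(hashes)
  if (is.na(p) || p < 0 || p > L - 1) stop("p must be in [0, L-1]", call. = FALSE)
  charge_index_cpp(as.numeric(hashes), p, as.integer(w))[1]
}

# all indices charged by p (used by uniqueness property tests)
charges_all <- function(p, hashes, w) {
  charge_index_all_cpp(as.numeric(hashes), as.integer(p), as.integer(w))
}

#' True Jaccard similarity of two k-mer spectra
#'
#' `J(A, B) = |Sp_k(A) n Sp_k(B)| / |Sp_k(A) u Sp_k(B)|`.  Depends only on
#' the two k-mer *sets*, never on where the shared k-mers sit — which is
#' exactly why a layout-sensitive estimator of it can be biased.
#'
#' @param A,B [kmer_seq] objects with the same `k`.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
true_jaccard <- function(A, B) {
  A <- as_kmer_seq(A, "A"); B <- as_kmer_seq(B, "B")
  check_same_k(A, B)
  if (!A$duplicate_free || !B$duplicate_free) {
    warning("sequences are not duplicate-free; using set semantics",
            call. = FALSE)
  }
  sa <- unique(A$kmers); sb <- unique(B$kmers)
  i <- sum(sa %in% sb)
  u <- length(sa) + length(sb) - i
  if (u == 0) return(0)
  i / u
}

#' Minimizer Jaccard estimator
#'
#' The Jaccard similarity of the two minimizer sketches computed under one
#' shared hash assignment:
#' `J_hat = |MS(A; w) n MS(B; w)| / |MS(A; w) u MS(B; w)|`.
#'
#' @param A,B [kmer_seq] objects with the same `k` and `L >= w`.
#' @param w window size in k-mers.
#' @param seed hash seed shared by both sketches.
#' @return The estimate in `[0, 1]`.
#' @seealso [monte_carlo()] to average the estimator over many hash seeds.
#' @export
jaccard_estimate <- function(A, B, w, seed = 1) {
  A <- as_kmer_seq(A, "A"); B <- as_kmer_seq(B, "B")
  check_same_k(A, B)
  res <- mc_replicates_cpp(A$kmers, B$kmers, as.integer(w),
                           as.double(seed))
  res[1, "J_hat"][[1]]
}
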