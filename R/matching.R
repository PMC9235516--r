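#' The k-mer matching between two duplicate-free sequences
#'
#' The set of position pairs `(p, q)` with `A_p = B_q`.  Because both
#' sequences are duplicate-free this relation is a matching: each position
#' appears in at most one pair.  The matching's *layout* (not just its size)
#' is what determines the expected minimizer-sketch intersection.
#'
#' @param A,B duplicate-free [kmer_seq] objects with the same `k`.
#' @return An object of class `kmer_matching`: tibble `pairs` (0-based
#'   columns `p`, `q`, plus `kmer`), counts `I` (shared k-mers),
#'   `U = L_A + L_B - I`, `J = I / U`, lengths `L_A`, `L_B`, and the match
#'   vectors `m_A`, `m_B` (0-based matched position or `NA`).
#' @export
kmer_matching <- function(A, B) {
  A <- as_kmer_seq(A, "A"); B <- as_kmer_seq(B, "B")
  check_same_k(A, B)
  if (!A$duplicate_free || !B$duplicate_free) {
    stop("k-mer matching requires duplicate-free sequences", call. = FALSE)
  }
  m <- match(A$kmers, B$kmers)
  p <- which(!is.na(m)) - 1L
  q <- m[!is.na(m)] - 1L
  I <- length(p)
  U <- A$L + B$L - I
  m_B <- match(B$kmers, A$kmers) - 1L
  structure(
    list(
      pairs = tibble::tibble(p = p, q = q, kmer = A$kmers[p + 1L]),
      I = I, U = U, J = if (U > 0) I / U else 0,
      L_A = A$L, L_B = B$L, k = A$k,
      m_A = m - 1L, m_B = m_B
    ),
    class = "kmer_matching"
  )
}

#' @export
print.kmer_matching <- function(x, ...) {
  cat(sprintf(
    "<kmer_matching> I = %d, U = %d, J = %.4f (L_A = %d, L_B = %d, k = %d)\n",
    x$I, x$U, x$J, x$L_A, x$L_B, x$k
  ))
  invisible(x)
}

as_matching <- function(A, B, matching = NULL) {
  if (is.null(matching)) matching <- kmer_matching(A, B)
  stopifnot(inherits(matching, "kmer_matching"))
  matching
}

# 0-based match vector with -1 for unmatched, as the C++ kernels expect
match_vec_c <- function(matching) {
  m <- matching$m_A
  m[is.na(m)] <- -1L
  as.integer(m)
}

#' Are two sequences padded?
#'
#' Padded means the boundary windows carry no shared content: no matched
#' position falls within the first or last `w` k-mers of either sequence.
#' This is the hash-independent sufficient condition (no shared k-mers in the
#' boundary windows implies no shared minimizers there, whatever the hash).
#'
#' @param A,B duplicate-free [kmer_seq] objects.
#' @param w window size.
#' @param matching optional pre-computed [kmer_matching()].
#' @return `TRUE` iff no matched pair sits in a boundary window.
#' @export
is_padded <- function(A, B, w, matching = NULL) {
  matching <- as_matching(A, B, matching)
  w <- as.integer(w)
  p <- matching$pairs$p; q <- matching$pairs$q
  !any(p < w | p >= matching$L_A - w | q < w | q >= matching$L_B - w)
}

#' Are two sequences sparsely matched?
#'
#' A padded pair is sparsely matched when every shared k-mer is isolated:
#' for each matched pair `(p, q)`, none of the `2w` k-mers within `w`
#' positions of `p` in `A` occurs in `B`'s spectrum, and symmetrically for
#' `q` in `B`.  Shared k-mers then never compete inside one window, which is
#' the regime of spurious matches between unrelated sequences.
#'
#' @inheritParams is_padded
#' @return `TRUE` iff the pair is padded and every match is isolated.
#' @export
is_sparsely_matched <- function(A, B, w, matching = NULL) {
  matching <- as_matching(A, B, matching)
  if (!is_padded(A, B, w, matching)) return(FALSE)
  w <- as.integer(w)
  isolated <- function(pos, m, L) {
    for (p in pos) {
      lo <- max(0L, p - w); hi <- min(L - 1L, p + w)
      nb <- setdiff(lo:hi, p)
      if (any(!is.na(m[nb + 1L]))) return(FALSE)
    }
    TRUE
  }
  isolated(matching$pairs$p, matching$m_A, matching$L_A) &&
    isolated(matching$pairs$q, matching$m_B, matching$L_B)
}

#' Tabulate a k-mer matching for export
#'
#' @param matching a [kmer_matching()].
#' @return The `pairs` tibble (columns `p`, `q`, `kmer`).
#' @export
matching_table <- function(matching) {
  stopifnot(inherits(matching, "kmer_matching"))
  matching$pairs
}
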