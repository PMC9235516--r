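#' Random duplicate-free nucleotide sequence
#'
#' Draws a nucleotide string whose `L` k-mers are pairwise distinct.  The
#' default strategy is randomized extension with backtracking on the
#' order-(k-1) de Bruijn graph; for dense draws (`L` close to `4^k`, where
#' backtracking can thrash) a random Eulerian circuit of the full de Bruijn
#' graph is built instead (feasible for `k <= 12`) and a window of it is
#' taken — every contiguous window of an Eulerian circuit is duplicate-free.
#' Randomness is governed by R's RNG (`set.seed()`).
#'
#' @param L number of k-mers (`1 <= L <= 4^k`).
#' @param k k-mer size (`2 <= k <= 31`).
#' @param method `"auto"`, `"backtrack"` or `"euler"`.
#' @param max_backtrack backtracking budget before a restart.
#' @return A duplicate-free [kmer_seq] with its source string.
#' @export
random_duplicate_free <- function(L, k, method = c("auto", "backtrack", "euler"),
                                  max_backtrack = NULL) {
  method <- match.arg(method)
  L <- as.integer(L); k <- as.integer(k)
  if (k < 2 || k > 31) stop("k must be in [2, 31]", call. = FALSE)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (log(L) > k * log(4)) stop("L exceeds 4^k: infeasible", call. = FALSE)
  if (is.null(max_backtrack)) max_backtrack <- max(1e6, 200 * L)
  dense <- k <= 12 && L > 0.4 * 4^k
  use_euler <- method == "euler" || (method == "auto" && dense)
  s <- if (use_euler) {
    euler_dupfree_cpp(L, k, cpp_seed())
  } else {
    tryCatch(
      random_dupfree_cpp(L, k, cpp_seed(), max_backtrack),
      error = function(e) {
        if (method == "auto" && k <= 12) euler_dupfree_cpp(L, k, cpp_seed())
        else stop(e)
      }
    )
  }
  ks <- kmerize(s, k)
  if (!ks$duplicate_free) stop("internal error: generated duplicates")
  ks
}

#' Unrelated sequence pair with a target Jaccard
#'
#' Two independent random duplicate-free sequences of
#' `L = floor(2 j 4^k / (j + 1))` k-mers each.  `L` is chosen so that for
#' uniformly drawn spectra the expected Jaccard equals the target `j`; the
#' realized Jaccard concentrates tightly around `j`.  This models spurious
#' k-mer sharing between biologically unrelated sequences across the whole
#' Jaccard range.
#'
#' @param j target Jaccard in `(0, 1]`.
#' @param k k-mer size.
#' @param w optional window size, only used to warn when `L < 7(w+1)`.
#' @param j_tol if non-`NULL`, redraw until `|J - j| <= j_tol`.
#' @param max_tries redraw limit.
#' @return A list with `A`, `B` ([kmer_seq]), `j`, `L`, the realized `J` and
#'   the number of `tries`.
#' @export
unrelated_pair <- function(j, k, w = NULL, j_tol = NULL, max_tries = 50) {
  if (j <= 0 || j > 1) stop("j must be in (0, 1]", call. = FALSE)
  k <- as.integer(k)
  L <- floor(2 * j * 4^k / (j + 1))
  if (L < 1) stop("target j and k give L < 1: infeasible", call. = FALSE)
  if (!is.null(w) && L < 7 * (w + 1)) {
    warning("L < 7(w+1): below the regime assumed by the bias theory",
            call. = FALSE)
  }
  for (tries in seq_len(max_tries)) {
    A <- random_duplicate_free(L, k)
    B <- random_duplicate_free(L, k)
    J <- true_jaccard(A, B)
    if (is.null(j_tol) || abs(J - j) <= j_tol) {
      return(list(A = A, B = B, j = j, L = L, J = J, tries = tries))
    }
  }
  stop("failed to hit |J - j| <= ", j_tol, " in ", max_tries, " draws",
       call. = FALSE)
}

#' Related sequence pair under per-position mutation
#'
#' Sweeps along the base sequence deciding at every nucleotide position with
#' probability `r1` whether to substitute, choosing the new nucleotide
#' uniformly from those that do not create a duplicate k-mer (positions where
#' all three alternatives would are left unmutated and counted as skips;
#' mutations apply left-to-right against the partially mutated string, so the
#' duplicate-free check always reflects the final sequence).
#'
#' @param base a duplicate-free [kmer_seq] carrying its source string
#'   (e.g. from [random_duplicate_free()] or [kmerize()]).
#' @param r1 per-position substitution probability in `[0, 1]`.
#' @return A list with `A` (the base), `B` (mutated, duplicate-free), `r1`,
#'   `n_mutated` and `n_skipped`.
#' @export
related_pair <- function(base, r1) {
  base <- as_kmer_seq(base, "base")
  if (is.null(base$source)) {
    stop("`base` must carry a source nucleotide string", call. = FALSE)
  }
  if (!base$duplicate_free) stop("`base` must be duplicate-free", call. = FALSE)
  if (r1 < 0 || r1 > 1) stop("r1 must be in [0, 1]", call. = FALSE)
  res <- related_mutate_cpp(base$source, base$k, r1, cpp_seed())
  list(A = base, B = kmerize(res$sequence, base$k), r1 = r1,
       n_mutated = res$n_mutated, n_skipped = res$n_skipped)
}

#' Deterministic-gap mutation pair
#'
#' A pair identical except for substitutions at nucleotide positions
#' `k - 1 + i g` for `i = 0, ..., ell` (0-based), with `L = ell * g + k`
#' k-mers.  Each substitution destroys exactly `k` k-mer matches, so with
#' isolated mutations (`g > w + 2k`) the matching consists of `ell` identical
#' runs and `I = L - (ell + 1) k`, making this the layout with a closed-form
#' bias ([gap_layout_bias()]).  Draws are rejected until the mutated sequence
#' is duplicate-free and the matching is exactly the intended one (accidental
#' extra matches are rare for realistic `k`).
#'
#' @param ell number of gaps (>= 1).
#' @param g gap length in nucleotides (`> w + 2k` for the target `w`).
#' @param k k-mer size.
#' @param w optional window size used to validate `g`.
#' @param max_tries rejection limit.
#' @return A list with `A`, `B`, `ell`, `g`, `k`, `L`, `I`, `J` and the
#'   0-based mutated nucleotide `positions`.
#' @export
deterministic_gap_pair <- function(ell, g, k, w = NULL, max_tries = 50) {
  ell <- as.integer(ell); g <- as.integer(g); k <- as.integer(k)
  if (ell < 1) stop("ell must be >= 1", call. = FALSE)
  if (!is.null(w)) {
    w <- as.integer(w)
    if (w < 2 || w >= k) stop("need 2 <= w < k", call. = FALSE)
    if (g <= w + 2 * k) stop("need g > w + 2k", call. = FALSE)
  }
  L <- ell * g + k
  I_target <- L - (ell + 1L) * k
  pos <- k - 1L + (0:ell) * g
  for (try in seq_len(max_tries)) {
    A <- random_duplicate_free(L, k)
    s <- strsplit(A$source, "")[[1]]
    for (t in pos) {
      s[t + 1L] <- sample(setdiff(c("A", "C", "G", "T"), s[t + 1L]), 1)
    }
    bstr <- paste(s, collapse = "")
    B <- kmerize(bstr, k)
    if (!B$duplicate_free) next
    m <- kmer_matching(A, B)
    if (m$I == I_target && all(m$pairs$p == m$pairs$q)) {
      return(list(A = A, B = B, ell = ell, g = g, k = k, L = L,
                  I = m$I, J = m$J, positions = pos))
    }
  }
  stop("failed to build a clean deterministic-gap pair in ", max_tries,
       " draws (accidental duplicate or extra match each time)", call. = FALSE)
}

#' Sparsely matched sequence pair
#'
#' Builds a padded pair whose matching has exactly `n_shared` pairs, each
#' isolated by more than `w` positions from every other shared k-mer on both
#' sequences, so [is_sparsely_matched()] holds by construction.  The
#' sequences are abstract ordered k-mer lists (no contiguous source string):
#' the estimator and all bias machinery depend only on k-mer identity, and
#' abstract lists allow exact placement control.
#'
#' @param L length of each sequence in k-mers.
#' @param n_shared number of shared k-mers (>= 0).
#' @param k k-mer size.
#' @param w window size the isolation is built for.
#' @return A list with `A`, `B`, the matched positions `p` and `q`
#'   (0-based), `L`, `k`, `w` and the realized `J`.
#' @export
sparsely_matched_pair <- function(L, n_shared, k, w) {
  L <- as.integer(L); m <- as.integer(n_shared)
  k <- as.integer(k); w <- as.integer(w)
  if (m < 0) stop("n_shared must be >= 0", call. = FALSE)
  R <- L - 2L * w                       # admissible positions: [w, L - w - 1]
  if (m > 0 && (R < 1 || (m - 1L) * (w + 1L) + 1L > R)) {
    stop("infeasible packing: cannot place ", m, " isolated shared k-mers ",
         "in L = ", L, " with w = ", w, call. = FALSE)
  }
  if (2 * L - m > 4^k) stop("not enough distinct k-mers: increase k", call. = FALSE)
  ids <- sample_distinct_kmer_ids(2L * L, k)
  Ak <- decode_kmer_ids(ids[1:L], k)
  Bk <- decode_kmer_ids(ids[(L + 1L):(2L * L)], k)
  p <- q <- integer(0)
  if (m > 0) {
    draw_positions <- function() {
      x <- sort(sample.int(R - (m - 1L) * (w + 1L), m))
      w + (x - 1L) + (seq_len(m) - 1L) * (w + 1L)
    }
    p <- draw_positions()
    q <- draw_positions()
    Bk[q + 1L] <- Ak[p + 1L]
  }
  A <- kmer_seq(Ak); B <- kmer_seq(Bk)
  list(A = A, B = B, p = p, q = q, L = L, k = k, w = w,
       J = if (m > 0) m / (2 * L - m) else 0)
}

# n distinct k-mer ids in [0, 4^k)
sample_distinct_kmer_ids <- function(n, k) {
  if (4^k <= .Machine$integer.max) {
    as.numeric(sample.int(4^k, n) - 1)
  } else {
    ids <- unique(floor(stats::runif(ceiling(n * 1.05)) * 4^k))
    while (length(ids) < n) {
      ids <- unique(c(ids, floor(stats::runif(n) * 4^k)))
    }
    ids[seq_len(n)]
  }
}

decode_kmer_ids <- function(ids, k) {
  out <- character(length(ids))
  bases <- c("A", "C", "G", "T")
  mat <- matrix("", nrow = length(ids), ncol = k)
  x <- ids
  for (j in k:1) {
    mat[, j] <- bases[(x %% 4) + 1]
    x <- x %/% 4
  }
  apply(mat, 1, paste, collapse = "")
}
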