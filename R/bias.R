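#' Sign pattern of a charging event
#'
#' The event "position `p` charges index `i`" fixes the anchor value
#' `a_p = x` and constrains the other window positions: every position of the
#' window `[i + 1, i + w]` other than `p` must hash above `x`, and — unless
#' `i` is the boundary index `max(-1, p - w)` — position `i` must hash below
#' `x`.  Patterns for different `i` are mutually exclusive, and their union is
#' the event that `p` is a minimizer.
#'
#' @param i charged index, in `[max(-1, p - w), min(p - 1, L - w - 1)]`.
#' @param p 0-based anchor position.
#' @param w window size (>= 2).
#' @param L sequence length in k-mers.
#' @return A list with fields `anchor`, `below` (positions constrained below
#'   `x`), `above` (positions constrained above `x`), `boundary` (logical),
#'   and the unconditional probability `prob` of the pattern for independent
#'   uniform hashes (a Beta integral; see [joint_integral()]).
#' @export
charge_pattern <- function(i, p, w, L) {
  i <- as.integer(i); p <- as.integer(p); w <- as.integer(w); L <- as.integer(L)
  if (p < 0 || p > L - 1) stop("p must be in [0, L-1]", call. = FALSE)
  imin <- max(-1L, p - w); imax <- min(p - 1L, L - w - 1L)
  if (i < imin || i > imax) {
    stop("i is outside the legal charging range [", imin, ", ", imax,
         "] for p = ", p, call. = FALSE)
  }
  boundary <- i == imin
  below <- if (boundary) integer(0) else i
  above <- setdiff((i + 1L):(i + w), p)
  list(
    anchor = p, below = below, above = above, boundary = boundary,
    prob = joint_integral(length(below), length(above))
  )
}

#' Beta integral of a joint sign configuration
#'
#' A joint charging configuration with `alpha` distinct below-constraints and
#' `beta` distinct above-constraints (matched pairs counted once) has
#' conditional probability `x^alpha (1 - x)^beta` given the anchor value `x`;
#' integrating over `x` gives the exact Beta integral
#' `alpha! beta! / (alpha + beta + 1)!`.
#'
#' @param alpha,beta non-negative integer constraint counts (vectorized).
#' @return `integral(x^alpha (1-x)^beta dx)` over `[0, 1]`, exactly.
#' @examples
#' joint_integral(0, 0) # 1
#' joint_integral(1, 1) # 1/6
#' @export
joint_integral <- function(alpha, beta) {
  if (any(alpha < 0) || any(beta < 0)) {
    stop("alpha and beta must be non-negative", call. = FALSE)
  }
  factorial(alpha) * factorial(beta) / factorial(alpha + beta + 1)
}

#' Configuration-count approximation C of the expected sketch intersection
#'
#' Sums, over every matched pair `(p, q)` and every legal pair of charged
#' indices `(i, j)` — boundary indices included, so the computation is valid
#' for non-padded input — the Beta integral of the merged joint sign pattern.
#' Merging follows the matching: a constrained position of `A` matched to a
#' constrained position of `B` is a single hash variable (consistent signs
#' count once; conflicting signs zero the term).  `C` brackets the exact
#' expectation: `C <= E[I_hat] <= C + 2`.
#'
#' @param A,B duplicate-free [kmer_seq] objects with `L >= w + 1`.
#' @param w window size (>= 2).
#' @param matching optional pre-computed [kmer_matching()].
#' @return The value of `C(A, B; w)` (non-negative double).
#' @export
expected_intersection <- function(A, B, w, matching = NULL) {
  A <- as_kmer_seq(A, "A"); B <- as_kmer_seq(B, "B")
  matching <- as_matching(A, B, matching)
  expected_intersection_cpp(match_vec_c(matching), matching$L_B,
                            as.integer(w))
}

#' Analytical bias estimate for the minimizer Jaccard estimator
#'
#' Approximates the bias `E[J_hat] - J` by
#' `B = C / (d L - C) - J` with `d = 4 / (w + 1)`, where `C` is the
#' configuration-count approximation of the expected sketch intersection and
#' `d L - C` approximates the expected sketch union.  The additive error of
#' the approximation is bounded by `epsilon = 15 w^2 / L^(1/3)` (see
#' [epsilon_bound()]); empirically the error is far smaller.
#'
#' @inheritParams expected_intersection
#' @param epsilon_constant leading constant of the error bound (default 15).
#' @return An object of class `bias_report` with fields `J`, `C`, `B`,
#'   `U_approx = 4L/(w+1) - C`, `epsilon`, `I`, `U`, `w`, `L`, `k`.
#' @export
bias_estimate <- function(A, B, w, matching = NULL, epsilon_constant = 15) {
  A <- as_kmer_seq(A, "A"); B <- as_kmer_seq(B, "B")
  w <- as.integer(w)
  matching <- as_matching(A, B, matching)
  L <- (matching$L_A + matching$L_B) / 2
  if (L < 7 * (w + 1)) {
    warning("L < 7(w+1): outside the regime where the bias approximation ",
            "is guaranteed", call. = FALSE)
  }
  C <- expected_intersection(A, B, w, matching)
  dL <- 4 * L / (w + 1)
  if (C >= dL) {
    stop("C >= 4L/(w+1): the configuration sum exceeds its ceiling, ",
         "which indicates invalid input or an internal error", call. = FALSE)
  }
  structure(
    list(
      J = matching$J,
      C = C,
      B = C / (dL - C) - matching$J,
      U_approx = dL - C,
      epsilon = epsilon_bound(w, L, epsilon_constant),
      I = matching$I, U = matching$U,
      w = w, L = L, k = matching$k
    ),
    class = "bias_report"
  )
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf(
    paste0("<bias_report> w = %d, L = %g, k = %d\n",
           "  J = %.6f  C = %.4f  B = %+.6f\n",
           "  E[J_hat] approx %.6f  (union approx %.2f, epsilon bound %.3g)\n"),
    x$w, x$L, x$k, x$J, x$C, x$B, x$J + x$B, x$U_approx, x$epsilon
  ))
  invisible(x)
}

#' @method as.data.frame bias_report
#' @export
as.data.frame.bias_report <- function(x, ...) {
  data.frame(J = x$J, C = x$C, B = x$B, U_approx = x$U_approx,
             epsilon = x$epsilon, I = x$I, U = x$U, w = x$w, L = x$L, k = x$k)
}

#' Error bound of the bias approximation
#'
#' `epsilon = constant * w^2 / L^(1/3)`.  The bound is loose: for `w = 20`
#' and any practical `L` it exceeds 1, while the observed error of the bias
#' approximation is two to three orders of magnitude smaller.
#'
#' @param w window size (>= 2).
#' @param L sequence length in k-mers.
#' @param constant leading constant (default 15).
#' @return The bound (vectorized over `w` and `L`).
#' @export
epsilon_bound <- function(w, L, constant = 15) {
  constant * w^2 / L^(1 / 3)
}

#' Quoted headline ratio for sparsely matched pairs
#'
#' Evaluates `(5w^2 - 3w - 2) / (8w^2 - 2)`, the ratio conventionally quoted
#' as the ceiling of `E[J_hat] / J` for long sparsely matched pairs: 40% at
#' `w = 2`, about 61% at `w = 20`, with limit `5/8` as `w` grows.  Note that
#' the companion ratio implied algebraically by [sparse_bias_bound()] is
#' `(5w^2 + 3w - 2) / (8w^2 - 2)`; the two agree in the large-`w` limit.
#'
#' @param w window size (>= 2), vectorized.
#' @return The ratio in `(0, 1)`.
#' @export
sparse_ratio_bound <- function(w) {
  if (any(w < 2)) stop("w must be >= 2", call. = FALSE)
  (5 * w^2 - 3 * w - 2) / (8 * w^2 - 2)
}

#' Bias bound for sparsely matched pairs
#'
#' For duplicate-free, padded, sparsely matched pairs the bias estimate
#' satisfies `B <= -J (3w^2 - 3w) / (8w^2 - 2)`.  The bound is tight in the
#' small-`J` limit, where each isolated shared k-mer is jointly selected with
#' probability `(5w - 2) / (4w^2 - 1)`.
#'
#' @param J true Jaccard similarity in `[0, 1]`.
#' @param w window size (>= 2).
#' @return The (non-positive) bound, vectorized.
#' @export
sparse_bias_bound <- function(J, w) {
  if (any(w < 2)) stop("w must be >= 2", call. = FALSE)
  if (any(J < 0 | J > 1)) stop("J must be in [0, 1]", call. = FALSE)
  -J * (3 * w^2 - 3 * w) / (8 * w^2 - 2)
}

#' n-th harmonic number
#'
#' @param n positive integer (vectorized).
#' @return `H_n = 1 + 1/2 + ... + 1/n`.
#' @export
harmonic <- function(n) {
  vapply(as.integer(n), function(m) sum(1 / seq_len(m)), numeric(1))
}

# per-run sketch-intersection deficiency of the periodic-mutation layout;
# negative for w >= 2 since H_{2w} - H_w > 1/2
gap_h <- function(w) {
  (w + 1) * (1 - 2 * (harmonic(2 * w) - harmonic(w))) / 2
}

#' Closed-form bias for the deterministic-gap mutation layout
#'
#' For a pair identical except for substitutions at nucleotide positions
#' `k - 1 + i g` (`i = 0, ..., ell`; spacing `g > w + 2k`, length
#' `L = ell * g + k` k-mers), the shared k-mers form `ell` identical isolated
#' runs and the bias estimate has the closed form
#' `B = 2 ell L h(w) / ((U - ell h(w)) U)` with `U = ell (g + k) + 2k` and
#' `h(w) = (w + 1)(1 - 2(H_{2w} - H_w)) / 2`, `H_n` the n-th harmonic number.
#' `h(w) < 0` for `w >= 2`, so `B < 0` as required for padded pairs.
#'
#' @param ell number of gaps (>= 1).
#' @param g gap length in nucleotides, `> w + 2k`.
#' @param k k-mer size, `> w`.
#' @param w window size, `2 <= w < k`.
#' @return A list with the closed-form `B`, the layout's exact `J`, `I`, `U`,
#'   `L`, and the relative bias `-B / J`.
#' @seealso [deterministic_gap_pair()] to realize the layout as sequences.
#' @export
gap_layout_bias <- function(ell, g, k, w) {
  ell <- as.integer(ell); g <- as.integer(g)
  k <- as.integer(k); w <- as.integer(w)
  if (w < 2 || w >= k) stop("need 2 <= w < k", call. = FALSE)
  if (g <= w + 2 * k) stop("need g > w + 2k", call. = FALSE)
  if (ell < 1) stop("ell must be >= 1", call. = FALSE)
  L <- ell * g + k
  I <- L - (ell + 1) * k
  U <- 2 * L - I                       # = ell (g + k) + 2 k
  h <- gap_h(w)
  B <- 2 * ell * L * h / ((U - ell * h) * U)
  J <- I / U
  list(B = B, J = J, I = I, U = U, L = L, relative_bias = -B / J, h = h)
}

#' Sequence divergence from a Jaccard estimate
#'
#' Converts a k-mer Jaccard value into a per-base divergence (one minus
#' identity) under the assumption of independent substitutions.  The
#' `poisson` mode is the classical Mash formula
#' `d = -(1/k) log(2J / (1 + J))`; the `binomial` mode inverts the exact
#' forward map `d -> J = t / (2 - t)` with `t = (1 - d)^k`, giving
#' `d = 1 - (2J / (1 + J))^(1/k)`.  The two agree to first order as
#' `d -> 0`, but the Poisson approximation overestimates larger divergences.
#'
#' @param j_hat Jaccard value(s) in `[0, 1]`.
#' @param k k-mer size.
#' @param mode `"binomial"` (exact inversion) or `"poisson"`.
#' @return Divergence in `[0, 1]`; `j_hat = 0` yields the sentinel 1
#'   (maximal divergence, the quantity is undefined at 0).
#' @export
mash_divergence <- function(j_hat, k, mode = c("binomial", "poisson")) {
  mode <- match.arg(mode)
  if (any(j_hat < 0 | j_hat > 1)) stop("j_hat must be in [0, 1]", call. = FALSE)
  t <- 2 * j_hat / (1 + j_hat)
  out <- switch(mode,
    binomial = 1 - t^(1 / k),
    poisson = -log(t) / k
  )
  out[j_hat == 0] <- 1
  pmin(out, 1)
}
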