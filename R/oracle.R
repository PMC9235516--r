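#' Exact expectations by permutation enumeration
#'
#' Under the idealized hash only the relative order of the hash values
#' matters, so expectations of sketch statistics equal averages over all
#' `n!` rank assignments to the `n` distinct k-mers of the union spectrum.
#' This is the exact ground-truth engine used to validate the
#' configuration-count approximation on small instances; results are exact
#' rationals.
#'
#' @param A,B [kmer_seq] objects with the same `k` and `L >= w`.
#' @param w window size.
#' @param limit refuse instances with more distinct k-mers than this
#'   (default 10, i.e. 3,628,800 orderings); use [monte_carlo()] beyond it.
#' @return An object of class `exact_expectation`: numerics `E_I`, `E_U`,
#'   `E_J` plus exact fractions (`*_num`, `*_den`) and `n` (distinct k-mers).
#' @export
exact_expectations <- function(A, B, w, limit = 10) {
  A <- as_kmer_seq(A, "A"); B <- as_kmer_seq(B, "B")
  check_same_k(A, B)
  univ <- unique(c(A$kmers, B$kmers))
  n <- length(univ)
  if (n > limit) {
    stop("instance has ", n, " distinct k-mers; exact enumeration is ",
         "limited to ", limit, ". Use monte_carlo() for larger instances.",
         call. = FALSE)
  }
  res <- exact_enum_cpp(match(A$kmers, univ) - 1L, match(B$kmers, univ) - 1L,
                        n, as.integer(w), integer(0), integer(0))
  np <- res$n_perm
  fr <- function(num, den) {
    g <- gcd_num(num, den)
    c(num = num / g, den = den / g)
  }
  ei <- fr(res$sum_I, np); eu <- fr(res$sum_U, np)
  ej <- fr(res$sum_J_num, res$J_den_unit * np)
  structure(
    list(
      E_I = ei[["num"]] / ei[["den"]], E_I_num = ei[["num"]], E_I_den = ei[["den"]],
      E_U = eu[["num"]] / eu[["den"]], E_U_num = eu[["num"]], E_U_den = eu[["den"]],
      E_J = ej[["num"]] / ej[["den"]], E_J_num = ej[["num"]], E_J_den = ej[["den"]],
      n = n, n_perm = np, w = as.integer(w)
    ),
    class = "exact_expectation"
  )
}

#' @export
print.exact_expectation <- function(x, ...) {
  cat(sprintf(
    paste0("<exact_expectation> over %d distinct k-mers (%g orderings), w = %d\n",
           "  E[I_hat] = %g/%g = %.6f\n  E[U_hat] = %g/%g = %.6f\n",
           "  E[J_hat] = %g/%g = %.6f\n"),
    x$n, x$n_perm, x$w, x$E_I_num, x$E_I_den, x$E_I,
    x$E_U_num, x$E_U_den, x$E_U, x$E_J_num, x$E_J_den, x$E_J
  ))
  invisible(x)
}

gcd_num <- function(a, b) {
  while (b > 0.5) {
    r <- a %% b
    a <- b
    b <- r
  }
  max(a, 1)
}

#' Exact joint minimizer probability of a matched pair
#'
#' The probability, over the idealized hash, that the shared k-mer at
#' positions `(p, q)` is a minimizer in *both* sequences.  This is the
#' per-shared-k-mer quantity whose sum over the matching gives the expected
#' sketch intersection.
#'
#' @param A,B [kmer_seq] objects.
#' @param w window size.
#' @param p,q 0-based matched positions with `A_p = B_q`.
#' @param limit enumeration limit on distinct k-mers (default 10).
#' @return A list with the exact fraction (`num`, `den`, reduced), the raw
#'   ordering counts (`count`, `n_perm`) and the numeric `value`.
#' @export
joint_minimizer_probability <- function(A, B, w, p, q, limit = 10) {
  A <- as_kmer_seq(A, "A"); B <- as_kmer_seq(B, "B")
  check_same_k(A, B)
  p <- as.integer(p); q <- as.integer(q)
  if (p < 0 || p >= A$L || q < 0 || q >= B$L) {
    stop("positions out of range", call. = FALSE)
  }
  if (A$kmers[p + 1L] != B$kmers[q + 1L]) {
    stop("(p, q) is not in the k-mer matching: A_p != B_q", call. = FALSE)
  }
  univ <- unique(c(A$kmers, B$kmers))
  n <- length(univ)
  if (n > limit) {
    stop("instance has ", n, " distinct k-mers; enumeration limited to ",
         limit, call. = FALSE)
  }
  res <- exact_enum_cpp(match(A$kmers, univ) - 1L, match(B$kmers, univ) - 1L,
                        n, as.integer(w), p, q)
  count <- res$joint[1]
  g <- gcd_num(count, res$n_perm)
  list(value = count / res$n_perm, num = count / g, den = res$n_perm / g,
       count = count, n_perm = res$n_perm)
}

#' Monte-Carlo estimation over hash replicates
#'
#' Re-runs the minimizer Jaccard estimator with `n_seeds` independent hash
#' seeds and reports the replicate table and summary statistics.  `J_bar`,
#' the mean estimate over replicates, is the empirical counterpart of
#' `E[J_hat]`.  Fully reproducible: the seed list is derived from
#' `master_seed` by counter-mode mixing (see [derive_hash_seeds()]) and is
#' returned with the object.
#'
#' @param A,B [kmer_seq] objects with the same `k` and `L >= w`.
#' @param w window size.
#' @param n_seeds number of hash replicates (>= 2).
#' @param master_seed master seed for the replicate seed list, ignored when
#'   `seeds` is given.
#' @param seeds optional explicit seed vector.
#' @return An object of class `mc_estimate`: tibble `replicates` (`seed`,
#'   `I_hat`, `U_hat`, `J_hat`), `mean_J_hat`, `mean_I_hat`, `mean_U_hat`,
#'   `var_I_hat`, `var_U_hat`, `percentile_2_5`, `percentile_97_5`,
#'   `n_seeds`, `seeds`.
#' @export
monte_carlo <- function(A, B, w, n_seeds = 50, master_seed = 1, seeds = NULL) {
  A <- as_kmer_seq(A, "A"); B <- as_kmer_seq(B, "B")
  check_same_k(A, B)
  if (is.null(seeds)) {
    if (n_seeds < 2) stop("n_seeds must be >= 2", call. = FALSE)
    seeds <- derive_hash_seeds(master_seed, n_seeds)
  }
  m <- mc_replicates_cpp(A$kmers, B$kmers, as.integer(w), as.double(seeds))
  j <- m[, "J_hat"]
  structure(
    list(
      replicates = tibble::tibble(seed = as.numeric(seeds),
                                  I_hat = m[, "I_hat"], U_hat = m[, "U_hat"],
                                  J_hat = j),
      mean_J_hat = mean(j),
      mean_I_hat = mean(m[, "I_hat"]),
      mean_U_hat = mean(m[, "U_hat"]),
      var_I_hat = stats::var(m[, "I_hat"]),
      var_U_hat = stats::var(m[, "U_hat"]),
      percentile_2_5 = unname(stats::quantile(j, 0.025)),
      percentile_97_5 = unname(stats::quantile(j, 0.975)),
      n_seeds = length(seeds),
      seeds = as.numeric(seeds),
      w = as.integer(w)
    ),
    class = "mc_estimate"
  )
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf(
    paste0("<mc_estimate> %d hash replicates, w = %d\n",
           "  J_bar = %.6f  [2.5%%: %.4f, 97.5%%: %.4f]\n",
           "  mean I_hat = %.2f (var %.2f), mean U_hat = %.2f (var %.2f)\n"),
    x$n_seeds, x$w, x$mean_J_hat, x$percentile_2_5, x$percentile_97_5,
    x$mean_I_hat, x$var_I_hat, x$mean_U_hat, x$var_U_hat
  ))
  invisible(x)
}
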