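#' Run a bias-evaluation sweep
#'
#' Reproduces the package's standard experiment grids: for every grid point
#' it generates a sequence pair, measures the empirical mean estimate
#' `J_bar` over a fixed list of hash replicates (the same seed list is shared
#' by every grid point and mutation replicate), computes the analytical bias
#' estimate `B`, and reports the empirical error `|J_bar - J - B|`.
#'
#' `cfg` is a list with fields:
#' \describe{
#'   \item{model}{`"unrelated"` or `"related"`.}
#'   \item{j}{(unrelated) vector of target Jaccard values.}
#'   \item{k}{k-mer size; for the unrelated model may be a vector parallel to
#'     `j` (default: 7 for `j <= 0.3`, 8 otherwise).}
#'   \item{r1, L, n_mutation_replicates}{(related) mutation-rate grid, length
#'     in k-mers, and replicate count (default 1).}
#'   \item{w}{vector of window sizes.}
#'   \item{n_hash_replicates}{hash replicates per grid point (default 50).}
#'   \item{master_seed}{master seed; the sweep is deterministic given it.}
#' }
#'
#' @param cfg configuration list, see Details.
#' @return A tibble with one row per grid point (and mutation replicate):
#'   parameters, realized `J`, `J_bar`, `bias_emp = J_bar - J`, `B`, `C`,
#'   `error = |bias_emp - B|` and the 2.5/97.5 replicate percentiles.
#' @export
run_sweep <- function(cfg) {
  stopifnot(is.list(cfg))
  model <- match.arg(cfg$model, c("unrelated", "related"))
  n_hash <- cfg$n_hash_replicates %||% 50
  master_seed <- cfg$master_seed %||% 1
  seeds <- derive_hash_seeds(master_seed, n_hash)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(master_seed %% 2147483647)
  rows <- list()
  if (model == "unrelated") {
    jg <- cfg$j %||% numeric(0)
    kk <- cfg$k %||% ifelse(jg <= 0.3, 7L, 8L)
    if (length(kk) == 1) kk <- rep(kk, length(jg))
    for (wi in (cfg$w %||% 20)) {
      for (i in seq_along(jg)) {
        pair <- unrelated_pair(jg[i], kk[i], w = wi, j_tol = cfg$j_tol)
        rows[[length(rows) + 1]] <- sweep_row(
          pair$A, pair$B, wi, seeds,
          tibble::tibble(model = "unrelated", j = jg[i], r1 = NA_real_,
                         k = kk[i], w = wi, mut_rep = 1L)
        )
      }
    }
  } else {
    r1g <- cfg$r1 %||% numeric(0)
    L <- cfg$L %||% 10000
    k <- cfg$k %||% 16
    nmut <- cfg$n_mutation_replicates %||% 1
    if (length(r1g) > 0) {
      base <- random_duplicate_free(L, k)
      for (wi in (cfg$w %||% 20)) {
        for (r1 in r1g) {
          for (rep in seq_len(nmut)) {
            pair <- related_pair(base, r1)
            rows[[length(rows) + 1]] <- sweep_row(
              pair$A, pair$B, wi, seeds,
              tibble::tibble(model = "related", j = NA_real_, r1 = r1,
                             k = k, w = wi, mut_rep = rep)
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      model = character(0), j = numeric(0), r1 = numeric(0), k = integer(0),
      w = integer(0), mut_rep = integer(0), L = integer(0), J = numeric(0),
      J_bar = numeric(0), bias_emp = numeric(0), B = numeric(0),
      C = numeric(0), error = numeric(0), p2_5 = numeric(0),
      p97_5 = numeric(0)
    ))
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("J", "J_bar", "p2_5", "p97_5"))

sweep_row <- function(A, B, w, seeds, meta) {
  matching <- kmer_matching(A, B)
  mc <- monte_carlo(A, B, w, seeds = seeds)
  rep_ <- suppressWarnings(bias_estimate(A, B, w, matching = matching))
  dplyr::bind_cols(meta, tibble::tibble(
    L = matching$L_A,
    J = matching$J,
    J_bar = mc$mean_J_hat,
    bias_emp = mc$mean_J_hat - matching$J,
    B = rep_$B,
    C = rep_$C,
    error = abs(mc$mean_J_hat - matching$J - rep_$B),
    p2_5 = mc$percentile_2_5,
    p97_5 = mc$percentile_97_5
  ))
}

#' Fit a power law to error-versus-length data
#'
#' Nonlinear least squares fit of `error = a * L^b`, started from the
#' log-log linear fit.  Used to characterize how the empirical error of the
#' bias approximation decays with sequence length.
#'
#' @param data data frame with the predictor and response columns.
#' @param L_col,error_col column names (defaults `"L"`, `"error"`).
#' @return An object of class `power_law_fit`: `amplitude` (a), `exponent`
#'   (b), the underlying `nls` fit and `n`.
#' @export
fit_error_power_law <- function(data, L_col = "L", error_col = "error") {
  L <- data[[L_col]]; err <- data[[error_col]]
  keep <- is.finite(L) & is.finite(err) & err > 0
  L <- L[keep]; err <- err[keep]
  if (length(unique(L)) < 4) {
    stop("need >= 4 distinct L values with positive errors", call. = FALSE)
  }
  start_fit <- stats::lm(log(err) ~ log(L))
  start <- list(a = exp(stats::coef(start_fit)[[1]]),
                b = stats::coef(start_fit)[[2]])
  fit <- stats::nls(err ~ a * L^b, start = start, algorithm = "port",
                    control = stats::nls.control(maxiter = 500,
                                                 warnOnly = TRUE))
  cf <- stats::coef(fit)
  structure(
    list(amplitude = cf[["a"]], exponent = cf[["b"]], fit = fit,
         n = length(L)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> error = %.4g * L^(%.4f)  (n = %d)\n",
              x$amplitude, x$exponent, x$n))
  invisible(x)
}

#' Tidiers for package result objects
#'
#' One-row tibbles in the broom style for [bias_estimate()],
#' [fit_error_power_law()] and [monte_carlo()] results.
#'
#' @param x a `bias_report`, `power_law_fit` or `mc_estimate`.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @importFrom generics tidy
#' @export
tidy.bias_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidiers
#' @importFrom generics glance
#' @export
glance.bias_report <- function(x, ...) tidy.bias_report(x)

#' @rdname tidiers
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "exponent"),
                 estimate = c(x$amplitude, x$exponent))
}

#' @rdname tidiers
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, exponent = x$exponent, n = x$n)
}

#' @rdname tidiers
#' @export
tidy.mc_estimate <- function(x, ...) x$replicates

#' @rdname tidiers
#' @export
glance.mc_estimate <- function(x, ...) {
  tibble::tibble(mean_J_hat = x$mean_J_hat, mean_I_hat = x$mean_I_hat,
                 mean_U_hat = x$mean_U_hat, var_I_hat = x$var_I_hat,
                 var_U_hat = x$var_U_hat,
                 percentile_2_5 = x$percentile_2_5,
                 percentile_97_5 = x$percentile_97_5,
                 n_seeds = x$n_seeds, w = x$w)
}

#' Plot a sweep result
#'
#' Mean estimate versus true Jaccard with 2.5/97.5 percentile band and the
#' unbiased diagonal, in the style of the standard bias figures.
#'
#' @param sweep tibble from [run_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(sweep, ggplot2::aes(x = J, y = J_bar)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = p2_5, ymax = p97_5),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "true Jaccard J", y = "mean estimate J_bar")
}
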