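#' Summarize draws by posterior mean and 95% equal-tailed interval
#'
#' Quantiles use linear interpolation of the empirical CDF (R's type-7 rule),
#' fixed and documented so intervals are reproducible.
#'
#' @param draws numeric vector of posterior draws.
#' @return named numeric vector `(mean, q2.5, q97.5)`.
#' @export
summarize_interval <- function(draws) {
  if (length(draws) == 0L) stop("empty draw vector")
  if (length(draws) < 100L)
    warning("fewer than 100 draws: tail quantiles may be unstable")
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(draws), q2.5 = q[1L], q97.5 = q[2L])
}

#' Bayesian R-squared (proportion of variance explained)
#'
#' Per-draw ratio of the variance of the linear predictor to that variance
#' plus the draw's residual variance:
#' `r2_d = var(X beta_d) / (var(X beta_d) + sigma_d^2)`.
#' Unlike the naive predicted/observed variance ratio, this is bounded in
#' \[0, 1) for every draw, which is why it is used for Bayesian models.
#'
#' @param fit a `posterior_draws` object.
#' @param design optional regressor matrix (rows matching the fitted sample);
#'   defaults to the design stored in the fit.
#' @return list of class `r2_draws`: per-draw `r2`, `var_pred`, `var_err`,
#'   and a `summary` (mean, q2.5, q97.5).
#' @export
bayes_r2 <- function(fit, design = fit$X) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (nrow(fit$draws) == 0L) stop("empty draws")
  if (!identical(colnames(design), colnames(fit$X)))
    stop("design columns must match the fitted design")
  p <- ncol(design)
  betas <- fit$draws[, seq_len(p), drop = FALSE]
  lp <- design %*% t(betas)                       # persons x draws
  var_pred <- apply(lp, 2L, stats::var)
  var_err <- fit$draws[, "sigma"]^2
  r2 <- var_pred / (var_pred + var_err)
  structure(list(r2 = r2, var_pred = var_pred, var_err = var_err,
                 summary = summarize_interval(r2)),
            class = "r2_draws")
}

# pair two pooled draw sequences by retained-draw index, trimming the longer
pair_draws <- function(a, b) {
  k <- min(length(a), length(b))
  if (length(a) != length(b))
    message(sprintf("unequal draw counts (%d vs %d): paired on the first %d",
                    length(a), length(b), k))
  list(a = a[seq_len(k)], b = b[seq_len(k)])
}

#' Measurement-error variance by residual-variance subtraction
#'
#' The standard model's residual variance includes measurement-error
#' variance; the measurement-error model's excludes it. Their per-paired-draw
#' difference `sigma2_standard - sigma2_me` estimates the measurement-error
#' variance. Negative values are permitted in individual draws (and can reach
#' into credible-interval bounds).
#'
#' @param draws_standard,draws_me `posterior_draws` objects fitted to the
#'   same rows and regressors.
#' @return list of class `mev_draws`: per-draw `diff` and a `summary`.
#' @export
me_variance <- function(draws_standard, draws_me) {
  stopifnot(inherits(draws_standard, "posterior_draws"),
            inherits(draws_me, "posterior_draws"))
  if (length(draws_standard$y) != length(draws_me$y) ||
      !identical(colnames(draws_standard$X), colnames(draws_me$X)))
    stop("fits must share the same analysis rows and regressors")
  pr <- pair_draws(draws_standard$draws[, "sigma"]^2,
                   draws_me$draws[, "sigma"]^2)
  d <- pr$a - pr$b
  structure(list(diff = d, summary = summarize_interval(d)),
            class = "mev_draws")
}

#' Compare variance-explained estimates between methods
#'
#' Per-paired-draw absolute difference `r2_me - r2_standard` and percent
#' increase `100 * (r2_me - r2_standard) / r2_standard`, each summarized by
#' the posterior mean and 95% equal-tailed interval. Draws with
#' `r2_standard == 0` cannot contribute a percent increase and are excluded
#' from that summary with a logged count.
#'
#' @param r2_standard,r2_me [bayes_r2()] results for the standard and
#'   measurement-error fits of the same model.
#' @param label optional model label.
#' @param stratum optional stratum label.
#' @return list of class `decomposition_result` with elements `r2_standard`,
#'   `r2_me` (their summaries), `abs_difference`, `pct_increase` (draws +
#'   summaries), `label`, `stratum`.
#' @export
compare_methods <- function(r2_standard, r2_me, label = NA_character_,
                            stratum = NA_character_) {
  stopifnot(inherits(r2_standard, "r2_draws"), inherits(r2_me, "r2_draws"))
  pr <- pair_draws(r2_standard$r2, r2_me$r2)
  d <- pr$b - pr$a
  ok <- pr$a != 0
  if (any(!ok))
    message(sprintf("%d draw(s) with zero standard-method r2 excluded from percent increase",
                    sum(!ok)))
  if (!any(ok)) stop("no draws with nonzero standard-method r2")
  pct <- 100 * d[ok] / pr$a[ok]
  structure(list(
    r2_standard = r2_standard$summary, r2_me = r2_me$summary,
    abs_difference = list(draws = d, summary = summarize_interval(d)),
    pct_increase = list(draws = pct, summary = summarize_interval(pct)),
    label = label, stratum = stratum
  ), class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  f <- function(s) sprintf("%.3f (%.3f, %.3f)", s["mean"], s["q2.5"], s["q97.5"])
  cat(sprintf("<decomposition_result> model %s, stratum %s\n",
              x$label, x$stratum))
  cat("  r2 (standard):       ", f(x$r2_standard), "\n")
  cat("  r2 (meas. error):    ", f(x$r2_me), "\n")
  cat("  abs difference:      ", f(x$abs_difference$summary), "\n")
  cat("  percent increase:    ", f(x$pct_increase$summary), "\n")
  invisible(x)
}
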