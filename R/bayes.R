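#' Prior specification for the regression models
#'
#' Defaults mirror the weakly informative defaults of mainstream Bayesian
#' regression software: improper flat priors on slope coefficients, a
#' Student-t(df 3, location 0, scale 2.5) prior on the intercept, and a
#' Student-t(df 3, location 0.4, scale 2.5) prior truncated to the positive
#' half-line on the residual SD.
#'
#' @param intercept_df,intercept_location,intercept_scale Student-t intercept
#'   prior.
#' @param sigma_df,sigma_location,sigma_scale truncated Student-t residual-SD
#'   prior.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(intercept_df = 3, intercept_location = 0,
                       intercept_scale = 2.5,
                       sigma_df = 3, sigma_location = 0.4, sigma_scale = 2.5) {
  stopifnot(intercept_df > 0, intercept_scale > 0, sigma_df > 0,
            sigma_scale > 0)
  structure(list(intercept_df = intercept_df,
                 intercept_location = intercept_location,
                 intercept_scale = intercept_scale,
                 sigma_df = sigma_df, sigma_location = sigma_location,
                 sigma_scale = sigma_scale),
            class = "prior_spec")
}

#' MCMC sampler configuration
#'
#' Defaults: 3 chains of 1000 iterations, first 200 discarded as warmup,
#' convergence gate at split-chain R-hat 1.05.
#'
#' @param n_chains number of chains (>= 2 for R-hat).
#' @param n_iterations iterations per chain.
#' @param n_warmup warmup iterations discarded per chain (< `n_iterations`).
#' @param seed integer seed; chain streams are derived from it.
#' @param rhat_threshold convergence gate.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 3L, n_iterations = 1000L,
                           n_warmup = 200L, seed = 1L,
                           rhat_threshold = 1.05) {
  stopifnot(n_chains >= 2L, n_warmup >= 0L, n_warmup < n_iterations,
            rhat_threshold > 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "sampler_config")
}

#' Model specification
#'
#' Names the outcome, the regressor columns (biomarkers and covariates), and
#' — for measurement-error fits — the column holding each person's known
#' standard error of measurement.
#'
#' @param outcome outcome column name (the observed cognition score).
#' @param regressors character vector of regressor column names.
#' @param account_for_me logical; fit the latent true-cognition
#'   measurement-error model?
#' @param sem SEM column name; required iff `account_for_me`.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(outcome, regressors, account_for_me = FALSE,
                       sem = if (account_for_me) "sem" else NULL) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(regressors), length(regressors) >= 0L)
  if (account_for_me && is.null(sem))
    stop("measurement-error model requested but no 'sem' column named")
  structure(list(outcome = outcome, regressors = unique(regressors),
                 account_for_me = isTRUE(account_for_me), sem = sem),
            class = "model_spec")
}

# Build (y, X, sem) from data + model; complete-case with a logged count;
# errors on rank deficiency naming the collinear columns.
build_design <- function(data, model) {
  cols <- c(model$outcome, model$regressors, model$sem)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (cl in cols) {
    if (!is.numeric(data[[cl]]))
      stop(sprintf("column '%s' must be numeric", cl))
  }
  keep <- stats::complete.cases(data[cols])
  if (any(!keep))
    message(sprintf("dropped %d row(s) with missing values (complete-case analysis)",
                    sum(!keep)))
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < length(model$regressors) + 2L)
    stop("too few complete rows to fit the model")
  X <- cbind(Intercept = 1,
             as.matrix(data[, model$regressors, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sem <- NULL
  if (!is.null(model$sem)) {
    sem <- data[[model$sem]]
    if (any(sem < 0)) stop("negative SEM values are invalid")
  }
  list(y = data[[model$outcome]], X = X, sem = sem, data = data)
}

# log density of the (truncated, non-central) Student-t prior on sigma
log_sigma_prior <- function(sigma, priors) {
  stats::dt((sigma - priors$sigma_location) / priors$sigma_scale,
            df = priors$sigma_df, log = TRUE) - log(priors$sigma_scale)
}

# Gibbs sampler for the normal linear model, optionally with a latent
# true-outcome layer observed with known per-person error SDs:
#   y_i ~ Normal(eta_i, sem_i^2),  eta_i ~ Normal(x_i'beta, sigma^2)
# (standard model: sem_i == 0, so eta_i == y_i).
# The (beta, sigma) updates work on the collapsed model
#   y_i ~ Normal(x_i'beta, sigma^2 + sem_i^2)
# — the exact marginal of the latent layer — so mixing does not degrade when
# the latent states are tightly coupled to the parameters (small sigma or
# large SEMs). beta has a closed-form normal conditional (GLS-weighted);
# sigma gets a random-walk Metropolis step on the log scale, step size
# adapted during warmup; the Student-t intercept prior enters through its
# normal scale-mixture representation (inverse-gamma mixing variance,
# Gibbs-updated). Latent true scores, when requested, are redrawn from their
# exact conditional given (beta, sigma) after each update — a valid
# partially collapsed Gibbs scheme sampling the identical joint posterior.
run_gibbs <- function(y, X, sem, priors, config, keep_latent = FALSE) {
  n <- length(y)
  p <- ncol(X)
  me <- !is.null(sem)
  sem2 <- if (me) sem^2 else rep(0, n)
  # initialization at the least-squares solution
  ols <- stats::lm.fit(X, y)
  beta0_init <- ols$coefficients
  sigma_init <- max(sqrt(sum(ols$residuals^2) / max(n - p, 1)), 1e-3)
  n_keep <- config$n_iterations - config$n_warmup
  total <- config$n_chains * n_keep
  draws <- matrix(NA_real_, total, p + 1L,
                  dimnames = list(NULL, c(colnames(X), "sigma")))
  chain_id <- integer(total)
  latent_sum <- if (me && keep_latent) numeric(n) else NULL
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  accept_rates <- numeric(config$n_chains)
  nu <- priors$intercept_df
  mu0 <- priors$intercept_location
  s0 <- priors$intercept_scale
  if (me) {
    fixed <- sem <= 1e-12     # known-truth rows: latent pinned to observed
    prec_obs <- ifelse(fixed, Inf, 1 / sem2)
  }
  row <- 0L
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    beta <- beta0_init + stats::rnorm(p, 0, 0.1 * (sigma_init + 0.1))
    sigma <- sigma_init * exp(stats::rnorm(1, 0, 0.2))
    lambda <- 1
    step <- 0.3
    n_acc <- 0L
    acc_window <- 0L
    for (it in seq_len(config$n_iterations)) {
      w <- 1 / (sigma^2 + sem2)
      # beta | sigma, y  (flat slopes; t intercept via scale mixture lambda)
      prior_prec <- c(1 / (s0^2 * lambda), rep(0, p - 1L))
      Vinv <- crossprod(X, X * w) + diag(prior_prec, p)
      b <- crossprod(X, y * w) + c(mu0 / (s0^2 * lambda), rep(0, p - 1L))
      R <- chol(Vinv)
      mean_beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
      beta <- drop(mean_beta + backsolve(R, stats::rnorm(p)))
      # lambda | beta0  (inverse-gamma)
      z2 <- ((beta[1L] - mu0) / s0)^2
      lambda <- 1 / stats::rgamma(1, (nu + 1) / 2, rate = (nu + z2) / 2)
      mu <- drop(X %*% beta)
      # sigma | beta, y: random-walk Metropolis on log sigma against the
      # collapsed likelihood (Jacobian term for the log parameterization)
      r2obs <- (y - mu)^2
      log_cond <- function(s) {
        v <- s^2 + sem2
        -0.5 * sum(log(v)) - 0.5 * sum(r2obs / v) +
          log_sigma_prior(s, priors) + log(s)
      }
      lp_cur <- log_cond(sigma)
      prop <- sigma * exp(stats::rnorm(1, 0, step))
      if (prop > 1e-8) {
        if (log(stats::runif(1)) < log_cond(prop) - lp_cur) {
          sigma <- prop
          n_acc <- n_acc + 1L
          acc_window <- acc_window + 1L
        }
      }
      if (it <= config$n_warmup && it %% 50L == 0L) {
        rate <- acc_window / 50
        step <- min(max(step * exp(rate - 0.35), 1e-3), 3)
        acc_window <- 0L
      }
      if (it > config$n_warmup) {
        row <- row + 1L
        draws[row, ] <- c(beta, sigma)
        chain_id[row] <- ch
        if (!is.null(latent_sum)) {
          # latent true outcome | beta, sigma, y: precision-weighted normal
          prec <- prec_obs + 1 / sigma^2
          m <- (y * prec_obs + mu / sigma^2) / prec
          eta <- ifelse(fixed, y, stats::rnorm(n, ifelse(fixed, y, m),
                                               ifelse(fixed, 0, 1 / sqrt(prec))))
          latent_sum <- latent_sum + eta
        }
      }
    }
    accept_rates[ch] <- n_acc / config$n_iterations
  }
  structure(
    list(draws = draws, chain = chain_id, n_chains = config$n_chains,
         n_kept = n_keep, X = X, y = y, sem = sem,
         latent_mean = if (!is.null(latent_sum)) latent_sum / total else NULL,
         accept_rates = accept_rates, priors = priors, config = config),
    class = "posterior_draws"
  )
}

#' Fit the standard Bayesian linear model (observed score as outcome)
#'
#' Normal linear regression of the observed cognition score on the
#' regressors, treating the observed score as if it were true cognition.
#' Its residual variance absorbs measurement-error variance, which is what
#' attenuates variance-explained estimates.
#'
#' @param data data.frame with the outcome and regressor columns.
#' @param model a [model_spec()] (with `account_for_me = FALSE`).
#' @param priors a [prior_spec()].
#' @param config a [sampler_config()].
#' @return A `posterior_draws` object: retained draws of the coefficients and
#'   residual SD with chain indices, plus the design matrix used.
#' @export
fit_standard <- function(data, model, priors = prior_spec(),
                         config = sampler_config()) {
  stopifnot(inherits(model, "model_spec"))
  d <- build_design(data, model_spec(model$outcome, model$regressors))
  run_gibbs(d$y, d$X, sem = NULL, priors = priors, config = config)
}

#' Fit the measurement-error model (latent true cognition)
#'
#' Joint model: `score_i ~ Normal(true_i, sem_i^2)` with
#' `true_i ~ Normal(x_i' beta, sigma^2)` — the per-person SEM is treated as a
#' known error SD, so the residual SD `sigma` excludes measurement-error
#' variance. Rows with `sem == 0` are treated as observed without error (the
#' latent state is pinned to the observation).
#'
#' @inheritParams fit_standard
#' @param model a [model_spec()] with `account_for_me = TRUE` and a `sem`
#'   column.
#' @param keep_latent also return the posterior mean of each latent true
#'   score.
#' @return A `posterior_draws` object.
#' @export
fit_me <- function(data, model, priors = prior_spec(),
                   config = sampler_config(), keep_latent = FALSE) {
  stopifnot(inherits(model, "model_spec"))
  if (is.null(model$sem))
    stop("fit_me requires a model_spec with a 'sem' column")
  d <- build_design(data, model)
  run_gibbs(d$y, d$X, sem = d$sem, priors = priors, config = config,
            keep_latent = keep_latent)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws (%d chains x %d kept), %s model\n",
              nrow(x$draws), x$n_chains, x$n_kept,
              if (is.null(x$sem)) "standard" else "measurement-error"))
  print(summary(x), ...)
  invisible(x)
}

#' Summarize posterior draws
#'
#' @param object a `posterior_draws` object.
#' @param ... unused.
#' @return data.frame with columns parameter, mean, sd, q2.5, q97.5, rhat.
#' @export
summary.posterior_draws <- function(object, ...) {
  pars <- colnames(object$draws)
  out <- do.call(rbind, lapply(pars, function(pp) {
    v <- object$draws[, pp]
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(parameter = pp, mean = mean(v), sd = stats::sd(v),
               q2.5 = q[1L], q97.5 = q[2L],
               rhat = suppressWarnings(split_rhat(object, pp)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Does a fit pass the convergence gate?
#'
#' @param fit a `posterior_draws` object.
#' @param threshold split-R-hat threshold (default from the fit's config).
#' @return TRUE iff every parameter's split R-hat is below the threshold.
#' @export
convergence_ok <- function(fit, threshold = fit$config$rhat_threshold) {
  r <- suppressWarnings(
    vapply(colnames(fit$draws), function(pp) split_rhat(fit, pp), numeric(1)))
  all(is.finite(r)) && all(r < threshold)
}

# core split-R-hat on an iterations x chains matrix
split_rhat_matrix <- function(m) {
  n <- nrow(m)
  half <- n %/% 2L
  if (half < 2L) stop("need at least 4 draws per chain")
  halves <- cbind(m[seq_len(half), , drop = FALSE],
                  m[(n - half + 1L):n, , drop = FALSE])
  W <- mean(apply(halves, 2L, stats::var))
  if (!is.finite(W) || W == 0) {
    warning("zero within-chain variance: R-hat undefined")
    return(NA_real_)
  }
  B <- half * stats::var(colMeans(halves))
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half; R-hat is the square root of the ratio of the
#' pooled variance estimate to the mean within-half-chain variance. Values
#' near 1 indicate mixing; the conventional gate used here is 1.05.
#'
#' @param draws a `posterior_draws` object, or a numeric matrix with one
#'   column per chain (iterations in rows).
#' @param parameter parameter name (required for `posterior_draws` input).
#' @return a single R-hat value (NA with a warning if within-chain variance
#'   is zero).
#' @export
split_rhat <- function(draws, parameter = NULL) {
  if (inherits(draws, "posterior_draws")) {
    stopifnot(!is.null(parameter))
    v <- draws$draws[, parameter]
    m <- matrix(v[order(draws$chain)], ncol = draws$n_chains)
    return(split_rhat_matrix(m))
  }
  if (!is.matrix(draws) || ncol(draws) < 2L)
    stop("need a posterior_draws object or a matrix with >= 2 chain columns")
  split_rhat_matrix(draws)
}

#' Deterministic marginal maximum-likelihood oracle
#'
#' Maximum likelihood for the collapsed measurement-error model
#' `y_i ~ Normal(x_i' beta, sigma^2 + sem_i^2)` via profile likelihood:
#' generalized least squares for beta at each candidate sigma^2, 1-D
#' optimization over sigma^2. With all SEMs zero this is exactly ordinary
#' least squares with the ML residual variance. Used as an independent check
#' on the MCMC fits; not part of the headline Bayesian pipeline.
#'
#' @param data data.frame.
#' @param model a [model_spec()] naming a `sem` column (use a column of
#'   zeros for the homoscedastic limit).
#' @return list with `beta` (named), `sigma2`, `sigma`, `loglik`.
#' @export
marginal_gls_fit <- function(data, model) {
  stopifnot(inherits(model, "model_spec"))
  if (is.null(model$sem)) stop("marginal_gls_fit requires a 'sem' column")
  d <- build_design(data, model)
  y <- d$y; X <- d$X; sem2 <- d$sem^2
  n <- length(y)
  profile <- function(s2) {
    v <- s2 + sem2
    w <- 1 / v
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% y)
    r <- y - drop(X %*% beta)
    list(ll = -0.5 * sum(log(2 * pi * v)) - 0.5 * sum(r^2 * w), beta = beta)
  }
  ub <- max(stats::var(y) * 10, 1)
  opt <- stats::optimize(function(s2) profile(s2)$ll, interval = c(0, ub),
                         maximum = TRUE, tol = 1e-10)
  if (opt$maximum > ub * 0.999)
    stop(sprintf("profile search did not converge inside (0, %g); loglik at upper bracket %g",
                 ub, opt$objective))
  pf <- profile(opt$maximum)
  list(beta = stats::setNames(drop(pf$beta), colnames(X)),
       sigma2 = max(opt$maximum, 0), sigma = sqrt(max(opt$maximum, 0)),
       loglik = pf$ll)
}

#' Brute-force grid posterior for the one-regressor measurement-error model
#'
#' Evaluates the marginalized posterior `y_i ~ Normal(b0 + b1 x_i,
#' sigma^2 + sem_i^2)` — with the same priors as the samplers — on a dense
#' (b0, b1, sigma) grid and returns exact-within-discretization posterior
#' means and SDs. This is a testing oracle, independent of the Gibbs sampler
#' code path; it is only feasible for tiny problems.
#'
#' @param y,x,sem numeric vectors of equal length.
#' @param priors a [prior_spec()].
#' @param n_beta,n_sigma grid resolution per dimension.
#' @param expand half-width of the beta grids in GLS standard errors.
#' @return list with `mean` and `sd`, each a named numeric vector over
#'   `(Intercept, x, sigma)`.
#' @export
grid_me_posterior <- function(y, x, sem, priors = prior_spec(),
                              n_beta = 201L, n_sigma = 241L, expand = 25) {
  stopifnot(length(y) == length(x), length(y) == length(sem))
  df <- data.frame(y = y, x = x, sem = sem)
  gls <- marginal_gls_fit(df, model_spec("y", "x", account_for_me = TRUE,
                                         sem = "sem"))
  v0 <- gls$sigma2 + sem^2
  XtWX <- crossprod(cbind(1, x) * (1 / v0), cbind(1, x))
  se <- sqrt(diag(solve(XtWX)))
  b0g <- seq(gls$beta[1L] - expand * se[1L], gls$beta[1L] + expand * se[1L],
             length.out = n_beta)
  b1g <- seq(gls$beta[2L] - expand * se[2L], gls$beta[2L] + expand * se[2L],
             length.out = n_beta)
  sg <- seq(1e-4, gls$sigma * 10 + 8, length.out = n_sigma)
  lp_b0 <- stats::dt((b0g - priors$intercept_location) /
                       priors$intercept_scale,
                     df = priors$intercept_df, log = TRUE)
  logpost_slab <- function(s) {
    v <- s^2 + sem^2
    S1 <- sum(1 / v)
    Sy <- sum(y / v); Sx <- sum(x / v)
    Syy <- sum(y^2 / v); Sxy <- sum(x * y / v); Sxx <- sum(x^2 / v)
    const <- -0.5 * sum(log(2 * pi * v)) + log_sigma_prior(s, priors)
    Sc <- Sy - b1g * Sx                          # per b1
    Scc <- Syy - 2 * b1g * Sxy + b1g^2 * Sxx
    # loglik(b0, b1) = const - 0.5 (S1 b0^2 - 2 b0 Sc + Scc)
    M <- outer(b0g, Sc) - 0.5 * outer(b0g^2, rep(S1, n_beta))
    M <- sweep(M, 2L, 0.5 * Scc, `-`) + const
    M + lp_b0
  }
  ref <- max(vapply(sg, function(s) max(logpost_slab(s)), numeric(1)))
  Z <- 0; m1 <- c(0, 0, 0); m2 <- c(0, 0, 0)
  for (s in sg) {
    W <- exp(logpost_slab(s) - ref)
    z <- sum(W)
    Z <- Z + z
    wb0 <- rowSums(W); wb1 <- colSums(W)
    m1 <- m1 + c(sum(wb0 * b0g), sum(wb1 * b1g), z * s)
    m2 <- m2 + c(sum(wb0 * b0g^2), sum(wb1 * b1g^2), z * s^2)
  }
  mu <- m1 / Z
  vv <- pmax(m2 / Z - mu^2, 0)
  nm <- c("Intercept", "x", "sigma")
  list(mean = stats::setNames(mu, nm), sd = stats::setNames(sqrt(vv), nm))
}
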