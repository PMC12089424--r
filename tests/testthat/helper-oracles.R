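# Independent oracles and shared fixtures for the test suite. These are
# deliberately coded from first principles, separate from the package's
# implementation paths.

# Fine-grid EAP oracle: direct numerical integration of the graded-response
# posterior on >= 10,001 equally spaced nodes with a normal prior.
oracle_eap <- function(responses, a, b_list, n_nodes = 10001L,
                       prior_mean = 0, prior_sd = 1) {
  th <- seq(prior_mean - 5 * prior_sd, prior_mean + 5 * prior_sd,
            length.out = n_nodes)
  logpost <- dnorm(th, prior_mean, prior_sd, log = TRUE)
  for (j in seq_along(a)) {
    bj <- b_list[[j]]
    pstar <- cbind(1, sapply(bj, function(bk) plogis(a[j] * (th - bk))), 0)
    K <- length(bj) + 1L
    pk <- pstar[, responses[j] + 1L] - pstar[, responses[j] + 2L]
    logpost <- logpost + log(pmax(pk, 1e-300))
  }
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  m1 <- sum(w * th)
  list(theta_hat = m1, sem = sqrt(sum(w * th^2) - m1^2))
}

# Reference split-chain R-hat, written longhand from the defining formula.
oracle_split_rhat <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  pieces <- list()
  for (j in seq_len(ncol(m))) {
    pieces[[length(pieces) + 1L]] <- m[1:half, j]
    pieces[[length(pieces) + 1L]] <- m[(n - half + 1L):n, j]
  }
  k <- length(pieces)
  means <- numeric(k); vars <- numeric(k)
  for (i in seq_len(k)) {
    v <- pieces[[i]]
    means[i] <- sum(v) / half
    vars[i] <- sum((v - means[i])^2) / (half - 1)
  }
  W <- sum(vars) / k
  grand <- sum(means) / k
  B <- half / (k - 1) * sum((means - grand)^2)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Small deterministic binary bank used across tests.
toy_bank <- function(n_items = 6L, a = seq(0.8, 1.6, length.out = n_items),
                     b = seq(-1.5, 1.5, length.out = n_items)) {
  item_bank(a, as.list(b), "toy")
}

# A small scored dataset with known latent structure for regression tests:
# true score = b0 + b1 * x + N(0, resid_sd); observed adds N(0, sem_i).
# exact_moments realizes the stated latent second moments exactly in-sample
# (x scaled to unit variance, residuals orthogonalized against x and scaled
# to resid_sd^2, SEMs laid out as uniform-distribution quantiles), so tests
# against analytic variance targets are not clouded by design sampling noise.
sim_scored <- function(n, b0 = 0, b1 = sqrt(0.5), resid_sd = sqrt(0.5),
                       sem_range = c(0.40, 0.49), seed = 1,
                       exact_moments = FALSE) {
  set.seed(seed)
  x <- rnorm(n)
  eps <- rnorm(n, 0, resid_sd)
  if (exact_moments) {
    x <- drop(scale(x))
    eps <- resid(lm(eps ~ x))
    eps <- eps * resid_sd / sd(eps)
    sem <- sample(qunif((seq_len(n) - 0.5) / n, sem_range[1], sem_range[2]))
  } else {
    sem <- runif(n, sem_range[1], sem_range[2])
  }
  true_score <- b0 + b1 * x + eps
  data.frame(score = true_score + rnorm(n, 0, sem), x = x, sem = sem,
             true_score = true_score)
}

# Construct a minimal posterior_draws object with prescribed draws, for
# exercising the decomposition arithmetic without running MCMC.
fake_fit <- function(betas, sigmas, X, n_chains = 2L) {
  draws <- cbind(betas, sigma = sigmas)
  colnames(draws) <- c(colnames(X), "sigma")
  structure(list(draws = draws,
                 chain = rep(seq_len(n_chains), length.out = nrow(draws)),
                 n_chains = n_chains, n_kept = nrow(draws) / n_chains,
                 X = X, y = rnorm(nrow(X)), sem = NULL),
            class = "posterior_draws")
}
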