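test_that("item bank validation enforces the psychometric invariants", {
  expect_s3_class(item_bank(c(1, 2), list(0, c(-1, 0.5)), "m"), "item_bank")
  expect_error(item_bank(-1, list(0)), "positive")
  expect_error(item_bank(1, list(c(1, 0))), "increasing")
  expect_error(item_bank(numeric(0), list()), "at least one")
})

test_that("category probabilities follow the graded response model", {
  bin <- list(a = 1, b = 0, K = 2L)
  expect_equal(category_probabilities(bin, 0), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(category_probabilities(bin, 50), c(0, 1), tolerance = 1e-12)
  expect_equal(category_probabilities(bin, 1)[2], plogis(1), tolerance = 1e-12)
  # polytomous: nonnegative, sums to one, matches cumulative differences
  it <- list(a = 1.7, b = c(-1, 0.2, 1.4), K = 4L)
  for (th in c(-2.3, 0, 0.7, 3)) {
    p <- category_probabilities(it, th)
    expect_length(p, 4)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    pstar <- plogis(1.7 * (th - c(-1, 0.2, 1.4)))
    expect_equal(p, -diff(c(1, pstar, 0)), tolerance = 1e-12)
  }
  expect_error(category_probabilities(bin, Inf), "finite")
  expect_error(category_probabilities(bin, NA_real_), "finite")
})

test_that("response simulation is seeded and has the right margins", {
  bank <- toy_bank()
  r1 <- simulate_responses(c(-1, 0, 1), bank, seed = 3)
  r2 <- simulate_responses(c(-1, 0, 1), bank, seed = 3)
  expect_identical(r1, r2)
  expect_false(identical(r1, simulate_responses(c(-1, 0, 1), bank, seed = 4)))
  # saturation: very able persons ace easy binary items
  easy <- item_bank(rep(2, 4), as.list(rep(-1, 4)), "easy")
  expect_true(all(simulate_responses(rep(10, 20), easy, seed = 1) == 1L))
  # binomial margin at theta = 0 for a = 1, b = 0: P(correct) = 0.5
  one <- item_bank(1, list(0), "one")
  p_hat <- mean(simulate_responses(rep(0, 10000), one, seed = 9))
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(simulate_responses(numeric(0), bank, seed = 1), "non-empty")
  expect_error(simulate_responses(0, bank), "seed")
})

test_that("EAP scores match a 10,001-node quadrature oracle", {
  bank <- toy_bank()
  a <- sapply(bank$items, `[[`, "a")
  b <- lapply(bank$items, `[[`, "b")
  pats <- list(rep(0L, 6), rep(1L, 6), c(1L, 0L, 1L, 0L, 1L, 0L),
               c(1L, 1L, 1L, 0L, 0L, 0L))
  for (pat in pats) {
    got <- eap_score(pat, bank)
    want <- oracle_eap(pat, a, b)
    expect_equal(got$theta_hat, want$theta_hat, tolerance = 1e-4)
    expect_equal(got$sem, want$sem, tolerance = 1e-4)
  }
  # polytomous bank against the same oracle
  poly <- item_bank(c(1.2, 0.9), list(c(-1, 0, 1), c(-0.5, 0.8)), "poly")
  got <- eap_score(c(2L, 1L), poly)
  want <- oracle_eap(c(2L, 1L), c(1.2, 0.9), list(c(-1, 0, 1), c(-0.5, 0.8)))
  expect_equal(got$theta_hat, want$theta_hat, tolerance = 1e-4)
  expect_equal(got$sem, want$sem, tolerance = 1e-4)
})

test_that("EAP limiting and symmetry behaviour", {
  # an uninformative item leaves the posterior at the prior
  flat <- item_bank(1e-6, list(0), "flat")
  s <- eap_score(1L, flat)
  expect_equal(s$theta_hat, 0, tolerance = 1e-4)
  expect_equal(s$sem, 1, tolerance = 1e-4)
  # symmetric bank: all-top vs all-bottom are mirror images
  sym <- item_bank(rep(1.3, 5), as.list(rep(0, 5)), "sym")
  up <- eap_score(rep(1L, 5), sym)
  dn <- eap_score(rep(0L, 5), sym)
  expect_equal(up$theta_hat, -dn$theta_hat, tolerance = 1e-10)
  expect_equal(up$sem, dn$sem, tolerance = 1e-10)
  # sem never exceeds the prior SD
  expect_lt(up$sem, 1 + 1e-8)
  expect_error(eap_score(c(2L, rep(0L, 4)), sym), "category")
  expect_error(eap_score(rep(0L, 3), sym), "align")
})

test_that("EAP shrinks toward the prior mean relative to the MLE", {
  bank <- toy_bank()
  a <- sapply(bank$items, `[[`, "a")
  b <- unlist(lapply(bank$items, `[[`, "b"))
  loglik <- function(th, pat) {
    p <- plogis(a * (th - b))
    sum(pat * log(p) + (1 - pat) * log(1 - p))
  }
  pats <- list(c(1L, 1L, 0L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L, 0L, 0L),
               c(0L, 1L, 0L, 0L, 1L, 0L), c(1L, 1L, 1L, 1L, 1L, 0L))
  for (pat in pats) {
    mle <- optimize(function(th) loglik(th, pat), c(-6, 6), maximum = TRUE)$maximum
    eap <- eap_score(pat, bank)$theta_hat
    expect_lte(abs(eap), abs(mle) + 1e-8)
  }
})

test_that("test information has the closed binary form and is additive", {
  one <- item_bank(1, list(0.3), "one")
  expect_equal(test_information(one, 0.3), 0.25, tolerance = 1e-12)
  two <- item_bank(c(1, 1), list(0.3, 0.3), "two")
  th <- seq(-2, 2, by = 0.5)
  expect_equal(test_information(two, th), 2 * test_information(one, th),
               tolerance = 1e-12)
  expect_error(test_information(one, NaN), "finite")
})

test_that("graded-item information matches a finite-difference oracle", {
  it <- item_bank(1.4, list(c(-0.8, 0.1, 1.2)), "g")
  h <- 1e-5
  for (th in c(-1.5, 0, 0.6, 2)) {
    # Fisher information = sum_k (dp_k/dtheta)^2 / p_k
    pk <- function(t) category_probabilities(it$items[[1]], t)
    dp <- (pk(th + h) - pk(th - h)) / (2 * h)
    want <- sum(dp^2 / pk(th))
    expect_equal(test_information(it, th), want, tolerance = 1e-4)
  }
})

test_that("sem_curve is internally consistent and orders battery sizes", {
  grid <- quadrature_grid(41)
  big <- item_bank(seq(1, 2, length.out = 30),
                   as.list(seq(-2, 1, length.out = 30)), "big")
  small <- item_bank(seq(1, 2, length.out = 6),
                     as.list(seq(-2, 1, length.out = 6)), "small")
  cb <- sem_curve(big, grid)
  cs <- sem_curve(small, grid)
  expect_true(all(cb$sem < cs$sem))                    # pointwise lower SEM
  expect_equal(cb$information, test_information(big, grid$nodes),
               tolerance = 1e-12)
  # long memory-like vs short easy visuospatial-like battery: mean SEM over
  # the bulk of the trait several-fold larger for the short bank
  banks <- default_item_banks()
  mid <- abs(grid$nodes) <= 2
  m_mem <- mean(sem_curve(banks$memory_like, grid)$sem[mid])
  m_vis <- mean(sem_curve(banks$visuospatial_like, grid)$sem[mid])
  expect_gt(m_vis / m_mem, 2)
})

test_that("EAP SEM tracks 1/sqrt(information + prior precision) for long banks", {
  bank <- item_bank(seq(1.2, 2.2, length.out = 24),
                    as.list(seq(-2, 2, length.out = 24)), "long")
  grid <- quadrature_grid(61)
  tab <- sem_curve(bank, grid)
  mid <- abs(tab$theta) <= 2
  approx_sem <- 1 / sqrt(tab$information[mid] + 1)
  expect_true(all(abs(tab$sem[mid] / approx_sem - 1) < 0.10))
})

test_that("mean EAP regressed on true theta has slope in (0, 1], rising with information", {
  slope_for <- function(bank, seed) {
    th <- rep(seq(-2, 2, length.out = 8), each = 250)
    resp <- simulate_responses(th, bank, seed = seed)
    sc <- eap_score_matrix(resp, bank)
    unname(coef(lm(sc$theta_hat ~ th))[2])
  }
  banks <- default_item_banks()
  s_big <- slope_for(banks$memory_like, 21)
  s_small <- slope_for(banks$visuospatial_like, 22)
  expect_gt(s_big, 0); expect_lte(s_big, 1 + 0.02)
  expect_gt(s_small, 0)
  expect_gt(s_big, s_small)  # more information, less shrinkage
})

test_that("standardize_scores does z-scoring and propagates the SEM scale", {
  expect_equal(standardize_scores(c(2, 4, 6)), c(-1, 0, 1) * sqrt(1.5),
               tolerance = 1e-6)  # population-SD z-scores: +/- 1.2247...
  out <- standardize_scores(c(2, 4, 6), reference_mean = 0, reference_sd = 2,
                            sems = c(0.5, 0.5, 0.5))
  expect_equal(out$sems, c(0.25, 0.25, 0.25))
  z <- standardize_scores(rnorm(50, 5, 3))
  expect_equal(standardize_scores(z), z, tolerance = 1e-12)  # idempotent
  expect_error(standardize_scores(1:3, reference_sd = 0), "positive")
})

test_that("item banks round-trip through the delimited format", {
  bank <- item_bank(c(1.1, 0.9, 1.7),
                    list(0.4, c(-1, 0, 1), c(-0.2, 0.9)), "mixed")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_item_bank(bank, path)
  back <- read_item_bank(path, "mixed")
  expect_equal(back$n_items, 3L)
  for (j in 1:3) {
    expect_equal(back$items[[j]]$a, bank$items[[j]]$a, tolerance = 1e-9)
    expect_equal(back$items[[j]]$b, bank$items[[j]]$b, tolerance = 1e-9)
  }
})
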