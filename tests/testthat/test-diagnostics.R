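# build a fit-like object directly from known parameters
params_fit <- function(params, itemset = seq_along(params$beta)) {
  list(params = params, itemset = itemset)
}

test_that("Infit and Outfit are exactly 1 in the symmetric dichotomous case", {
  # theta = beta for every subject: P = 0.5, so (x - E)^2 = W = 0.25 always
  X <- matrix(c(1L, 0L, 1L, 1L, 0L, 0L), 6, 1)
  dat <- response_data(X, max_categories = 1)
  memb <- dif_membership(matrix(0, 6, 1))
  prm <- gdif_params(rep(0.7, 6), list(0.7), 1, matrix(0, 1, 1))
  fits <- item_fit(dat, memb, params_fit(prm))
  expect_equal(fits$infit, 1)
  expect_equal(fits$outfit, 1)
})

test_that("item fit matches a direct mean-square computation", {
  sim <- tiny_sim(31, alpha = c(0.4, 1, 1, 2))
  fits <- item_fit(sim$data, sim$membership, params_fit(sim$truth))
  X <- sim$data$responses
  for (i in c(1, 4)) {
    p <- category_probabilities(sim$truth$theta, sim$truth$beta[[i]],
                                sim$truth$alpha[i],
                                sim$truth$delta[i, ], sim$membership$kappa)
    cats <- 0:(length(sim$truth$beta[[i]]))
    E <- drop(p %*% cats); W <- drop(p %*% cats^2) - E^2
    expect_equal(fits$outfit[i], mean((X[, i] - E)^2 / W), tolerance = 1e-10)
    expect_equal(fits$infit[i], sum((X[, i] - E)^2) / sum(W),
                 tolerance = 1e-10)
  }
  # low discrimination underfits, high discrimination overfits, when the
  # scoring model fixes the slope at 1
  pcm <- fit_gdif(sim$data, sim$membership,
                  constraint = constraint_for("pcm"))
  f <- item_fit(sim$data, sim$membership, pcm)
  expect_gt(f$infit[1], f$infit[4])
})

test_that("duplicated items give residual correlation 1", {
  sim <- tiny_sim(32, n_items = 2)
  X <- sim$data$responses
  X[, 2] <- X[, 1]
  dat <- response_data(X, max_categories = sim$data$m)
  prm <- sim$truth
  prm$beta[[2]] <- prm$beta[[1]]; prm$alpha[2] <- prm$alpha[1]
  rc <- residual_correlation(dat, sim$membership, params_fit(prm))
  expect_equal(as.numeric(rc), 1, tolerance = 1e-12)
  expect_error(residual_correlation(dat, sim$membership, params_fit(prm), 1),
               "two items")
})

test_that("independent items at true parameters have near-zero residual correlation", {
  tg <- rep(0.02 * (0:244) - 3, 2)
  beta <- lapply(1:12, function(i) ((i - 1) %% 6) - (1.3 + 0.8 * (0:3)))
  spec <- sim_spec(tg, beta, rep(1, 12), matrix(0, 12, 1),
                   matrix(rep(c(0, 1), each = 245), ncol = 1))
  sim <- simulate_gdif(spec, 33)
  rc <- residual_correlation(sim$data, sim$membership, params_fit(sim$truth))
  expect_lt(abs(as.numeric(rc)), 0.05)
})

test_that("two-item residual correlation equals the hand formula", {
  sim <- tiny_sim(34, n_items = 2)
  ew <- raschdif:::expected_scores(sim$data, sim$membership, sim$truth, 1:2)
  Z <- (sim$data$responses - ew$E) / sqrt(ew$W)
  expect_equal(as.numeric(residual_correlation(sim$data, sim$membership,
                                               params_fit(sim$truth))),
               cor(Z[, 1], Z[, 2]), tolerance = 1e-12)
})

test_that("person separation reliability behaves at its anchors", {
  sim <- tiny_sim(35)
  fit <- fit_gdif(sim$data, sim$membership)
  psr <- person_separation_reliability(sim$data, sim$membership, fit)
  expect_lte(psr, 1)
  # wide ability spread is measured more reliably than a narrow one
  mk <- function(scale, seed) {
    tg <- rep(seq(-3, 3, length.out = 100), 2) * scale
    spec <- sim_spec(tg, lapply(1:6, function(i) c(-1, 0, 1)), rep(1, 6),
                     matrix(0, 6, 1), matrix(rep(c(0, 1), each = 100), ncol = 1))
    sim <- simulate_gdif(spec, seed)
    fit <- fit_gdif(sim$data, sim$membership,
                    constraint = constraint_for("pcm"))
    person_separation_reliability(sim$data, sim$membership, fit)
  }
  expect_gt(mk(1, 36), mk(0.15, 36))
  # constant abilities: undefined
  prm <- sim$truth; prm$theta[] <- 1
  expect_warning(
    psr0 <- person_separation_reliability(sim$data, sim$membership,
                                          params_fit(prm)),
    "constant")
  expect_true(is.na(psr0))
})

test_that("Cronbach's alpha and the removal curve are computed correctly", {
  # two perfectly correlated items
  x2 <- cbind(a = c(0, 1, 2, 3, 1), b = c(0, 1, 2, 3, 1))
  expect_equal(cronbach_alpha(x2), 1)
  # 3 x 3 integer toy table, hand arithmetic:
  x3 <- cbind(c(0, 1, 2), c(1, 1, 2), c(0, 2, 2))
  k <- 3
  hand <- k / (k - 1) * (1 - sum(apply(x3, 2, var)) / var(rowSums(x3)))
  expect_equal(cronbach_alpha(x3), hand)
  crv <- cronbach_mesbah_curve(x3, c(3, 1, 2))
  expect_equal(crv$n_items, c(3, 2))
  expect_equal(crv$alpha[2], cronbach_alpha(x3[, 1:2]))
  expect_error(cronbach_mesbah_curve(x3, c(1, 2)), "permutation")
})

test_that("overlap probabilities are exact hypergeometric tails", {
  expect_equal(round(overlap_probability(16, 8, 8, 6), 2), 0.07)
  expect_equal(overlap_probability(16, 8, 8, 6), 849 / 12870,
               tolerance = 1e-12)
  expect_equal(overlap_probability(10, 4, 5, 0), 1, tolerance = 1e-12)
  expect_equal(overlap_probability(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  # dual route: agree with the distribution function implementation
  for (mo in 0:8)
    expect_equal(overlap_probability(30, 12, 12, mo),
                 phyper(mo - 1, 12, 18, 12, lower.tail = FALSE),
                 tolerance = 1e-12)
  # probabilities over the full support sum to 1
  pt <- vapply(0:8, function(k)
    overlap_probability(16, 8, 8, k) -
      if (k < 8) overlap_probability(16, 8, 8, k + 1) else 0, 0)
  expect_equal(sum(pt), 1, tolerance = 1e-12)
  expect_error(overlap_probability(10, 11, 2, 1), "total_items")
})

test_that("ability correlations hit their anchors", {
  sim <- tiny_sim(37)
  fit <- fit_gdif(sim$data, sim$membership)
  expect_equal(ability_correlation(fit, fit), 1)
  flip <- fit; flip$params$theta <- -flip$params$theta
  expect_equal(ability_correlation(fit, flip), -1)
  a <- list(params = list(theta = c(1, 2, 4)))
  b <- list(params = list(theta = c(0, 1, 1)))
  expect_equal(ability_correlation(a, b), cor(c(1, 2, 4), c(0, 1, 1)))
  cst <- list(params = list(theta = c(1, 1, 1)))
  expect_warning(expect_true(is.na(ability_correlation(a, cst))),
                 "zero-variance")
})

test_that("random instrument baselines are reproducible and bounded by search", {
  sim <- tiny_sim(38, n_items = 4, n_per_group = 30)
  b1 <- random_instrument_baseline(sim$data, sim$membership, k = 2,
                                   n_draws = 8, seed = 5)
  b2 <- random_instrument_baseline(sim$data, sim$membership, k = 2,
                                   n_draws = 8, seed = 5)
  expect_identical(b1$scores, b2$scores)
  expect_identical(b1$draws, b2$draws)
  # k = P: only one possible draw
  bP <- random_instrument_baseline(sim$data, sim$membership, k = 4,
                                   n_draws = 5, seed = 1)
  expect_equal(var(bP$scores), 0)
  tr <- stepwise_search(sim$data, sim$membership)
  expect_gte(tr$best_score$ipoq_ll_dif, max(b1$scores) - 1e-6)
})
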