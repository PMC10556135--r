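test_that("category probabilities match direct evaluation of the model", {
  # symmetric dichotomous case
  expect_equal(drop(category_probabilities(0, 0, 1, 0, 0)), c(0.5, 0.5))
  # theta = 1, two zero thresholds: weights {1, e, e^2} normalized
  p <- drop(category_probabilities(1, c(0, 0), 1, 0, 0))
  expect_equal(p, c(1, exp(1), exp(2)) / sum(c(1, exp(1), exp(2))))
  expect_equal(round(p, 4), c(0.0900, 0.2447, 0.6652))
  # random admissible inputs against the independent oracle
  set.seed(11)
  for (r in 1:25) {
    m <- sample(1:4, 1)
    mf <- sample(1:2, 1)
    th <- rnorm(1); be <- rnorm(m); al <- exp(rnorm(1, 0, 0.5))
    de <- rnorm(mf); ka <- rbinom(mf, 1, 0.5)
    expect_equal(drop(category_probabilities(th, be, al, de, ka)),
                 oracle_probs(th, be, al, de, ka), tolerance = 1e-12)
  }
})

test_that("probabilities normalize and respect the DIF-shift identity", {
  set.seed(21)
  for (r in 1:50) {
    m <- sample(1:5, 1)
    th <- rnorm(5, 0, 2); be <- rnorm(m, 0, 2); al <- exp(rnorm(1, 0, 1))
    de <- rnorm(1, 0, 3)
    p <- category_probabilities(th, be, al, de, matrix(1, 5, 1))
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
    if (max(abs(c(th, be, de))) < 3 && al < 3)  # no underflow regime
      expect_true(all(p > 0 & p < 1))
    # offset enters only through beta - delta * kappa
    p2 <- category_probabilities(th, be - de, al, 0, matrix(0, 5, 1))
    expect_equal(p, p2, tolerance = 1e-14)
  }
  # extreme logits survive the log-sum-exp guard
  p <- category_probabilities(40, c(-30, 30), 2, 0, 0)
  expect_equal(rowSums(p), 1, tolerance = 1e-12)
  expect_false(anyNA(p))
})

test_that("expected score is strictly increasing in theta", {
  th <- seq(-4, 4, by = 0.25)
  for (al in c(0.3, 1, 2.5)) {
    p <- category_probabilities(th, c(-0.5, 0.2, 1.1), al, 0,
                                matrix(0, length(th), 1))
    es <- drop(p %*% (0:3))
    expect_true(all(diff(es) > 0))
  }
})

test_that("constraint flags reproduce the nested models", {
  prm <- gdif_params(theta = c(-1, 0, 1),
                     beta = list(c(0.3), c(-0.2, 0.5)),
                     alpha = c(1.7, 0.6),
                     delta = matrix(c(0.4, -0.8), 2, 1))
  both <- apply_constraint(prm, model_constraint(TRUE, TRUE))
  expect_equal(both$alpha, c(1, 1))
  expect_equal(drop(both$delta), c(0, 0))
  expect_identical(apply_constraint(prm, model_constraint(FALSE, FALSE)), prm)
  # dichotomous PCM = the Rasch logistic form
  for (th in c(-2, 0, 1.3)) for (be in c(-1, 0.4)) {
    p <- drop(category_probabilities(th, be, 1, 0, 0))
    expect_equal(p[2], oracle_rasch(th, be), tolerance = 1e-12)
  }
})

test_that("log likelihood sums per-cell log probabilities and skips missing", {
  expect_identical(loglik_gdif(
    response_data(matrix(0:1, 2, 1), max_categories = 1),
    dif_membership(matrix(0, 2, 1)),
    gdif_params(c(0, 0), list(0), 1, matrix(0, 1, 1)),
    integer(0)), 0)

  d1 <- response_data(matrix(1L, 1, 1), max_categories = 1)
  m1 <- dif_membership(matrix(0, 1, 1))
  p1 <- gdif_params(0, list(0), 1, matrix(0, 1, 1))
  expect_equal(loglik_gdif(d1, m1, p1), log(0.5), tolerance = 1e-12)

  X <- matrix(c(0L, 2L, 1L, 1L, NA, 0L), 3, 2)
  dat <- response_data(X, max_categories = c(2, 1))
  kap <- matrix(c(0, 1, 1), 3, 1)
  memb <- dif_membership(kap)
  prm <- gdif_params(c(-0.5, 0.2, 1), list(c(-0.3, 0.6), 0.1),
                     c(0.8, 1.4), matrix(c(0.5, -0.2), 2, 1))
  expect_equal(loglik_gdif(dat, memb, prm),
               oracle_loglik(X, prm$theta, prm$beta, prm$alpha, prm$delta,
                             kap),
               tolerance = 1e-12)
  expect_lt(loglik_gdif(dat, memb, prm), 0)
})

test_that("penalized objective applies the three penalty terms", {
  sim <- tiny_sim(3)
  prm <- sim$truth
  all_items <- seq_along(prm$beta)
  ll <- loglik_gdif(sim$data, sim$membership, prm, all_items)
  expect_equal(penalized_objective(sim$data, sim$membership, prm, all_items,
                                   penalty_config(0, 0, 0)), ll)
  # anchored parameters incur no penalty
  prm0 <- prm; prm0$theta[] <- 0; prm0$alpha[] <- 1; prm0$delta[] <- 0
  ll0 <- loglik_gdif(sim$data, sim$membership, prm0, all_items)
  expect_equal(penalized_objective(sim$data, sim$membership, prm0, all_items,
                                   penalty_config(3, 7, 11)), ll0)
  # hand evaluation on a toy instance
  prm2 <- gdif_params(c(1, -1), list(c(0, 0)), exp(1),
                      matrix(0.5, 1, 1))
  dat2 <- response_data(matrix(c(0L, 2L), 2, 1), max_categories = 2)
  memb2 <- dif_membership(matrix(c(0, 1), 2, 1))
  L <- loglik_gdif(dat2, memb2, prm2)
  expect_equal(penalized_objective(dat2, memb2, prm2, 1,
                                   penalty_config(0.05, 50, 10)),
               L - 0.05 * 2 - 50 * 1 - 10 * 0.5, tolerance = 1e-12)
})

test_that("response data validates categories and labels", {
  expect_error(response_data(matrix(c(0L, 3L), 2, 1), max_categories = 2),
               "outside")
  expect_error(response_data(matrix(c(0L, 1L, 3L), 3, 1)), "middle categor")
  # declared category count permits sampling zeros
  d <- response_data(matrix(c(0L, 1L, 3L), 3, 1), max_categories = 3)
  expect_equal(d$m, 3L)
  expect_error(response_data(matrix(0L, 2, 1), max_categories = 1), NA)
  expect_error(dif_membership(matrix(c(0, 2), 2, 1)), "exactly 0 or 1")
  expect_error(gdif_params(0, list(0), -1, matrix(0, 1, 1)), "positive")
})
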