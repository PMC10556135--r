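test_that("starting values follow the score and log-odds rules", {
  # constant raw scores: z-score of a constant is defined as 0
  d0 <- response_data(matrix(0L, 5, 2), max_categories = 1)
  m0 <- dif_membership(matrix(0, 5, 1))
  init <- suppressWarnings(initialize_params(d0, m0))
  expect_equal(init$theta, rep(0, 5))
  expect_equal(init$alpha, c(1, 1))
  expect_equal(unname(drop(init$delta)), c(0, 0))
  # balanced dichotomous item: threshold starts at the log-odds of 0.5
  d1 <- response_data(matrix(c(0L, 1L, 0L, 1L), 4, 1), max_categories = 1)
  m1 <- dif_membership(matrix(0, 4, 1))
  init1 <- initialize_params(d1, m1)
  expect_equal(init1$beta[[1]], 0)
  # single observed category warns (once per degenerate item)
  expect_warning(
    expect_warning(initialize_params(d0, m0), "single observed category"),
    "single observed category")
})

test_that("no group signal drives all DIF offsets to zero", {
  sim <- tiny_sim(5, n_per_group = 60)   # groups share the generating model
  fit <- fit_gdif(sim$data, sim$membership,
                  penalties = penalty_config(0.05, 50, 10))
  expect_true(all(fit$params$delta == 0))
  expect_true(fit$converged)
})

test_that("a huge lasso coefficient forces every DIF offset to zero", {
  sim <- tiny_sim(6, dif_item = 2, dif_shift = -2)
  fit <- fit_gdif(sim$data, sim$membership,
                  penalties = penalty_config(0.05, 50, 1e6),
                  constraint = constraint_for("pcm_dif"))
  expect_true(all(fit$params$delta == 0))
  # while at a moderate penalty the planted item is detected
  fit2 <- fit_gdif(sim$data, sim$membership,
                   penalties = penalty_config(0.05, 50, 2),
                   constraint = constraint_for("pcm_dif"))
  expect_true(abs(fit2$params$delta[2, 1]) > 0.5)
})

test_that("one-dimensional DIF updates match a fine grid search", {
  sim <- tiny_sim(7, dif_item = 1, dif_shift = -1.5)
  prm <- sim$truth
  prm$delta[1, 1] <- 0
  for (ld in c(0, 0.5, 5)) {
    upd <- update_delta_coordinate(prm, 1, 1, sim$data, sim$membership,
                                   penalty_config(0.05, 50, ld))
    grid <- seq(-10, 10, by = 1e-4)
    p2 <- prm
    vals <- vapply(grid, function(d) {
      p2$delta[1, 1] <- d
      loglik_gdif(sim$data, sim$membership, p2, 1) - ld * abs(d)
    }, 0)
    expect_equal(upd, grid[which.max(vals)], tolerance = 2e-4)
  }
})

test_that("the objective trace ascends and the fit reaches stationarity", {
  for (seed in 1:3) {
    sim <- tiny_sim(seed, dif_item = 2, dif_shift = 1.2,
                    alpha = c(0.7, 1, 1.3, 1))
    fit <- fit_gdif(sim$data, sim$membership,
                    penalties = penalty_config(0.05, 5, 3))
    expect_false(is.unsorted(fit$trace))
    expect_true(fit$converged)
    # L1 optimality: zero coordinates have |smooth derivative| <= lambda
    # (unless suppressed as negligible), nonzero ones maximize their axis
    prm <- fit$params
    prm$delta[is.na(prm$delta)] <- 0
    for (i in fit$itemset) {
      d_hat <- prm$delta[i, 1]
      upd <- update_delta_coordinate(prm, i, 1, sim$data, sim$membership,
                                     penalty_config(0.05, 5, 3))
      if (d_hat == 0) expect_lt(abs(upd), 0.43 + 1e-6)
      else expect_equal(upd, d_hat, tolerance = 1e-4)
    }
  }
})

test_that("tiny instances match an exhaustive grid-search oracle", {
  # one dichotomous item, four subjects, alpha and delta fixed: by the
  # symmetry of identical response patterns the free coordinates reduce to
  # (theta for x=1, theta for x=0, beta)
  X <- matrix(c(1L, 1L, 0L, 0L), 4, 1)
  dat <- response_data(X, max_categories = 1)
  memb <- dif_membership(matrix(0, 4, 1))
  pen <- penalty_config(0.05, 50, 10)
  fit <- fit_gdif(dat, memb, 1, pen, constraint_for("pcm"))
  f <- function(p) {
    prm <- gdif_params(c(p[1], p[1], p[2], p[2]), list(p[3]), 1,
                       matrix(0, 1, 1))
    penalized_objective(dat, memb, prm, 1, pen)
  }
  oracle <- grid_maximize(f, lower = rep(-4, 3), upper = rep(4, 3))
  expect_equal(fit$objective, oracle$value, tolerance = 1e-3)
  expect_equal(unname(fit$params$theta),
               unname(c(oracle$par[1], oracle$par[1], oracle$par[2],
                        oracle$par[2])),
               tolerance = 5e-3)
  expect_equal(unname(fit$params$beta[[1]]), unname(oracle$par[3]),
               tolerance = 5e-3)
})

test_that("fitting with abilities held fixed leaves them untouched", {
  sim <- tiny_sim(9)
  th <- sim$truth$theta
  init <- sim$truth
  fit <- fit_gdif(sim$data, sim$membership, 2,
                  penalty_config(0.05, 1, 10), init = init,
                  fix_theta = TRUE)
  expect_identical(fit$params$theta, th)
  expect_error(fit_gdif(sim$data, sim$membership, 2, fix_theta = TRUE),
               "init")
  expect_error(fit_gdif(sim$data, sim$membership, integer(0)), "nonempty")
})
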