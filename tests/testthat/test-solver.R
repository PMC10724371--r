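test_that("at or above lambda_max the fit is intercept-only and immediate", {
  ds <- toy_itemset()
  fit <- solve_point(ds, 0.5, 0)
  expect_length(fit$coef, 0)
  expect_equal(fit$beta0, mean(ds$y))
  expect_lte(fit$n_iter, 2L)
  expect_true(fit$converged)
  expect_equal(fit$gap, 0, tolerance = 1e-12)
})

test_that("converged coefficients match the brute-force oracle", {
  sy <- small_synth("itemset", seed = 3, n = 30)
  ds <- sy$dataset
  loss <- loss_spec("squared", ds$y)
  lmax <- spp_lambda_max(ds, loss, 3)
  for (kap in c(0, 0.1)) {
    fit <- solve_point(ds, 0.25 * lmax, kap, loss = loss, max_length = 3,
                       cfg = spp_config(tol = 1e-11))
    orc <- brute_force_fit(ds, 0.25 * lmax, kap, loss, 3, tol = 1e-12)
    expect_lt(fit_oracle_diff(fit, orc), 1e-5)
  }
  # squared hinge on classification data
  syc <- small_synth("itemset", seed = 4, n = 30, task = "classification")
  dc <- syc$dataset
  lossc <- loss_spec("squared_hinge", dc$y)
  lmaxc <- spp_lambda_max(dc, lossc, 3)
  fitc <- solve_point(dc, 0.3 * lmaxc, 0.1, loss = lossc, max_length = 3,
                      cfg = spp_config(tol = 1e-11))
  orcc <- brute_force_fit(dc, 0.3 * lmaxc, 0.1, lossc, 3, tol = 1e-12)
  expect_lt(fit_oracle_diff(fitc, orcc), 1e-5)
})

test_that("dynamic screening accelerates without changing the answer", {
  sy <- small_synth("itemset", seed = 13, n = 40)
  ds <- sy$dataset
  loss <- loss_spec("squared", ds$y)
  lmax <- spp_lambda_max(ds, loss, 3)
  lam <- 0.2 * lmax
  on <- solve_point(ds, lam, 0, loss = loss, max_length = 3,
                    cfg = spp_config(tol = 1e-10))
  off <- solve_point(ds, lam, 0, loss = loss, max_length = 3,
                     cfg = spp_config(tol = 1e-10, dynamic_screening = FALSE))
  expect_lt(coef_diff(on$coef, off$coef), 1e-6)
  # working set only shrinks across screening events
  expect_true(all(diff(on$screen_log$n_active) <= 0))
  # the reported gap never increases from one screening event to the next
  expect_true(all(diff(on$screen_log$gap) <= 1e-10))
})

test_that("the convergence certificate holds against an independent recomputation", {
  sy <- small_synth("sequence", seed = 9, n = 25)
  ds <- sy$dataset
  loss <- loss_spec("squared", ds$y)
  lmax <- spp_lambda_max(ds, loss, 3)
  for (kap in c(0, 0.1)) {
    fit <- solve_point(ds, 0.3 * lmax, kap, loss = loss, max_length = 3)
    expect_true(fit$converged)
    # recompute P and D from first principles over the full enumeration
    ep <- enumerate_patterns(ds, 3)
    n <- 25
    X <- matrix(0, n, nrow(ep))
    for (j in seq_len(nrow(ep))) X[ep$support[[j]], j] <- 1
    bfull <- numeric(nrow(ep))
    bfull[match(names(fit$coef), ep$key)] <- fit$coef
    v <- fit$beta0 + as.numeric(X %*% bfull)
    P <- sum((v - ds$y)^2) / (2 * n) +
      fit$lambda * sum(abs(bfull) + kap / 2 * bfull^2)
    abar <- (ds$y - v) / n
    a <- abar - mean(abar)
    if (kap == 0) {
      mc <- max(abs(crossprod(X, a)))
      mu <- min(max(sum(a * ds$y) / (n * sum(a^2)), -fit$lambda / mc),
                fit$lambda / mc)
      a <- mu * a
    }
    corr <- as.numeric(crossprod(X, a))
    D <- sum(a * ds$y) - n / 2 * sum(a^2) -
      if (kap > 0) sum(pmax(abs(corr) - fit$lambda, 0)^2) /
        (2 * kap * fit$lambda) else 0
    expect_lte(P - D, 1e-4 * max(1, abs(P)))
    # every reported active pattern really carries a nonzero coefficient
    expect_true(all(fit$coef != 0))
  }
})

test_that("hitting the iteration cap flags non-convergence", {
  sy <- small_synth("itemset", seed = 3, n = 30)
  ds <- sy$dataset
  lmax <- spp_lambda_max(ds, max_length = 3)
  fit <- solve_point(ds, 0.2 * lmax, 0, max_length = 3,
                     cfg = spp_config(tol = 1e-14, max_iter = 3L))
  expect_false(fit$converged)
})

test_that("dual iterates along the trajectory are always feasible", {
  for (task in c("regression", "classification")) {
    sy <- small_synth("itemset", seed = 10, n = 30, task = task)
    ds <- sy$dataset
    loss <- sppmine:::default_loss(ds)
    lmax <- spp_lambda_max(ds, loss, 3)
    ep <- enumerate_patterns(ds, 3)
    X <- matrix(0, 30, nrow(ep))
    for (j in seq_len(nrow(ep))) X[ep$support[[j]], j] <- 1
    for (kap in c(0, 0.1)) {
      fit <- solve_point(ds, 0.3 * lmax, kap, loss = loss, max_length = 3,
                         cfg = spp_config(tol = 1e-9,
                                          record_trajectory = TRUE))
      expect_gt(length(fit$trajectory), 0)
      for (a in fit$trajectory) {
        expect_lt(abs(sum(a)), 1e-9)
        if (task == "classification") expect_true(all(ds$y * a >= -1e-12))
        expect_true(is.finite(loss$conj_neg(a)))
      }
      if (kap == 0) {
        # the box constraint holds over the *working-set* columns the
        # solver screens with; full-space feasibility is restored at
        # certification time by the exact rescale
        final_a <- fit$alpha
        expect_lt(max(abs(crossprod(X, final_a))),
                  fit$lambda * (1 + 1e-9) + 1e-12)
      }
    }
  }
})

test_that("M-capped multi-reference dynamic screening matches single-reference answers", {
  sy <- small_synth("itemset", seed = 29, n = 40)
  ds <- sy$dataset
  loss <- loss_spec("squared", ds$y)
  lmax <- spp_lambda_max(ds, loss, 3)
  lam <- 0.25 * lmax
  mk <- function(at_lam, tl) {
    f <- solve_point(ds, at_lam, 0, loss = loss, max_length = 3,
                     cfg = spp_config(tol = tl, dynamic_screening = FALSE))
    make_reference(ds, loss, lam, 0, f$beta0, f$patterns, unname(f$coef),
                   f$supports, 3)
  }
  refs <- list(mk(lam * 1.3, 1e-3), mk(lam * 1.6, 1e-2))
  fits <- lapply(c(0L, 1L, 3L), function(M) {
    solve_point(ds, lam, 0, refs = refs, loss = loss, max_length = 3,
                cfg = spp_config(tol = 1e-10, M = M))
  })
  for (k in 2:3) expect_lt(coef_diff(fits[[1]]$coef, fits[[k]]$coef), 1e-6)
  for (f in fits) expect_true(f$converged)
})
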