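test_that("the lambda grid is log-spaced, decreasing, and kappa starts at zero", {
  g <- spp_grid(0.8, n_lambda = 5)
  expect_equal(g$lambda[1], 0.8)
  expect_equal(g$lambda[5], 0.008)
  expect_true(all(diff(log(g$lambda)) < 0))
  expect_equal(diff(log(g$lambda)), rep(diff(log(g$lambda))[1], 4))
  expect_equal(g$kappa[1], 0)
  expect_error(spp_grid(0.8, kappa = c(0.1, 1)), "start at 0")
})

test_that("the 1-D path starts empty, grows on the toy data, and matches cold starts", {
  sy <- small_synth("itemset", seed = 11, n = 40, noise_sd = 0.1)
  ds <- sy$dataset
  cfg <- spp_config(tol = 1e-11)
  pt <- spp_path(ds, kappa = 0, n_lambda = 6, max_length = 3, cfg = cfg)
  expect_equal(pt$results$n_active[1], 0L)
  expect_true(all(pt$results$converged))
  for (k in seq_along(pt$lambda)) {
    cold <- solve_point(ds, pt$lambda[k], 0, max_length = 3, cfg = cfg)
    expect_true(same_model(cold, pt$fits[[k]], ds), info = paste("k =", k))
  }
  # active-set growth along the toy path (monotone on this instance)
  expect_true(all(diff(pt$results$n_active) >= 0))
})

test_that("every 2-D grid cell matches the full-enumeration oracle", {
  sy <- small_synth("itemset", seed = 16, n = 25)
  ds <- sy$dataset
  cfg <- spp_config(tol = 1e-11)
  p2 <- spp_path2d(ds, n_lambda = 4, kappa = c(0, 0.1, 1), max_length = 3,
                   cfg = cfg)
  expect_equal(nrow(p2$results), 12L)
  for (k in 2:4) {
    for (kp in 1:3) {
      fit <- p2$fits[[k]][[kp]]
      orc <- brute_force_fit(ds, fit$lambda, fit$kappa, max_length = 3,
                             tol = 1e-12)
      eq <- oracle_equiv(fit, orc)
      expect_true(eq$ok, info = sprintf(
        "cell (%d,%d): fitted %.2e P %.2e unique %s coord %.2e",
        k, kp, eq$fitted_diff, eq$P_diff, eq$unique, eq$coord_diff))
    }
  }
  # the lambda_max column is copied, not solved
  expect_true(all(p2$results$n_active[p2$results$lambda == p2$lambda[1]] == 0))
})

test_that("two references prune and visit no more than one forced reference", {
  sy <- small_synth("itemset", seed = 16, n = 25)
  ds <- sy$dataset
  p2 <- spp_path2d(ds, n_lambda = 4, kappa = c(0, 0.1, 1), max_length = 3)
  p1 <- spp_path2d(ds, n_lambda = 4, kappa = c(0, 0.1, 1), max_length = 3,
                   cfg = spp_config(multi_ref = FALSE))
  expect_lte(sum(p2$results$nodes_visited), sum(p1$results$nodes_visited))
  expect_lte(sum(p2$results$ws_size), sum(p1$results$ws_size))
  expect_lt(coef_diff(p2$fits[[4]][[2]]$coef, p1$fits[[4]][[2]]$coef), 1e-3)
})

test_that("CV folds match cold starts, score held-out data, and select by mean loss", {
  sy <- small_synth("itemset", seed = 11, n = 40, noise_sd = 0.1)
  ds <- sy$dataset
  cfg <- spp_config(tol = 1e-11)
  set.seed(5)
  cv <- spp_cv(ds, kappa = 0, n_lambda = 5, folds = 3, max_length = 3,
               cfg = cfg)
  expect_equal(nrow(cv$cv_table), 15L)
  # fold fits equal cold starts on the fold's own training data
  for (f in 1:2) {
    dtrain <- subset_dataset(ds, cv$fold_train[[f]])
    for (k in c(3L, 5L)) {
      cold <- solve_point(dtrain, cv$lambda[k], 0, max_length = 3, cfg = cfg)
      expect_true(same_model(cold, cv$fold_fits[[f]][[k]], dtrain),
                  info = sprintf("fold %d k %d", f, k))
    }
  }
  # the selected lambda minimizes the mean validation loss
  means <- tapply(cv$cv_table$val_loss, cv$cv_table$lambda, mean)
  expect_equal(cv$lambda_min,
               max(as.numeric(names(means)[means == min(means)])))
})

test_that("leave-one-out folds hold out exactly one instance", {
  sy <- small_synth("itemset", seed = 25, n = 12)
  ds <- sy$dataset
  set.seed(1)
  cv <- spp_cv(ds, kappa = 0, n_lambda = 3, folds = "loo", max_length = 3)
  expect_equal(length(cv$fold_fits), 12L)
  expect_true(all(cv$cv_table$n_val == 1L))
})

test_that("ties in validation loss break toward the larger lambda", {
  tbl <- tibble::tibble(
    lambda = rep(c(0.5, 0.2, 0.1), each = 2),
    fold = rep(1:2, 3),
    val_loss = c(0.4, 0.6, 0.3, 0.7, 0.9, 0.1))  # means: 0.5, 0.5, 0.5
  expect_equal(sppmine:::select_lambda_cv(tbl)$lambda_min, 0.5)
  tbl2 <- tbl
  tbl2$val_loss[3] <- 0.25                        # means: 0.5, 0.475, 0.5
  expect_equal(sppmine:::select_lambda_cv(tbl2)$lambda_min, 0.2)
})

test_that("zero-noise planted patterns are recovered at the CV optimum", {
  hits <- 0L
  for (seed in 1:10) {
    sy <- spp_synth("itemset", n = 200, k_patterns = 3, pattern_size = 2,
                    noise_sd = 0, seed = 100 + seed)
    set.seed(seed)
    cv <- spp_cv(sy$dataset, kappa = 0, n_lambda = 10, folds = 5,
                 max_length = 3)
    if (all(sy$truth$key %in% names(cv$best_fit$coef))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("classification CV scores squared-hinge loss and 0/1 error", {
  sy <- small_synth("itemset", seed = 41, n = 40, task = "classification",
                    noise_sd = 0.1)
  ds <- sy$dataset
  set.seed(3)
  cv <- spp_cv(ds, kappa = 0, n_lambda = 4, folds = 3, max_length = 3)
  expect_true(all(is.finite(cv$cv_table$val_loss)))
  expect_true(all(cv$cv_table$val_error >= 0 & cv$cv_table$val_error <= 1))
})

test_that("tidy, glance and autoplot surfaces are well-formed tibbles/plots", {
  sy <- small_synth("itemset", seed = 11, n = 30)
  ds <- sy$dataset
  pt <- spp_path(ds, kappa = 0, n_lambda = 4, max_length = 3)
  td <- tidy(pt)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("key", "coefficient", "lambda") %in% names(td)))
  expect_s3_class(glance(pt), "tbl_df")
  expect_s3_class(autoplot(pt), "ggplot")
  fit <- pt$fits[[length(pt$fits)]]
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), length(fit$coef))
  set.seed(4)
  cv <- spp_cv(ds, kappa = 0, n_lambda = 3, folds = 3, max_length = 3)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(glance(cv), "tbl_df")
  expect_s3_class(plot_screening_stats(pt), "ggplot")
})
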