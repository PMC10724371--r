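#' Regularization grid
#'
#' `lambda` runs from `lambda_max` down to `lambda_min_ratio * lambda_max`,
#' log-spaced; `kappa` defaults to the increasing sequence
#' `{0, 0.01, 0.1, 1, 10, 100}` with `kappa[1] = 0` required.
#'
#' @param lambda_max smallest L1 strength with an all-zero model (see
#'   [spp_lambda_max()]).
#' @param n_lambda number of lambda grid points.
#' @param lambda_min_ratio ratio of the last to the first lambda.
#' @param kappa increasing vector of relative L2 strengths.
#' @return list with `lambda` (decreasing) and `kappa` (increasing).
#' @export
spp_grid <- function(lambda_max, n_lambda = 10L, lambda_min_ratio = 0.01,
                     kappa = c(0, 0.01, 0.1, 1, 10, 100)) {
  stopifnot(lambda_max > 0, n_lambda >= 1L,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  if (is.unsorted(kappa, strictly = TRUE) || kappa[1L] != 0) {
    stop("kappa grid must be strictly increasing and start at 0", call. = FALSE)
  }
  lam <- lambda_max * lambda_min_ratio^(seq(0, 1, length.out = n_lambda))
  list(lambda = lam, kappa = kappa)
}

fit_as_reference <- function(dataset, loss, fit, lambda, kappa, max_length,
                             seq_mode) {
  make_reference(dataset, loss, lambda, kappa, beta0 = fit$beta0,
                 patterns = fit$patterns, coefs = unname(fit$coef),
                 supports = fit$supports, max_length = max_length,
                 seq_mode = seq_mode)
}

# the k=1 grid point: all-zero model, optimal for lambda >= lambda_max
zero_fit <- function(dataset, loss, lambda, kappa, max_length, seq_mode) {
  b0 <- loss$fit_intercept()
  eg <- exact_gap(dataset, loss, lambda, kappa, b0, list(), numeric(0),
                  max_length, seq_mode)
  structure(list(
    lambda = lambda, kappa = kappa, beta0 = b0,
    coef = stats::setNames(numeric(0), character(0)),
    patterns = list(), supports = list(),
    P = eg$P, D = eg$D, gap = eg$gap,
    rel_gap = eg$gap / max(1, abs(eg$P)), alpha = eg$alpha,
    n_iter = 0L, converged = TRUE,
    ws_counters = list(visited = 0L, pruned = 0L, expanded = 0L, kept = 0L),
    ws_size_final = 0L,
    screen_log = tibble::tibble(cycle = integer(0), n_active = integer(0),
                                gap = numeric(0), n_removed = integer(0)),
    trajectory = NULL, loss_kind = loss$kind, task = dataset$task,
    max_length = max_length, seq_mode = seq_mode
  ), class = "spp_fit")
}

path_row <- function(fit) {
  tibble::tibble(
    lambda = fit$lambda, kappa = fit$kappa, beta0 = fit$beta0,
    n_active = length(fit$coef), gap = fit$gap, rel_gap = fit$rel_gap,
    n_iter = fit$n_iter, converged = fit$converged,
    nodes_visited = fit$ws_counters$visited,
    subtrees_pruned = fit$ws_counters$pruned,
    ws_size = fit$ws_counters$kept,
    ws_size_final = fit$ws_size_final
  )
}

#' One-dimensional regularization path
#'
#' Sweeps `lambda` from `lambda_max` downward at fixed `kappa`, warm-starting
#' each point with the previous optimum as the (dual-rescaled) reference
#' solution for pruning, screening and initialization.
#'
#' @param dataset an [spp_dataset()].
#' @param kappa fixed relative L2 strength.
#' @param n_lambda,lambda_min_ratio grid controls (see [spp_grid()]).
#' @param lambda optional explicit decreasing lambda sequence overriding the
#'   grid controls (must start at `lambda_max`).
#' @param loss,max_length,seq_mode,cfg as in [solve_point()].
#' @return an `spp_path`: tibble of per-point results plus the fitted models.
#' @export
spp_path <- function(dataset, kappa = 0, n_lambda = 10L,
                     lambda_min_ratio = 0.01, lambda = NULL, loss = NULL,
                     max_length = NULL, seq_mode = c("gapped", "contiguous"),
                     cfg = spp_config()) {
  seq_mode <- match.arg(seq_mode)
  if (is.null(loss)) loss <- default_loss(dataset)
  if (is.null(max_length)) max_length <- default_max_length(dataset$type)
  if (is.null(lambda)) {
    lmax <- spp_lambda_max(dataset, loss, max_length, seq_mode)
    if (lmax <= 0) stop("lambda_max is 0: no pattern can ever activate", call. = FALSE)
    lambda <- spp_grid(lmax, n_lambda, lambda_min_ratio)$lambda
  }
  fits <- vector("list", length(lambda))
  fits[[1L]] <- zero_fit(dataset, loss, lambda[1L], kappa, max_length, seq_mode)
  for (k in seq_along(lambda)[-1L]) {
    ref <- fit_as_reference(dataset, loss, fits[[k - 1L]], lambda[k], kappa,
                            max_length, seq_mode)
    fits[[k]] <- solve_point(dataset, lambda[k], kappa, refs = list(ref),
                             loss = loss, max_length = max_length,
                             seq_mode = seq_mode, cfg = cfg)
  }
  structure(list(
    results = dplyr::bind_rows(lapply(fits, path_row)),
    fits = fits, lambda = lambda, kappa = kappa,
    task = dataset$task, type = dataset$type
  ), class = "spp_path")
}

#' @export
print.spp_path <- function(x, ...) {
  cat(sprintf("<spp_path> %d lambda points, kappa=%.3g\n",
              length(x$lambda), x$kappa[1L]))
  print(x$results)
  invisible(x)
}

#' Two-dimensional (lambda, kappa) regularization path
#'
#' Traverses the grid in the order (lambda1, kappa1), (lambda1, kappa2), ...,
#' (lambda2, kappa1), ...; each cell's reference set holds the optimum at
#' the previous lambda (same kappa) and, when `kappa' > kappa[1]`, the
#' optimum at the previous kappa (same lambda) — two references whenever
#' both neighbors exist, enabling two-sphere screening and min-rule pruning.
#' At `lambda = lambda_max` the model is zero for every kappa, so the kappa
#' sweep there is skipped by copying the zero solution.
#'
#' @inheritParams spp_path
#' @param kappa increasing kappa sequence starting at 0.
#' @return an `spp_path2d` with a results tibble (one row per grid cell) and
#'   the fitted models in `fits[[k_lambda]][[k_kappa]]`.
#' @export
spp_path2d <- function(dataset, n_lambda = 10L, lambda_min_ratio = 0.01,
                       kappa = c(0, 0.01, 0.1, 1, 10, 100), lambda = NULL,
                       loss = NULL, max_length = NULL,
                       seq_mode = c("gapped", "contiguous"),
                       cfg = spp_config()) {
  seq_mode <- match.arg(seq_mode)
  if (is.null(loss)) loss <- default_loss(dataset)
  if (is.null(max_length)) max_length <- default_max_length(dataset$type)
  if (is.null(lambda)) {
    lmax <- spp_lambda_max(dataset, loss, max_length, seq_mode)
    if (lmax <= 0) stop("lambda_max is 0: no pattern can ever activate", call. = FALSE)
    lambda <- spp_grid(lmax, n_lambda, lambda_min_ratio, kappa)$lambda
  }
  K <- length(lambda); Kp <- length(kappa)
  fits <- lapply(seq_len(K), function(i) vector("list", Kp))
  rows <- list()
  for (k in seq_len(K)) {
    for (kp in seq_len(Kp)) {
      if (k == 1L) {
        fits[[k]][[kp]] <- zero_fit(dataset, loss, lambda[1L], kappa[kp],
                                    max_length, seq_mode)
      } else {
        refs <- list(fit_as_reference(dataset, loss, fits[[k - 1L]][[kp]],
                                      lambda[k], kappa[kp], max_length, seq_mode))
        if (kp > 1L) {
          refs <- c(refs, list(fit_as_reference(dataset, loss,
                                                fits[[k]][[kp - 1L]],
                                                lambda[k], kappa[kp],
                                                max_length, seq_mode)))
        }
        fits[[k]][[kp]] <- solve_point(dataset, lambda[k], kappa[kp],
                                       refs = refs, loss = loss,
                                       max_length = max_length,
                                       seq_mode = seq_mode, cfg = cfg)
      }
      rows[[length(rows) + 1L]] <- path_row(fits[[k]][[kp]])
    }
  }
  structure(list(
    results = dplyr::bind_rows(rows), fits = fits,
    lambda = lambda, kappa = kappa,
    task = dataset$task, type = dataset$type
  ), class = "spp_path2d")
}

#' @export
print.spp_path2d <- function(x, ...) {
  cat(sprintf("<spp_path2d> %d x %d (lambda x kappa) grid\n",
              length(x$lambda), length(x$kappa)))
  print(x$results)
  invisible(x)
}

restrict_support <- function(support, idx) {
  which(idx %in% support)
}

# lambda minimizing the mean validation loss; ties go to the larger lambda
select_lambda_cv <- function(cv_table) {
  means <- dplyr::summarise(dplyr::group_by(cv_table, .data$lambda),
                            mean_loss = mean(.data$val_loss), .groups = "drop")
  ord <- dplyr::arrange(means, .data$mean_loss, dplyr::desc(.data$lambda))
  list(lambda_min = ord$lambda[1L], means = means)
}

#' Cross-validation path with full-data reference solutions
#'
#' First solves the full-data lambda path; then, for each fold and each
#' lambda, screens with two references — the full-data optimum at the same
#' lambda and the fold's own optimum at the previous lambda — both
#' dual-rescaled onto the fold's training data.  Held-out instances are
#' scored with the squared error (regression) or the squared hinge loss and
#' 0/1 error (classification); the selected lambda minimizes the mean
#' validation loss, ties broken toward the larger lambda.
#'
#' @inheritParams spp_path
#' @param folds number of folds, `"loo"` for leave-one-out, or an explicit
#'   list of training-index vectors (each a strict subset of `1:n`).
#' @return an `spp_cv`: the CV table (`lambda`, `fold`, `val_loss`, ...),
#'   the selected `lambda_min`, the full-data path, and per-fold paths.
#' @export
spp_cv <- function(dataset, kappa = 0, n_lambda = 10L,
                   lambda_min_ratio = 0.01, folds = 5L, loss = NULL,
                   max_length = NULL, seq_mode = c("gapped", "contiguous"),
                   cfg = spp_config()) {
  seq_mode <- match.arg(seq_mode)
  if (is.null(loss)) loss <- default_loss(dataset)
  if (is.null(max_length)) max_length <- default_max_length(dataset$type)
  n <- n_instances(dataset)
  full <- spp_path(dataset, kappa, n_lambda, lambda_min_ratio, loss = loss,
                   max_length = max_length, seq_mode = seq_mode, cfg = cfg)
  lambda <- full$lambda
  if (is.list(folds)) {
    train_sets <- lapply(folds, as.integer)
  } else if (identical(folds, "loo")) {
    train_sets <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  } else {
    blk <- sample(rep_len(seq_len(as.integer(folds)), n))
    train_sets <- lapply(seq_len(as.integer(folds)),
                         function(f) which(blk != f))
  }
  rows <- list()
  fold_fits <- vector("list", length(train_sets))
  for (f in seq_along(train_sets)) {
    idx <- train_sets[[f]]
    vidx <- setdiff(seq_len(n), idx)
    if (dataset$task == "classification" &&
        length(unique(dataset$y[idx])) < 2L) {
      warning("fold ", f, " has a single class; skipped", call. = FALSE)
      next
    }
    dtrain <- subset_dataset(dataset, idx)
    dval <- subset_dataset(dataset, vidx)
    floss <- loss_spec(loss$kind, dtrain$y)
    ffits <- vector("list", length(lambda))
    for (k in seq_along(lambda)) {
      if (k == 1L) {
        # lambda[1] = full-data lambda_max may sit below the fold's own
        # lambda_max, so the fold's first point is solved, cold-started
        ffits[[k]] <- solve_point(dtrain, lambda[1L], kappa, refs = NULL,
                                  loss = floss, max_length = max_length,
                                  seq_mode = seq_mode, cfg = cfg)
      } else {
        fullfit <- full$fits[[k]]
        ref_full <- make_reference(
          dtrain, floss, lambda[k], kappa, beta0 = fullfit$beta0,
          patterns = fullfit$patterns, coefs = unname(fullfit$coef),
          supports = lapply(fullfit$supports, restrict_support, idx = idx),
          max_length = max_length, seq_mode = seq_mode)
        ref_prev <- fit_as_reference(dtrain, floss, ffits[[k - 1L]],
                                     lambda[k], kappa, max_length, seq_mode)
        ffits[[k]] <- solve_point(dtrain, lambda[k], kappa,
                                  refs = list(ref_full, ref_prev),
                                  loss = floss, max_length = max_length,
                                  seq_mode = seq_mode, cfg = cfg)
      }
      pred <- predict(ffits[[k]], dval)
      if (dataset$task == "classification") {
        vl <- mean(pmax(1 - dval$y * pred, 0)^2)
        err <- mean(sign(pred) != dval$y)
      } else {
        vl <- mean((dval$y - pred)^2)
        err <- NA_real_
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lambda = lambda[k], fold = f, n_val = length(vidx),
        val_loss = vl, val_error = err,
        n_active = length(ffits[[k]]$coef),
        nodes_visited = ffits[[k]]$ws_counters$visited,
        ws_size = ffits[[k]]$ws_counters$kept,
        converged = ffits[[k]]$converged)
    }
    fold_fits[[f]] <- ffits
  }
  cv_table <- dplyr::bind_rows(rows)
  sel <- select_lambda_cv(cv_table)
  means <- sel$means
  lambda_min <- sel$lambda_min
  structure(list(
    cv_table = cv_table, cv_means = dplyr::arrange(means, dplyr::desc(.data$lambda)),
    lambda = lambda, lambda_min = lambda_min,
    best_fit = full$fits[[which(lambda == lambda_min)]],
    full_path = full, fold_fits = fold_fits, fold_train = train_sets,
    kappa = kappa, task = dataset$task
  ), class = "spp_cv")
}

#' @export
print.spp_cv <- function(x, ...) {
  cat(sprintf("<spp_cv> %d lambdas x %d folds; lambda_min = %.5g (%d active)\n",
              length(x$lambda), length(x$fold_fits), x$lambda_min,
              length(x$best_fit$coef)))
  invisible(x)
}
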