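#' Brute-force elastic-net fit over the fully enumerated pattern space
#'
#' Verification oracle: enumerates every pattern up to `max_length` with no
#' pruning, builds the dense design matrix, and solves the elastic-net
#' problem with accelerated proximal gradient descent (FISTA with adaptive
#' restart) to a certified duality gap — an algorithm family deliberately
#' different from the package's coordinate-descent solver, so agreement
#' between the two is a meaningful check.
#'
#' @param dataset an [spp_dataset()].
#' @param lambda,kappa regularization parameters.
#' @param loss a [loss_spec()]; default chosen by task.
#' @param max_length maximum pattern size.
#' @param seq_mode sequence containment mode.
#' @param tol duality-gap tolerance (relative to `max(1, |P|)`).
#' @param max_iter iteration cap.
#' @param guard maximum number of enumerated patterns.
#' @return an `spp_oracle`: pattern table, dense design `X`, `beta0`,
#'   `beta` (aligned with the pattern table), dual vector `alpha`, certified
#'   `gap`, the active key set, and `dup_group` (identifier of identical
#'   occurrence columns; for `kappa = 0` only the within-group coefficient
#'   sum is identified).
#' @export
brute_force_fit <- function(dataset, lambda, kappa = 0, loss = NULL,
                            max_length = NULL,
                            seq_mode = c("gapped", "contiguous"),
                            tol = 1e-10, max_iter = 200000L, guard = 10000L) {
  seq_mode <- match.arg(seq_mode)
  if (is.null(loss)) loss <- default_loss(dataset)
  if (is.null(max_length)) max_length <- default_max_length(dataset$type)
  n <- n_instances(dataset)
  pats <- enumerate_patterns(dataset, max_length, seq_mode = seq_mode,
                             guard = guard)
  p <- nrow(pats)
  X <- matrix(0, n, p)
  for (j in seq_len(p)) X[pats$support[[j]], j] <- 1
  sig <- vapply(pats$support, paste, character(1), collapse = ",")
  dup_group <- match(sig, unique(sig))

  fit <- fista_enet(X, loss, lambda, kappa, tol = tol, max_iter = max_iter)
  active <- which(abs(fit$beta) > 1e-9)
  structure(list(
    patterns = pats, X = X, dup_group = dup_group,
    beta0 = fit$beta0, beta = fit$beta, alpha = fit$alpha,
    P = fit$P, D = fit$D, gap = fit$gap, converged = fit$converged,
    active = active, active_keys = pats$key[active],
    lambda = lambda, kappa = kappa
  ), class = "spp_oracle")
}

# FISTA on 1/(2n)-normalized losses with the elastic-net prox; the dual
# certificate is computed from first principles on the dense design.
fista_enet <- function(X, loss, lambda, kappa, tol = 1e-10,
                       max_iter = 200000L) {
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(1, X)
  lip <- (svd(Xa, nu = 0, nv = 0)$d[1L])^2 / n
  step <- 1 / lip
  th <- numeric(p + 1L)    # (beta0, beta)
  zv <- th; tk <- 1
  obj <- function(th) {
    loss$value(as.numeric(Xa %*% th)) +
      elastic_net_penalty(th[-1L], lambda, kappa)
  }
  prox <- function(th) {
    th[-1L] <- soft_threshold(th[-1L], step * lambda) /
      (1 + step * lambda * kappa)
    th
  }
  best_D <- -Inf; best_alpha <- NULL
  P <- obj(th); prev_P <- Inf
  gap <- Inf; it <- 0L
  max_corr <- function(a) if (p) max(abs(crossprod(X, a))) else 0
  while (it < max_iter) {
    it <- it + 1L
    v <- as.numeric(Xa %*% zv)
    g <- as.numeric(crossprod(Xa, loss$grad(v)))
    th_new <- prox(zv - step * g)
    P_new <- obj(th_new)
    if (P_new > P) {            # adaptive restart on objective increase
      zv <- th; tk <- 1
      v <- as.numeric(Xa %*% zv)
      g <- as.numeric(crossprod(Xa, loss$grad(v)))
      th_new <- prox(zv - step * g)
      P_new <- obj(th_new)
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zv <- th_new + ((tk - 1) / tk_new) * (th_new - th)
    th <- th_new; tk <- tk_new; P <- P_new
    if (it %% 25L == 0L || it == max_iter) {
      vf <- as.numeric(Xa %*% th)
      alpha <- dual_scale(vf, loss, lambda, kappa, max_corr = max_corr)
      D <- loss$conj_neg(alpha)
      if (kappa > 0 && p) {
        D <- D - omega_star_sum(as.numeric(crossprod(X, alpha)), lambda, kappa)
      }
      if (D > best_D) { best_D <- D; best_alpha <- alpha }
      gap <- max(P - best_D, 0)
      if (gap <= tol * max(1, abs(P))) break
    }
  }
  list(beta0 = th[1L], beta = th[-1L], alpha = best_alpha,
       P = P, D = best_D, gap = gap,
       converged = gap <= tol * max(1, abs(P)), n_iter = it)
}

#' Collapse coefficients over duplicate occurrence columns
#'
#' Patterns with identical occurrence vectors are interchangeable features;
#' when `kappa = 0` only the coefficient sum within such a group is
#' identified, so oracle-equivalence comparisons are made on the collapsed
#' coordinates.
#'
#' @param keys pattern keys.
#' @param coef named coefficient vector (possibly sparse: only nonzeros).
#' @param dup_group group id per key (identical columns share an id).
#' @return named numeric vector: per-group coefficient sums, named by the
#'   first key of each group.
#' @export
collapse_duplicates <- function(keys, coef, dup_group) {
  full <- stats::setNames(numeric(length(keys)), keys)
  hit <- intersect(names(coef), keys)
  full[hit] <- coef[hit]
  sums <- tapply(full, dup_group, sum)
  reps <- keys[!duplicated(dup_group)]
  stats::setNames(as.numeric(sums[as.character(sort(unique(dup_group)))]), reps)
}
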