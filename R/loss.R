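#' Loss specifications
#'
#' Both supported losses are normalized by `1/(2n)` and have gradients that
#' are Lipschitz with constant `gamma = 1/n`, which sets the radius of the
#' GAP safe sphere via `r = sqrt(2 * gamma * gap)`.
#'
#' * squared loss: `L(v) = ||v - y||^2 / (2n)` (regression)
#' * squared hinge: `L(v) = sum(max(1 - y_i v_i, 0)^2) / (2n)` (classification,
#'   `y` in {-1, +1})
#'
#' The negated conjugate `-L*(-alpha)` is `alpha'y - (n/2)||alpha||^2` for
#' both losses; for the squared hinge it is finite only on the orthant
#' `y_i alpha_i >= 0` (the orientation produced by `alpha = -grad L`).
#'
#' @param kind `"squared"` or `"squared_hinge"`.
#' @param y response vector.
#' @return a `loss_spec` list with fields `kind`, `y`, `n`, `gamma` and
#'   closures `value`, `grad`, `conj_neg` (returns `-Inf` off the feasible
#'   region), and `fit_intercept` (the intercept-only minimizer).
#' @export
loss_spec <- function(kind = c("squared", "squared_hinge"), y) {
  kind <- match.arg(kind)
  y <- as.numeric(y)
  n <- length(y)
  if (kind == "squared_hinge" && !all(y %in% c(-1, 1))) {
    stop("squared hinge loss requires y in {-1, +1}", call. = FALSE)
  }
  feas_tol <- 1e-12
  if (kind == "squared") {
    list(
      kind = kind, y = y, n = n, gamma = 1 / n,
      value = function(v) sum((v - y)^2) / (2 * n),
      grad = function(v) (v - y) / n,
      conj_neg = function(alpha) sum(alpha * y) - (n / 2) * sum(alpha^2),
      fit_intercept = function() mean(y)
    )
  } else {
    list(
      kind = kind, y = y, n = n, gamma = 1 / n,
      value = function(v) sum(pmax(1 - y * v, 0)^2) / (2 * n),
      grad = function(v) -y * pmax(1 - y * v, 0) / n,
      conj_neg = function(alpha) {
        if (any(y * alpha < -feas_tol)) return(-Inf)
        sum(alpha * y) - (n / 2) * sum(alpha^2)
      },
      fit_intercept = function() {
        stats::optimize(function(b) sum(pmax(1 - y * b, 0)^2),
                        lower = -2, upper = 2, tol = 1e-12)$minimum
      }
    )
  }
}

#' Elastic-net penalty and its conjugate
#'
#' Penalty `lambda * sum_j(|beta_j| + (kappa/2) * beta_j^2)` over non-intercept
#' coefficients.  The per-column conjugate is 0 for `|v| <= lambda`,
#' `(|v| - lambda)^2 / (2 kappa lambda)` for `kappa > 0`, and `+Inf` for
#' `kappa = 0` with `|v| > lambda`.
#'
#' @param beta coefficient vector (no intercept).
#' @param lambda positive L1 strength.
#' @param kappa nonnegative relative L2 strength.
#' @export
elastic_net_penalty <- function(beta, lambda, kappa) {
  lambda * sum(abs(beta) + (kappa / 2) * beta^2)
}

# conjugate term sum over a vector of column correlations c_j = X_j' alpha
omega_star_sum <- function(corr, lambda, kappa, feas_tol = 1e-9) {
  a <- abs(corr)
  if (kappa > 0) {
    sum(pmax(a - lambda, 0)^2) / (2 * kappa * lambda)
  } else {
    if (any(a > lambda * (1 + feas_tol) + 1e-12)) Inf else 0
  }
}

#' Primal objective of the elastic-net pattern model
#'
#' @param X design matrix of occurrence columns (no intercept column).
#' @param beta0 intercept (never penalized).
#' @param beta coefficients aligned with `X`'s columns.
#' @param loss a [loss_spec()].
#' @param lambda,kappa regularization parameters.
#' @export
primal_objective <- function(X, beta0, beta, loss, lambda, kappa) {
  if (length(beta) != ncol(X)) stop("dimension mismatch", call. = FALSE)
  v <- beta0 + as.numeric(X %*% beta)
  loss$value(v) + elastic_net_penalty(beta, lambda, kappa)
}

#' Dual objective of the elastic-net pattern model
#'
#' `D(alpha) = -L*(-alpha) - sum_j omega*_j(X_j' alpha)` evaluated over the
#' supplied columns.  Infeasible `alpha` (uncentered, off-orthant for the
#' squared hinge, or box-violating when `kappa = 0`) yields `-Inf` rather
#' than an error.
#'
#' @inheritParams primal_objective
#' @param alpha dual vector of length `n`.
#' @export
dual_objective <- function(X, alpha, loss, lambda, kappa) {
  if (abs(sum(alpha)) > 1e-8 * max(1, sqrt(loss$n) * max(abs(alpha)))) {
    return(-Inf)
  }
  cn <- loss$conj_neg(alpha)
  if (!is.finite(cn)) return(-Inf)
  corr <- as.numeric(crossprod(X, alpha))
  os <- omega_star_sum(corr, lambda, kappa)
  if (!is.finite(os)) return(-Inf)
  cn - os
}

#' Map a primal point to a dual-feasible point (dual scaling)
#'
#' Computes `alpha_bar = -grad L(v)` at the fitted values `v` and moves it
#' into the dual-feasible region: centering onto the hyperplane
#' `1'alpha = 0` (the intercept's feasibility condition), sign-split scaling
#' for the squared hinge so both orthant and centering hold, and, when
#' `kappa = 0`, a gap-minimizing scalar `mu` clipped so that
#' `max_j |X_j' alpha| <= lambda`.
#'
#' @param v fitted values `X beta` (including intercept).
#' @param loss a [loss_spec()].
#' @param lambda,kappa regularization parameters.
#' @param max_corr function(alpha) returning `max_j |X_j' alpha|` over all
#'   candidate columns (for the full pattern space, a bounded tree search;
#'   for a working set, a matrix product).  Required when `kappa = 0`;
#'   for `kappa > 0` it is unused.
#' @return dual vector `alpha` satisfying `1'alpha = 0` (and the box/orthant
#'   constraints that apply).
#' @export
dual_scale <- function(v, loss, lambda, kappa, max_corr = NULL) {
  n <- loss$n
  abar <- -loss$grad(v)
  if (all(abar == 0)) return(abar)
  if (loss$kind == "squared_hinge") {
    # sign-split scaling: alpha_i <- mu+ alpha_i (y=+1), mu- alpha_i (y=-1),
    # with mu+/mu- = -sum_{y=-1} / sum_{y=+1}, so that 1'alpha = 0 while the
    # orthant y_i alpha_i >= 0 is preserved
    sp <- sum(abar[loss$y > 0]); sm <- sum(abar[loss$y < 0])
    att <- abar
    if (sp != 0) {
      att[loss$y > 0] <- (-sm / sp) * abar[loss$y > 0]
    } else if (sm != 0) {
      att[loss$y < 0] <- (-sp / sm) * abar[loss$y < 0]  # = 0
    }
  } else {
    att <- abar - mean(abar)
  }
  ss <- sum(att^2)
  if (ss == 0) return(att * 0)
  mu_opt <- sum(att * loss$y) / (n * ss)   # gap-minimizing scale (kappa = 0)
  if (kappa > 0) {
    # no box constraint: the centered (sign-split) vector at its natural
    # scale is feasible, and equals the dual optimum as the primal point
    # approaches the optimum; rescaling by the box-free gap-minimizer would
    # ignore the conjugate-penalty term and can loosen the bound
    mu <- 1
  } else {
    if (is.null(max_corr)) stop("max_corr required when kappa = 0", call. = FALSE)
    mc <- max_corr(att)
    cap <- if (mc > 0) lambda / mc else Inf
    mu <- min(max(mu_opt, if (loss$kind == "squared_hinge") 0 else -cap), cap)
  }
  att * mu
}

#' Duality gap and GAP safe sphere radius
#'
#' @param P primal value, `D` dual value.
#' @param loss a [loss_spec()] (supplies the Lipschitz constant `gamma = 1/n`).
#' @return list with `gap` (clamped at 0; an error beyond a `-1e-10` slack)
#'   and `r = sqrt(2 * gamma * gap)`.
#' @export
gap_and_radius <- function(P, D, loss) {
  gap <- P - D
  if (is.nan(gap)) stop("invalid primal/dual pair", call. = FALSE)
  if (gap < -1e-10 * max(1, abs(P))) {
    stop(sprintf("negative duality gap (%.3e): infeasible pair", gap),
         call. = FALSE)
  }
  gap <- max(gap, 0)
  list(gap = gap, r = sqrt(2 * loss$gamma * gap))
}

# ---- bounded tree searches over the full pattern space ---------------------

# The first term of the SPP score, max(sum of positive alpha on the support,
# -sum of negative alpha on the support), upper-bounds |X_k' alpha| for every
# descendant k of a node (supports only shrink), so branch-and-bound over the
# tree computes exact maxima / conjugate sums without full enumeration.

# exact max_j |X_j' alpha| over all patterns up to max_length
tree_max_abs_corr <- function(dataset, alpha, max_length,
                              seq_mode = "gapped") {
  best <- 0
  visit <- function(node) {
    s <- alpha[node$support]
    pos <- sum(s[s > 0]); neg <- -sum(s[s < 0])
    cur <- abs(pos - neg)
    if (cur > best) best <<- cur
    max(pos, neg) > best   # expand only if a descendant could beat the best
  }
  pattern_tree_dfs(dataset, max_length, visit, seq_mode = seq_mode)
  best
}

# exact sum of omega*_j(X_j' alpha) over ALL patterns (kappa > 0); only
# subtrees whose bound exceeds lambda can contribute
tree_omega_star <- function(dataset, alpha, lambda, kappa, max_length,
                            seq_mode = "gapped") {
  stopifnot(kappa > 0)
  total <- 0
  visit <- function(node) {
    s <- alpha[node$support]
    pos <- sum(s[s > 0]); neg <- -sum(s[s < 0])
    c <- abs(pos - neg)
    if (c > lambda) total <<- total + (c - lambda)^2 / (2 * kappa * lambda)
    max(pos, neg) > lambda
  }
  pattern_tree_dfs(dataset, max_length, visit, seq_mode = seq_mode)
  total
}

#' Smallest L1 strength with an all-zero model
#'
#' Fits the intercept-only model, dual-scales it, and returns the maximum
#' absolute correlation `|X_j' alpha|` over the whole pattern space, found by
#' a bounded tree search.  Solving at any `lambda >= lambda_max` leaves every
#' non-intercept coefficient at zero.
#'
#' @param dataset an [spp_dataset()].
#' @param loss a [loss_spec()]; defaults to the task's canonical loss.
#' @param max_length maximum pattern size.
#' @param seq_mode sequence containment mode.
#' @export
spp_lambda_max <- function(dataset, loss = NULL, max_length,
                           seq_mode = c("gapped", "contiguous")) {
  seq_mode <- match.arg(seq_mode)
  if (is.null(loss)) loss <- default_loss(dataset)
  b0 <- loss$fit_intercept()
  abar <- -loss$grad(rep(b0, loss$n))
  # at the intercept-only optimum 1'abar = 0 up to numerical error; center
  # exactly (sign-split for the squared hinge) so alpha is dual feasible
  if (loss$kind == "squared_hinge") {
    sp <- sum(abar[loss$y > 0]); sm <- sum(abar[loss$y < 0])
    if (sp > 0) abar[loss$y > 0] <- (-sm / sp) * abar[loss$y > 0]
  } else {
    abar <- abar - mean(abar)
  }
  if (all(abs(abar) < 1e-15)) return(0)
  tree_max_abs_corr(dataset, abar, max_length, seq_mode = seq_mode)
}

default_loss <- function(dataset) {
  loss_spec(if (dataset$task == "classification") "squared_hinge" else "squared",
            dataset$y)
}
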