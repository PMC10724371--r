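#' Build a reference solution at a given regularization point
#'
#' A reference solution is a primal-feasible model (intercept plus sparse
#' pattern coefficients) paired with a dual-feasible vector obtained by
#' [dual_scale()], together with its duality gap and GAP sphere radius,
#' evaluated at the *current* `(lambda, kappa)` — the primal point may come
#' from a neighboring grid point, a different CV fold, or the full data;
#' re-scaling its dual image is what makes it usable here.
#'
#' The dual value is exact over the whole pattern space: the conjugate
#' penalty sum (`kappa > 0`) and the feasibility cap (`kappa = 0`) are
#' computed by bounded branch-and-bound tree searches, never truncated to a
#' working set.
#'
#' @param dataset an [spp_dataset()].
#' @param loss a [loss_spec()] on `dataset$y`.
#' @param lambda,kappa regularization parameters to screen at.
#' @param beta0 intercept of the reference model.
#' @param patterns list of `spp_pattern` carrying the nonzero coefficients.
#' @param coefs numeric coefficients aligned with `patterns`.
#' @param supports optional list of support index vectors of `patterns` on
#'   `dataset` (computed via [occurrence_vector()] when missing).
#' @param max_length maximum pattern size (for the tree searches).
#' @param seq_mode sequence containment mode.
#' @return a `ReferenceSolution`: list with `beta0`, `patterns`, `coefs`,
#'   `supports`, `alpha`, `P`, `D`, `gap`, `r`, `lambda`, `kappa`.
#' @export
make_reference <- function(dataset, loss, lambda, kappa, beta0,
                           patterns = list(), coefs = numeric(0),
                           supports = NULL, max_length,
                           seq_mode = c("gapped", "contiguous")) {
  seq_mode <- match.arg(seq_mode)
  n <- n_instances(dataset)
  if (is.null(supports)) {
    supports <- lapply(patterns, function(p) {
      attr(occurrence_vector(p, dataset, seq_mode = seq_mode), "support")
    })
  }
  v <- rep(beta0, n)
  for (j in seq_along(coefs)) {
    if (coefs[j] != 0) v[supports[[j]]] <- v[supports[[j]]] + coefs[j]
  }
  P <- loss$value(v) + elastic_net_penalty(coefs, lambda, kappa)
  alpha <- dual_scale(v, loss, lambda, kappa,
                      max_corr = function(a) {
                        tree_max_abs_corr(dataset, a, max_length, seq_mode)
                      })
  D <- loss$conj_neg(alpha)
  if (kappa > 0 && any(alpha != 0)) {
    D <- D - tree_omega_star(dataset, alpha, lambda, kappa, max_length, seq_mode)
  }
  gr <- gap_and_radius(P, D, loss)
  list(beta0 = beta0, patterns = patterns, coefs = coefs, supports = supports,
       alpha = alpha, P = P, D = D, gap = gr$gap, r = gr$r,
       lambda = lambda, kappa = kappa)
}

# cold-start reference: the intercept-only model
zero_reference <- function(dataset, loss, lambda, kappa, max_length,
                           seq_mode = "gapped") {
  make_reference(dataset, loss, lambda, kappa, beta0 = loss$fit_intercept(),
                 max_length = max_length, seq_mode = seq_mode)
}

# exact full-space duality gap of a fitted model (certification)
exact_gap <- function(dataset, loss, lambda, kappa, beta0, supports, coefs,
                      max_length, seq_mode = "gapped") {
  n <- n_instances(dataset)
  v <- rep(beta0, n)
  for (j in seq_along(coefs)) {
    if (coefs[j] != 0) v[supports[[j]]] <- v[supports[[j]]] + coefs[j]
  }
  P <- loss$value(v) + elastic_net_penalty(coefs, lambda, kappa)
  alpha <- dual_scale(v, loss, lambda, kappa,
                      max_corr = function(a) {
                        tree_max_abs_corr(dataset, a, max_length, seq_mode)
                      })
  D <- loss$conj_neg(alpha)
  if (kappa > 0 && any(alpha != 0)) {
    D <- D - tree_omega_star(dataset, alpha, lambda, kappa, max_length, seq_mode)
  }
  list(P = P, D = D, gap = max(P - D, 0), alpha = alpha)
}
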