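#' Solver configuration
#'
#' @param tol relative duality-gap convergence tolerance `epsilon`
#'   (converged when `gap <= tol * max(1, |P|)`, re-certified against the
#'   exact full-space dual).
#' @param max_iter cap on coordinate-descent cycles; hitting it flags the
#'   fit as non-converged, never silently.
#' @param T dynamic screening runs at every other cycle (1, 3, ..., 2T-1)
#'   for the first `T` rounds.
#' @param screen_period thereafter screening runs every `screen_period`
#'   cycles.
#' @param M cap on multi-reference dynamic-screening rounds: the first `M`
#'   screening events update and use both maintained solutions, then the
#'   larger-gap solution is discarded and optimization continues seamlessly.
#' @param dynamic_screening disable to keep the working set fixed during
#'   optimization (control runs).
#' @param multi_ref disable to force single-reference screening/pruning even
#'   when two references are available (control runs).
#' @param prune disable subtree pruning in the miner (control runs).
#' @param record_trajectory keep every dual-scaled iterate produced at
#'   screening events (feasibility audits).
#' @export
spp_config <- function(tol = 1e-4, max_iter = 20000L, T = 5L,
                       screen_period = 10L, M = 1L,
                       dynamic_screening = TRUE, multi_ref = TRUE,
                       prune = TRUE, record_trajectory = FALSE) {
  stopifnot(tol > 0, M >= 0)
  list(tol = tol, max_iter = as.integer(max_iter), T = as.integer(T),
       screen_period = as.integer(screen_period), M = as.integer(M),
       dynamic_screening = isTRUE(dynamic_screening),
       multi_ref = isTRUE(multi_ref), prune = isTRUE(prune),
       record_trajectory = isTRUE(record_trajectory))
}

default_max_length <- function(type) {
  switch(type, itemset = 3L, sequence = 10L, graph = 5L)
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

is_screen_event <- function(cycle, T, period) {
  if (cycle < 2L * T) cycle %% 2L == 1L else cycle %% period == 0L
}

#' Solve one regularization point over the mined working set
#'
#' Mines the working set with SPP (single- or two-reference), then runs
#' cyclic coordinate descent with the elastic-net proximal update (exact
#' closed form for the squared loss, Lipschitz-majorized for the squared
#' hinge; the intercept is updated but never penalized or screened).  On the
#' dynamic-screening schedule the current iterate is dual-scaled, the best
#' dual value seen is kept (so the reported gap is monotone), and safe
#' screening shrinks the working set; with two references the first `M`
#' events maintain both solutions and screen with the two-sphere bound.
#' Convergence at the working-set gap is re-certified against the exact
#' full-pattern-space dual before the fit is declared converged.
#'
#' @param dataset an [spp_dataset()].
#' @param lambda,kappa regularization parameters.
#' @param refs list of reference solutions from [make_reference()] (cold
#'   start from the intercept-only model when `NULL`).
#' @param loss a [loss_spec()]; default chosen by task.
#' @param max_length maximum pattern size (default: itemsets 3, sequences
#'   10, graphs 5).
#' @param seq_mode sequence containment mode.
#' @param cfg a [spp_config()].
#' @return an `spp_fit`: intercept, nonzero coefficients keyed by canonical
#'   pattern key, exact duality gap, iteration count, working-set counters
#'   and the dynamic-screening log.
#' @export
solve_point <- function(dataset, lambda, kappa = 0, refs = NULL, loss = NULL,
                        max_length = NULL, seq_mode = c("gapped", "contiguous"),
                        cfg = spp_config()) {
  seq_mode <- match.arg(seq_mode)
  if (is.null(loss)) loss <- default_loss(dataset)
  if (is.null(max_length)) max_length <- default_max_length(dataset$type)
  n <- n_instances(dataset)
  if (is.null(refs)) {
    refs <- list(zero_reference(dataset, loss, lambda, kappa, max_length, seq_mode))
  }
  if (!cfg$multi_ref && length(refs) > 1L) {
    refs <- refs[which.min(vapply(refs, function(r) r$gap, 0))]
  }
  ws <- mine_working_set(dataset, refs, lambda, kappa, max_length,
                         seq_mode = seq_mode, prune = cfg$prune)
  m <- length(ws$keys)
  supports <- ws$supports
  slen <- lengths(supports)
  sy <- vapply(supports, function(s) sum(loss$y[s]), numeric(1))
  active <- rep(TRUE, m)
  y <- loss$y
  squared <- loss$kind == "squared"

  ws_corr <- function(alpha) {
    vapply(supports[active], function(s) sum(alpha[s]), numeric(1))
  }
  ws_max_corr <- function(alpha) {
    if (!any(active)) return(0)
    max(abs(ws_corr(alpha)))
  }

  init_state <- function(rf) {
    st <- new.env(parent = emptyenv())
    st$beta0 <- rf$beta0
    st$beta <- numeric(m)
    if (length(rf$coefs)) {
      idx <- match(vapply(rf$patterns, function(p) p$key, character(1)), ws$keys)
      ok <- which(!is.na(idx))
      st$beta[idx[ok]] <- rf$coefs[ok]
    }
    v <- rep(st$beta0, n)
    for (j in which(st$beta != 0)) {
      v[supports[[j]]] <- v[supports[[j]]] + st$beta[j]
    }
    st$v <- v
    st$best_D <- -Inf
    st$best_alpha <- NULL
    st$gap <- Inf
    st$P <- Inf
    st
  }

  cd_cycle <- function(st) {
    g0 <- sum(loss$grad(st$v))
    if (g0 != 0) {
      st$beta0 <- st$beta0 - g0
      st$v <- st$v - g0
    }
    lam_kap <- lambda * kappa
    for (j in which(active)) {
      s <- supports[[j]]
      g <- if (squared) {
        (sum(st$v[s]) - sy[j]) / n
      } else {
        ys <- y[s]
        -sum(ys * pmax(1 - ys * st$v[s], 0)) / n
      }
      cj <- slen[j] / n
      z <- cj * st$beta[j] - g
      bn <- soft_threshold(z, lambda) / (cj + lam_kap)
      d <- bn - st$beta[j]
      if (d != 0) {
        st$beta[j] <- bn
        st$v[s] <- st$v[s] + d
      }
    }
    invisible()
  }

  eval_state <- function(st) {
    st$P <- loss$value(st$v) +
      elastic_net_penalty(st$beta[active], lambda, kappa)
    alpha <- dual_scale(st$v, loss, lambda, kappa, max_corr = ws_max_corr)
    D <- loss$conj_neg(alpha)
    if (kappa > 0 && any(active)) {
      D <- D - omega_star_sum(ws_corr(alpha), lambda, kappa)
    }
    if (D > st$best_D) {
      st$best_D <- D
      st$best_alpha <- alpha
    }
    st$last_alpha <- alpha
    st$gap <- max(st$P - st$best_D, 0)
    invisible()
  }

  remove_cols <- function(drop, states) {
    for (j in drop) {
      for (st in states) {
        if (st$beta[j] != 0) {
          st$v[supports[[j]]] <- st$v[supports[[j]]] - st$beta[j]
          st$beta[j] <- 0
        }
      }
    }
    active[drop] <<- FALSE
  }

  screen_once <- function(states, multi) {
    idx <- which(active)
    if (!length(idx)) return(0L)
    if (multi) {
      rr <- lapply(states, function(st) {
        list(alpha = st$best_alpha, r = sqrt(2 * loss$gamma * st$gap))
      })
      geo <- multi_ref_geometry(rr[[1L]], rr[[2L]])
      u <- vapply(idx, function(j) {
        multi_screening_score(supports[[j]], rr[[1L]], rr[[2L]], geo, n)
      }, numeric(1))
    } else {
      st <- states[[which.min(vapply(states, function(s) s$gap, 0))]]
      rf <- list(alpha = st$best_alpha, r = sqrt(2 * loss$gamma * st$gap))
      u <- vapply(idx, function(j) screening_score(supports[[j]], rf, n),
                  numeric(1))
    }
    drop <- idx[u < lambda]
    if (length(drop)) remove_cols(drop, states)
    length(drop)
  }

  two_states <- length(refs) >= 2L && cfg$multi_ref &&
    cfg$dynamic_screening && cfg$M >= 1L
  states <- if (two_states) {
    list(init_state(refs[[1L]]), init_state(refs[[2L]]))
  } else {
    list(init_state(refs[[which.min(vapply(refs, function(r) r$gap, 0))]]))
  }

  log_cycle <- integer(0); log_active <- integer(0); log_gap <- numeric(0)
  log_removed <- integer(0)
  trajectory <- list()
  multi_rounds <- 0L
  converged <- FALSE
  final <- NULL
  cycle <- 0L
  last_cert_gap <- Inf

  finish_check <- function(st) {
    # certify against the exact full-space dual before declaring convergence
    # (coefficients below noise floor count as zero)
    nz <- which(active & abs(st$beta) > 1e-12)
    eg <- exact_gap(dataset, loss, lambda, kappa, st$beta0,
                    supports[nz], st$beta[nz], max_length, seq_mode)
    list(ok = eg$gap <= cfg$tol * max(1, abs(eg$P)), eg = eg, nz = nz)
  }

  if (m == 0L) {
    b0 <- loss$fit_intercept()
    eg <- exact_gap(dataset, loss, lambda, kappa, b0, list(), numeric(0),
                    max_length, seq_mode)
    states[[1L]]$beta0 <- b0
    states[[1L]]$beta <- numeric(0)
    final <- list(eg = eg, nz = integer(0))
    converged <- eg$gap <= cfg$tol * max(1, abs(eg$P))
    states <- states[1L]
  } else {
    while (cycle < cfg$max_iter) {
      cycle <- cycle + 1L
      for (st in states) cd_cycle(st)
      if (!is_screen_event(cycle, cfg$T, cfg$screen_period) &&
          cycle < cfg$max_iter) next
      for (st in states) eval_state(st)
      if (cfg$record_trajectory) {
        for (st in states) trajectory[[length(trajectory) + 1L]] <- st$last_alpha
      }
      nrem <- 0L
      if (cfg$dynamic_screening) {
        if (length(states) == 2L && multi_rounds < cfg$M) {
          nrem <- screen_once(states, multi = TRUE)
          multi_rounds <- multi_rounds + 1L
          if (multi_rounds >= cfg$M) {
            keep <- which.min(vapply(states, function(s) s$gap, 0))
            states <- states[keep]
          }
        } else {
          if (length(states) == 2L) {
            keep <- which.min(vapply(states, function(s) s$gap, 0))
            states <- states[keep]
          }
          nrem <- screen_once(states, multi = FALSE)
        }
      } else if (length(states) == 2L) {
        keep <- which.min(vapply(states, function(s) s$gap, 0))
        states <- states[keep]
      }
      best <- states[[which.min(vapply(states, function(s) s$gap, 0))]]
      log_cycle <- c(log_cycle, cycle)
      log_active <- c(log_active, sum(active))
      log_gap <- c(log_gap, best$gap)
      log_removed <- c(log_removed, nrem)
      if (best$gap <= cfg$tol * max(1, abs(best$P)) &&
          best$gap < 0.999 * last_cert_gap) {
        chk <- finish_check(best)
        last_cert_gap <- best$gap
        if (chk$ok) {
          converged <- TRUE
          final <- chk
          states <- list(best)
          break
        }
      }
    }
    if (is.null(final)) {
      best <- states[[which.min(vapply(states, function(s) s$gap, 0))]]
      states <- list(best)
      final <- finish_check(best)
      converged <- converged || final$ok
    }
  }

  st <- states[[1L]]
  nz <- if (m > 0L) which(active & abs(st$beta) > 1e-12) else integer(0)
  coef <- st$beta[nz]
  names(coef) <- ws$keys[nz]
  patterns <- lapply(nz, function(j) {
    node_pattern(dataset, list(type = dataset$type, body = ws$bodies[[j]]))
  })
  structure(list(
    lambda = lambda, kappa = kappa,
    beta0 = st$beta0, coef = coef,
    patterns = patterns, supports = supports[nz],
    P = final$eg$P, D = final$eg$D, gap = final$eg$gap,
    rel_gap = final$eg$gap / max(1, abs(final$eg$P)),
    alpha = final$eg$alpha,
    n_iter = cycle, converged = converged,
    ws_counters = ws$counters, ws_size_final = sum(active),
    screen_log = tibble::tibble(cycle = log_cycle, n_active = log_active,
                                gap = log_gap, n_removed = log_removed),
    trajectory = if (cfg$record_trajectory) trajectory else NULL,
    loss_kind = loss$kind, task = dataset$task,
    max_length = max_length, seq_mode = seq_mode
  ), class = "spp_fit")
}

#' @export
print.spp_fit <- function(x, ...) {
  cat(sprintf("<spp_fit> lambda=%.4g kappa=%.3g | %d active patterns | gap=%.2e%s\n",
              x$lambda, x$kappa, length(x$coef), x$gap,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Predict from a fitted pattern model
#'
#' @param object an `spp_fit`.
#' @param dataset an [spp_dataset()] of the same structure type.
#' @param ... unused.
#' @return numeric vector of linear predictions `beta0 + sum_j beta_j x_ij`.
#' @export
predict.spp_fit <- function(object, dataset, ...) {
  v <- rep(object$beta0, n_instances(dataset))
  for (j in seq_along(object$coef)) {
    x <- occurrence_vector(object$patterns[[j]], dataset,
                           seq_mode = object$seq_mode)
    v <- v + object$coef[j] * x
  }
  as.numeric(v)
}
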