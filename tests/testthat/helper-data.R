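# Shared fixtures and independent oracles used across the suite.

# worked toy: S1={1}, S2={1,2}, S3={2}, S4={}, y = 1:4, squared loss.
# Hand-derived values: lambda_max = 0.5 attained by pattern {1};
# intercept-only P = D = 0.625; centered dual (-.375,-.125,.125,.375).
toy_itemset <- function() {
  spp_dataset(list(1L, c(1L, 2L), 2L, integer(0)), c(1, 2, 3, 4), "itemset")
}

# max absolute difference between two sparse named coefficient vectors
coef_diff <- function(a, b) {
  keys <- union(names(a), names(b))
  if (!length(keys)) return(0)
  av <- stats::setNames(numeric(length(keys)), keys); av[names(a)] <- a
  bv <- stats::setNames(numeric(length(keys)), keys); bv[names(b)] <- b
  max(abs(av - bv))
}

# coefficient difference between a fit and the brute-force oracle, on
# duplicate-column-collapsed coordinates (the identifiable ones)
fit_oracle_diff <- function(fit, orc) {
  oc <- collapse_duplicates(orc$patterns$key,
                            stats::setNames(orc$beta, orc$patterns$key),
                            orc$dup_group)
  fc <- collapse_duplicates(orc$patterns$key, fit$coef, orc$dup_group)
  max(c(abs(oc - fc), abs(fit$beta0 - orc$beta0)))
}

# Full equivalence check of a fit against the brute-force oracle.
# The fitted values and the objective are always identified.  Coefficients
# are compared on duplicate-column-collapsed coordinates (the within-group
# split under kappa > 0 is the ill-conditioned direction: its error scales
# like sqrt(2 gap / (lambda kappa))); the collapsed coordinates are
# identified iff kappa > 0 or the deduplicated equicorrelation set has full
# column rank, and are compared exactly then.
oracle_equiv <- function(fit, orc, coef_tol = 1e-5, fit_tol = 1e-5) {
  X <- orc$X
  bfull <- numeric(nrow(orc$patterns))
  bfull[match(names(fit$coef), orc$patterns$key)] <- fit$coef
  vfit <- fit$beta0 + as.numeric(X %*% bfull)
  vorc <- orc$beta0 + as.numeric(X %*% orc$beta)
  fitted_diff <- max(abs(vfit - vorc))
  P_diff <- abs(fit$P - orc$P)
  reps <- !duplicated(orc$dup_group)
  corr <- abs(as.numeric(crossprod(X[, reps, drop = FALSE], orc$alpha)))
  E <- which(corr >= orc$lambda - 1e-6)
  unique_opt <- orc$kappa > 0 || length(E) == 0L ||
    qr(X[, reps, drop = FALSE][, E, drop = FALSE])$rank == length(E)
  oc <- collapse_duplicates(orc$patterns$key,
                            stats::setNames(orc$beta, orc$patterns$key),
                            orc$dup_group)
  fc <- collapse_duplicates(orc$patterns$key, fit$coef, orc$dup_group)
  coord_diff <- max(c(abs(oc - fc), abs(fit$beta0 - orc$beta0)))
  list(fitted_diff = fitted_diff, P_diff = P_diff,
       unique = unique_opt, coord_diff = coord_diff,
       ok = fitted_diff < fit_tol && P_diff < 1e-6 &&
         (!unique_opt || coord_diff < coef_tol))
}

# model-level equivalence of two fits of the same problem (CD vs CD):
# compares the identified functionals (predictions and objective value)
same_model <- function(f1, f2, dataset, tol = 1e-6) {
  max(abs(predict(f1, dataset) - predict(f2, dataset))) < tol &&
    abs(f1$P - f2$P) < 1e-8 * max(1, abs(f1$P))
}

# independent numeric oracle for the two-sphere screening bound:
# max of a'alpha over B1 cap B2 cap H by minimizing the 2-multiplier
# Lagrangian dual (convex; strong duality when the lens has interior)
numeric_lens_max <- function(a, c1, r1, c2, r2) {
  aH <- a - mean(a)
  dual <- function(mu) {
    s <- mu[1] + mu[2]
    if (s < 1e-12) return(1e10)
    x <- (aH + mu[1] * c1 + mu[2] * c2) / s
    sum(aH * x) - mu[1] / 2 * (sum((x - c1)^2) - r1^2) -
      mu[2] / 2 * (sum((x - c2)^2) - r2^2)
  }
  o <- stats::optim(c(1, 1), dual, method = "L-BFGS-B",
                    lower = c(1e-9, 1e-9), control = list(factr = 10))
  o$value
}

# exhaustive labeled-subgraph containment by injective vertex mapping,
# independent of the DFS-code embedding machinery
brute_graph_contains <- function(pg, g) {
  np <- length(pg$vlab); ng <- length(g$vlab)
  if (np > ng) return(FALSE)
  pedge <- function(u, v) {
    e <- pg$edges
    hit <- which((e[, 1L] == u & e[, 2L] == v) | (e[, 1L] == v & e[, 2L] == u))
    if (length(hit)) e[hit[1L], 3L] else NA_integer_
  }
  gedge <- function(u, v) {
    e <- g$edges
    hit <- which((e[, 1L] == u & e[, 2L] == v) | (e[, 1L] == v & e[, 2L] == u))
    if (length(hit)) e[hit[1L], 3L] else NA_integer_
  }
  rec <- function(map) {
    k <- length(map) + 1L
    if (k > np) return(TRUE)
    for (w in seq_len(ng)) {
      if (w %in% map) next
      if (g$vlab[w] != pg$vlab[k]) next
      ok <- TRUE
      for (u in seq_len(k - 1L)) {
        pe <- pedge(u, k)
        if (!is.na(pe)) {
          ge <- gedge(map[u], w)
          if (is.na(ge) || ge != pe) { ok <- FALSE; break }
        }
      }
      if (ok && rec(c(map, w))) return(TRUE)
    }
    FALSE
  }
  rec(integer(0))
}

# label-respecting graph isomorphism by permutation search (small graphs)
graphs_isomorphic <- function(g1, g2) {
  if (length(g1$vlab) != length(g2$vlab)) return(FALSE)
  if (nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  if (!identical(sort(g1$vlab), sort(g2$vlab))) return(FALSE)
  brute_graph_contains(g1, g2) && brute_graph_contains(g2, g1)
}

# brute-force enumeration of connected labeled subgraphs (<= max_edges
# edges) occurring in >= 1 instance, deduplicated by isomorphism;
# independent oracle for the gSpan enumeration tree
brute_subgraph_classes <- function(dataset, max_edges) {
  classes <- list()
  for (g in dataset$instances) {
    ne <- nrow(g$edges)
    if (!ne) next
    for (k in seq_len(min(max_edges, ne))) {
      combos <- utils::combn(ne, k, simplify = FALSE)
      for (sel in combos) {
        ed <- g$edges[sel, , drop = FALSE]
        keep <- sort(unique(as.integer(ed[, 1:2])))
        # connectivity of the edge-induced subgraph
        seen <- keep[1L]
        repeat {
          nb <- unique(c(ed[ed[, 1L] %in% seen, 2L],
                         ed[ed[, 2L] %in% seen, 1L]))
          grow <- setdiff(intersect(nb, keep), seen)
          if (!length(grow)) break
          seen <- c(seen, grow)
        }
        if (length(seen) != length(keep)) next
        remap <- match(ed[, 1:2], keep)
        sub <- list(vlab = g$vlab[keep],
                    edges = cbind(matrix(remap, ncol = 2L), ed[, 3L]))
        new <- TRUE
        for (cl in classes) {
          if (graphs_isomorphic(cl, sub)) { new <- FALSE; break }
        }
        if (new) classes[[length(classes) + 1L]] <- sub
      }
    }
  }
  classes
}

# traversal audit: parent support must contain every child support
check_support_monotone <- function(dataset, max_length, seq_mode = "gapped") {
  stack <- list()
  ok <- TRUE
  visit <- function(node) {
    if (node$size > 1L) {
      parent <- stack[[node$size - 1L]]
      if (!all(node$support %in% parent)) ok <<- FALSE
    }
    stack[[node$size]] <<- node$support
    TRUE
  }
  sppmine:::pattern_tree_dfs(dataset, max_length, visit, seq_mode = seq_mode)
  ok
}

small_synth <- function(type, seed, n = 30L, task = "regression",
                        noise_sd = 0.3) {
  switch(type,
    itemset = spp_synth("itemset", n = n, n_items = 7, k_patterns = 2,
                        pattern_size = 2, noise_sd = noise_sd, task = task,
                        seed = seed),
    sequence = spp_synth("sequence", n = n, alphabet = 3, seq_len = c(5, 8),
                         k_patterns = 2, pattern_size = 2,
                         noise_sd = noise_sd, task = task, seed = seed),
    graph = spp_synth("graph", n = n, graph_nodes = c(3, 5), n_labels = 2,
                      k_patterns = 2, pattern_size = 1:2,
                      noise_sd = noise_sd, task = task, seed = seed))
}
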