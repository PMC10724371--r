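#' Synthetic structured datasets with planted predictive patterns
#'
#' Generates itemset, sequence, or graph datasets in which a small set of
#' planted patterns carries all of the signal:
#' `y_i = beta0 + sum_p beta_p x_ip + noise` for regression, or the sign of
#' that noisy score for classification.  The occurrence indicators `x_ip`
#' are computed by actual containment tests, so the generating model is
#' exactly the model class being fitted.  Planted patterns are injected into
#' a fraction of instances on top of random background structure; a draw is
#' rejected and re-sampled unless every planted support lies in
#' `[0.1, 0.9] * n` (identifiability) and no planted pattern's occurrence
#' column coincides with that of one of its own sub-patterns.
#'
#' Defaults (n = 200, three planted patterns of unit effect, Gaussian noise
#' sd 0.1) are the conditions under which support-recovery behaviour is
#' studied in the package's tests.
#'
#' @param type structure type.
#' @param n number of instances.
#' @param task `"regression"` or `"classification"`.
#' @param k_patterns number of planted patterns.
#' @param pattern_size sizes (items/symbols/edges) planted patterns are
#'   drawn from.
#' @param beta coefficients of the planted patterns (recycled).
#' @param beta0 intercept of the generating model.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_items itemset universe size.
#' @param item_prob background inclusion probability per item.
#' @param alphabet sequence alphabet size (symbols are letters).
#' @param seq_len range of sequence lengths.
#' @param graph_nodes range of node counts per instance graph.
#' @param n_labels node-label alphabet size (graphs; edge labels use
#'   `max(2, n_labels - 1)` values).
#' @param edge_prob extra-edge probability beyond the random spanning tree.
#' @param plant_prob probability a planted pattern is injected into an
#'   instance.
#' @param seed RNG seed (same seed, same dataset).
#' @param max_tries rejection-sampling attempts before a typed error.
#' @return list with `dataset` (an [spp_dataset()]) and `truth` (tibble:
#'   `key`, `coefficient`, `support_frac`, plus the planted `pattern`
#'   objects).
#' @export
spp_synth <- function(type = c("itemset", "sequence", "graph"), n = 200L,
                      task = c("regression", "classification"),
                      k_patterns = 3L, pattern_size = 2:3, beta = 1,
                      beta0 = 0, noise_sd = 0.1,
                      n_items = 10L, item_prob = 0.3,
                      alphabet = 4L, seq_len = c(8L, 15L),
                      graph_nodes = c(4L, 7L), n_labels = 3L,
                      edge_prob = 0.15, plant_prob = 0.3,
                      seed = 1L, max_tries = 50L) {
  type <- match.arg(type)
  task <- match.arg(task)
  set.seed(seed)
  beta <- rep_len(beta, k_patterns)
  vocab <- if (type == "sequence") LETTERS[seq_len(alphabet)] else NULL
  for (try in seq_len(max_tries)) {
    planted <- draw_planted(type, k_patterns, pattern_size, n_items,
                            alphabet, n_labels, vocab)
    if (is.null(planted)) next
    insts <- lapply(seq_len(n), function(i) {
      draw_instance(type, n_items, item_prob, alphabet, seq_len, graph_nodes,
                    n_labels, edge_prob, planted, plant_prob)
    })
    ds0 <- spp_dataset(insts, rep(0, n), type = type, task = "regression",
                       vocab = vocab)
    occ <- lapply(planted, function(p) occurrence_vector(p, ds0))
    frac <- vapply(occ, mean, numeric(1))
    if (any(frac < 0.1 | frac > 0.9)) next
    if (planted_degenerate(planted, occ, ds0)) next
    score <- beta0 + Reduce(`+`, Map(function(b, x) b * as.numeric(x),
                                     beta, occ))
    eps <- stats::rnorm(n, 0, noise_sd)
    if (task == "regression") {
      y <- score + eps
    } else {
      # center the raw score so neither class collapses; re-draw the
      # intercept until both classes hold at least 20% of instances
      ok <- FALSE
      for (bt in seq_len(max_tries)) {
        b0c <- -stats::quantile(score + eps, stats::runif(1, 0.3, 0.7),
                                names = FALSE)
        y <- sign(score + eps + b0c)
        y[y == 0] <- 1
        if (min(mean(y > 0), mean(y < 0)) >= 0.2) { ok <- TRUE; break }
      }
      if (!ok) next
    }
    dataset <- spp_dataset(insts, y, type = type, task = task, vocab = vocab)
    truth <- tibble::tibble(
      key = vapply(planted, function(p) p$key, character(1)),
      coefficient = beta, support_frac = frac, pattern = planted)
    return(list(dataset = dataset, truth = truth))
  }
  stop("could not satisfy planted-support constraints after ", max_tries,
       " attempts", call. = FALSE)
}

draw_planted <- function(type, k, sizes, n_items, alphabet, n_labels, vocab) {
  out <- list(); keys <- character(0)
  for (i in seq_len(k)) {
    for (rep in 1:20) {
      sz <- sample(sizes, 1L)
      p <- switch(type,
        itemset = {
          if (sz > n_items) return(NULL)
          spp_pattern(sort(sample.int(n_items, sz)), "itemset")
        },
        sequence = spp_pattern(sample.int(alphabet, sz, replace = TRUE),
                               "sequence", vocab = vocab),
        graph = {
          # labeled path with sz edges
          vlab <- sample.int(n_labels, sz + 1L, replace = TRUE)
          el <- sample.int(max(2L, n_labels - 1L), sz, replace = TRUE)
          edges <- cbind(seq_len(sz), seq_len(sz) + 1L, el)
          spp_pattern(list(vlab = vlab, edges = edges), "graph")
        })
      if (!(p$key %in% keys)) break
      p <- NULL
    }
    if (is.null(p)) return(NULL)
    keys <- c(keys, p$key)
    out[[i]] <- p
  }
  out
}

draw_instance <- function(type, n_items, item_prob, alphabet, seq_len,
                          graph_nodes, n_labels, edge_prob, planted,
                          plant_prob) {
  switch(type,
    itemset = {
      s <- which(stats::runif(n_items) < item_prob)
      for (p in planted) if (stats::runif(1) < plant_prob) s <- union(s, p$items)
      sort(as.integer(s))
    },
    sequence = {
      len <- sample(seq_len[1L]:seq_len[2L], 1L)
      s <- sample.int(alphabet, len, replace = TRUE)
      for (p in planted) {
        if (stats::runif(1) < plant_prob) {
          # contiguous insertion: contained under both matching modes
          pos <- sample.int(length(s) + 1L, 1L)
          s <- append(s, p$symbols, after = pos - 1L)
        }
      }
      s
    },
    graph = {
      nv <- sample(graph_nodes[1L]:graph_nodes[2L], 1L)
      vlab <- sample.int(n_labels, nv, replace = TRUE)
      edges <- matrix(integer(0), ncol = 3L)
      if (nv > 1L) {
        nel <- max(2L, n_labels - 1L)
        for (v in 2:nv) {  # random spanning tree
          u <- sample.int(v - 1L, 1L)
          edges <- rbind(edges, c(u, v, sample.int(nel, 1L)))
        }
        for (u in seq_len(nv - 1L)) {
          for (v in (u + 1L):nv) {
            if (any(edges[, 1L] == u & edges[, 2L] == v)) next
            if (stats::runif(1) < edge_prob) {
              edges <- rbind(edges, c(u, v, sample.int(nel, 1L)))
            }
          }
        }
      }
      for (p in planted) {
        if (stats::runif(1) < plant_prob) {
          g <- p$graph
          off <- length(vlab)
          vlab <- c(vlab, g$vlab)
          pe <- g$edges
          pe[, 1L:2L] <- pe[, 1L:2L] + off
          edges <- rbind(edges, pe)
          if (off > 0L) {  # connect the planted component to the background
            nel <- max(2L, n_labels - 1L)
            edges <- rbind(edges, c(sample.int(off, 1L),
                                    off + sample.int(length(g$vlab), 1L),
                                    sample.int(nel, 1L)))
          }
        }
      }
      list(vlab = vlab, edges = edges)
    })
}

# a planted pattern whose column equals a proper sub-pattern's column is not
# separately identifiable (the sub-pattern precedes it in canonical order)
planted_degenerate <- function(planted, occ, ds) {
  for (i in seq_along(planted)) {
    p <- planted[[i]]
    subs <- proper_subpatterns(p)
    for (sp in subs) {
      if (identical(as.integer(occurrence_vector(sp, ds)),
                    as.integer(occ[[i]]))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

proper_subpatterns <- function(p) {
  switch(p$type,
    itemset = {
      k <- length(p$items)
      if (k <= 1L) return(list())
      lapply(seq_len(k), function(d) spp_pattern(p$items[-d], "itemset"))
    },
    sequence = {
      k <- length(p$symbols)
      if (k <= 1L) return(list())
      lapply(seq_len(k), function(d) {
        q <- list(type = "sequence", symbols = p$symbols[-d], vocab = p$vocab)
        q$key <- pattern_key(q)
        structure(q, class = "spp_pattern")
      })
    },
    graph = {
      ne <- nrow(p$graph$edges)
      if (ne <= 1L) return(list())
      out <- list()
      for (d in seq_len(ne)) {
        ed <- p$graph$edges[-d, , drop = FALSE]
        keep <- sort(unique(as.integer(ed[, 1:2])))
        if (!connected_graph(length(p$graph$vlab), ed, keep)) next
        remap <- match(ed[, 1:2], keep)
        ed2 <- cbind(matrix(remap, ncol = 2L), ed[, 3L])
        out[[length(out) + 1L]] <-
          spp_pattern(list(vlab = p$graph$vlab[keep], edges = ed2), "graph")
      }
      out
    })
}

connected_graph <- function(nv, edges, keep) {
  if (length(keep) <= 1L) return(TRUE)
  seen <- keep[1L]
  repeat {
    nb <- unique(c(edges[edges[, 1L] %in% seen, 2L],
                   edges[edges[, 2L] %in% seen, 1L]))
    grow <- setdiff(intersect(nb, keep), seen)
    if (!length(grow)) break
    seen <- c(seen, grow)
  }
  length(seen) == length(keep)
}
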