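# Depth-first traversal of the pattern enumeration tree.
#
# The tree has the empty pattern at its root (support = all instances; never
# emitted as a feature).  Children are generated from the parent's support
# only (projected-database style), so support sets shrink monotonically along
# every tree edge — the monotonicity that makes subtree pruning sound.
#
# `visit(node)` is called for every non-root node, where `node` has fields
# `body` (items / symbols / DFS-code matrix), `size`, and `support` (sorted
# instance indices).  It must return TRUE to expand the node's children or
# FALSE to prune the subtree.  Children are generated in canonical key order,
# so traversal order is deterministic.

pattern_tree_dfs <- function(dataset, max_length, visit,
                             seq_mode = c("gapped", "contiguous")) {
  seq_mode <- match.arg(seq_mode)
  n <- n_instances(dataset)
  counters <- new.env(parent = emptyenv())
  counters$visited <- 0L; counters$pruned <- 0L; counters$expanded <- 0L
  step <- function(node) {
    counters$visited <- counters$visited + 1L
    expand <- isTRUE(visit(node))
    if (!expand) {
      counters$pruned <- counters$pruned + 1L
      return(FALSE)
    }
    if (node$size >= max_length) return(FALSE)
    counters$expanded <- counters$expanded + 1L
    TRUE
  }
  switch(dataset$type,
    itemset = dfs_itemset(dataset, max_length, step),
    sequence = if (seq_mode == "gapped") dfs_seq_gapped(dataset, max_length, step)
               else dfs_seq_contig(dataset, max_length, step),
    graph = dfs_graph(dataset, max_length, step)
  )
  list(visited = counters$visited, pruned = counters$pruned,
       expanded = counters$expanded)
}

dfs_itemset <- function(dataset, max_length, step) {
  n <- n_instances(dataset)
  universe <- sort(unique(unlist(dataset$instances)))
  if (!length(universe)) return(invisible())
  inc <- matrix(FALSE, n, max(universe))
  for (i in seq_len(n)) inc[i, dataset$instances[[i]]] <- TRUE
  rec <- function(items, support) {
    maxit <- if (length(items)) items[length(items)] else 0L
    for (a in universe[universe > maxit]) {
      child_supp <- support[inc[support, a]]
      if (!length(child_supp)) next
      child <- c(items, a)
      node <- list(type = "itemset", body = child,
                   size = length(child), support = child_supp)
      if (step(node)) rec(child, child_supp)
    }
  }
  rec(integer(0), seq_len(n))
  invisible()
}

dfs_seq_gapped <- function(dataset, max_length, step) {
  n <- n_instances(dataset)
  insts <- dataset$instances
  # PrefixSpan projection: pos[k] = first position in instance support[k]
  # where the search for the next symbol may start
  rec <- function(symbols, support, pos) {
    # earliest occurrence of each symbol in each projected suffix
    firsts <- vector("list", length(support))
    syms <- integer(0)
    for (k in seq_along(support)) {
      s <- insts[[support[k]]]
      if (pos[k] > length(s)) next
      suff <- s[pos[k]:length(s)]
      u <- !duplicated(suff)
      firsts[[k]] <- cbind(suff[u], pos[k] - 1L + which(u))
      syms <- c(syms, suff[u])
    }
    for (a in sort(unique(syms))) {
      child_supp <- integer(0); child_pos <- integer(0)
      for (k in seq_along(support)) {
        f <- firsts[[k]]
        if (is.null(f)) next
        hit <- which(f[, 1L] == a)
        if (length(hit)) {
          child_supp <- c(child_supp, support[k])
          child_pos <- c(child_pos, f[hit, 2L] + 1L)
        }
      }
      if (!length(child_supp)) next
      child <- c(symbols, a)
      node <- list(type = "sequence", body = child,
                   size = length(child), support = child_supp)
      if (step(node)) rec(child, child_supp, child_pos)
    }
  }
  rec(integer(0), seq_len(n), rep(1L, n))
  invisible()
}

dfs_seq_contig <- function(dataset, max_length, step) {
  n <- n_instances(dataset)
  insts <- dataset$instances
  # projection: ends[[k]] = positions in instance support[k] where an
  # occurrence of the prefix may continue (next symbol position)
  rec <- function(symbols, support, ends) {
    ext <- list()  # symbol -> list(supp, ends)
    syms <- integer(0)
    nxt <- vector("list", length(support))
    for (k in seq_along(support)) {
      s <- insts[[support[k]]]
      e <- ends[[k]]
      e <- e[e <= length(s)]
      if (!length(e)) next
      nxt[[k]] <- cbind(s[e], e)
      syms <- c(syms, unique(s[e]))
    }
    for (a in sort(unique(syms))) {
      child_supp <- integer(0); child_ends <- list()
      for (k in seq_along(support)) {
        f <- nxt[[k]]
        if (is.null(f)) next
        hit <- f[f[, 1L] == a, 2L]
        if (length(hit)) {
          child_supp <- c(child_supp, support[k])
          child_ends[[length(child_ends) + 1L]] <- hit + 1L
        }
      }
      if (!length(child_supp)) next
      child <- c(symbols, a)
      node <- list(type = "sequence", body = child,
                   size = length(child), support = child_supp)
      if (step(node)) rec(child, child_supp, child_ends)
    }
  }
  rec(integer(0), seq_len(n), lapply(insts, function(s) seq_along(s)))
  invisible()
}

dfs_graph <- function(dataset, max_length, step) {
  n <- n_instances(dataset)
  insts <- dataset$instances
  rec <- function(code, support) {
    for (child in graph_code_children(code, support, insts)) {
      node <- list(type = "graph", body = child$code,
                   size = nrow(child$code), support = child$support)
      if (step(node)) rec(child$code, child$support)
    }
  }
  rec(NULL, seq_len(n))
  invisible()
}

# canonical (minimum-DFS-code) rightmost-path extensions of `code` observed
# within the supporting instances; code = NULL means the empty root
graph_code_children <- function(code, support, insts) {
  tuples <- list()  # key -> list(row, support accumulator)
  if (is.null(code)) {
    for (t in support) {
      ed <- insts[[t]]$edges
      if (!nrow(ed)) next
      vl <- insts[[t]]$vlab
      for (k in seq_len(nrow(ed))) {
        la <- vl[ed[k, 1L]]; lb <- vl[ed[k, 2L]]
        row <- c(0L, 1L, min(la, lb), ed[k, 3L], max(la, lb))
        key <- paste(row, collapse = ".")
        if (is.null(tuples[[key]])) tuples[[key]] <- list(row = row, supp = integer(0))
        if (!length(tuples[[key]]$supp) ||
            tuples[[key]]$supp[length(tuples[[key]]$supp)] != t) {
          tuples[[key]]$supp <- c(tuples[[key]]$supp, t)
        }
      }
    }
    kept <- lapply(tuples, function(tp) {
      list(code = matrix(tp$row, nrow = 1L), support = tp$supp)
    })
  } else {
    rmp <- code_rightmost_path(code)
    vr <- rmp[length(rmp)]
    pg <- code_to_graph(code)
    nv <- length(pg$vlab)
    has_edge <- matrix(FALSE, nv, nv)
    for (k in seq_len(nrow(code))) {
      has_edge[code[k, 1L] + 1L, code[k, 2L] + 1L] <- TRUE
      has_edge[code[k, 2L] + 1L, code[k, 1L] + 1L] <- TRUE
    }
    for (t in support) {
      g <- insts[[t]]
      for (emb in code_embeddings(code, g)) {
        gvr <- emb[vr + 1L]
        for (a in rmp) {   # backward extensions
          if (a == vr || has_edge[vr + 1L, a + 1L]) next
          el <- g_edge_label(g, gvr, emb[a + 1L])
          if (is.na(el)) next
          row <- c(vr, a, pg$vlab[vr + 1L], el, pg$vlab[a + 1L])
          key <- paste(row, collapse = ".")
          if (is.null(tuples[[key]])) tuples[[key]] <- list(row = row, supp = integer(0))
          sp <- tuples[[key]]$supp
          if (!length(sp) || sp[length(sp)] != t) tuples[[key]]$supp <- c(sp, t)
        }
        for (a in rmp) {   # forward extensions
          ga <- emb[a + 1L]
          nb <- g$adj[[ga]]
          if (!nrow(nb)) next
          for (q in seq_len(nrow(nb))) {
            w <- nb[q, 1L]
            if (w %in% emb) next
            row <- c(a, nv, pg$vlab[a + 1L], nb[q, 2L], g$vlab[w])
            key <- paste(row, collapse = ".")
            if (is.null(tuples[[key]])) tuples[[key]] <- list(row = row, supp = integer(0))
            sp <- tuples[[key]]$supp
            if (!length(sp) || sp[length(sp)] != t) tuples[[key]]$supp <- c(sp, t)
          }
        }
      }
    }
    kept <- list()
    for (tp in tuples) {
      cand <- rbind(code, tp$row)
      mc <- min_dfs_code(code_to_graph(cand))
      if (cmp_code(cand, mc) == 0L) {
        kept[[length(kept) + 1L]] <- list(code = cand, support = tp$supp)
      }
    }
  }
  if (!length(kept)) return(list())
  # deterministic canonical order on the extension tuple
  last_rows <- lapply(kept, function(ch) ch$code[nrow(ch$code), ])
  ord <- order_edge_tuples(last_rows)
  kept[ord]
}

order_edge_tuples <- function(rows) {
  m <- length(rows)
  if (m <= 1L) return(seq_len(m))
  idx <- seq_len(m)
  # insertion sort with the gSpan comparator (m is small)
  for (i in 2L:m) {
    j <- i
    while (j > 1L && cmp_edge_tuple(rows[[idx[j - 1L]]], rows[[idx[j]]]) > 0L) {
      tmp <- idx[j]; idx[j] <- idx[j - 1L]; idx[j - 1L] <- tmp
      j <- j - 1L
    }
  }
  idx
}

# canonical key of a traversal node body
body_key <- function(type, body, vocab = NULL) {
  switch(type,
    itemset = paste(body, collapse = ","),
    sequence = if (!is.null(vocab)) paste(vocab[body], collapse = "-")
               else paste(body, collapse = "-"),
    graph = paste(apply(body, 1L, paste, collapse = "."), collapse = ";")
  )
}

# materialize an spp_pattern from a traversal node
node_pattern <- function(dataset, node) {
  switch(node$type,
    itemset = spp_pattern(node$body, "itemset"),
    sequence = {
      p <- list(type = "sequence", symbols = node$body, vocab = dataset$vocab)
      p$key <- pattern_key(p)
      structure(p, class = "spp_pattern")
    },
    graph = pattern_from_code(node$body)
  )
}

#' Enumerate all patterns occurring in a dataset
#'
#' Exhaustive (unpruned) traversal of the pattern tree up to `max_length`.
#' Used by the brute-force oracle and by enumeration tests; guarded against
#' explosion.
#'
#' @param dataset an [spp_dataset()].
#' @param max_length maximum pattern size (items / symbols / edges).
#' @param seq_mode sequence containment mode.
#' @param guard maximum number of patterns enumerated before aborting.
#' @return tibble with columns `key`, `size`, `support` (list of integer
#'   vectors) and `pattern` (list of `spp_pattern`).
#' @export
enumerate_patterns <- function(dataset, max_length,
                               seq_mode = c("gapped", "contiguous"),
                               guard = 10000L) {
  seq_mode <- match.arg(seq_mode)
  keys <- character(0); sizes <- integer(0)
  supports <- list(); patterns <- list()
  visit <- function(node) {
    if (length(keys) >= guard) {
      stop("enumeration guard exceeded (", guard,
           " patterns); reduce max_length", call. = FALSE)
    }
    keys[length(keys) + 1L] <<- body_key(node$type, node$body, dataset$vocab)
    sizes[length(sizes) + 1L] <<- node$size
    supports[[length(supports) + 1L]] <<- node$support
    patterns[[length(patterns) + 1L]] <<- node_pattern(dataset, node)
    TRUE
  }
  pattern_tree_dfs(dataset, max_length, visit, seq_mode = seq_mode)
  tibble::tibble(key = keys, size = sizes, support = supports,
                 pattern = patterns)
}
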