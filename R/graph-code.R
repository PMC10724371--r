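# gSpan DFS codes: canonical serialization of connected labeled graphs.
#
# A DFS code is an integer matrix with one row per edge, columns
# (i, j, li, le, lj): dfs-indices of the endpoints (0-based), the label of
# vertex i, the edge label, and the label of vertex j.  Forward edges have
# i < j (j is the newly discovered vertex), backward edges have i > j.
# The minimum DFS code under the gSpan lexicographic order is a canonical
# key for the isomorphism class, so each class appears exactly once in the
# enumeration tree.

# gSpan linear order on edge tuples: -1 if a < b, 0 if equal, 1 if a > b.
cmp_edge_tuple <- function(a, b) {
  fa <- a[1L] < a[2L]; fb <- b[1L] < b[2L]
  if (fa && fb) {
    if (a[2L] != b[2L]) return(if (a[2L] < b[2L]) -1L else 1L)
    if (a[1L] != b[1L]) return(if (a[1L] > b[1L]) -1L else 1L)
  } else if (!fa && !fb) {
    if (a[1L] != b[1L]) return(if (a[1L] < b[1L]) -1L else 1L)
    if (a[2L] != b[2L]) return(if (a[2L] < b[2L]) -1L else 1L)
  } else if (!fa && fb) {
    return(if (a[1L] < b[2L]) -1L else 1L)   # backward vs forward
  } else {
    return(if (a[2L] <= b[1L]) -1L else 1L)  # forward vs backward
  }
  for (k in 3L:5L) {
    if (a[k] != b[k]) return(if (a[k] < b[k]) -1L else 1L)
  }
  0L
}

cmp_code <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  for (k in seq_len(min(na, nb))) {
    c <- cmp_edge_tuple(A[k, ], B[k, ])
    if (c != 0L) return(c)
  }
  if (na == nb) 0L else if (na < nb) -1L else 1L
}

# label of the edge between graph vertices u and v, or NA if absent
g_edge_label <- function(g, u, v) {
  a <- g$adj[[u]]
  hit <- which(a[, 1L] == v)
  if (length(hit)) a[hit[1L], 2L] else NA_integer_
}

# reconstruct the labeled graph described by a DFS code
code_to_graph <- function(code) {
  nv <- max(code[, 1L:2L]) + 1L
  vlab <- integer(nv)
  vlab[code[1L, 1L] + 1L] <- code[1L, 3L]
  ed <- matrix(integer(0), ncol = 3L)
  for (k in seq_len(nrow(code))) {
    r <- code[k, ]
    vlab[r[1L] + 1L] <- r[3L]
    vlab[r[2L] + 1L] <- r[5L]
    u <- min(r[1L], r[2L]) + 1L; v <- max(r[1L], r[2L]) + 1L
    ed <- rbind(ed, c(u, v, r[4L]))
  }
  as_spp_graph(list(vlab = vlab, edges = ed))
}

# minimum DFS code of a connected labeled graph (exhaustive DFS enumeration
# with prefix pruning; exponential worst case, intended for small patterns)
min_dfs_code <- function(g) {
  ne <- nrow(g$edges)
  if (ne == 0L) stop("min_dfs_code: graph has no edges", call. = FALSE)
  eid <- matrix(0L, length(g$vlab), length(g$vlab))
  for (k in seq_len(ne)) {
    u <- g$edges[k, 1L]; v <- g$edges[k, 2L]
    eid[u, v] <- k; eid[v, u] <- k
  }
  env <- new.env(parent = emptyenv())
  env$best <- NULL

  rec <- function(code, gmap, used, rmp, tight) {
    k <- nrow(code)
    if (k == ne) {
      if (is.null(env$best) || cmp_code(code, env$best) < 0L) env$best <- code
      return(invisible())
    }
    vr <- rmp[length(rmp)]
    gvr <- gmap[vr + 1L]
    cand <- list()
    # backward extensions from the rightmost vertex to the rightmost path
    for (a in rmp) {
      if (a == vr) next
      ga <- gmap[a + 1L]
      e <- eid[gvr, ga]
      if (e != 0L && !used[e]) {
        cand[[length(cand) + 1L]] <- list(
          row = c(vr, a, g$vlab[gvr], g$edges[e, 3L], g$vlab[ga]),
          e = e, fwd = FALSE, from = NA_integer_, to = ga)
      }
    }
    # forward extensions from vertices on the rightmost path
    nextidx <- length(gmap)  # next 0-based dfs index
    for (a in rmp) {
      ga <- gmap[a + 1L]
      nb <- g$adj[[ga]]
      if (!nrow(nb)) next
      for (q in seq_len(nrow(nb))) {
        w <- nb[q, 1L]
        if (w %in% gmap) next
        e <- eid[ga, w]
        if (used[e]) next
        cand[[length(cand) + 1L]] <- list(
          row = c(a, nextidx, g$vlab[ga], nb[q, 2L], g$vlab[w]),
          e = e, fwd = TRUE, from = a, to = w)
      }
    }
    for (cd in cand) {
      t2 <- tight
      if (t2 && !is.null(env$best)) {
        c <- cmp_edge_tuple(cd$row, env$best[k + 1L, ])
        if (c > 0L) next
        if (c < 0L) t2 <- FALSE
      }
      used2 <- used; used2[cd$e] <- TRUE
      if (cd$fwd) {
        gmap2 <- c(gmap, cd$to)
        rmp2 <- c(rmp[seq_len(which(rmp == cd$from))], cd$row[2L])
      } else {
        gmap2 <- gmap
        rmp2 <- rmp
      }
      rec(rbind(code, cd$row), gmap2, used2, rmp2, t2)
    }
    invisible()
  }

  for (k in seq_len(ne)) {
    u <- g$edges[k, 1L]; v <- g$edges[k, 2L]; l <- g$edges[k, 3L]
    for (ori in list(c(u, v), c(v, u))) {
      row <- c(0L, 1L, g$vlab[ori[1L]], l, g$vlab[ori[2L]])
      code <- matrix(row, nrow = 1L)
      tight <- TRUE
      if (!is.null(env$best)) {
        c <- cmp_edge_tuple(row, env$best[1L, ])
        if (c > 0L) next
        if (c < 0L) tight <- FALSE
      }
      used <- rep(FALSE, ne); used[k] <- TRUE
      rec(code, c(ori[1L], ori[2L]), used, c(0L, 1L), tight)
    }
  }
  env$best
}

# Enumerate embeddings of a DFS code into an instance graph.
# Returns a list of 0-based-dfs -> graph-vertex maps (integer vectors),
# or at most `limit` of them.
code_embeddings <- function(code, g, limit = Inf) {
  out <- list()
  ne <- nrow(code)
  rec <- function(k, gmap, used) {
    if (length(out) >= limit) return(invisible())
    if (k > ne) {
      out[[length(out) + 1L]] <<- gmap
      return(invisible())
    }
    r <- code[k, ]
    if (r[1L] < r[2L]) {  # forward: extend to an unmapped neighbor
      gu <- gmap[r[1L] + 1L]
      nb <- g$adj[[gu]]
      if (!nrow(nb)) return(invisible())
      for (q in seq_len(nrow(nb))) {
        w <- nb[q, 1L]
        if (!used[w] && nb[q, 2L] == r[4L] && g$vlab[w] == r[5L]) {
          used[w] <- TRUE
          rec(k + 1L, c(gmap, w), used)
          used[w] <- FALSE
          if (length(out) >= limit) return(invisible())
        }
      }
    } else {              # backward: required edge must exist
      gu <- gmap[r[1L] + 1L]; gv <- gmap[r[2L] + 1L]
      el <- g_edge_label(g, gu, gv)
      if (!is.na(el) && el == r[4L]) rec(k + 1L, gmap, used)
    }
    invisible()
  }
  starts <- which(g$vlab == code[1L, 3L])
  used <- rep(FALSE, length(g$vlab))
  for (s in starts) {
    used[s] <- TRUE
    rec(1L, s, used)
    used[s] <- FALSE
    if (length(out) >= limit) break
  }
  out
}

# rightmost path (0-based dfs indices, root first) of a DFS code
code_rightmost_path <- function(code) {
  vr <- max(code[, 1L:2L])
  path <- vr
  cur <- vr
  while (cur != 0L) {
    fr <- which(code[, 2L] == cur & code[, 1L] < code[, 2L])[1L]
    cur <- code[fr, 1L]
    path <- c(cur, path)
  }
  path
}
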