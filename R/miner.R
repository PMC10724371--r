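#' Mine the working set by safe-pattern-pruned tree traversal
#'
#' Depth-first traversal of the pattern tree.  At every node the pruning
#' score (`v_j` with one reference, `min(v_j(R1), v_j(R2))` with two) is
#' evaluated first: below `lambda` the whole subtree is eliminated.
#' Otherwise the screening score (`u_j`, or the two-sphere closed form
#' `u'_j`) decides whether the pattern itself joins the working set, and the
#' node is expanded regardless — a node can fail its own screening test while
#' a descendant is still active, so only the pruning score controls descent.
#'
#' The returned working set is a certified superset of the active set at
#' `(lambda, kappa)`.
#'
#' @param dataset an [spp_dataset()].
#' @param refs list of one or two reference solutions from
#'   [make_reference()], dual-scaled at the current `(lambda, kappa)`.
#' @param lambda,kappa regularization parameters.
#' @param max_length maximum pattern size.
#' @param seq_mode sequence containment mode.
#' @param prune set `FALSE` to disable subtree pruning (full traversal with
#'   screening only; used by control runs and tests).
#' @param guard maximum number of surviving patterns.
#' @return a `working_set`: list with `keys`, `bodies`, `supports`,
#'   `sizes`, and `counters` (`visited`, `pruned`, `kept`, `expanded`).
#' @export
mine_working_set <- function(dataset, refs, lambda, kappa, max_length,
                             seq_mode = c("gapped", "contiguous"),
                             prune = TRUE, guard = 50000L) {
  seq_mode <- match.arg(seq_mode)
  n <- n_instances(dataset)
  for (rf in refs) {
    if (!is.finite(rf$gap) || rf$gap < -1e-10) {
      stop("invalid reference solution (non-finite or negative gap)",
           call. = FALSE)
    }
  }
  two <- length(refs) >= 2L
  geo <- if (two) multi_ref_geometry(refs[[1L]], refs[[2L]]) else NULL
  keys <- character(0); bodies <- list(); supports <- list(); sizes <- integer(0)
  kept <- 0L
  visit <- function(node) {
    sup <- node$support
    if (prune) {
      v <- spp_score(sup, refs[[1L]], n)
      if (two) v <- min(v, spp_score(sup, refs[[2L]], n))
      if (v < lambda) return(FALSE)
    }
    u <- if (two) multi_screening_score(sup, refs[[1L]], refs[[2L]], geo, n)
         else screening_score(sup, refs[[1L]], n)
    if (u >= lambda) {
      kept <<- kept + 1L
      if (kept > guard) stop("working-set guard exceeded", call. = FALSE)
      keys[kept] <<- body_key(node$type, node$body, dataset$vocab)
      bodies[[kept]] <<- node$body
      supports[[kept]] <<- sup
      sizes[kept] <<- node$size
    }
    TRUE
  }
  cnt <- pattern_tree_dfs(dataset, max_length, visit, seq_mode = seq_mode)
  list(keys = keys, bodies = bodies, supports = supports, sizes = sizes,
       type = dataset$type, n = n, lambda = lambda, kappa = kappa,
       n_refs = length(refs),
       counters = list(visited = cnt$visited, pruned = cnt$pruned,
                       expanded = cnt$expanded, kept = kept))
}
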