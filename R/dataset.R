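#' Structured datasets for predictive pattern mining
#'
#' An `spp_dataset` bundles `n` structured instances with a numeric response.
#' Three structure types are supported:
#'
#' * `"itemset"` — each instance is a strictly increasing vector of positive
#'   integer item ids; patterns are sub-itemsets.
#' * `"sequence"` — each instance is an ordered vector of symbol ids (a
#'   character vocabulary maps ids back to tokens); patterns are gapped
#'   subsequences (default) or contiguous substrings.
#' * `"graph"` — each instance is an undirected graph with integer node and
#'   edge labels, no self-loops and no parallel edges; patterns are connected
#'   labeled subgraphs up to isomorphism.
#'
#' @param instances list of instances; see Details for the per-type layout.
#' @param y numeric response vector; for `task = "classification"` it must be
#'   coded in {-1, +1}.
#' @param type one of `"itemset"`, `"sequence"`, `"graph"`.
#' @param task `"regression"` or `"classification"`.
#' @param vocab optional character vector mapping symbol ids to tokens
#'   (sequences only).
#'
#' @details Itemset instances are integer vectors, sorted strictly
#'   increasing.  Sequence instances are integer vectors of ids into
#'   `vocab`.  Graph instances are lists with elements `vlab` (integer node
#'   labels) and `edges` (3-column integer matrix `u, v, elab`, `1 <= u < v`);
#'   an adjacency index is precomputed at construction.
#'
#' @return an object of class `spp_dataset`.
#' @export
spp_dataset <- function(instances, y,
                        type = c("itemset", "sequence", "graph"),
                        task = c("regression", "classification"),
                        vocab = NULL) {
  type <- match.arg(type)
  task <- match.arg(task)
  if (length(instances) != length(y)) {
    stop("`instances` and `y` must have the same length", call. = FALSE)
  }
  if (length(y) == 0L) stop("empty dataset", call. = FALSE)
  y <- as.numeric(y)
  if (task == "classification" && !all(y %in% c(-1, 1))) {
    stop("classification responses must be coded in {-1, +1}", call. = FALSE)
  }
  instances <- switch(type,
    itemset = lapply(instances, function(s) {
      s <- as.integer(s)
      if (any(s <= 0L)) stop("item ids must be positive integers", call. = FALSE)
      if (is.unsorted(s, strictly = TRUE)) {
        su <- sort(unique(s))
        if (length(su) != length(s)) {
          warning("duplicate item ids removed", call. = FALSE)
        }
        s <- su
      }
      s
    }),
    sequence = lapply(instances, as.integer),
    graph = lapply(instances, as_spp_graph)
  )
  structure(
    list(instances = instances, y = y, type = type, task = task, vocab = vocab),
    class = "spp_dataset"
  )
}

# normalize a graph instance and attach an adjacency index
as_spp_graph <- function(g) {
  vlab <- as.integer(g$vlab)
  ed <- g$edges
  if (is.null(ed) || nrow(ed) == 0L) {
    ed <- matrix(integer(0), ncol = 3L)
  } else {
    ed <- matrix(as.integer(ed), ncol = 3L)
    u <- pmin(ed[, 1L], ed[, 2L]); v <- pmax(ed[, 1L], ed[, 2L])
    if (any(u == v)) stop("self-loops are not allowed", call. = FALSE)
    if (any(v > length(vlab)) || any(u < 1L)) {
      stop("edge endpoint outside node range", call. = FALSE)
    }
    key <- paste(u, v)
    if (anyDuplicated(key)) stop("parallel edges are not allowed", call. = FALSE)
    ed <- cbind(u, v, ed[, 3L])
  }
  nv <- length(vlab)
  adj <- vector("list", nv)   # adj[[v]] = 2-col matrix (neighbor, edge label)
  for (v in seq_len(nv)) adj[[v]] <- matrix(integer(0), ncol = 2L)
  if (nrow(ed)) {
    for (k in seq_len(nrow(ed))) {
      u <- ed[k, 1L]; v <- ed[k, 2L]; l <- ed[k, 3L]
      adj[[u]] <- rbind(adj[[u]], c(v, l))
      adj[[v]] <- rbind(adj[[v]], c(u, l))
    }
  }
  list(vlab = vlab, edges = ed, adj = adj)
}

#' @export
print.spp_dataset <- function(x, ...) {
  cat(sprintf("<spp_dataset> %d %s instances (%s)\n",
              length(x$y), x$type, x$task))
  invisible(x)
}

#' Number of instances in a dataset
#' @param x an `spp_dataset`.
#' @export
n_instances <- function(x) length(x$y)

#' Subset a dataset by instance index
#'
#' Used to carve cross-validation folds; occurrence vectors on the subset are
#' the restriction of occurrence vectors on the full data.
#'
#' @param dataset an `spp_dataset`.
#' @param idx integer vector of instance indices to keep.
#' @return an `spp_dataset` with attribute `"parent_idx"` recording `idx`.
#' @export
subset_dataset <- function(dataset, idx) {
  out <- dataset
  out$instances <- dataset$instances[idx]
  out$y <- dataset$y[idx]
  attr(out, "parent_idx") <- as.integer(idx)
  out
}
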