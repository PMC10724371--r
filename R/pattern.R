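#' Patterns: sub-structures used as binary features
#'
#' A pattern is a sub-itemset, subsequence, or connected labeled subgraph.
#' Each pattern carries a canonical key that uniquely identifies it (for
#' graphs, the gSpan minimum DFS code identifies the isomorphism class).
#'
#' @param x the pattern body: an integer (or coercible) vector of item ids
#'   for `type = "itemset"`; a vector of symbol ids or vocabulary tokens for
#'   `type = "sequence"`; for `type = "graph"` a list with `vlab` and `edges`
#'   as in [spp_dataset()].
#' @param type structure type.
#' @param vocab optional vocabulary used to translate character sequence
#'   tokens to ids.
#' @return an object of class `spp_pattern` with fields depending on type
#'   and a `key` string (itemset `"1,5,9"`; sequence tokens joined by `"-"`;
#'   graph the serialized minimum DFS code).
#' @export
spp_pattern <- function(x, type = c("itemset", "sequence", "graph"),
                        vocab = NULL) {
  type <- match.arg(type)
  p <- switch(type,
    itemset = {
      items <- sort(unique(as.integer(x)))
      if (any(items <= 0L)) stop("item ids must be positive", call. = FALSE)
      list(type = type, items = items)
    },
    sequence = {
      if (is.character(x)) {
        if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1L]]
        if (is.null(vocab)) stop("vocab needed for character symbols", call. = FALSE)
        ids <- match(x, vocab)
        if (anyNA(ids)) stop("unknown sequence symbol", call. = FALSE)
      } else ids <- as.integer(x)
      list(type = type, symbols = ids, vocab = vocab)
    },
    graph = {
      g <- as_spp_graph(x)
      code <- min_dfs_code(g)
      list(type = type, code = code, graph = code_to_graph(code))
    }
  )
  p$key <- pattern_key(p)
  structure(p, class = "spp_pattern")
}

# pattern from a DFS code already known to be minimal
pattern_from_code <- function(code) {
  p <- list(type = "graph", code = code, graph = code_to_graph(code))
  p$key <- pattern_key(p)
  structure(p, class = "spp_pattern")
}

pattern_key <- function(p) {
  switch(p$type,
    itemset = paste(p$items, collapse = ","),
    sequence = {
      if (!is.null(p$vocab)) paste(p$vocab[p$symbols], collapse = "-")
      else paste(p$symbols, collapse = "-")
    },
    graph = paste(apply(p$code, 1L, paste, collapse = "."), collapse = ";")
  )
}

#' @export
print.spp_pattern <- function(x, ...) {
  cat(sprintf("<spp_pattern %s> %s\n", x$type, x$key))
  invisible(x)
}

#' Pattern size
#'
#' Itemset: number of items; sequence: number of symbols; graph: number of
#' edges.  This is the depth of the pattern in the enumeration tree.
#' @param pattern an `spp_pattern`.
#' @export
pattern_size <- function(pattern) {
  switch(pattern$type,
    itemset = length(pattern$items),
    sequence = length(pattern$symbols),
    graph = nrow(pattern$code)
  )
}

#' Containment test under the pattern partial order
#'
#' Tests whether `pattern` occurs in `instance`: subset containment for
#' itemsets; gapped-subsequence (default) or contiguous-substring containment
#' for sequences; labeled-subgraph isomorphism for graphs.
#'
#' @param pattern an `spp_pattern`.
#' @param instance one instance from an [spp_dataset()] of the same type.
#' @param type structure type of `instance` (defaults to the pattern's).
#' @param seq_mode `"gapped"` or `"contiguous"` sequence matching.
#' @return logical scalar.
#' @export
spp_contains <- function(pattern, instance, type = pattern$type,
                         seq_mode = c("gapped", "contiguous")) {
  if (!identical(type, pattern$type)) {
    stop("pattern/instance variant mismatch: pattern is ", pattern$type,
         ", instance is ", type, call. = FALSE)
  }
  switch(pattern$type,
    itemset = all(pattern$items %in% instance),
    sequence = {
      seq_mode <- match.arg(seq_mode)
      if (seq_mode == "gapped") is_subsequence(pattern$symbols, instance)
      else is_substring(pattern$symbols, instance)
    },
    graph = length(code_embeddings(pattern$code, instance, limit = 1L)) > 0L
  )
}

is_subsequence <- function(p, s) {
  np <- length(p)
  if (np == 0L) return(TRUE)
  j <- 1L
  for (x in s) {
    if (x == p[j]) {
      j <- j + 1L
      if (j > np) return(TRUE)
    }
  }
  FALSE
}

is_substring <- function(p, s) {
  np <- length(p); ns <- length(s)
  if (np == 0L) return(TRUE)
  if (np > ns) return(FALSE)
  for (st in 1L:(ns - np + 1L)) {
    if (all(s[st:(st + np - 1L)] == p)) return(TRUE)
  }
  FALSE
}

#' Occurrence vector of a pattern over a dataset
#'
#' The binary column of the (implicit) design matrix: entry `i` is 1 iff
#' instance `i` contains the pattern.
#'
#' @inheritParams spp_contains
#' @param dataset an [spp_dataset()].
#' @return integer 0/1 vector of length `n` with attribute `"support"`
#'   holding the indices of containing instances.
#' @export
occurrence_vector <- function(pattern, dataset,
                              seq_mode = c("gapped", "contiguous")) {
  seq_mode <- match.arg(seq_mode)
  if (n_instances(dataset) == 0L) stop("empty dataset", call. = FALSE)
  hit <- vapply(dataset$instances, function(s) {
    spp_contains(pattern, s, type = dataset$type, seq_mode = seq_mode)
  }, logical(1L))
  x <- as.integer(hit)
  attr(x, "support") <- which(hit)
  x
}
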