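#' Read and write itemset datasets
#'
#' Line format: whitespace-separated `y i1 i2 ...` with positive integer item
#' ids.  Ids are sorted and deduplicated on read (with a warning when
#' duplicates were present).
#'
#' @param path file path.
#' @param task response type.
#' @return an [spp_dataset()].
#' @export
read_itemset <- function(path, task = c("regression", "classification")) {
  task <- match.arg(task)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  y <- numeric(length(lines)); insts <- vector("list", length(lines))
  dup <- FALSE
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    yv <- suppressWarnings(as.numeric(tok[1L]))
    if (is.na(yv)) stop("line ", i, ": malformed response", call. = FALSE)
    ids <- suppressWarnings(as.integer(tok[-1L]))
    if (anyNA(ids)) stop("line ", i, ": malformed item id", call. = FALSE)
    su <- sort(unique(ids))
    if (length(su) != length(ids)) dup <- TRUE
    y[i] <- yv; insts[[i]] <- su
  }
  if (dup) warning("duplicate item ids removed", call. = FALSE)
  spp_dataset(insts, y, type = "itemset", task = task)
}

#' @rdname read_itemset
#' @param dataset an itemset [spp_dataset()].
#' @export
write_itemset <- function(dataset, path) {
  stopifnot(dataset$type == "itemset")
  lines <- vapply(seq_along(dataset$y), function(i) {
    paste(c(format(dataset$y[i], digits = 17),
            dataset$instances[[i]]), collapse = " ")
  }, character(1))
  writeLines(lines, path)
}

#' Read and write sequence datasets
#'
#' TSV format: `y<TAB>SYMBOLS` with one character per symbol; FASTA format:
#' headers `>id y=<value>` with the sequence on the following lines (read
#' via Biostrings).
#'
#' @param path file path.
#' @param format `"tsv"` or `"fasta"`.
#' @param task response type.
#' @return an [spp_dataset()] with a character vocabulary.
#' @export
read_sequences <- function(path, format = c("tsv", "fasta"),
                           task = c("regression", "classification")) {
  format <- match.arg(format)
  task <- match.arg(task)
  if (format == "tsv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    y <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
    seqs <- vapply(parts, function(p) p[2L], character(1))
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("Biostrings is required to read FASTA", call. = FALSE)
    }
    ss <- Biostrings::readBStringSet(path)
    hdr <- names(ss)
    ym <- regmatches(hdr, regexpr("y=[-+0-9.eE]+", hdr))
    if (length(ym) != length(hdr)) {
      stop("every FASTA header must carry 'y=<value>'", call. = FALSE)
    }
    y <- as.numeric(sub("^y=", "", ym))
    seqs <- unname(as.character(ss))
  }
  if (anyNA(y)) stop("malformed response", call. = FALSE)
  chars <- strsplit(seqs, "")
  vocab <- sort(unique(unlist(chars)))
  insts <- lapply(chars, function(s) match(s, vocab))
  spp_dataset(insts, y, type = "sequence", task = task, vocab = vocab)
}

#' @rdname read_sequences
#' @param dataset a sequence [spp_dataset()].
#' @export
write_sequences <- function(dataset, path, format = c("tsv", "fasta")) {
  stopifnot(dataset$type == "sequence")
  format <- match.arg(format)
  txt <- vapply(dataset$instances, function(s) {
    paste(dataset$vocab[s], collapse = "")
  }, character(1))
  if (format == "tsv") {
    writeLines(paste(format(dataset$y, digits = 17), txt, sep = "\t"), path)
  } else {
    writeLines(as.vector(rbind(
      sprintf(">seq%d y=%s", seq_along(txt), format(dataset$y, digits = 17)),
      txt)), path)
  }
}

#' Read and write graph datasets (gSpan text format)
#'
#' Graph blocks `t # <id>` / `v <id> <label>` / `e <u> <v> <label>` with
#' 0-based vertex ids; responses in a side TSV `graph_id<TAB>y`.
#'
#' @param graph_path path of the gSpan-format graph file.
#' @param response_path path of the response TSV.
#' @param task response type.
#' @return an [spp_dataset()].
#' @export
read_gspan <- function(graph_path, response_path,
                       task = c("regression", "classification")) {
  task <- match.arg(task)
  lines <- trimws(readLines(graph_path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  ids <- character(0); graphs <- list()
  vlab <- integer(0); edges <- NULL
  flush <- function() {
    if (length(vlab)) {
      graphs[[length(graphs) + 1L]] <<-
        list(vlab = vlab, edges = if (is.null(edges)) {
          matrix(integer(0), ncol = 3L)
        } else edges)
    }
  }
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\\s+")[[1L]]
    if (tok[1L] == "t") {
      flush()
      vlab <- integer(0); edges <- NULL
      ids <- c(ids, tok[3L])
    } else if (tok[1L] == "v") {
      vlab[as.integer(tok[2L]) + 1L] <- as.integer(tok[3L])
    } else if (tok[1L] == "e") {
      edges <- rbind(edges, as.integer(tok[2L:4L]) + c(1L, 1L, 0L))
    } else {
      stop("line ", i, ": unknown record '", tok[1L], "'", call. = FALSE)
    }
  }
  flush()
  resp <- utils::read.table(response_path, sep = "\t",
                            col.names = c("id", "y"),
                            colClasses = c("character", "numeric"))
  pos <- match(ids, resp$id)
  if (anyNA(pos)) {
    stop("missing response for graph id(s): ",
         paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  spp_dataset(graphs, resp$y[pos], type = "graph", task = task)
}

#' @rdname read_gspan
#' @param dataset a graph [spp_dataset()].
#' @export
write_gspan <- function(dataset, graph_path, response_path) {
  stopifnot(dataset$type == "graph")
  out <- character(0)
  for (i in seq_along(dataset$instances)) {
    g <- dataset$instances[[i]]
    out <- c(out, sprintf("t # %d", i),
             sprintf("v %d %d", seq_along(g$vlab) - 1L, g$vlab))
    if (nrow(g$edges)) {
      out <- c(out, sprintf("e %d %d %d", g$edges[, 1L] - 1L,
                            g$edges[, 2L] - 1L, g$edges[, 3L]))
    }
  }
  writeLines(out, graph_path)
  writeLines(paste(seq_along(dataset$y),
                   format(dataset$y, digits = 17), sep = "\t"),
             response_path)
}

#' Serialize a fitted model to JSON
#'
#' @param fit an `spp_fit`.
#' @param path output path (JSON written with intercept and a
#'   `pattern_key`/`coefficient` table).
#' @export
write_model_json <- function(fit, path) {
  obj <- list(
    lambda = fit$lambda, kappa = fit$kappa, beta0 = fit$beta0,
    gap = fit$gap, converged = fit$converged,
    coefficients = lapply(seq_along(fit$coef), function(j) {
      list(pattern_key = names(fit$coef)[j], coefficient = unname(fit$coef[j]))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
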