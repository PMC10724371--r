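#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted pattern model
#'
#' @param x an `spp_fit`.
#' @param ... unused.
#' @return tibble with one row per active pattern: `key`, `coefficient`,
#'   `support_size`, `lambda`, `kappa`.
#' @export
tidy.spp_fit <- function(x, ...) {
  tibble::tibble(
    key = names(x$coef),
    coefficient = unname(x$coef),
    support_size = lengths(x$supports),
    lambda = x$lambda, kappa = x$kappa)
}

#' @rdname tidy.spp_fit
#' @export
glance.spp_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, kappa = x$kappa, n_active = length(x$coef),
    beta0 = x$beta0, gap = x$gap, rel_gap = x$rel_gap,
    n_iter = x$n_iter, converged = x$converged,
    nodes_visited = x$ws_counters$visited,
    ws_size = x$ws_counters$kept)
}

#' Tidy a regularization path
#'
#' @param x an `spp_path` or `spp_path2d`.
#' @param ... unused.
#' @return long tibble: one row per (grid point, active pattern).
#' @export
tidy.spp_path <- function(x, ...) {
  dplyr::bind_rows(lapply(x$fits, tidy))
}

#' @rdname tidy.spp_path
#' @export
glance.spp_path <- function(x, ...) x$results

#' @rdname tidy.spp_path
#' @export
tidy.spp_path2d <- function(x, ...) {
  dplyr::bind_rows(lapply(unlist(x$fits, recursive = FALSE), tidy))
}

#' @rdname tidy.spp_path
#' @export
glance.spp_path2d <- function(x, ...) x$results

#' @rdname tidy.spp_path
#' @export
tidy.spp_cv <- function(x, ...) x$cv_table

#' @rdname tidy.spp_path
#' @export
glance.spp_cv <- function(x, ...) {
  tibble::tibble(lambda_min = x$lambda_min,
                 n_active = length(x$best_fit$coef),
                 mean_loss_min = min(x$cv_means$mean_loss),
                 n_folds = length(x$fold_fits))
}

#' Coefficient-path plot
#'
#' @param object an `spp_path`.
#' @param ... unused.
#' @return a ggplot: coefficient trajectories against `log10(lambda)`.
#' @export
autoplot.spp_path <- function(object, ...) {
  td <- tidy(object)
  if (!nrow(td)) td <- tibble::tibble(key = character(0), lambda = numeric(0),
                                      coefficient = numeric(0))
  ggplot2::ggplot(td, ggplot2::aes(x = log10(.data$lambda),
                                   y = .data$coefficient,
                                   colour = .data$key)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "log10(lambda)", y = "coefficient",
                  colour = "pattern") +
    ggplot2::theme_minimal()
}

#' Cross-validation curve plot
#'
#' @param object an `spp_cv`.
#' @param ... unused.
#' @return a ggplot: mean validation loss against `log10(lambda)` with the
#'   selected lambda marked.
#' @export
autoplot.spp_cv <- function(object, ...) {
  ggplot2::ggplot(object$cv_means,
                  ggplot2::aes(x = log10(.data$lambda), y = .data$mean_loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = log10(object$lambda_min),
                        linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "log10(lambda)", y = "mean validation loss") +
    ggplot2::theme_minimal()
}

#' Screening-statistics plot
#'
#' @param path an `spp_path` or `spp_path2d`.
#' @return a ggplot comparing tree nodes visited and working-set size along
#'   the path.
#' @export
plot_screening_stats <- function(path) {
  res <- glance(path)
  long <- tidyr_pivot(res)
  ggplot2::ggplot(long, ggplot2::aes(x = log10(.data$lambda),
                                     y = .data$value,
                                     colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "log10(lambda)", y = "count") +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(res) {
  dplyr::bind_rows(
    tibble::tibble(lambda = res$lambda, statistic = "nodes_visited",
                   value = res$nodes_visited),
    tibble::tibble(lambda = res$lambda, statistic = "ws_size",
                   value = res$ws_size),
    tibble::tibble(lambda = res$lambda, statistic = "n_active",
                   value = res$n_active))
}
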