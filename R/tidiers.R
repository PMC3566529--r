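#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a connectivity map into a voxel-level tibble
#'
#' @param x A `connectivity_map`.
#' @param ... Unused.
#' @return A tibble with `i`, `j`, `k`, `value` for every masked voxel that
#'   carries a value.
#' @export
tidy.connectivity_map <- function(x, ...) {
  idx <- which(x$mask & !is.na(x$values), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                 value = x$values[idx])
}

#' One-row summary of a connectivity map
#'
#' @param x A `connectivity_map`.
#' @param ... Unused.
#' @export
glance.connectivity_map <- function(x, ...) {
  v <- x$values[x$mask]
  tibble::tibble(method = x$method,
                 n_voxels = sum(x$mask),
                 mean_value = mean(v, na.rm = TRUE),
                 max_value = max(v, na.rm = TRUE),
                 fisher_transformed = x$fisher_transformed,
                 smoothed_fwhm_mm = x$smoothed_fwhm_mm %||% NA_real_,
                 n_degenerate = x$n_degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy a group result into its cluster table
#'
#' @param x A `group_result`.
#' @param ... Unused.
#' @return The corrected cluster tibble (id, size, peak t, peak
#'   coordinates).
#' @export
tidy.group_result <- function(x, ...) x$clusters

#' One-row summary of a group analysis
#'
#' @param x A `group_result`.
#' @param ... Unused.
#' @export
glance.group_result <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 threshold_p = x$threshold_p,
                 min_cluster_size = x$min_cluster_size,
                 n_significant_clusters = nrow(x$clusters),
                 largest_cluster = if (nrow(x$clusters))
                   max(x$clusters$size_voxels) else 0L)
}

#' Plot a discriminability timeseries
#'
#' The per-time-point multi-voxel pattern discriminability trace: positive
#' values mark time-points the correlation classifier would label correctly.
#'
#' @param object A `discrim_ts`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.discrim_ts <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition), size = 0.8) +
    ggplot2::labs(x = "analyzed time-point (n)",
                  y = "pattern discriminability (Fisher-z difference)",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a connectivity map
#'
#' @param object A `connectivity_map`.
#' @param k Slice index (defaults to the seed center's slice).
#' @param ... Unused.
#' @return A ggplot heatmap of the slice.
#' @export
autoplot.connectivity_map <- function(object, k = NULL, ...) {
  if (is.null(k)) k <- object$seed$center[3]
  df <- tidy(object)
  df <- df[df$k == k, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(object$method, " map, slice k = ", k),
                  fill = object$method) +
    ggplot2::theme_minimal()
}

#' Plot the null max-cluster-size distribution of a group result
#'
#' @param object A `group_result` with an attached null distribution.
#' @param ... Unused.
#' @return A ggplot histogram with the corrected threshold marked.
#' @export
autoplot.group_result <- function(object, ...) {
  if (is.null(object$null)) {
    stop("Group result carries no null distribution.", call. = FALSE)
  }
  df <- tibble::tibble(size = object$null$max_cluster_sizes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$min_cluster_size,
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "max cluster size under permutation (voxels)",
                  y = "null group maps",
                  title = "Permutation null of maximum cluster size") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
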