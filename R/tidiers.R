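## broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a shared PCA model: one row per component
#' @param x a `msw_pca`.
#' @param ... unused.
#' @return tibble: `component` (0-based name), `variance`, `proportion`,
#'   `cumulative`.
#' @export
tidy.msw_pca <- function(x, ...) {
  v <- x$explained_variance
  tibble::tibble(
    component = paste0("pc", seq_along(v) - 1L),
    variance = v,
    proportion = v / x$total_variance,
    cumulative = cumsum(v / x$total_variance)
  )
}

#' One-row summary of a shared PCA model
#' @param x a `msw_pca`.
#' @param ... unused.
#' @return tibble: `n_components`, `n_coordinates`, `total_variance`,
#'   `proportion_retained`.
#' @export
glance.msw_pca <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$explained_variance),
    n_coordinates = ncol(x$components),
    total_variance = x$total_variance,
    proportion_retained = sum(x$explained_variance) / x$total_variance
  )
}

#' Tidy a microstate cluster assignment: one row per cluster
#' @param x a `msw_clusters`.
#' @param ... unused.
#' @return tibble: `cluster`, `population_pct`, `center_pc0`, `center_pc1`,
#'   `medoid_replica`, `medoid_frame`.
#' @export
tidy.msw_clusters <- function(x, ...) {
  centers <- attr(x, "centers")
  med <- attr(x, "medoids")
  tibble::tibble(
    cluster = seq_len(attr(x, "k")),
    population_pct = unname(attr(x, "populations")),
    center_pc0 = centers[, 1],
    center_pc1 = if (ncol(centers) > 1) centers[, 2] else NA_real_,
    medoid_replica = med$replica,
    medoid_frame = med$frame
  )
}

#' One-row summary of a cluster assignment
#' @param x a `msw_clusters`.
#' @param ... unused.
#' @return tibble: `ensemble`, `k`, `n_frames`, `n_dims`,
#'   `mean_silhouette` (of the chosen k, `NA` if not evaluated).
#' @export
glance.msw_clusters <- function(x, ...) {
  sil <- attr(x, "silhouette")
  tibble::tibble(
    ensemble = x$ensemble[1],
    k = attr(x, "k"),
    n_frames = nrow(x),
    n_dims = attr(x, "n_dims"),
    mean_silhouette = sil$mean_silhouette[match(attr(x, "k"), sil$k)]
  )
}

#' Tidy a conditional histogram set: per-state fractions
#' @param x a `msw_conditional`.
#' @param ... unused.
#' @return the `fractions` tibble (`state`, `fraction`, `minor`).
#' @export
tidy.msw_conditional <- function(x, ...) x$fractions
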