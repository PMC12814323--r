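## Shared-basis backbone PCA, per-ensemble microstate clustering, medoids,
## and PC-space histograms. One PCA model is fitted to the pooled frames of
## all ensembles so scores are directly comparable across ensembles.

#' Fit one shared PCA to a pooled backbone matrix
#'
#' Mean-centred eigendecomposition of the coordinate covariance (via SVD).
#' Component signs are fixed by making each component's largest-magnitude
#' entry positive, so plots are reproducible across runs. Components are
#' named `pc0`, `pc1`, ... with `pc0` carrying the largest variance.
#'
#' @param backbone a superposed `msw_backbone` pooling all ensembles.
#' @param n_components number of components to retain (default
#'   `min(20, n_frames - 1, n_coordinates)`).
#' @return a `msw_pca`: list with `mean`, `components` (n_components x
#'   n_coordinates), `explained_variance` (non-increasing), `total_variance`
#'   and the backbone `atom_index`.
#' @export
fit_shared_pca <- function(backbone, n_components = NULL) {
  stopifnot(inherits(backbone, "msw_backbone"))
  xyz <- backbone$xyz
  if (nrow(xyz) < 2) stop("PCA needs at least 2 frames", call. = FALSE)
  if (!backbone$superposed) {
    warning("backbone matrix is not superposed; PCA variance will mix ",
            "internal motion with rigid-body drift", call. = FALSE)
  }
  if (is.null(n_components)) n_components <- min(20L, nrow(xyz) - 1L, ncol(xyz))
  stopifnot(n_components >= 1, n_components <= min(nrow(xyz) - 1L, ncol(xyz)))
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE, rank. = n_components)
  comp <- t(pc$rotation)  # n_components x n_coordinates
  # deterministic sign: largest-|entry| positive per component
  for (i in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  dimnames(comp) <- NULL
  structure(list(
    mean = unname(pc$center),
    components = comp,
    explained_variance = unname(pc$sdev[seq_len(n_components)]^2),
    total_variance = sum(pc$sdev^2),
    atom_index = backbone$atom_index
  ), class = "msw_pca")
}

#' @export
print.msw_pca <- function(x, ...) {
  k <- length(x$explained_variance)
  cat("<msw_pca> ", k, " components over ", ncol(x$components),
      " coordinates; pc0 explains ",
      round(100 * x$explained_variance[1] / x$total_variance, 1), "% of variance\n",
      sep = "")
  invisible(x)
}

#' Project frames onto a shared PCA basis
#'
#' `scores = (frames - mean) %*% t(components)`. Projection of one ensemble
#' never depends on which other ensembles are present: only the fit does.
#'
#' @param model a `msw_pca`.
#' @param backbone a `msw_backbone` with the same column ordering as the
#'   matrix the model was fitted to.
#' @return a `msw_scores` tibble: `ensemble`, `replica`, `frame`,
#'   `pc0` ... `pc<k-1>`.
#' @export
project_scores <- function(model, backbone) {
  stopifnot(inherits(model, "msw_pca"), inherits(backbone, "msw_backbone"))
  if (ncol(backbone$xyz) != ncol(model$components)) {
    stop("column-count mismatch: model has ", ncol(model$components),
         " coordinates, matrix has ", ncol(backbone$xyz), call. = FALSE)
  }
  sc <- sweep(backbone$xyz, 2, model$mean) %*% t(model$components)
  colnames(sc) <- paste0("pc", seq_len(ncol(sc)) - 1L)
  out <- dplyr::bind_cols(backbone$labels, tibble::as_tibble(sc))
  class(out) <- c("msw_scores", class(out))
  out
}

pc_cols <- function(scores) grep("^pc[0-9]+$", names(scores), value = TRUE)

score_matrix <- function(scores, n_dims = NULL) {
  cols <- pc_cols(scores)
  if (!is.null(n_dims)) cols <- cols[seq_len(min(n_dims, length(cols)))]
  as.matrix(scores[, cols, drop = FALSE])
}

#' Cluster one ensemble's PC scores into backbone microstates
#'
#' k-means (multiple restarts, fixed seed) on the first `n_dims` principal
#' components; when `k_range` offers several candidates, k is chosen by the
#' mean silhouette width, evaluated on a deterministic subsample of at most
#' `silhouette_n` frames. Clusters are canonically renumbered by descending
#' population, so reports are stable. Cluster centres are reported in the
#' full available PC space; each cluster's medoid is the actual frame
#' closest (in the first `n_dims` PCs) to its centre, ties broken by lowest
#' (replica, frame).
#'
#' @param scores a `msw_scores` tibble (all rows are used: filter to one
#'   ensemble first, or pass `ensemble`).
#' @param ensemble optional ensemble label to filter on.
#' @param k_range candidate cluster counts (default 4:6).
#' @param n_dims PC dimensions used for the metric (default 5).
#' @param seed RNG seed for k-means restarts and the silhouette subsample.
#' @param nstart k-means restarts per candidate k.
#' @param silhouette_n max frames entering the silhouette computation.
#' @return a `msw_clusters` tibble (`ensemble`, `replica`, `frame`,
#'   `cluster`) with attributes `centers`, `populations` (percent),
#'   `medoids`, `k`, `n_dims`, `silhouette`.
#' @export
cluster_ensemble <- function(scores, ensemble = NULL, k_range = 4:6,
                             n_dims = 5, seed = 1L, nstart = 10,
                             silhouette_n = 2000) {
  stopifnot(all(k_range >= 1), all(k_range <= 12))
  if (!is.null(ensemble)) scores <- scores[scores$ensemble == ensemble, ]
  scores <- dplyr::arrange(scores, .data$replica, .data$frame)
  n <- nrow(scores)
  if (n < max(k_range)) {
    stop("fewer frames (", n, ") than clusters (", max(k_range), ")", call. = FALSE)
  }
  X <- score_matrix(scores, n_dims)
  fits <- list()
  sil <- rep(NA_real_, length(k_range))
  sub <- withr::with_seed(seed, sort(sample.int(n, min(silhouette_n, n))))
  dsub <- if (length(k_range) > 1) stats::dist(X[sub, , drop = FALSE]) else NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    # restarts that stall (quick-transfer cap, empty cluster) simply lose
    # the nstart comparison, so those warnings carry no information here
    fits[[i]] <- withr::with_seed(seed, withCallingHandlers(
      stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100),
      warning = function(w) {
        if (grepl("empty cluster|Quick-TRANSfer", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }))
    if (length(k_range) > 1 && k > 1) {
      s <- cluster::silhouette(fits[[i]]$cluster[sub], dsub)
      sil[i] <- mean(s[, "sil_width"])
    }
  }
  best <- if (length(k_range) == 1) 1L else which.max(sil)
  km <- fits[[best]]
  k <- as.integer(k_range[best])

  # canonical ordering: descending population
  sizes <- tabulate(km$cluster, k)
  ord <- order(-sizes, seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  cl <- relab[km$cluster]

  full <- score_matrix(scores)
  centers <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(full[cl == j, , drop = FALSE])
  }))
  rownames(centers) <- seq_len(k)
  populations <- 100 * tabulate(cl, k) / n

  med <- lapply(seq_len(k), function(j) {
    rows <- which(cl == j)
    d2 <- rowSums(sweep(X[rows, , drop = FALSE], 2,
                        centers[j, seq_len(ncol(X))])^2)
    r <- rows[which.min(d2)]  # rows sorted by (replica, frame): first = lowest
    tibble::tibble(cluster = j, replica = scores$replica[r],
                   frame = scores$frame[r], distance = sqrt(min(d2)))
  })

  out <- dplyr::bind_cols(scores[, c("ensemble", "replica", "frame")],
                          tibble::tibble(cluster = cl))
  class(out) <- c("msw_clusters", class(out))
  attr(out, "centers") <- centers
  attr(out, "populations") <- populations
  attr(out, "medoids") <- dplyr::bind_rows(med)
  attr(out, "k") <- as.integer(k)
  attr(out, "n_dims") <- ncol(X)
  attr(out, "silhouette") <- tibble::tibble(k = k_range, mean_silhouette = sil)
  out
}

#' Medoid frames of a cluster assignment
#' @param assignment a `msw_clusters`.
#' @return tibble: `cluster`, `replica`, `frame`, `distance` (PC space).
#' @export
medoid_frames <- function(assignment) attr(assignment, "medoids")

#' Cluster populations (percent of ensemble frames)
#' @param assignment a `msw_clusters`.
#' @return named numeric vector summing to 100.
#' @export
cluster_populations <- function(assignment) {
  p <- attr(assignment, "populations")
  stats::setNames(p, seq_along(p))
}

#' 2-D histogram of PC scores
#'
#' @param scores a `msw_scores` tibble (filter to one ensemble for
#'   per-ensemble panels).
#' @param pcs names of the two PC columns (default `pc0`, `pc1`).
#' @param bins number of bins per axis.
#' @param edges optional list(x, y) of shared bin edges, so histograms of
#'   different ensembles are comparable; default spans this data.
#' @param normalize if `TRUE`, the grid sums to 1.
#' @return a `msw_hist2d`: list(`counts`, `xedges`, `yedges`, `n`,
#'   `normalized`, `pcs`).
#' @export
histogram2d <- function(scores, pcs = c("pc0", "pc1"), bins = 100,
                        edges = NULL, normalize = FALSE) {
  stopifnot(length(pcs) == 2, all(pcs %in% names(scores)))
  if (nrow(scores) == 0) stop("empty score selection", call. = FALSE)
  x <- scores[[pcs[1]]]; y <- scores[[pcs[2]]]
  if (is.null(edges)) {
    edges <- list(x = hist_edges(x, bins), y = hist_edges(y, bins))
  }
  ix <- bin_1d(x, edges$x); iy <- bin_1d(y, edges$y)
  keep <- !is.na(ix) & !is.na(iy)
  counts <- matrix(0L, length(edges$x) - 1L, length(edges$y) - 1L)
  tab <- table(factor(ix[keep], levels = seq_len(nrow(counts))),
               factor(iy[keep], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  out <- list(counts = counts, xedges = edges$x, yedges = edges$y,
              n = sum(keep), normalized = normalize, pcs = pcs)
  if (normalize) out$counts <- out$counts / sum(out$counts)
  structure(out, class = "msw_hist2d")
}

hist_edges <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = bins + 1L)
}

# 1-based bin index with right-closed final bin; NA outside the edge range
bin_1d <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' 1-D histogram along an oblique axis in the PC0-PC1 plane
#'
#' Scores are projected onto the axis `(cos(theta), sin(theta))`, measured
#' counterclockwise from the first PC, then histogrammed; `theta = 0`
#' reproduces the PC0 histogram, `theta = 90` the PC1 histogram. The
#' default 60 degrees targets the direction separating overlapped
#' microstates that neither PC resolves alone.
#'
#' @param scores a `msw_scores` tibble.
#' @param angle_deg axis angle in degrees (default 60).
#' @param bins bin count.
#' @param edges optional shared bin edges.
#' @param pcs the two PC columns spanning the plane.
#' @param normalize if `TRUE`, counts sum to 1.
#' @return a `msw_hist1d`: list(`counts`, `edges`, `angle_deg`, `n`).
#' @export
oblique_histogram <- function(scores, angle_deg = 60, bins = 100,
                              edges = NULL, pcs = c("pc0", "pc1"),
                              normalize = FALSE) {
  stopifnot(all(pcs %in% names(scores)))
  th <- angle_deg * pi / 180
  v <- cos(th) * scores[[pcs[1]]] + sin(th) * scores[[pcs[2]]]
  if (is.null(edges)) edges <- hist_edges(v, bins)
  i <- bin_1d(v, edges)
  counts <- tabulate(i[!is.na(i)], length(edges) - 1L)
  if (normalize) counts <- counts / sum(counts)
  structure(list(counts = counts, edges = edges, angle_deg = angle_deg,
                 n = sum(!is.na(i)), normalized = normalize),
            class = "msw_hist1d")
}

#' Pairwise backbone RMSD between all cluster centres
#'
#' Each centre is back-projected to coordinate space
#' (`mean + center %*% components`) and pairwise RMSD is computed after
#' rigid-body superposition, giving one symmetric matrix across the
#' clusters of all ensembles.
#'
#' @param assignments a `msw_clusters` or list of them (one per ensemble).
#' @param model the shared `msw_pca`.
#' @return symmetric matrix (zero diagonal) with `label:cluster` dimnames.
#' @export
cluster_center_rmsd <- function(assignments, model) {
  stopifnot(inherits(model, "msw_pca"))
  if (inherits(assignments, "msw_clusters")) assignments <- list(assignments)
  rows <- list()
  for (asg in assignments) {
    centers <- attr(asg, "centers")
    lab <- asg$ensemble[1]
    nc <- min(ncol(centers), nrow(model$components))
    for (j in seq_len(nrow(centers))) {
      coord <- model$mean +
        as.vector(centers[j, seq_len(nc)] %*% model$components[seq_len(nc), ])
      rows[[paste0(lab, ":", j)]] <- coord
    }
  }
  m <- length(rows)
  out <- matrix(0, m, m, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j > i) {
        out[i, j] <- out[j, i] <-
          bio3d::rmsd(rows[[i]], rows[[j]], fit = TRUE)
      }
    }
  }
  out
}
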