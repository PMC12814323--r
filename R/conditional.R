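## Rotamer-conditioned PC-space distributions: partition an ensemble's
## frames by the rotamer state of one residue and histogram each part on
## shared bin edges, so the per-state histograms sum bin-wise to the
## unconditioned histogram exactly.

#' Condition PC histograms on the rotamer state of one residue
#'
#' @param scores a `msw_scores` tibble for one ensemble.
#' @param states a `msw_states` tibble covering the same frames; filtered
#'   to `resno` if it holds several residues.
#' @param resno conditioning residue (default: the only residue present).
#' @param pcs the two PC columns (default `pc0`, `pc1`).
#' @param bins bins per axis.
#' @param oblique_angle angle (degrees) of the additional 1-D oblique
#'   histogram; default 60.
#' @param minor_threshold per-state fractions below this are flagged.
#' @return a `msw_conditional`: list with `resno`, `fractions` tibble
#'   (`state`, `fraction`, `minor`), `histograms` (named list per state of
#'   `msw_hist2d`), `oblique` (named list of `msw_hist1d`), and
#'   `unconditioned` (`msw_hist2d` plus `oblique`).
#' @export
condition_histograms <- function(scores, states, resno = NULL,
                                 pcs = c("pc0", "pc1"), bins = 100,
                                 oblique_angle = 60, minor_threshold = 0.05) {
  if (is.null(resno)) {
    resno <- unique(states$resno)
    if (length(resno) != 1) {
      stop("states covers several residues; pass resno", call. = FALSE)
    }
  }
  st <- states[states$resno == resno, ]
  key <- c("ensemble", "replica", "frame")
  merged <- dplyr::inner_join(dplyr::as_tibble(scores),
                              st[, c(key, "state")], by = key)
  if (nrow(merged) != nrow(scores) || nrow(merged) != nrow(st)) {
    stop("misaligned frames between scores (", nrow(scores),
         ") and rotamer series (", nrow(st), ")", call. = FALSE)
  }
  edges <- list(x = hist_edges(merged[[pcs[1]]], bins),
                y = hist_edges(merged[[pcs[2]]], bins))
  th <- oblique_angle * pi / 180
  ob_edges <- hist_edges(cos(th) * merged[[pcs[1]]] +
                         sin(th) * merged[[pcs[2]]], bins)
  uncond <- histogram2d(merged, pcs = pcs, edges = edges)
  uncond_ob <- oblique_histogram(merged, oblique_angle, edges = ob_edges, pcs = pcs)
  obs_states <- sort(unique(merged$state))
  hists <- list(); obliques <- list(); frac <- numeric(length(obs_states))
  for (i in seq_along(obs_states)) {
    part <- merged[merged$state == obs_states[i], ]
    frac[i] <- nrow(part) / nrow(merged)
    hists[[as.character(obs_states[i])]] <-
      histogram2d(part, pcs = pcs, edges = edges)
    obliques[[as.character(obs_states[i])]] <-
      oblique_histogram(part, oblique_angle, edges = ob_edges, pcs = pcs)
  }
  structure(list(
    resno = resno,
    fractions = tibble::tibble(state = obs_states, fraction = frac,
                               minor = frac < minor_threshold),
    histograms = hists,
    oblique = obliques,
    unconditioned = list(hist2d = uncond, oblique = uncond_ob),
    pcs = pcs
  ), class = "msw_conditional")
}

#' @export
print.msw_conditional <- function(x, ...) {
  cat("<msw_conditional> residue ", x$resno, ", ",
      nrow(x$fractions), " rotamer states (fractions ",
      paste(sprintf("%.1f%%", 100 * x$fractions$fraction), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Overlap coefficient of two histograms on shared edges
#'
#' Bin-wise minimum of the two probability-normalised grids, summed:
#' 1 for identical distributions, 0 for disjoint supports.
#'
#' @param a,b `msw_hist2d` (or `msw_hist1d`) objects on identical edges.
#' @return scalar in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  check_shared_edges(a, b)
  pa <- a$counts / sum(a$counts)
  pb <- b$counts / sum(b$counts)
  sum(pmin(pa, pb))
}

check_shared_edges <- function(a, b) {
  ea <- if (inherits(a, "msw_hist1d")) list(a$edges) else list(a$xedges, a$yedges)
  eb <- if (inherits(b, "msw_hist1d")) list(b$edges) else list(b$xedges, b$yedges)
  if (length(ea) != length(eb) ||
      !all(mapply(function(x, y) isTRUE(all.equal(x, y)), ea, eb))) {
    stop("histograms do not share bin edges", call. = FALSE)
  }
  invisible(TRUE)
}

#' Overlay histograms for plotting and compute pairwise overlaps
#'
#' @param layers named list of `msw_hist2d` objects on shared edges (names
#'   identify the layers, e.g. `"apo:state2"`).
#' @return list with `table` (long tibble: `layer`, `x`, `y`, `density`)
#'   and `overlaps` (tibble: `layer_a`, `layer_b`, `overlap`).
#' @export
overlay_histograms <- function(layers) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  for (l in layers[-1]) check_shared_edges(layers[[1]], l)
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  tab <- dplyr::bind_rows(lapply(names(layers), function(nm) {
    h <- layers[[nm]]
    g <- expand.grid(x = mids(h$xedges), y = mids(h$yedges))
    g$density <- as.vector(h$counts / sum(h$counts))
    g$layer <- nm
    tibble::as_tibble(g)
  }))
  pairs <- utils::combn(names(layers), 2, simplify = FALSE)
  if (length(layers) == 1) pairs <- list(c(names(layers), names(layers)))
  overlaps <- dplyr::bind_rows(lapply(pairs, function(p) {
    tibble::tibble(layer_a = p[1], layer_b = p[2],
                   overlap = overlap_coefficient(layers[[p[1]]], layers[[p[2]]]))
  }))
  list(table = tab[, c("layer", "x", "y", "density")], overlaps = overlaps)
}

#' Residues with side-chain contacts within a cutoff
#'
#' Lists every other residue having any heavy atom within `cutoff` of the
#' query residue's side-chain heavy atoms in one frame, sorted by minimum
#' distance. Hydrogens are not modelled; all atoms are heavy.
#'
#' @param ensemble a `msw_ensemble`.
#' @param replica replica index.
#' @param frame frame index within the replica.
#' @param resno query residue number.
#' @param cutoff distance cutoff in Angstrom (default 4).
#' @return tibble: `resno`, `resid`, `min_distance`.
#' @export
contact_shell <- function(ensemble, replica, frame, resno, cutoff = 4) {
  stopifnot(inherits(ensemble, "msw_ensemble"), cutoff > 0)
  top <- ensemble$topology
  if (!resno %in% top$resno) stop("unknown residue ", resno, call. = FALSE)
  rep <- NULL
  for (r in ensemble$replicas) if (r$replica == replica) { rep <- r; break }
  if (is.null(rep)) stop("unknown replica ", replica, call. = FALSE)
  stopifnot(frame >= 1, frame <= nrow(rep$xyz))
  coords <- matrix(rep$xyz[frame, ], ncol = 3, byrow = TRUE)
  sc <- which(top$resno == resno & !top$elety %in% c("N", "CA", "C"))
  if (!length(sc)) sc <- which(top$resno == resno)  # fall back to all atoms
  others <- which(top$resno != resno)
  d <- sqrt(outer(rowSums(coords[sc, , drop = FALSE]^2),
                  rowSums(coords[others, , drop = FALSE]^2), "+") -
            2 * coords[sc, , drop = FALSE] %*% t(coords[others, , drop = FALSE]))
  min_d <- tapply(apply(d, 2, min), top$resno[others], min)
  out <- tibble::tibble(
    resno = as.integer(names(min_d)),
    min_distance = as.numeric(min_d)
  )
  out$resid <- top$resid[match(out$resno, top$resno)]
  out <- out[out$min_distance <= cutoff, c("resno", "resid", "min_distance")]
  dplyr::arrange(out, .data$min_distance)
}
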