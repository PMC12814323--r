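## chi1/chi2 computation over trajectories, rotamer-state assignment,
## population summaries, and dwell-segment analysis of the resulting
## categorical time series.

#' Compute chi1 (and chi2 where defined) for selected residues
#'
#' Dihedrals use the standard IUPAC atom quadruples (chi1: N-CA-CB-G where
#' G is CG/CG1/OG/...; chi2: CA-CB-CG-D) and sign convention, wrapped into
#' `(-180, 180]`.
#'
#' @param ensemble a `msw_ensemble`.
#' @param residues residue numbers (default: every chi-bearing residue).
#' @return tibble: `ensemble`, `replica`, `frame`, `resno`, `resid`,
#'   `chi1`, `chi2` (`NA` where the residue has no chi2).
#' @export
compute_chi <- function(ensemble, residues = NULL) {
  stopifnot(inherits(ensemble, "msw_ensemble"))
  top <- ensemble$topology
  res_tab <- unique(top[, c("resno", "resid")])
  if (is.null(residues)) {
    residues <- res_tab$resno[res_tab$resid %in% names(.chi_defs)]
  }
  out <- list()
  for (r in residues) {
    rt <- res_tab$resid[match(r, res_tab$resno)]
    if (is.na(rt)) stop("unknown residue ", r, call. = FALSE)
    def <- .chi_defs[[rt]]
    if (is.null(def)) {
      stop("no-chi error: residue ", r, " (", rt,
           ") has no chi angles", call. = FALSE)
    }
    idx <- function(names_) {
      vapply(names_, function(a) {
        i <- which(top$resno == r & top$elety == a)
        if (length(i) != 1L) {
          stop("missing-atom error: residue ", r, " (", rt, ") lacks atom ",
               a, " needed for chi", call. = FALSE)
        }
        i
      }, integer(1))
    }
    q1 <- idx(def$chi1)
    q2 <- if (!is.null(def$chi2)) idx(def$chi2) else NULL
    for (rep in ensemble$replicas) {
      at <- function(i) rep$xyz[, (i - 1L) * 3L + 1:3, drop = FALSE]
      chi1 <- dihedral_angle(at(q1[1]), at(q1[2]), at(q1[3]), at(q1[4]))
      chi2 <- if (is.null(q2)) NA_real_ else
        dihedral_angle(at(q2[1]), at(q2[2]), at(q2[3]), at(q2[4]))
      out[[length(out) + 1L]] <- tibble::tibble(
        ensemble = rep$ensemble, replica = rep$replica,
        frame = seq_len(nrow(rep$xyz)), resno = as.integer(r), resid = rt,
        chi1 = chi1, chi2 = chi2)
    }
  }
  dplyr::bind_rows(out)
}

#' Discretise chi series into rotamer states
#'
#' Per-frame state index is the mixed-radix combination of the per-angle
#' bin indices (chi1 slowest-varying), 1-based in `[1, n_states]`. Angles
#' outside `(-180, 180]` are wrapped, so adding any multiple of 360 degrees
#' leaves the assignment unchanged.
#'
#' @param chi tibble from [compute_chi()] (or [dihedral_only_fixture()]).
#' @param scheme a `rotamer_scheme` (default [build_default_scheme()]).
#' @return a `msw_states` tibble: the input columns plus `state` and
#'   `state_label`, with the scheme attached as an attribute.
#' @export
assign_states <- function(chi, scheme = build_default_scheme()) {
  needed <- c("resno", "resid", "chi1")
  stopifnot(all(needed %in% names(chi)))
  out <- list()
  for (rt in unique(chi$resid)) {
    r <- scheme$residues[[rt]]
    if (is.null(r)) {
      stop("no-chi error: residue type ", rt,
           " is excluded from the rotamer scheme", call. = FALSE)
    }
    rows <- chi[chi$resid == rt, ]
    b1 <- bin_angle(rows$chi1, r$angles$chi1)
    if (!is.null(r$angles$chi2)) {
      if (anyNA(rows$chi2)) {
        stop("missing chi2 for residue type ", rt, call. = FALSE)
      }
      n2 <- length(r$angles$chi2$labels)
      b2 <- bin_angle(rows$chi2, r$angles$chi2)
      state <- (b1 - 1L) * n2 + b2
    } else {
      state <- b1
    }
    rows$state <- as.integer(state)
    rows$state_label <- scheme_state_labels(scheme, rt)[state]
    out[[length(out) + 1L]] <- rows
  }
  res <- dplyr::arrange(dplyr::bind_rows(out),
                        .data$resno, .data$replica, .data$frame)
  class(res) <- c("msw_states", class(res))
  attr(res, "scheme") <- scheme
  res
}

#' Per-state populations of a rotamer state series
#' @param states a `msw_states` tibble.
#' @return tibble: `resno`, `resid`, `state`, `population` (per-residue
#'   fractions summing to 1).
#' @export
state_populations <- function(states) {
  dplyr::count(states, .data$resno, .data$resid, .data$state) |>
    dplyr::group_by(.data$resno, .data$resid) |>
    dplyr::mutate(population = .data$n / sum(.data$n), n = NULL) |>
    dplyr::ungroup()
}

circular_mean <- function(deg) {
  r <- deg * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Summary table of rotamer states: population and mean angles
#'
#' Circular means are used for the per-state average chi1/chi2. States are
#' additionally numbered by descending population (`rank`, "state 1" = most
#' populated) as microswitch states are conventionally reported; states
#' below `minor_threshold` are flagged minor.
#'
#' @param states a `msw_states` tibble (from [assign_states()], which keeps
#'   the chi columns).
#' @param minor_threshold populations below this fraction are flagged
#'   (default 0.05, under which spectroscopic signal is not expected).
#' @return tibble: `resno`, `resid`, `state`, `state_label`, `rank`,
#'   `population`, `mean_chi1`, `mean_chi2`, `minor`.
#' @export
state_summary <- function(states, minor_threshold = 0.05) {
  stopifnot(nrow(states) > 0)
  states |>
    dplyr::group_by(.data$resno, .data$resid, .data$state, .data$state_label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_chi1 = circular_mean(.data$chi1),
      mean_chi2 = if (all(is.na(.data$chi2))) NA_real_ else
        circular_mean(.data$chi2),
      .groups = "drop") |>
    dplyr::group_by(.data$resno, .data$resid) |>
    dplyr::mutate(population = .data$n / sum(.data$n),
                  rank = rank(-.data$population, ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::mutate(minor = .data$population < minor_threshold, n = NULL) |>
    dplyr::arrange(.data$resno, .data$rank)
}

#' Maximal single-state dwell segments of a categorical series
#'
#' Finds non-overlapping, left-to-right maximal windows of length at least
#' `min_length` in which one state's occupancy is at least `dominance`
#' (greater than 0.5, so the dominant state is unique). Each reported
#' segment is trimmed so it starts and ends on a frame of its dominant
#' state; scanning resumes after the untrimmed window. This mirrors the
#' selection of long trajectory chunks during which a side chain stays in
#' one rotameric state apart from infrequent short excursions.
#'
#' @param series integer state vector, or a `msw_states` tibble (segmented
#'   per residue and replica).
#' @param min_length minimum window length in frames.
#' @param dominance required occupancy of the dominant state (default 0.9).
#' @return tibble: `start`, `end`, `state`, `occupancy` (plus `ensemble`,
#'   `replica`, `resno` when the input is a tibble), sorted by start.
#' @export
dwell_segments <- function(series, min_length, dominance = 0.9) {
  stopifnot(dominance > 0.5, dominance <= 1, min_length >= 1)
  if (is.data.frame(series)) {
    return(series |>
      dplyr::group_by(.data$ensemble, .data$replica, .data$resno) |>
      dplyr::group_modify(~ dwell_segments(
        .x$state[order(.x$frame)], min_length, dominance)) |>
      dplyr::ungroup())
  }
  s <- as.integer(series)
  n <- length(s)
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          state = integer(0), occupancy = numeric(0))
  if (min_length > n) return(empty)
  k <- max(s)
  # cumulative counts: C[t + 1, j] = #{u <= t : s[u] = j}
  C <- apply(stats::model.matrix(~ factor(s, levels = seq_len(k)) - 1), 2, cumsum)
  C <- rbind(0, C)
  segs <- list()
  i <- 1L
  while (i + min_length - 1L <= n) {
    ends <- seq.int(i + min_length - 1L, n)
    len <- ends - i + 1L
    occ <- (C[ends + 1L, , drop = FALSE] -
            matrix(C[i, ], length(ends), k, byrow = TRUE)) / len
    best <- occ[, 1]
    for (j in seq_len(k)[-1]) best <- pmax(best, occ[, j])
    ok <- which(best >= dominance)
    if (length(ok)) {
      e <- ends[max(ok)]
      st <- which.max(occ[max(ok), ])
      in_win <- i - 1L + which(s[i:e] == st)
      segs[[length(segs) + 1L]] <- tibble::tibble(
        start = min(in_win), end = max(in_win), state = as.integer(st),
        occupancy = max(occ[max(ok), ]))
      i <- e + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(segs)) return(empty)
  dplyr::bind_rows(segs)
}
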