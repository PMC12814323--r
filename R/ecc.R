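## Entropy-based cross-correlation (ECC) between the categorical backbone
## microstate series and side-chain rotamer state series.
##
## For a categorical series with empirical state frequencies p_i, the
## entropy is S = -sum_i p_i ln p_i (the Boltzmann prefactor cancels in the
## ratio below and is dropped). With S_BB the backbone-cluster entropy,
## S_SC the rotamer entropy and S_total the entropy of the paired series,
##
##   ECC = 2 (S_BB + S_SC - S_total) / (S_BB + S_SC)
##
## is 0 when the series are independent (S_total = S_BB + S_SC) and 1 when
## they are copies up to relabelling (S_BB = S_SC = S_total).

#' Entropy of a categorical series
#'
#' `S = -sum p_i ln p_i` over the empirical frequencies of the observed
#' states (natural log, dimensionless; unobserved states contribute 0).
#'
#' @param x atomic vector of per-frame states.
#' @return entropy in nats.
#' @examples
#' state_entropy(rep(1:4, 25))        # ln 4
#' state_entropy(c(1, 1, 2, 3))       # 1.5 ln 2
#' @export
state_entropy <- function(x) {
  if (length(x) == 0) stop("empty series", call. = FALSE)
  p <- tabulate(as.integer(factor(x)))
  p <- p[p > 0] / length(x)
  -sum(p * log(p))
}

#' Joint entropy of two aligned categorical series
#'
#' Entropy of the paired-state series `(a_t, b_t)`.
#'
#' @param a,b equal-length atomic vectors.
#' @return joint entropy in nats.
#' @export
joint_entropy <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  state_entropy(paste(a, b, sep = "\r"))
}

#' Entropy-based cross-correlation of two categorical series
#'
#' @param series_bb backbone state series (e.g. cluster indices).
#' @param series_sc side-chain rotamer state series, same length.
#' @return one-row tibble: `s_bb`, `s_sc`, `s_total`, `ecc` (in `[0, 1]`),
#'   `n_frames`, `degenerate`. When both series are constant the
#'   correlation is undefined; 0 is returned with `degenerate = TRUE`.
#' @examples
#' ecc(rep(1:3, 100), rep(1:3, 100))$ecc           # identical series: 1
#' ecc(rep(1:2, each = 50), rep(1:2, times = 50))$ecc  # independent: 0
#' @export
ecc <- function(series_bb, series_sc) {
  if (length(series_bb) != length(series_sc)) {
    stop("length mismatch", call. = FALSE)
  }
  s_bb <- state_entropy(series_bb)
  s_sc <- state_entropy(series_sc)
  degenerate <- (s_bb + s_sc) == 0
  if (degenerate) {
    s_total <- 0
    val <- 0
  } else {
    s_total <- joint_entropy(series_bb, series_sc)
    val <- 2 * (s_bb + s_sc - s_total) / (s_bb + s_sc)
    val <- min(max(val, 0), 1)  # guard tiny negative rounding
  }
  tibble::tibble(s_bb = s_bb, s_sc = s_sc, s_total = s_total, ecc = val,
                 n_frames = length(series_bb), degenerate = degenerate)
}

#' Scan all eligible residues for backbone-rotamer coupling
#'
#' Computes the ECC between the backbone microstate series and each
#' residue's rotamer state series, frame-aligned on (ensemble, replica,
#' frame). Ala, Gly and Pro carry no discrete rotamer states and are
#' excluded by default.
#'
#' @param assignment a `msw_clusters` tibble (one ensemble).
#' @param states a `msw_states` tibble covering the same frames.
#' @param exclude residue types to drop (default `ALA`, `GLY`, `PRO`).
#' @param null_permutations if > 0, additionally reports the mean ECC of
#'   this many random permutations of the rotamer series (a shuffle null
#'   for interpreting finite-sample bias); off by default.
#' @param seed seed for the shuffle null.
#' @return tibble sorted by residue number: `resno`, `resid`, `s_bb`,
#'   `s_sc`, `s_total`, `ecc`, `n_frames`, `degenerate` (and `null_ecc`
#'   when requested).
#' @export
ecc_scan <- function(assignment, states, exclude = c("ALA", "GLY", "PRO"),
                     null_permutations = 0, seed = 1L) {
  stopifnot(inherits(assignment, "msw_clusters") || is.data.frame(assignment))
  key <- c("ensemble", "replica", "frame")
  bb <- dplyr::as_tibble(assignment)[, c(key, "cluster")]
  rows <- list()
  for (r in sort(unique(states$resno))) {
    st <- states[states$resno == r, ]
    if (st$resid[1] %in% exclude) next
    merged <- dplyr::inner_join(bb, st[, c(key, "state")], by = key)
    if (nrow(merged) != nrow(bb) || nrow(merged) != nrow(st)) {
      stop("misaligned frames: residue ", r, " rotamer series covers ",
           nrow(st), " frames, clusters ", nrow(bb), " (matched ",
           nrow(merged), ")", call. = FALSE)
    }
    res <- ecc(merged$cluster, merged$state)
    res$resno <- as.integer(r)
    res$resid <- st$resid[1]
    if (null_permutations > 0) {
      res$null_ecc <- withr::with_seed(seed + r, mean(vapply(
        seq_len(null_permutations),
        function(i) ecc(merged$cluster, sample(merged$state))$ecc,
        numeric(1))))
    }
    rows[[length(rows) + 1L]] <- res
  }
  out <- dplyr::bind_rows(rows)
  front <- c("resno", "resid")
  out[, c(front, setdiff(names(out), front))]
}

#' Stamp per-residue ECC values into the B-factor column of a PDB
#'
#' Every atom of a residue carries `100 * ecc` (the PDB B-factor field has
#' two decimals); residues without a value carry 0. Useful for colouring
#' or sphere-size rendering of coupling on the structure.
#'
#' @param results tibble from [ecc_scan()] (columns `resno`, `ecc`).
#' @param topology a `msw_topology`.
#' @param file output PDB path.
#' @return `file`, invisibly.
#' @export
ecc_to_bfactor <- function(results, topology, file) {
  b <- rep(0, nrow(topology))
  m <- match(topology$resno, results$resno)
  hit <- !is.na(m)
  b[hit] <- round(100 * results$ecc[m[hit]], 2)
  write_topology_pdb(topology, file, b = b)
  invisible(file)
}
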