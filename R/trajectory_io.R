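## Reading topology/trajectory files, backbone extraction, superposition and
## per-residue RMSF. Format parsing is delegated to bio3d (PDB, multi-model
## PDB, DCD); this module fixes the ordering and labelling conventions the
## analysis stages rely on.

new_msw_ensemble <- function(topology, replicas) {
  n_atoms <- nrow(topology)
  for (rep in replicas) {
    if (ncol(rep$xyz) != 3L * n_atoms) {
      stop("format error: replica '", rep$ensemble, "' atom count (",
           ncol(rep$xyz) / 3, ") does not match topology (", n_atoms, ")",
           call. = FALSE)
    }
    if (nrow(rep$xyz) < 1L) {
      stop("format error: replica '", rep$ensemble, "' has no frames", call. = FALSE)
    }
  }
  structure(list(topology = topology, replicas = replicas),
            class = "msw_ensemble")
}

#' @export
print.msw_ensemble <- function(x, ...) {
  labs <- vapply(x$replicas, function(r) r$ensemble, character(1))
  nf <- vapply(x$replicas, function(r) nrow(r$xyz), integer(1))
  cat("<msw_ensemble> ", nrow(x$topology), " atoms, ",
      length(unique(x$topology$resno)), " residues, ",
      length(x$replicas), " replicas (", sum(nf), " frames)\n", sep = "")
  for (l in unique(labs)) {
    cat("  ", l, ": ", sum(labs == l), " x ",
        paste(unique(nf[labs == l]), collapse = "/"), " frames\n", sep = "")
  }
  invisible(x)
}

#' Per-replica metadata of an ensemble
#' @param x a `msw_ensemble`.
#' @param ... unused.
#' @return tibble with `ensemble`, `replica`, `n_frames`, `frame_dt`.
#' @export
tidy.msw_ensemble <- function(x, ...) {
  tibble::tibble(
    ensemble = vapply(x$replicas, function(r) r$ensemble, character(1)),
    replica = vapply(x$replicas, function(r) r$replica, integer(1)),
    n_frames = vapply(x$replicas, function(r) nrow(r$xyz), integer(1)),
    frame_dt = vapply(x$replicas, function(r) r$frame_dt, numeric(1))
  )
}

#' Load a labelled trajectory ensemble from standard files
#'
#' @param topology_path single-model PDB file defining atoms and residues.
#' @param trajectories data frame with columns `path` and `label` (one row
#'   per replica trajectory), or a named character vector of paths with
#'   labels as names. Formats: DCD or (multi-model) PDB, by file extension.
#' @param frame_dt time per frame attached to every replica.
#' @return a `msw_ensemble`.
#' @export
load_ensemble <- function(topology_path, trajectories, frame_dt = 1) {
  if (!file.exists(topology_path)) {
    stop("I/O error: topology file not found: ", topology_path, call. = FALSE)
  }
  if (is.character(trajectories)) {
    trajectories <- tibble::tibble(path = unname(trajectories),
                                   label = names(trajectories))
  }
  stopifnot(all(c("path", "label") %in% names(trajectories)))
  pdb <- bio3d::read.pdb(topology_path)
  top <- tibble::tibble(
    eleno = pdb$atom$eleno, elety = pdb$atom$elety,
    resno = pdb$atom$resno, resid = pdb$atom$resid,
    x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z
  )
  class(top) <- c("msw_topology", class(top))
  n_atoms <- nrow(top)
  replicas <- list()
  counts <- table(character(0))
  for (i in seq_len(nrow(trajectories))) {
    p <- trajectories$path[i]
    lab <- trajectories$label[i]
    if (!file.exists(p)) stop("I/O error: trajectory file not found: ", p, call. = FALSE)
    ext <- tolower(tools::file_ext(p))
    xyz <- switch(ext,
      dcd = as.matrix(bio3d::read.dcd(p, verbose = FALSE)),
      pdb = {
        m <- bio3d::read.pdb(p, multi = TRUE)
        mat <- m$xyz
        if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1)
        mat
      },
      stop("format error: unsupported trajectory format '.", ext, "'", call. = FALSE)
    )
    if (is.null(xyz) || nrow(xyz) == 0 || all(is.na(xyz))) {
      stop("format error: trajectory ", p, " contains no frames", call. = FALSE)
    }
    if (ncol(xyz) != 3L * n_atoms) {
      stop("format error: trajectory ", p, " has ", ncol(xyz) / 3,
           " atoms but topology has ", n_atoms, call. = FALSE)
    }
    rep_id <- sum(vapply(replicas, function(r) r$ensemble == lab, logical(1))) + 1L
    replicas[[length(replicas) + 1L]] <- list(
      ensemble = lab, replica = rep_id, xyz = xyz, frame_dt = frame_dt)
  }
  new_msw_ensemble(top, replicas)
}

#' Extract the backbone (N, CA, C) coordinate matrix of an ensemble
#'
#' Rows are ordered by (replica in load order, frame); columns by (residue
#' in ascending number, then N, CA, C; x/y/z per atom). Two loads of the
#' same files therefore give identical matrices.
#'
#' @param ensemble a `msw_ensemble`.
#' @param residues residue numbers to include (default all).
#' @return a `msw_backbone`: list with `xyz` matrix, `atom_index` tibble
#'   (`resno`, `elety`), `labels` tibble (`ensemble`, `replica`, `frame`)
#'   and a `superposed` flag.
#' @export
extract_backbone <- function(ensemble, residues = NULL) {
  stopifnot(inherits(ensemble, "msw_ensemble"))
  top <- ensemble$topology
  if (is.null(residues)) residues <- sort(unique(top$resno))
  atom_rows <- integer(0)
  for (r in residues) {
    for (a in c("N", "CA", "C")) {
      i <- which(top$resno == r & top$elety == a)
      if (length(i) != 1L) {
        stop("missing-atom error: residue ", r, " (",
             top$resid[top$resno == r][1], ") lacks backbone atom ", a,
             call. = FALSE)
      }
      atom_rows <- c(atom_rows, i)
    }
  }
  cols <- as.vector(rbind((atom_rows - 1L) * 3L + 1L,
                          (atom_rows - 1L) * 3L + 2L,
                          (atom_rows - 1L) * 3L + 3L))
  mats <- lapply(ensemble$replicas, function(rep) rep$xyz[, cols, drop = FALSE])
  labels <- dplyr::bind_rows(lapply(ensemble$replicas, function(rep) {
    tibble::tibble(ensemble = rep$ensemble, replica = rep$replica,
                   frame = seq_len(nrow(rep$xyz)))
  }))
  structure(list(
    xyz = do.call(rbind, mats),
    atom_index = tibble::tibble(resno = top$resno[atom_rows],
                                elety = top$elety[atom_rows]),
    labels = labels,
    superposed = FALSE
  ), class = "msw_backbone")
}

#' @export
print.msw_backbone <- function(x, ...) {
  cat("<msw_backbone> ", nrow(x$xyz), " frames x ", ncol(x$xyz),
      " coordinates (", nrow(x$atom_index), " atoms), superposed: ",
      x$superposed, "\n", sep = "")
  invisible(x)
}

#' Rigid-body least-squares superposition of every frame
#'
#' Each frame is fitted (rotation + translation, Kabsch) onto the
#' reference over all backbone atoms. The default reference is the
#' coordinate-wise mean of the whole matrix computed after one pass of
#' fitting to the first frame, so all ensembles share one frame of
#' reference -- a prerequisite for a single shared PCA.
#'
#' @param backbone a `msw_backbone`.
#' @param reference `"mean"` (default) or `"first"`, or a numeric
#'   coordinate vector of matching length.
#' @return the superposed `msw_backbone` (`superposed = TRUE`).
#' @export
superpose <- function(backbone, reference = c("mean", "first")) {
  stopifnot(inherits(backbone, "msw_backbone"))
  xyz <- backbone$xyz
  if (is.numeric(reference)) {
    ref <- reference
    stopifnot(length(ref) == ncol(xyz))
    check_reference(ref)
    fitted <- fit_frames(ref, xyz)
  } else {
    reference <- match.arg(reference)
    check_reference(xyz[1, ])
    if (reference == "first") {
      fitted <- fit_frames(xyz[1, ], xyz)
    } else {
      pass1 <- fit_frames(xyz[1, ], xyz)
      ref <- colMeans(pass1)
      check_reference(ref)
      fitted <- fit_frames(ref, pass1)
    }
  }
  backbone$xyz <- fitted
  backbone$superposed <- TRUE
  backbone
}

# Kabsch superposition of every row of `xyz` onto `ref`, batched: the 3x3
# cross-covariances of all frames come from three matrix products, leaving
# only a tight per-frame loop over 3x3 SVDs.
fit_frames <- function(ref, xyz) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n <- nrow(xyz)
  refm <- matrix(ref, ncol = 3, byrow = TRUE)
  ref_c <- colMeans(refm)
  Y <- sweep(refm, 2, ref_c)                     # m x 3, centred reference
  xi <- seq(1L, ncol(xyz), 3L)
  X1 <- xyz[, xi, drop = FALSE]                  # n x m per axis
  X2 <- xyz[, xi + 1L, drop = FALSE]
  X3 <- xyz[, xi + 2L, drop = FALSE]
  X1 <- X1 - rowMeans(X1); X2 <- X2 - rowMeans(X2); X3 <- X3 - rowMeans(X3)
  H1 <- X1 %*% Y; H2 <- X2 %*% Y; H3 <- X3 %*% Y # cross-covariance rows
  out <- matrix(0, n, ncol(xyz))
  for (f in seq_len(n)) {
    H <- rbind(H1[f, ], H2[f, ], H3[f, ])
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)     # optimal rotation x -> y
    r <- R %*% rbind(X1[f, ], X2[f, ], X3[f, ]) + ref_c
    out[f, xi] <- r[1, ]; out[f, xi + 1L] <- r[2, ]; out[f, xi + 2L] <- r[3, ]
  }
  out
}

check_reference <- function(ref) {
  m <- matrix(ref, ncol = 3, byrow = TRUE)
  s <- svd(scale(m, scale = FALSE))$d
  if (length(s) < 2 || s[2] < 1e-8 * max(s[1], 1)) {
    stop("numerical-degeneracy error: reference coordinates are collinear",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-frame RMSD of a backbone matrix to a reference
#' @param backbone a `msw_backbone`.
#' @param ref coordinate vector (default the column mean).
#' @return numeric vector, one RMSD per frame (Angstrom).
#' @export
rmsd_to_reference <- function(backbone, ref = colMeans(backbone$xyz)) {
  d2 <- sweep(backbone$xyz, 2, ref)^2
  sqrt(rowSums(d2) / (ncol(backbone$xyz) / 3))
}

#' Per-residue backbone RMSF
#'
#' Root-mean-square fluctuation of each residue about its mean position
#' over a subset of frames: per-atom mean-square deviations are averaged
#' over the residue's N, CA and C atoms before the square root. A
#' log10-scaled column is included for structure colouring.
#'
#' @param backbone a superposed `msw_backbone`.
#' @param rows integer frame-row subset (default all rows).
#' @return tibble with `resno`, `rmsf`, `log_rmsf`.
#' @export
rmsf_per_residue <- function(backbone, rows = NULL) {
  stopifnot(inherits(backbone, "msw_backbone"))
  if (is.null(rows)) rows <- seq_len(nrow(backbone$xyz))
  if (length(rows) == 0) stop("empty frame subset", call. = FALSE)
  xyz <- backbone$xyz[rows, , drop = FALSE]
  dev2 <- sweep(xyz, 2, colMeans(xyz))^2
  # per-atom mean square fluctuation: sum x/y/z columns, mean over frames
  msf_atom <- colMeans(dev2[, seq(1, ncol(xyz), 3), drop = FALSE] +
                       dev2[, seq(2, ncol(xyz), 3), drop = FALSE] +
                       dev2[, seq(3, ncol(xyz), 3), drop = FALSE])
  res <- backbone$atom_index$resno
  msf_res <- tapply(msf_atom, res, mean)
  tibble::tibble(
    resno = as.integer(names(msf_res)),
    rmsf = sqrt(as.numeric(msf_res)),
    log_rmsf = log10(pmax(sqrt(as.numeric(msf_res)), .Machine$double.eps))
  ) |> dplyr::arrange(.data$resno)
}
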