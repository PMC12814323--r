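## Ground-truth-labelled synthetic trajectory generator. A hidden Markov
## chain over backbone microstates drives (i) rigid displacements of a
## contiguous "TM6-like" backbone segment and (ii) categorical rotamer
## emissions for designated coupled side chains, so every downstream stage
## (PCA, clustering, rotamer assignment, ECC) can be validated against a
## known truth.

#' Specification for a synthetic trajectory ensemble
#'
#' Materialises every default at construction time so the returned object is
#' fully concrete: same spec (including `seed`) always regenerates the same
#' ensemble, byte for byte.
#'
#' The geometry is a toy idealised helix; each labelled ensemble displaces a
#' contiguous C-terminal backbone segment by its `ensemble_offset`
#' (emulating distinct binding states occupying distinct regions of
#' conformational space), and each hidden microstate adds a further
#' `microstate_offset` to the same segment (emulating sub-clusters within a
#' binding state, e.g. inward tilting of a helix). Side-chain chi angles are
#' emitted from a per-(microstate, residue) categorical distribution whose
#' dependence on the microstate is controlled per residue by a coupling
#' strength kappa in \[0, 1\]: kappa = 0 gives a microstate-independent
#' emission (negative control), kappa = 1 a deterministic function of the
#' microstate.
#'
#' @param n_ensembles number of labelled ensembles (binding states).
#' @param replicas_per_ensemble trajectory replicas per ensemble.
#' @param n_frames frames per replica.
#' @param frame_dt time per frame (abstract units).
#' @param n_residues number of toy residues (>= 4).
#' @param residue_types character vector of three-letter residue types, one
#'   per residue; default mixes Val (uncoupled controls), one Leu (the
#'   default coupling target), one Trp, and excluded Ala/Gly/Pro.
#' @param n_microstates microstates per ensemble: scalar, per-ensemble
#'   vector, or `NULL` to draw each from \{4, 5, 6\}.
#' @param ensemble_offsets `n_ensembles` x 3 matrix of rigid displacements
#'   (Angstrom) applied to the moving segment, or `NULL` for defaults.
#' @param microstate_offsets list (one per ensemble) of `n_microstates` x 3
#'   displacement matrices, or `NULL` for a regular polygon of radius
#'   `microstate_spread` in the x-y plane.
#' @param transition_matrix row-stochastic microstate transition matrix
#'   (shared, or a list per ensemble), or `NULL` for a sticky chain with
#'   stay probability `stay_prob` and uniform exits.
#' @param noise_sigma isotropic Gaussian positional noise (Angstrom) added
#'   to every backbone atom each frame.
#' @param coupled_residues data frame with columns `resno` and `kappa`;
#'   residues not listed are uncoupled (kappa = 0).
#' @param rotamer_emission optional named list (by residue number) of
#'   explicit emission matrices (`n_microstates` x `n_states`), overriding
#'   the kappa construction.
#' @param segment integer residue numbers forming the moving segment;
#'   default the C-terminal third.
#' @param microstate_spread radius (Angstrom) of the default microstate
#'   offset polygon.
#' @param ensemble_spread spacing (Angstrom) between default ensemble
#'   offsets.
#' @param chi_jitter_sd wrapped-Gaussian jitter (degrees) about the emitted
#'   rotamer bin centre.
#' @param stay_prob diagonal of the default transition matrix.
#' @param ensemble_labels labels, default `ens1`, `ens2`, ...
#' @param seed integer seed governing every random draw.
#' @return A `synthetic_spec` object (list).
#' @seealso [simulate_ensemble()], [dihedral_only_fixture()],
#'   [generate_topology()]
#' @export
synthetic_spec <- function(n_ensembles = 4,
                           replicas_per_ensemble = 3,
                           n_frames = 20000,
                           frame_dt = 1,
                           n_residues = 10,
                           residue_types = NULL,
                           n_microstates = NULL,
                           ensemble_offsets = NULL,
                           microstate_offsets = NULL,
                           transition_matrix = NULL,
                           noise_sigma = 0.3,
                           coupled_residues = NULL,
                           rotamer_emission = NULL,
                           segment = NULL,
                           microstate_spread = 2,
                           ensemble_spread = 5,
                           chi_jitter_sd = 15,
                           stay_prob = 0.99,
                           ensemble_labels = NULL,
                           seed = 1L) {
  if (n_residues < 4) stop("invalid spec: n_residues must be >= 4", call. = FALSE)
  stopifnot(n_ensembles >= 1, replicas_per_ensemble >= 1, n_frames >= 1,
            noise_sigma >= 0, chi_jitter_sd >= 0)

  if (is.null(residue_types)) residue_types <- default_residue_types(n_residues)
  if (length(residue_types) != n_residues) {
    stop("invalid spec: residue_types must have length n_residues", call. = FALSE)
  }
  residue_types <- toupper(residue_types)

  if (is.null(ensemble_labels)) ensemble_labels <- paste0("ens", seq_len(n_ensembles))

  if (is.null(n_microstates)) {
    n_microstates <- withr::with_seed(seed + 101L,
                                      sample(4:6, n_ensembles, replace = TRUE))
  }
  n_microstates <- as.integer(rep_len(n_microstates, n_ensembles))
  if (any(n_microstates < 1 | n_microstates > 12)) {
    stop("invalid spec: n_microstates must lie in [1, 12]", call. = FALSE)
  }

  if (is.null(ensemble_offsets)) {
    # ensembles spread along z so each binding state owns a PC-space region
    ensemble_offsets <- cbind(0, 0, ensemble_spread * (seq_len(n_ensembles) - 1))
  }
  ensemble_offsets <- as.matrix(ensemble_offsets)
  stopifnot(nrow(ensemble_offsets) == n_ensembles, ncol(ensemble_offsets) == 3)

  if (is.null(microstate_offsets)) {
    microstate_offsets <- lapply(n_microstates, function(k) {
      ang <- 2 * pi * (seq_len(k) - 1) / k
      microstate_spread * cbind(cos(ang), sin(ang), 0)
    })
  }
  stopifnot(length(microstate_offsets) == n_ensembles)

  if (is.null(transition_matrix)) {
    transition_matrix <- lapply(n_microstates, sticky_chain, stay_prob = stay_prob)
  } else if (is.matrix(transition_matrix)) {
    if (length(unique(n_microstates)) != 1L) {
      stop("a single transition_matrix requires equal n_microstates per ensemble",
           call. = FALSE)
    }
    transition_matrix <- rep(list(transition_matrix), n_ensembles)
  }
  for (P in transition_matrix) validate_stochastic(P)
  for (e in seq_len(n_ensembles)) {
    if (nrow(transition_matrix[[e]]) != n_microstates[e]) {
      stop("transition_matrix dimension does not match n_microstates", call. = FALSE)
    }
  }

  if (is.null(coupled_residues)) {
    target <- which(residue_types == "LEU")[1]
    if (is.na(target)) target <- which(!residue_types %in% .excluded_restypes)[1]
    coupled_residues <- tibble::tibble(resno = as.integer(target), kappa = 1)
  }
  coupled_residues <- tibble::as_tibble(coupled_residues)
  stopifnot(all(c("resno", "kappa") %in% names(coupled_residues)),
            all(coupled_residues$kappa >= 0 & coupled_residues$kappa <= 1))
  bad <- setdiff(coupled_residues$resno, seq_len(n_residues))
  if (length(bad)) stop("invalid spec: coupled residue outside topology", call. = FALSE)
  if (any(residue_types[coupled_residues$resno] %in% c(.excluded_restypes))) {
    stop("invalid spec: coupled residue has no rotamer states", call. = FALSE)
  }

  if (is.null(segment)) {
    segment <- seq.int(n_residues - ceiling(n_residues / 3) + 1L, n_residues)
  }
  stopifnot(all(segment %in% seq_len(n_residues)))

  structure(list(
    n_ensembles = as.integer(n_ensembles),
    replicas_per_ensemble = as.integer(replicas_per_ensemble),
    n_frames = as.integer(n_frames),
    frame_dt = frame_dt,
    n_residues = as.integer(n_residues),
    residue_types = residue_types,
    n_microstates = n_microstates,
    ensemble_offsets = ensemble_offsets,
    microstate_offsets = microstate_offsets,
    transition_matrix = transition_matrix,
    noise_sigma = noise_sigma,
    coupled_residues = coupled_residues,
    rotamer_emission = rotamer_emission,
    segment = as.integer(segment),
    chi_jitter_sd = chi_jitter_sd,
    ensemble_labels = ensemble_labels,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

default_residue_types <- function(n) {
  types <- rep("VAL", n)
  types[1] <- "ALA"
  types[min(4L, n)] <- "LEU"
  if (n >= 6) types[6] <- "GLY"
  if (n >= 8) types[8] <- "TRP"
  if (n >= 10) types[10] <- "PRO"
  types
}

sticky_chain <- function(k, stay_prob = 0.99) {
  if (k == 1L) return(matrix(1, 1, 1))
  P <- matrix((1 - stay_prob) / (k - 1), k, k)
  diag(P) <- stay_prob
  P
}

validate_stochastic <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("invalid spec: transition matrix must be square, non-negative, ",
         "rows summing to 1 within 1e-12", call. = FALSE)
  }
  invisible(P)
}

#' Stationary distribution of a row-stochastic matrix
#' @param P row-stochastic square matrix.
#' @return numeric probability vector `p` with `p %*% P = p`.
#' @export
stationary_distribution <- function(P) {
  validate_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_ensembles, " ensembles x ",
      x$replicas_per_ensemble, " replicas x ", x$n_frames, " frames, ",
      x$n_residues, " residues, microstates: ",
      paste(x$n_microstates, collapse = "/"), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## ---- topology ----

helix_point <- function(t, radius = 2.3, rise = 1.5, turn_deg = 100) {
  th <- t * turn_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * t)
}

#' Generate the toy topology for a synthetic spec
#'
#' Residues are laid along an idealised helix; N, CA and C sit on the helix
#' curve at fractional positions so backbone geometry is never collinear.
#' chi-bearing residues additionally carry the atoms of each defined chi
#' angle (e.g. CB/CG1 for Val; CB/CG/CD1 for Leu and Trp), placed at the
#' trans reference rotamer.
#'
#' @param spec a [synthetic_spec()].
#' @return A `msw_topology`: tibble with columns `eleno`, `elety`, `resno`,
#'   `resid`, `x`, `y`, `z`.
#' @export
generate_topology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- list()
  eleno <- 0L
  for (i in seq_len(spec$n_residues)) {
    rt <- spec$residue_types[i]
    bb <- rbind(helix_point(i - 1 / 3), helix_point(i), helix_point(i + 1 / 3))
    at <- data.frame(elety = c("N", "CA", "C"), x = bb[, 1], y = bb[, 2], z = bb[, 3])
    def <- .chi_defs[[rt]]
    if (!is.null(def)) {
      n <- bb[1, ]; ca <- bb[2, ]; c3 <- bb[3, ]
      cb <- place_atom(c3, n, ca, 1.53, 110, -122)
      at <- rbind(at, data.frame(elety = "CB", x = cb[1], y = cb[2], z = cb[3]))
      g_name <- def$chi1[4]
      g <- place_atom(n, ca, cb, 1.52, 114, 180)
      at <- rbind(at, data.frame(elety = g_name, x = g[1], y = g[2], z = g[3]))
      if (!is.null(def$chi2)) {
        d_name <- def$chi2[4]
        d <- place_atom(ca, cb, g, 1.52, 114, 180)
        at <- rbind(at, data.frame(elety = d_name, x = d[1], y = d[2], z = d[3]))
      }
    }
    at$resno <- i
    at$resid <- rt
    at$eleno <- eleno + seq_len(nrow(at))
    eleno <- eleno + nrow(at)
    rows[[i]] <- at
  }
  top <- tibble::as_tibble(do.call(rbind, rows))[
    , c("eleno", "elety", "resno", "resid", "x", "y", "z")]
  class(top) <- c("msw_topology", class(top))
  top
}

topology_xyz <- function(top) as.vector(t(as.matrix(top[, c("x", "y", "z")])))

#' Write a topology as a single-model PDB file
#' @param top a `msw_topology`.
#' @param file output path.
#' @param b optional per-atom B-factor vector.
#' @return `file`, invisibly.
#' @export
write_topology_pdb <- function(top, file, b = NULL) {
  bio3d::write.pdb(file = file, xyz = topology_xyz(top),
                   eleno = top$eleno, elety = top$elety,
                   resno = top$resno, resid = top$resid,
                   b = if (is.null(b)) rep(0, nrow(top)) else b)
  invisible(file)
}

## ---- hidden-state and rotamer sampling ----

sample_markov <- function(P, n, init = NULL) {
  k <- nrow(P)
  if (is.null(init)) init <- sample.int(k, 1, prob = stationary_distribution(P))
  s <- integer(n)
  s[1] <- init
  if (n > 1) {
    cp <- t(apply(P, 1, cumsum))
    u <- stats::runif(n)
    for (t in 2:n) s[t] <- 1L + sum(u[t] > cp[s[t - 1], ])
  }
  s
}

# Emission matrix (n_microstates x n_states) for one residue: convex blend of
# a uniform base with a deterministic microstate -> state map.
emission_matrix <- function(kappa, n_micro, n_states) {
  E <- matrix((1 - kappa) / n_states, n_micro, n_states)
  map <- ((seq_len(n_micro) - 1L) %% n_states) + 1L
  E[cbind(seq_len(n_micro), map)] <- E[cbind(seq_len(n_micro), map)] + kappa
  E
}

residue_emissions <- function(spec, ensemble_index, scheme = build_default_scheme()) {
  chi_res <- which(spec$residue_types %in% names(scheme$residues))
  n_micro <- spec$n_microstates[ensemble_index]
  kap <- stats::setNames(rep(0, length(chi_res)), chi_res)
  hit <- as.character(spec$coupled_residues$resno)
  kap[hit[hit %in% names(kap)]] <-
    spec$coupled_residues$kappa[match(hit[hit %in% names(kap)], hit)]
  out <- lapply(seq_along(chi_res), function(j) {
    resno <- chi_res[j]
    ns <- scheme_n_states(scheme, spec$residue_types[resno])
    override <- spec$rotamer_emission[[as.character(resno)]]
    if (!is.null(override)) {
      stopifnot(nrow(override) == n_micro, ncol(override) == ns)
      E <- override / rowSums(override)
    } else {
      E <- emission_matrix(kap[[as.character(resno)]], n_micro, ns)
    }
    E
  })
  names(out) <- as.character(chi_res)
  out
}

sample_emitted_states <- function(micro, E) {
  out <- integer(length(micro))
  for (m in seq_len(nrow(E))) {
    idx <- which(micro == m)
    if (length(idx)) {
      out[idx] <- sample.int(ncol(E), length(idx), replace = TRUE, prob = E[m, ])
    }
  }
  out
}

# chi angle (degrees) realising a given state index of a residue type:
# bin centre plus wrapped-Gaussian jitter.
state_to_angles <- function(states, restype, scheme, jitter_sd) {
  ang <- scheme$residues[[restype]]$angles
  n <- length(states)
  if (!is.null(ang$chi2)) {
    n2 <- length(ang$chi2$labels)
    b1 <- ((states - 1L) %/% n2) + 1L
    b2 <- ((states - 1L) %% n2) + 1L
    chi2 <- wrap_angle(ang$chi2$centers[b2] + stats::rnorm(n, 0, jitter_sd))
  } else {
    b1 <- states
    chi2 <- NULL
  }
  chi1 <- wrap_angle(ang$chi1$centers[b1] + stats::rnorm(n, 0, jitter_sd))
  list(chi1 = chi1, chi2 = chi2)
}

## ---- full coordinate simulation ----

#' Simulate a labelled synthetic trajectory ensemble with ground truth
#'
#' Samples a hidden microstate path per replica from the spec's Markov
#' chain, builds per-frame backbone coordinates (helix + ensemble offset +
#' microstate offset on the moving segment + isotropic Gaussian noise), and
#' places side-chain atoms so that the computed chi angles fall in the bin
#' of the emitted rotamer state (bin centre + wrapped-Gaussian jitter).
#'
#' @param spec a [synthetic_spec()].
#' @return A list with components `ensemble` (a `msw_ensemble`) and `truth`
#'   (list of tibbles `microstates` and `rotamers` holding the hidden
#'   series).
#' @examples
#' sim <- simulate_ensemble(synthetic_spec(n_ensembles = 1, n_frames = 50,
#'                                         replicas_per_ensemble = 1))
#' sim$ensemble
#' head(sim$truth$microstates)
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  scheme <- build_default_scheme()
  top <- generate_topology(spec)
  n_atoms <- nrow(top)
  bb_idx <- which(top$elety %in% c("N", "CA", "C"))
  seg_bb <- which(top$elety %in% c("N", "CA", "C") & top$resno %in% spec$segment)
  chi_res <- which(spec$residue_types %in% names(scheme$residues))
  base <- topology_xyz(top)

  replicas <- list()
  micro_tr <- list()
  rot_tr <- list()
  withr::with_seed(spec$seed, {
    for (e in seq_len(spec$n_ensembles)) {
      P <- spec$transition_matrix[[e]]
      E_list <- residue_emissions(spec, e, scheme)
      for (r in seq_len(spec$replicas_per_ensemble)) {
        micro <- sample_markov(P, spec$n_frames)
        xyz <- matrix(rep(base, each = spec$n_frames), nrow = spec$n_frames)
        # noise on backbone atoms
        for (a in bb_idx) {
          cols <- (a - 1L) * 3L + 1:3
          xyz[, cols] <- xyz[, cols] +
            matrix(stats::rnorm(3L * spec$n_frames, 0, spec$noise_sigma),
                   ncol = 3)
        }
        # rigid segment displacement: ensemble offset + per-frame microstate offset
        shift <- spec$microstate_offsets[[e]][micro, , drop = FALSE]
        shift <- sweep(shift, 2, spec$ensemble_offsets[e, ], "+")
        for (a in seg_bb) {
          cols <- (a - 1L) * 3L + 1:3
          xyz[, cols] <- xyz[, cols] + shift
        }
        # side chains rebuilt from the (noisy, displaced) backbone
        for (resno in chi_res) {
          rt <- spec$residue_types[resno]
          states <- sample_emitted_states(micro, E_list[[as.character(resno)]])
          angs <- state_to_angles(states, rt, scheme, spec$chi_jitter_sd)
          at <- function(name) {
            a <- which(top$resno == resno & top$elety == name)
            xyz[, (a - 1L) * 3L + 1:3, drop = FALSE]
          }
          def <- .chi_defs[[rt]]
          n_m <- at("N"); ca_m <- at("CA"); c_m <- at("C")
          cb <- place_atom(c_m, n_m, ca_m, 1.53, 110, -122)
          g <- place_atom(n_m, ca_m, cb, 1.52, 114, angs$chi1)
          set_at <- function(name, m) {
            a <- which(top$resno == resno & top$elety == name)
            xyz[, (a - 1L) * 3L + 1:3] <<- m
          }
          set_at("CB", cb)
          set_at(def$chi1[4], g)
          if (!is.null(def$chi2)) {
            d <- place_atom(ca_m, cb, g, 1.52, 114, angs$chi2)
            set_at(def$chi2[4], d)
          }
          rot_tr[[length(rot_tr) + 1L]] <- tibble::tibble(
            ensemble = spec$ensemble_labels[e], replica = r,
            frame = seq_len(spec$n_frames), resno = resno, state = states)
        }
        micro_tr[[length(micro_tr) + 1L]] <- tibble::tibble(
          ensemble = spec$ensemble_labels[e], replica = r,
          frame = seq_len(spec$n_frames), microstate = micro)
        replicas[[length(replicas) + 1L]] <- list(
          ensemble = spec$ensemble_labels[e], replica = r,
          xyz = xyz, frame_dt = spec$frame_dt)
      }
    }
  })
  ensemble <- new_msw_ensemble(top, replicas)
  truth <- list(microstates = dplyr::bind_rows(micro_tr),
                rotamers = dplyr::bind_rows(rot_tr))
  list(ensemble = ensemble, truth = truth)
}

#' Coordinate-free fixture: hidden microstates and chi-angle series
#'
#' Same statistical model as [simulate_ensemble()] (Markov microstate path,
#' kappa-controlled rotamer emission, bin-centre chi angles with
#' wrapped-Gaussian jitter) but skipping all coordinate construction, for
#' fast tests of the rotamer and ECC stages.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `microstates` (tibble: ensemble, replica, frame,
#'   microstate), `chi` (tibble: ensemble, replica, frame, resno, resid,
#'   chi1, chi2) and `states` (tibble of the emitted true rotamer states).
#' @export
dihedral_only_fixture <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  scheme <- build_default_scheme()
  chi_res <- which(spec$residue_types %in% names(scheme$residues))
  micro_tr <- list(); chi_tr <- list(); st_tr <- list()
  withr::with_seed(spec$seed, {
    for (e in seq_len(spec$n_ensembles)) {
      P <- spec$transition_matrix[[e]]
      E_list <- residue_emissions(spec, e, scheme)
      for (r in seq_len(spec$replicas_per_ensemble)) {
        micro <- sample_markov(P, spec$n_frames)
        micro_tr[[length(micro_tr) + 1L]] <- tibble::tibble(
          ensemble = spec$ensemble_labels[e], replica = r,
          frame = seq_len(spec$n_frames), microstate = micro)
        for (resno in chi_res) {
          rt <- spec$residue_types[resno]
          states <- sample_emitted_states(micro, E_list[[as.character(resno)]])
          angs <- state_to_angles(states, rt, scheme, spec$chi_jitter_sd)
          chi_tr[[length(chi_tr) + 1L]] <- tibble::tibble(
            ensemble = spec$ensemble_labels[e], replica = r,
            frame = seq_len(spec$n_frames), resno = resno, resid = rt,
            chi1 = angs$chi1,
            chi2 = if (is.null(angs$chi2)) NA_real_ else angs$chi2)
          st_tr[[length(st_tr) + 1L]] <- tibble::tibble(
            ensemble = spec$ensemble_labels[e], replica = r,
            frame = seq_len(spec$n_frames), resno = resno, state = states)
        }
      }
    }
  })
  list(microstates = dplyr::bind_rows(micro_tr),
       chi = dplyr::bind_rows(chi_tr),
       states = dplyr::bind_rows(st_tr))
}

## ---- file output ----

#' Write a synthetic ensemble (and its ground truth) to disk
#'
#' Writes the topology as a single-model PDB, each replica trajectory as a
#' CHARMM-format DCD (or multi-model PDB), ground-truth tables as CSV, and
#' a JSON echo of the generating spec. Identical specs produce
#' byte-identical files.
#'
#' @param sim result of [simulate_ensemble()] (or a bare `msw_ensemble`).
#' @param dir output directory (created if missing).
#' @param format `"dcd"` or `"pdb"` for the trajectories.
#' @param spec optional [synthetic_spec()] echoed to JSON.
#' @return tibble manifest: `path`, `kind`.
#' @export
write_ensemble <- function(sim, dir, format = c("dcd", "pdb"), spec = NULL) {
  format <- match.arg(format)
  if (inherits(sim, "msw_ensemble")) sim <- list(ensemble = sim, truth = NULL)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ens <- sim$ensemble
  paths <- list()
  top_path <- file.path(dir, "topology.pdb")
  write_topology_pdb(ens$topology, top_path)
  paths[[length(paths) + 1L]] <- c(top_path, "topology")
  for (rep in ens$replicas) {
    stem <- sprintf("%s_rep%d", rep$ensemble, rep$replica)
    if (format == "dcd") {
      p <- file.path(dir, paste0(stem, ".dcd"))
      write_dcd(rep$xyz, p, frame_dt = rep$frame_dt)
    } else {
      p <- file.path(dir, paste0(stem, ".pdb"))
      bio3d::write.pdb(file = p, xyz = rep$xyz,
                       eleno = ens$topology$eleno, elety = ens$topology$elety,
                       resno = ens$topology$resno, resid = ens$topology$resid)
    }
    paths[[length(paths) + 1L]] <- c(p, "trajectory")
  }
  if (!is.null(sim$truth)) {
    p <- file.path(dir, "truth_microstates.csv")
    utils::write.csv(sim$truth$microstates, p, row.names = FALSE)
    paths[[length(paths) + 1L]] <- c(p, "truth")
    p <- file.path(dir, "truth_rotamers.csv")
    utils::write.csv(sim$truth$rotamers, p, row.names = FALSE)
    paths[[length(paths) + 1L]] <- c(p, "truth")
  }
  if (!is.null(spec)) {
    p <- file.path(dir, "spec.json")
    echo <- spec[setdiff(names(spec), c("transition_matrix", "microstate_offsets"))]
    jsonlite::write_json(echo, p, auto_unbox = TRUE, digits = NA, force = TRUE)
    paths[[length(paths) + 1L]] <- c(p, "spec")
  }
  m <- do.call(rbind, paths)
  tibble::tibble(path = m[, 1], kind = m[, 2])
}

#' Write a coordinate matrix as a CHARMM-format DCD trajectory
#'
#' Minimal single-segment CHARMM DCD layout (no unit cell), readable by
#' [bio3d::read.dcd()] and the usual MD toolchains. Coordinates are stored
#' as 32-bit floats, so round-tripping is exact to about 1e-6 relative.
#'
#' @param xyz `n_frames` x `3 * n_atoms` coordinate matrix.
#' @param file output path.
#' @param frame_dt time step stored in the header.
#' @return `file`, invisibly.
#' @export
write_dcd <- function(xyz, file, frame_dt = 1) {
  stopifnot(is.matrix(xyz), ncol(xyz) %% 3 == 0)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) %/% 3L
  con <- file(file, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header record: 'CORD' + 20 control ints (nframes, istart, nsavc, ...,
  # delta as float bits at slot 10, version 24 at slot 20)
  icntrl <- integer(20)
  icntrl[1] <- n_frames; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- n_frames
  icntrl[10] <- float_bits(frame_dt)
  icntrl[20] <- 24L
  wint(84L); writeChar("CORD", con, nchars = 4, eos = NULL); wint(icntrl); wint(84L)
  title <- formatC("synthetic trajectory written by microswitchr", width = -80)
  wint(80L + 4L); wint(1L); writeChar(substr(title, 1, 80), con, nchars = 80, eos = NULL)
  wint(80L + 4L)
  wint(4L); wint(n_atoms); wint(4L)
  reclen <- 4L * n_atoms
  xi <- seq(1L, ncol(xyz), by = 3L)
  for (f in seq_len(n_frames)) {
    fr <- xyz[f, ]
    for (off in 0:2) {
      wint(reclen)
      writeBin(fr[xi + off], con, size = 4, endian = "little")
      wint(reclen)
    }
  }
  invisible(file)
}

# reinterpret a double as the integer bit pattern of its float32 value
float_bits <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
          "integer", size = 4, endian = "little")
}
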