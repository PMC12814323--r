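## End-to-end orchestration: generate (or load) -> superpose -> shared PCA ->
## per-ensemble microstate clustering -> chi/rotamers -> ECC scan ->
## conditional histograms -> kinetics, with one seed, CSV/PDB outputs and a
## hashed manifest.

#' Build and validate a pipeline configuration
#'
#' Exactly one of `synthetic` (a [synthetic_spec()]) or `input` (a list
#' with `topology` path and `trajectories` data frame of `path`/`label`)
#' must be supplied. One seed governs every stochastic step; each stage
#' derives its own stream from it, so adding stages never shifts earlier
#' stages' randomness.
#'
#' @param synthetic a [synthetic_spec()], or `NULL`.
#' @param input list(topology=, trajectories=) of file inputs, or `NULL`.
#' @param n_components PCA components to retain.
#' @param k_range candidate microstate counts per ensemble.
#' @param n_dims PC dimensions used for clustering.
#' @param ecc_ensemble ensemble label analysed for coupling (default the
#'   first label, i.e. the apo-like ensemble).
#' @param conditioning_residue residue for conditional histograms (default
#'   the top-ranked ECC residue).
#' @param minor_threshold minor rotamer-state population threshold.
#' @param contact_cutoff side-chain contact cutoff (Angstrom).
#' @param dwell_dominance dwell-segment occupancy threshold.
#' @param dwell_min_length dwell minimum length (default one third of a
#'   replica).
#' @param oblique_angle oblique histogram angle (degrees).
#' @param kinetics list of `k_on`, `k_off`, `exchange_rate`,
#'   `concentration` for the conformational-selection stage.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            n_components = 10, k_range = 4:6, n_dims = 5,
                            ecc_ensemble = NULL, conditioning_residue = NULL,
                            minor_threshold = 0.05, contact_cutoff = 4,
                            dwell_dominance = 0.9, dwell_min_length = NULL,
                            oblique_angle = 60,
                            kinetics = list(k_on = 1, k_off = 1,
                                            exchange_rate = 1000,
                                            concentration = 1),
                            seed = 1L) {
  if (is.null(synthetic) == is.null(input)) {
    stop("validation error: supply exactly one of 'synthetic' or 'input'",
         call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  if (!is.null(input)) {
    stopifnot(is.list(input), !is.null(input$topology),
              !is.null(input$trajectories))
  }
  stopifnot(n_components >= 2, all(k_range >= 1), n_dims >= 2,
            minor_threshold >= 0, contact_cutoff > 0,
            dwell_dominance > 0.5, dwell_dominance <= 1)
  structure(list(synthetic = synthetic, input = input,
                 n_components = n_components, k_range = k_range,
                 n_dims = n_dims, ecc_ensemble = ecc_ensemble,
                 conditioning_residue = conditioning_residue,
                 minor_threshold = minor_threshold,
                 contact_cutoff = contact_cutoff,
                 dwell_dominance = dwell_dominance,
                 dwell_min_length = dwell_min_length,
                 oblique_angle = oblique_angle, kinetics = kinetics,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; keys mirror the arguments of [pipeline_config()],
#'   with `synthetic` given as a list of [synthetic_spec()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_spec, y$synthetic)
  if (!is.null(y$k_range)) y$k_range <- as.integer(y$k_range)
  do.call(pipeline_config, y)
}

# derive a per-stage seed from the master seed and the stage name, so the
# stream of one stage is independent of which other stages run
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((seed + h) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writes every artifact under
#' `outdir`, and returns a manifest tibble (`stage`, `path`, `md5`). A
#' failing stage aborts with an error of class `msw_pipeline_error` naming
#' the stage; a `manifest.json` with status `"failed"` and the artifacts
#' produced so far is still written.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created).
#' @param verbose log stage progress via `message()`.
#' @return manifest tibble, invisibly.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(stage = character(0), path = character(0))
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  add <- function(stage, path) {
    manifest <<- dplyr::bind_rows(manifest,
                                  tibble::tibble(stage = stage, path = path))
    path
  }
  run_stage <- function(stage, expr) {
    say("stage ", stage)
    tryCatch(expr, error = function(e) {
      finish("failed", stage)
      stop(errorCondition(paste0("pipeline stage '", stage, "' failed: ",
                                 conditionMessage(e)),
                          class = c("msw_pipeline_error", "error"),
                          stage = stage))
    })
  }
  finish <- function(status, failed_stage = NULL) {
    mf <- manifest
    mf$md5 <- unname(tools::md5sum(mf$path))
    j <- list(status = status, failed_stage = failed_stage,
              seed = config$seed,
              artifacts = lapply(seq_len(nrow(mf)), function(i) {
                list(stage = mf$stage[i], path = mf$path[i], md5 = mf$md5[i])
              }))
    jsonlite::write_json(j, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    mf
  }
  wcsv <- function(x, stage, name) {
    p <- file.path(outdir, name)
    utils::write.csv(x, p, row.names = FALSE)
    add(stage, p)
  }

  truth <- NULL
  ensemble <- run_stage("generate", {
    if (!is.null(config$synthetic)) {
      sim <- simulate_ensemble(config$synthetic)
      truth <- sim$truth
      m <- write_ensemble(sim, file.path(outdir, "input"), spec = config$synthetic)
      for (i in seq_len(nrow(m))) add("generate", m$path[i])
      sim$ensemble
    } else {
      load_ensemble(config$input$topology, config$input$trajectories)
    }
  })

  backbone <- run_stage("superpose", {
    bb <- superpose(extract_backbone(ensemble))
    rmsf <- rmsf_per_residue(bb)
    wcsv(rmsf, "superpose", "rmsf.csv")
    bb
  })

  scores <- run_stage("pca", {
    model <- fit_shared_pca(backbone, n_components = config$n_components)
    sc <- project_scores(model, backbone)
    wcsv(tidy(model), "pca", "pca_variance.csv")
    wcsv(dplyr::as_tibble(sc), "pca", "scores.csv")
    sc
  })

  clusters <- run_stage("cluster", {
    labs <- unique(scores$ensemble)
    cls <- lapply(labs, function(l) {
      cluster_ensemble(scores, ensemble = l, k_range = config$k_range,
                       n_dims = config$n_dims,
                       seed = stage_seed(config$seed, paste0("cluster:", l)))
    })
    names(cls) <- labs
    tab <- dplyr::bind_rows(lapply(cls, function(a) {
      dplyr::bind_cols(tidy(a), tibble::tibble(ensemble = a$ensemble[1]))
    }))
    wcsv(tab, "cluster", "clusters.csv")
    wcsv(dplyr::bind_rows(lapply(cls, dplyr::as_tibble)), "cluster",
         "cluster_assignments.csv")
    rm_mat <- cluster_center_rmsd(cls, model)
    wcsv(tibble::as_tibble(rm_mat, rownames = "cluster"), "cluster",
         "cluster_center_rmsd.csv")
    for (a in cls) {
      med <- medoid_frames(a)
      for (i in seq_len(nrow(med))) {
        rep <- Filter(function(r) r$ensemble == a$ensemble[1] &&
                                  r$replica == med$replica[i],
                      ensemble$replicas)[[1]]
        p <- file.path(outdir, sprintf("medoid_%s_c%d.pdb", a$ensemble[1],
                                       med$cluster[i]))
        bio3d::write.pdb(file = p, xyz = rep$xyz[med$frame[i], ],
                         eleno = ensemble$topology$eleno,
                         elety = ensemble$topology$elety,
                         resno = ensemble$topology$resno,
                         resid = ensemble$topology$resid)
        add("cluster", p)
      }
    }
    cls
  })

  states <- run_stage("rotamers", {
    chi <- compute_chi(ensemble)
    wcsv(chi, "rotamers", "chi.csv")
    st <- assign_states(chi)
    wcsv(dplyr::as_tibble(st), "rotamers", "rotamer_states.csv")
    wcsv(state_summary(st, config$minor_threshold), "rotamers",
         "rotamer_summary.csv")
    st
  })

  run_stage("dwells", {
    min_len <- config$dwell_min_length
    if (is.null(min_len)) {
      min_len <- max(1L, floor(min(tidy(ensemble)$n_frames) / 3))
    }
    dw <- dwell_segments(states, min_len, config$dwell_dominance)
    wcsv(dw, "dwells", "dwell_segments.csv")
  })

  ecc_tab <- run_stage("ecc", {
    lab <- config$ecc_ensemble %||% unique(scores$ensemble)[1]
    res <- ecc_scan(clusters[[lab]], states[states$ensemble == lab, ])
    wcsv(res, "ecc", "ecc.csv")
    p <- file.path(outdir, "ecc_bfactor.pdb")
    ecc_to_bfactor(res, ensemble$topology, p)
    add("ecc", p)
    res
  })

  run_stage("conditional", {
    lab <- config$ecc_ensemble %||% unique(scores$ensemble)[1]
    target <- config$conditioning_residue %||%
      ecc_tab$resno[which.max(ecc_tab$ecc)]
    cond <- condition_histograms(
      scores[scores$ensemble == lab, ],
      states[states$ensemble == lab, ], resno = target,
      oblique_angle = config$oblique_angle,
      minor_threshold = config$minor_threshold)
    wcsv(cond$fractions, "conditional", "conditional_fractions.csv")
    grids <- dplyr::bind_rows(lapply(names(cond$histograms), function(s) {
      h <- cond$histograms[[s]]
      g <- expand.grid(xbin = seq_len(nrow(h$counts)),
                       ybin = seq_len(ncol(h$counts)))
      g$count <- as.vector(h$counts)
      g$state <- s
      g
    }))
    wcsv(grids, "conditional", "conditional_histograms.csv")
    med <- medoid_frames(clusters[[lab]])
    contacts <- contact_shell(ensemble, med$replica[1], med$frame[1],
                              target, config$contact_cutoff)
    wcsv(contacts, "conditional", "contacts.csv")
  })

  run_stage("kinetics", {
    target <- config$conditioning_residue %||%
      ecc_tab$resno[which.max(ecc_tab$ecc)]
    lab <- config$ecc_ensemble %||% unique(scores$ensemble)[1]
    pops <- state_populations(states[states$ensemble == lab &
                                     states$resno == target, ])
    # minor/alternate rotamer states gate binding competence: p_competent is
    # the fraction of frames outside the dominant state, kept off 0/1
    p_comp <- min(max(1 - max(pops$population), 0.05), 0.95)
    sch <- kinetic_scheme(c(p_comp, 1 - p_comp), c(TRUE, FALSE),
                          k_on = config$kinetics$k_on,
                          k_off = config$kinetics$k_off,
                          exchange_rate = config$kinetics$exchange_rate,
                          concentration = config$kinetics$concentration)
    wcsv(dplyr::bind_rows(effective_rates(sch),
                          effective_rates(sch, "numerical")),
         "kinetics", "kinetics_rates.csv")
    wcsv(fine_tuning_curve(sch), "kinetics", "kinetics_tuning.csv")
  })

  out <- finish("ok")
  say("pipeline complete: ", nrow(out), " artifacts")
  invisible(out)
}
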