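test_that("load_ensemble attaches labels and rejects malformed inputs", {
  sp <- tiny_spec(n_frames = 20, replicas = 3, seed = 3)
  d <- withr::local_tempdir()
  m <- write_ensemble(simulate_ensemble(sp), d)
  top <- m$path[m$kind == "topology"]
  trj <- m$path[m$kind == "trajectory"]
  ens <- load_ensemble(top, tibble::tibble(path = trj, label = "apo"))
  expect_identical(length(ens$replicas), 3L)
  expect_identical(tidy(ens)$n_frames, rep(20L, 3))
  expect_identical(unique(tidy(ens)$ensemble), "apo")

  # atom-count mismatch: topology from a bigger system
  sp2 <- tiny_spec(n_frames = 5, n_residues = 12, seed = 3)
  d2 <- withr::local_tempdir()
  m2 <- write_ensemble(simulate_ensemble(sp2), d2)
  expect_error(load_ensemble(m2$path[m2$kind == "topology"],
                             tibble::tibble(path = trj[1], label = "x")),
               "format error")

  # empty trajectory file must error, not produce an empty ensemble
  empty <- file.path(d, "empty.dcd")
  file.create(empty)
  expect_error(load_ensemble(top, tibble::tibble(path = empty, label = "x")))
  expect_error(load_ensemble("nope.pdb", tibble::tibble(path = trj[1],
                                                        label = "x")),
               "I/O error")
})

test_that("backbone extraction has the documented column layout", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 10, seed = 4))
  bb <- extract_backbone(sim$ensemble)
  expect_identical(ncol(bb$xyz), 90L)  # 10 residues x 3 atoms x 3 coords
  expect_identical(bb$atom_index$elety, rep(c("N", "CA", "C"), 10))
  bb3 <- extract_backbone(sim$ensemble, residues = 2:4)
  expect_identical(ncol(bb3$xyz), 27L)
  expect_identical(unique(bb3$atom_index$resno), 2:4)
  # two extractions of the same ensemble are identical
  expect_identical(bb$xyz, extract_backbone(sim$ensemble)$xyz)
})

test_that("a residue missing a backbone atom is reported by name", {
  atoms <- data.frame(elety = c("N", "CA", "C", "N", "CA"),
                      resno = c(1, 1, 1, 2, 2),
                      resid = c("GLY", "GLY", "GLY", "GLY", "GLY"))
  xyz <- matrix(rnorm(15), 1)
  ens <- manual_ensemble(atoms, xyz)
  expect_error(extract_backbone(ens), "residue 2.*lacks backbone atom C")
})

test_that("superposition exactly undoes a rigid rotation and is idempotent", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 30, seed = 6))
  bb <- extract_backbone(sim$ensemble)
  ref <- bb$xyz[1, ]
  withr::with_seed(8, {
    rot <- rotate_coords(matrix(ref, 1), random_rotation(), center = c(1, 2, 3))
  })
  bb$xyz <- rbind(ref, rot)
  bb$labels <- bb$labels[1:2, ]
  fitted <- superpose(bb, reference = "first")
  expect_lt(max(rmsd_to_reference(fitted, ref)), 1e-6)

  again <- superpose(fitted, reference = "first")
  expect_lt(max(abs(again$xyz - fitted$xyz)), 1e-9)
})

test_that("superposition matches the bio3d least-squares fit", {
  withr::with_seed(21, {
    for (i in 1:5) {
      ref <- rnorm(15, sd = 2)           # 5-atom instance
      mobile <- matrix(rnorm(4 * 15, sd = 2), 4)
      mine <- microswitchr:::fit_frames(ref, mobile)
      oracle <- bio3d::fit.xyz(fixed = ref, mobile = mobile,
                               fixed.inds = 1:15, mobile.inds = 1:15)
      expect_equal(mine, matrix(oracle, 4), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
  # random rotations of a rigid structure all collapse onto the reference
  ref <- as.vector(t(microswitchr:::helix_point(1:5)))
  withr::with_seed(22, {
    frames <- t(sapply(1:10, function(i) rotate_coords(ref, random_rotation())))
  })
  fitted <- microswitchr:::fit_frames(ref, frames)
  rms <- sqrt(rowSums(sweep(fitted, 2, ref)^2) / 5)
  expect_lt(max(rms), 1e-6)
})

test_that("superposition never increases the RMSD to the reference", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 100, n_ensembles = 2, seed = 7))
  bb <- extract_backbone(sim$ensemble)
  fitted <- superpose(bb)
  ref <- colMeans(fitted$xyz)
  before <- rmsd_to_reference(bb, ref)
  after <- rmsd_to_reference(fitted, ref)
  expect_true(all(after <= before + 1e-12))
})

test_that("collinear reference coordinates are rejected", {
  line <- as.vector(t(cbind(1:5, 0, 0)))
  bb <- structure(list(xyz = rbind(line, line),
                       atom_index = tibble::tibble(resno = rep(1L, 5),
                                                   elety = rep("CA", 5)),
                       labels = tibble::tibble(ensemble = "x", replica = 1L,
                                               frame = 1:2),
                       superposed = FALSE), class = "msw_backbone")
  expect_error(superpose(bb), "degeneracy")
})

test_that("RMSF is zero for frozen frames and d/sqrt(3) for one oscillating atom", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 4, noise_sigma = 0, seed = 9,
                                     transition_matrix = diag(4)))
  bb <- extract_backbone(sim$ensemble)
  bb$superposed <- TRUE
  r0 <- rmsf_per_residue(bb)
  expect_true(all(r0$rmsf < 1e-9))

  # two frames, one atom displaced +/- d along x: residue RMSF = d / sqrt(3)
  d <- 0.8
  f1 <- bb$xyz[1, ]; f2 <- f1
  f1[1] <- f1[1] + d; f2[1] <- f2[1] - d
  bb2 <- bb; bb2$xyz <- rbind(f1, f2); bb2$labels <- bb$labels[1:2, ]
  r2 <- rmsf_per_residue(bb2)
  expect_equal(r2$rmsf[r2$resno == 1], d / sqrt(3), tolerance = 1e-12)
  expect_true(all(r2$rmsf[r2$resno != 1] < 1e-12))
  expect_error(rmsf_per_residue(bb2, rows = integer(0)), "empty")
})

test_that("doubling the positional noise increases every residue's RMSF", {
  for (s in 1:10) {
    lo <- simulate_ensemble(tiny_spec(n_frames = 150, noise_sigma = 0.2,
                                      seed = 100 + s))
    hi <- simulate_ensemble(tiny_spec(n_frames = 150, noise_sigma = 0.4,
                                      seed = 100 + s))
    r_lo <- rmsf_per_residue(superpose(extract_backbone(lo$ensemble)))
    r_hi <- rmsf_per_residue(superpose(extract_backbone(hi$ensemble)))
    expect_true(all(r_hi$rmsf > r_lo$rmsf))
  }
})
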