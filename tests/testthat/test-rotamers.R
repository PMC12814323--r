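val_ensemble <- function(chi1_values) {
  # one Val analogue; CG1 placed at the requested chi1 for every frame
  n <- c(0, 1, 0); ca <- c(0, 0, 0); cc <- c(1, -1, 1); cb <- c(1, 1, 1)
  frames <- t(vapply(chi1_values, function(phi) {
    cg1 <- as.vector(place_atom(n, ca, cb, 1.52, 114, phi))
    c(n, ca, cc, cb, cg1)
  }, numeric(15)))
  atoms <- data.frame(elety = c("N", "CA", "C", "CB", "CG1"),
                      resno = 1L, resid = "VAL")
  manual_ensemble(atoms, frames)
}

test_that("chi angles hit cis, trans and constructed targets exactly", {
  ens <- val_ensemble(c(0, 180, 60, -60, 123.456))
  chi <- compute_chi(ens)
  expect_equal(chi$chi1, c(0, 180, 60, -60, 123.456), tolerance = 1e-6)
  expect_true(all(is.na(chi$chi2)))
})

test_that("missing atoms and chi-less residues raise named errors", {
  atoms <- data.frame(elety = c("N", "CA", "C", "CB"),
                      resno = 1L, resid = "VAL")
  ens <- manual_ensemble(atoms, matrix(rnorm(12), 1))
  expect_error(compute_chi(ens, 1), "residue 1.*lacks atom CG1")

  atoms2 <- data.frame(elety = c("N", "CA", "C"), resno = 1L, resid = "ALA")
  ens2 <- manual_ensemble(atoms2, matrix(rnorm(9), 1))
  expect_error(compute_chi(ens2, 1), "no-chi")
  expect_identical(nrow(compute_chi(ens2)), 0L)  # default selection skips it
})

test_that("state assignment is constant-correct and 360-degree invariant", {
  ens <- val_ensemble(rep(-60, 8))
  st <- assign_states(compute_chi(ens))
  expect_true(all(st$state == 1L))            # g- bin
  expect_true(all(st$state_label == "g-"))
  pops <- state_populations(st)
  expect_equal(pops$population, 1)

  chi <- compute_chi(val_ensemble(c(-170, -50, 40, 170, 100)))
  shifted <- chi; shifted$chi1 <- shifted$chi1 + 360
  expect_identical(assign_states(chi)$state, assign_states(shifted)$state)
  shifted$chi1 <- chi$chi1 - 720
  expect_identical(assign_states(chi)$state, assign_states(shifted)$state)
})

test_that("emitted rotamer states are recovered from jittered chi angles", {
  sp <- tiny_spec(n_frames = 3000, seed = 33)
  fx <- dihedral_only_fixture(sp)
  st <- assign_states(fx$chi)
  j <- dplyr::inner_join(st, fx$states,
                         by = c("ensemble", "replica", "frame", "resno"))
  expect_identical(nrow(j), nrow(fx$states))
  # 15-degree wrapped jitter vs 60-degree-wide bins: essentially always right
  expect_gte(mean(j$state.x == j$state.y), 0.999)
})

test_that("full-geometry chi recovery matches the fixture statistics", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 400, seed = 34))
  st <- assign_states(compute_chi(sim$ensemble))
  j <- dplyr::inner_join(st, sim$truth$rotamers,
                         by = c("ensemble", "replica", "frame", "resno"))
  expect_gte(mean(j$state.x == j$state.y), 0.999)
})

test_that("state summaries report circular means, ranks and minor flags", {
  chi <- tibble::tibble(
    ensemble = "a", replica = 1L, frame = 1:100, resno = 1L, resid = "VAL",
    chi1 = c(rep(c(-170, 170), 48), rep(-60, 4)),  # 96% trans, 4% g-
    chi2 = NA_real_)
  st <- assign_states(chi)
  sm <- state_summary(st)
  expect_equal(sum(sm$population), 1, tolerance = 1e-12)
  trans <- sm[sm$state_label == "t", ]
  expect_equal(trans$mean_chi1, 180)           # circular, not arithmetic 0
  expect_identical(trans$rank, 1L)
  expect_false(trans$minor)
  expect_true(sm$minor[sm$state_label == "g-"])

  one <- state_summary(assign_states(chi[chi$chi1 > 90 | chi$chi1 < -90, ]))
  expect_identical(nrow(one), 1L)
  expect_equal(one$population, 1)
})

test_that("dwell segmentation handles the degenerate shapes", {
  const <- rep(2L, 50)
  d <- dwell_segments(const, min_length = 50)
  expect_identical(nrow(d), 1L)
  expect_identical(c(d$start, d$end, d$state), c(1L, 50L, 2L))

  alt <- rep(c(1L, 2L), 100)
  expect_identical(nrow(dwell_segments(alt, 10, dominance = 0.9)), 0L)

  expect_identical(nrow(dwell_segments(const, min_length = 51)), 0L)
  expect_error(dwell_segments(const, 10, dominance = 0.5), "dominance")
})

test_that("planted dwells are recovered exactly at 0.9 dominance", {
  # three pure dwells separated by spacers that never visit the dwell states
  withr::with_seed(40, {
    spacer <- function(n) rep(c(4L, 5L), length.out = n)
    s <- c(spacer(60), rep(1L, 200), spacer(80), rep(2L, 150), spacer(50),
           rep(3L, 300), spacer(60))
  })
  d <- dwell_segments(s, min_length = 100, dominance = 0.9)
  expect_identical(d$state, 1:3)
  expect_identical(d$start, c(61L, 341L, 541L))
  expect_identical(d$end, c(260L, 490L, 840L))
  expect_identical(as.data.frame(d[, 1:3]),
                   oracle_dwells(s, 100, 0.9))
})

test_that("dwell segmentation equals the exhaustive window scan", {
  withr::with_seed(41, {
    for (rep in 1:12) {
      n <- sample(80:300, 1)
      k <- sample(2:4, 1)
      # sticky series so that real dwells occur
      s <- integer(n); s[1] <- sample.int(k, 1)
      for (t in 2:n) {
        s[t] <- if (runif(1) < 0.9) s[t - 1] else sample.int(k, 1)
      }
      ml <- sample(c(10, 25, 60), 1)
      dom <- sample(c(0.8, 0.9, 1), 1)
      mine <- as.data.frame(dwell_segments(s, ml, dom)[, 1:3])
      expect_identical(mine, oracle_dwells(s, ml, dom))
    }
  })
})

test_that("grouped dwell segmentation covers every residue and replica", {
  fx <- dihedral_only_fixture(tiny_spec(n_frames = 600, replicas = 2, seed = 35))
  st <- assign_states(fx$chi)
  d <- dwell_segments(st, min_length = 200, dominance = 0.9)
  expect_true(all(c("ensemble", "replica", "resno", "start", "end", "state")
                  %in% names(d)))
  # the kappa=1 residue inherits the sticky microstate path: dwells exist
  expect_gt(nrow(d[d$resno == 4, ]), 0)
})
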