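make_backbone <- function(xyz, ensemble = "a") {
  n_at <- ncol(xyz) / 3
  structure(list(
    xyz = xyz,
    atom_index = tibble::tibble(resno = rep(seq_len(ceiling(n_at / 3)),
                                            each = 3)[seq_len(n_at)],
                                elety = rep(c("N", "CA", "C"),
                                            length.out = n_at)),
    labels = tibble::tibble(ensemble = ensemble, replica = 1L,
                            frame = seq_len(nrow(xyz))),
    superposed = TRUE), class = "msw_backbone")
}

test_that("degenerate inputs: identical frames and rank-1 data", {
  base <- rnorm(12)
  bb <- make_backbone(matrix(base, 5, 12, byrow = TRUE))
  m <- fit_shared_pca(bb, n_components = 3)
  expect_true(all(m$explained_variance < 1e-20))

  other <- base + c(rep(0, 9), 1, 1, 1)
  bb2 <- make_backbone(rbind(base, other, base, other))
  m2 <- fit_shared_pca(bb2, n_components = 3)
  expect_gt(m2$explained_variance[1], 0)
  expect_true(all(m2$explained_variance[-1] < 1e-20))
  cosang <- sum(m2$components[1, ] * (other - base)) /
    sqrt(sum((other - base)^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-9)

  expect_error(fit_shared_pca(make_backbone(matrix(base, 1, 12))), "2 frames")
})

test_that("pc0 recovers the known displacement axis of two blobs", {
  withr::with_seed(31, {
    axis <- rnorm(30); axis <- axis / sqrt(sum(axis^2))
    blob <- matrix(rnorm(400 * 30, sd = 0.05), 400, 30)
    blob[201:400, ] <- blob[201:400, ] + matrix(5 * axis, 200, 30, byrow = TRUE)
  })
  m <- fit_shared_pca(make_backbone(blob), n_components = 3)
  expect_gte(abs(sum(m$components[1, ] * axis)), 0.99)
  # variances non-increasing, bounded by the total
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_lte(sum(m$explained_variance), m$total_variance + 1e-6)
})

test_that("projection is centred, variance-preserving and label-carrying", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 80, n_ensembles = 2, seed = 12))
  bb <- superpose(extract_backbone(sim$ensemble))
  m <- fit_shared_pca(bb, n_components = 5)
  sc <- project_scores(m, bb)
  # the mean frame projects to the origin
  mean_bb <- bb; mean_bb$xyz <- matrix(m$mean, 1); mean_bb$labels <- bb$labels[1, ]
  expect_lt(max(abs(project_scores(m, mean_bb)[, c("pc0", "pc1")])), 1e-9)
  # per-component variance of training scores equals the explained variance
  v <- apply(as.matrix(sc[, paste0("pc", 0:4)]), 2, stats::var)
  expect_equal(unname(v), m$explained_variance, tolerance = 1e-9)
  expect_identical(sc$ensemble, bb$labels$ensemble)
  bad <- bb; bad$xyz <- bb$xyz[, 1:30]
  expect_error(project_scores(m, bad), "mismatch")
})

test_that("shared-basis scores do not depend on co-projected ensembles", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 50, n_ensembles = 2, seed = 13))
  bb <- superpose(extract_backbone(sim$ensemble))
  m <- fit_shared_pca(bb, n_components = 4)
  all_scores <- project_scores(m, bb)
  one <- bb
  keep <- bb$labels$ensemble == "ens2"
  one$xyz <- bb$xyz[keep, ]; one$labels <- bb$labels[keep, ]
  expect_equal(as.matrix(project_scores(m, one)[, paste0("pc", 0:3)]),
               as.matrix(all_scores[keep, paste0("pc", 0:3)]))
})

test_that("unsuperposed rigid rotations corrupt the projection", {
  # documents why superposition must precede the shared PCA: rotated copies
  # of the same structures project elsewhere unless refitted
  sim <- simulate_ensemble(tiny_spec(n_frames = 40, seed = 14))
  bb <- superpose(extract_backbone(sim$ensemble))
  m <- fit_shared_pca(bb, n_components = 3)
  rotated <- bb
  withr::with_seed(15, {
    rotated$xyz <- rotate_coords(bb$xyz, random_rotation())
  })
  raw <- project_scores(m, rotated)
  refit <- project_scores(m, superpose(rotated, reference = m$mean))
  direct <- project_scores(m, bb)
  expect_gt(max(abs(raw$pc0 - direct$pc0)), 0.1)
  expect_lt(max(abs(refit$pc0 - direct$pc0)), 1e-4)
})

test_that("clustering recovers well-separated blobs and canonicalises labels", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 1200, n_microstates = 5,
                                     seed = 16))
  bb <- superpose(extract_backbone(sim$ensemble))
  sc <- project_scores(fit_shared_pca(bb, 6), bb)
  cl <- cluster_ensemble(sc, k_range = 4:6, seed = 2)
  expect_identical(attr(cl, "k"), 5L)
  # populations: percent, sum 100, non-increasing under canonical ordering
  expect_equal(sum(cluster_populations(cl)), 100, tolerance = 1e-9)
  expect_true(all(diff(attr(cl, "populations")) <= 1e-12))
  expect_equal(mclust::adjustedRandIndex(cl$cluster,
                                         sim$truth$microstates$microstate), 1)

  # permuting frame order changes nothing after canonicalisation
  perm <- withr::with_seed(3, sample(nrow(sc)))
  cl2 <- cluster_ensemble(sc[perm, ], k_range = 4:6, seed = 2)
  merged <- dplyr::inner_join(dplyr::as_tibble(cl), dplyr::as_tibble(cl2),
                              by = c("ensemble", "replica", "frame"))
  expect_identical(merged$cluster.x, merged$cluster.y)

  expect_error(cluster_ensemble(sc[1:3, ], k_range = 4:6), "fewer frames")
})

test_that("a single forced cluster holds all frames", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 60, seed = 17))
  bb <- superpose(extract_backbone(sim$ensemble))
  sc <- project_scores(fit_shared_pca(bb, 3), bb)
  cl <- cluster_ensemble(sc, k_range = 1, seed = 1)
  expect_identical(attr(cl, "k"), 1L)
  expect_equal(unname(cluster_populations(cl)), 100)
})

test_that("medoids are real frames, nearest the centre, ties to lowest index", {
  sc <- tibble::tibble(
    ensemble = "a", replica = rep(1:2, each = 4), frame = rep(1:4, 2),
    pc0 = c(0, 1, 1, 10, -1, 10, 11, 10.5), pc1 = 0)
  class(sc) <- c("msw_scores", class(sc))
  cl <- cluster_ensemble(sc, k_range = 2, n_dims = 2, seed = 1)
  med <- medoid_frames(cl)
  # the cluster holding frame (1, 1): frames at 0, 1, 1, -1; centre 0.25, so
  # the frame at 0 -- replica 1, frame 1 -- is its nearest member
  c_low <- cl$cluster[cl$replica == 1 & cl$frame == 1]
  low <- med[med$cluster == c_low, ]
  expect_identical(low$replica, 1L)
  expect_identical(low$frame, 1L)

  # explicit tie: two frames equidistant from the centre
  sc2 <- tibble::tibble(ensemble = "a", replica = 1L, frame = 1:4,
                        pc0 = c(-1, 1, 5, 7), pc1 = 0)
  class(sc2) <- c("msw_scores", class(sc2))
  cl2 <- cluster_ensemble(sc2, k_range = 2, n_dims = 2, seed = 1)
  med2 <- medoid_frames(cl2)
  expect_true(all(med2$frame %in% c(1L, 3L)))  # lower of each equidistant pair
})

test_that("2-D histograms conserve mass and add across ensembles", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 150, n_ensembles = 2, seed = 18))
  bb <- superpose(extract_backbone(sim$ensemble))
  sc <- project_scores(fit_shared_pca(bb, 3), bb)
  h_all <- histogram2d(sc, bins = 25)
  edges <- list(x = h_all$xedges, y = h_all$yedges)
  h1 <- histogram2d(sc[sc$ensemble == "ens1", ], edges = edges)
  h2 <- histogram2d(sc[sc$ensemble == "ens2", ], edges = edges)
  expect_identical(h1$counts + h2$counts, h_all$counts)
  hn <- histogram2d(sc, bins = 25, normalize = TRUE)
  expect_equal(sum(hn$counts), 1, tolerance = 1e-12)

  pt <- sc[rep(1, 7), ]
  hp <- histogram2d(pt, bins = 10, normalize = TRUE)
  expect_identical(sum(hp$counts > 0), 1L)
  expect_equal(max(hp$counts), 1)
  expect_error(histogram2d(sc[0, ]), "empty")
})

test_that("oblique histograms reduce to the PC axes and rotate consistently", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 120, seed = 19))
  bb <- superpose(extract_backbone(sim$ensemble))
  sc <- project_scores(fit_shared_pca(bb, 3), bb)
  edges <- seq(-15, 15, length.out = 61)
  h0 <- oblique_histogram(sc, 0, edges = edges)
  hx <- histogram2d(sc, bins = 60,
                    edges = list(x = edges, y = seq(-15, 15, length.out = 2)))
  expect_identical(h0$counts, as.integer(rowSums(hx$counts)))
  h90 <- oblique_histogram(sc, 90, edges = edges)
  hy <- histogram2d(sc, edges = list(x = seq(-15, 15, length.out = 2),
                                     y = edges))
  expect_identical(h90$counts, as.integer(colSums(hy$counts)))

  # rotating the scores by -theta and histogramming at 0 equals theta directly
  th <- 60 * pi / 180
  rot <- sc
  rot$pc0 <- cos(th) * sc$pc0 + sin(th) * sc$pc1
  rot$pc1 <- -sin(th) * sc$pc0 + cos(th) * sc$pc1
  expect_identical(oblique_histogram(sc, 60, edges = edges)$counts,
                   oblique_histogram(rot, 0, edges = edges)$counts)
})

test_that("cluster-centre RMSD matrix is symmetric, zero-diagonal, fit-invariant", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 400, n_microstates = 3,
                                     seed = 20))
  bb <- superpose(extract_backbone(sim$ensemble))
  m <- fit_shared_pca(bb, 5)
  sc <- project_scores(m, bb)
  cl <- cluster_ensemble(sc, k_range = 3, seed = 1)
  rm <- cluster_center_rmsd(cl, m)
  expect_equal(rm, t(rm))
  expect_true(all(diag(rm) == 0))
  expect_true(all(rm[upper.tri(rm)] > 0))

  # centres that differ by a pure rigid rotation have zero fitted RMSD
  c1 <- m$mean
  withr::with_seed(23, { c2 <- rotate_coords(c1, random_rotation()) })
  expect_lt(bio3d::rmsd(c1, c2, fit = TRUE), 1e-6)
})

test_that("partial-segment displacement RMSD matches a brute-force Kabsch oracle", {
  # two artificial cluster centres differing by displacing m of M atoms by d
  M <- 12; m_disp <- 4; d <- 3
  base <- as.vector(t(microswitchr:::helix_point(1:M)))
  shifted <- base
  shifted[seq_len(3 * m_disp)] <- shifted[seq_len(3 * m_disp)] +
    rep(c(d, 0, 0), m_disp)
  v <- numeric(3 * M)
  v[seq(1, 3 * m_disp, 3)] <- 1 / sqrt(m_disp)  # unit vector: x of first m atoms
  model <- structure(list(
    mean = base, components = matrix(v, 1),
    explained_variance = 1, total_variance = 1,
    atom_index = NULL), class = "msw_pca")
  fake <- function(center, lab) {
    structure(tibble::tibble(ensemble = lab, replica = 1L, frame = 1L,
                             cluster = 1L),
              centers = matrix(center, 1), populations = 100,
              medoids = tibble::tibble(cluster = 1L, replica = 1L, frame = 1L,
                                       distance = 0),
              k = 1L, n_dims = 1L, class = c("msw_clusters", "tbl_df", "tbl",
                                             "data.frame"))
  }
  rm <- cluster_center_rmsd(list(fake(0, "a"), fake(d * sqrt(m_disp), "b")),
                            model)
  # oracle: independent fit + RMSD on the explicit coordinates
  oracle <- bio3d::rmsd(base, shifted, fit = TRUE)
  expect_equal(rm["a:1", "b:1"], oracle, tolerance = 1e-6)
  # fitting absorbs part of a partial rigid displacement, so the fitted RMSD
  # sits strictly below the unfitted closed form d * sqrt(m/M)
  expect_lt(rm["a:1", "b:1"], d * sqrt(m_disp / M))
  expect_gt(rm["a:1", "b:1"], 0)
})

test_that("tidiers summarise PCA and cluster objects", {
  sim <- simulate_ensemble(tiny_spec(n_frames = 100, seed = 24))
  bb <- superpose(extract_backbone(sim$ensemble))
  m <- fit_shared_pca(bb, 4)
  td <- tidy(m)
  expect_identical(td$component, paste0("pc", 0:3))
  expect_equal(td$cumulative, cumsum(td$proportion))
  expect_identical(glance(m)$n_components, 4L)
  sc <- project_scores(m, bb)
  cl <- cluster_ensemble(sc, k_range = 4, seed = 1)
  expect_identical(nrow(tidy(cl)), 4L)
  expect_identical(glance(cl)$k, 4L)
})
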