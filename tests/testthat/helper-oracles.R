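# Independent brute-force oracles and small fixture factories shared across
# the test files. Oracles are deliberately naive implementations that never
# share code with the package internals they check.

# small, fast synthetic spec for unit tests
tiny_spec <- function(n_frames = 300, n_ensembles = 1, replicas = 1,
                      n_microstates = 4, seed = 1, ...) {
  synthetic_spec(n_ensembles = n_ensembles,
                 replicas_per_ensemble = replicas,
                 n_frames = n_frames, n_microstates = n_microstates,
                 seed = seed, ...)
}

# ECC directly from a joint count table, written from the definition
oracle_ecc_from_table <- function(tab) {
  n <- sum(tab)
  H <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
  s_bb <- H(rowSums(tab))
  s_sc <- H(colSums(tab))
  s_tot <- H(as.vector(tab))
  2 * (s_bb + s_sc - s_tot) / (s_bb + s_sc)
}

# expand a joint count table into a pair of aligned categorical series
table_to_series <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  a <- rep(idx[, 1], tab[idx])
  b <- rep(idx[, 2], tab[idx])
  list(a = a, b = b)
}

# exhaustive dwell-segment scan: for each start, try every end (occupancy
# counts updated incrementally so the scan stays affordable at 2000 frames)
oracle_dwells <- function(s, min_length, dominance) {
  n <- length(s)
  k <- max(s)
  segs <- list()
  i <- 1
  while (i + min_length - 1 <= n) {
    best_e <- NA_integer_; best_st <- NA_integer_
    counts <- if (min_length >= 2) {
      tabulate(s[i:(i + min_length - 2)], k)
    } else {
      integer(k)
    }
    for (e in seq.int(i + min_length - 1, n)) {
      counts[s[e]] <- counts[s[e]] + 1
      if (max(counts) / (e - i + 1) >= dominance) {
        best_e <- e
        best_st <- which.max(counts)
      }
    }
    if (!is.na(best_e)) {
      w <- which(s[i:best_e] == best_st) + i - 1
      segs[[length(segs) + 1]] <- data.frame(
        start = as.integer(min(w)), end = as.integer(max(w)), state = best_st)
      i <- best_e + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(segs)) {
    return(data.frame(start = integer(0), end = integer(0), state = integer(0)))
  }
  do.call(rbind, segs)
}

# build a minimal one-residue ensemble from explicit atom coordinates
manual_ensemble <- function(atoms, xyz_frames) {
  top <- tibble::tibble(
    eleno = seq_len(nrow(atoms)), elety = atoms$elety,
    resno = atoms$resno, resid = atoms$resid,
    x = xyz_frames[1, seq(1, ncol(xyz_frames), 3)],
    y = xyz_frames[1, seq(2, ncol(xyz_frames), 3)],
    z = xyz_frames[1, seq(3, ncol(xyz_frames), 3)])
  class(top) <- c("msw_topology", class(top))
  microswitchr:::new_msw_ensemble(
    top, list(list(ensemble = "test", replica = 1L, xyz = xyz_frames,
                   frame_dt = 1)))
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply one rotation to every atom of a coordinate vector/matrix
rotate_coords <- function(xyz, R, center = c(0, 0, 0)) {
  one <- function(v) {
    m <- matrix(v, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m, 2, center) %*% t(R) + rep(center, each = nrow(m))))
  }
  if (is.matrix(xyz)) t(apply(xyz, 1, one)) else one(xyz)
}
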