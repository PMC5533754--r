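# Independent oracles and small fixture builders shared across tests.

# Reference torsion via bio3d (independent of the package's atan2 path).
oracle_torsion <- function(p1, p2, p3, p4) {
  bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)
}

# Circular mean by explicit complex-vector averaging.
oracle_circ_mean <- function(x) {
  z <- mean(exp(1i * x * pi / 180))
  Arg(z) * 180 / pi
}

# Random rigid-body transform (rotation from QR of a Gaussian matrix).
random_rigid <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = stats::rnorm(3, 0, 20))
}

apply_rigid <- function(traj, rig) {
  for (t in seq_len(n_frames(traj))) {
    traj$xyz[t, , ] <- rigid_transform(matrix(traj$xyz[t, , ], ncol = 3),
                                       rig$rotation, rig$translation)
  }
  traj
}

# Naive scan of label changes (oracle for transition_counts totals).
oracle_n_changes <- function(labels) {
  l <- labels[!is.na(labels)]
  sum(l[-1] != l[-length(l)])
}

# Brute-force coordination scan: donor atoms within cutoff of the metal.
oracle_ligand_set <- function(traj, frame, metal_idx, cutoff,
                              donors = c("O", "N", "S")) {
  xyz <- frame_xyz(traj, frame)
  m <- xyz[metal_idx, ]
  idx <- setdiff(which(toupper(traj$atoms$elesy) %in% donors), metal_idx)
  d <- sqrt(colSums((t(xyz[idx, , drop = FALSE]) - m)^2))
  sort(idx[d <= cutoff])
}

# Two synthetic rotamer blobs with known means (degrees).
two_blob_fixture <- function(n = 100, seed = 42) {
  with_seed(seed, {
    list(chi1 = c(stats::rnorm(n, -60, 5), stats::rnorm(n, 180, 5)),
         chi2 = c(stats::rnorm(n, -60, 5), stats::rnorm(n, 60, 5)))
  })
}
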