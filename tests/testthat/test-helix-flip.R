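make_series <- function(kind, values, resno = seq_len(ncol(values))) {
  dihedral_series(kind, resno, values)
}

test_that("ideal helix dihedral sums sit at the -105 degree landmark", {
  h <- make_ideal_helix(20, n_frames = 5)
  bb <- backbone_dihedrals(h$trajectory)
  prof <- dihedral_sum_profile(bb$phi, bb$psi)
  interior <- prof$mean[prof$resno > 1 & prof$resno < 19]
  expect_lt(max(abs(interior - (-105))), 2)
})

test_that("sums are exact circular arithmetic on the canonical interval", {
  psi <- make_series("psi", matrix(100, 3, 4))
  phi <- make_series("phi", matrix(100, 3, 4))
  prof <- dihedral_sum_profile(phi, psi)
  expect_equal(unname(prof$sums[1, ]), rep(200, 3))
  expect_equal(unname(prof$mean), rep(200, 3))

  # 150 + 100 = 250 wraps to -110 on [-135, 225)
  psi2 <- make_series("psi", matrix(150, 1, 2))
  phi2 <- make_series("phi", matrix(100, 1, 2))
  expect_equal(unname(dihedral_sum_profile(phi2, psi2)$sums[1, 1]), -110)
})

test_that("circular time average matches the unit-vector oracle at the wrap", {
  vals <- matrix(c(112, -67), nrow = 10, ncol = 2)  # sums 224, -134 alternating
  psi <- make_series("psi", vals)
  phi <- make_series("phi", vals)
  prof <- dihedral_sum_profile(phi, psi)
  s <- prof$sums[, 1]
  expect_setequal(unique(s), c(224, -134))
  expect_lt(circ_dist(prof$mean[1], oracle_circ_mean(s)), 1e-6)
})

test_that("profiles are equivariant to full-turn shifts of the inputs", {
  set.seed(41)
  raw <- matrix(runif(40, -180, 180), 10, 4)
  psi <- make_series("psi", raw)
  phi <- make_series("phi", raw)
  shifted <- make_series("phi", wrap180(raw + 360))
  expect_equal(dihedral_sum_profile(phi, psi)$mean,
               dihedral_sum_profile(shifted, psi)$mean)
})

step_profile <- function(before, after, n_before = 50, n_after = 50) {
  v <- c(rep(before, n_before), rep(after, n_after))
  # psi carries the step; phi fixed at 0 for residue pairs
  psi <- make_series("psi", matrix(v, ncol = 2, nrow = length(v)))
  phi <- make_series("phi", matrix(0, length(v), 2))
  dihedral_sum_profile(phi, psi)
}

test_that("a persistent step from helical to flipped yields one event", {
  prof <- step_profile(-105, wrap180(200))
  ev <- detect_flips(prof)
  ev1 <- ev[ev$resno == 1, ]
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$frame, 51)
  expect_equal(ev1$from, "helical")
  expect_equal(ev1$to, "flipped")
})

test_that("an unbroken helix produces no flip events", {
  h <- make_ideal_helix(15, n_frames = 50, thermal_sd = 5, seed = 42)
  bb <- backbone_dihedrals(h$trajectory)
  ev <- detect_flips(dihedral_sum_profile(bb$phi, bb$psi))
  expect_equal(nrow(ev), 0)
})

test_that("short excursions are debounced and overlap is rejected", {
  v <- c(rep(-105, 30), rep(wrap180(200), 3), rep(-105, 30))
  psi <- make_series("psi", matrix(v, ncol = 2, nrow = length(v)))
  phi <- make_series("phi", matrix(0, length(v), 2))
  prof <- dihedral_sum_profile(phi, psi)
  expect_equal(nrow(detect_flips(prof, min_dwell = 5)), 0)
  expect_gt(nrow(detect_flips(prof, min_dwell = 2)), 0)
  expect_error(detect_flips(prof, helical_center = -105,
                            flipped_center = -40, tolerance = 60),
               "overlap")
})

test_that("reversing frame order mirrors flip events", {
  prof <- step_profile(-105, wrap180(200))
  rev_prof <- prof
  rev_prof$sums <- prof$sums[rev(seq_len(nrow(prof$sums))), , drop = FALSE]
  ev <- detect_flips(prof)
  rev_ev <- detect_flips(rev_prof)
  expect_equal(nrow(rev_ev), nrow(ev))
  expect_equal(rev_ev$from[1], ev$to[1])
  expect_equal(rev_ev$to[1], ev$from[1])
})

test_that("injected flips are recovered exactly at their schedule", {
  h <- make_ideal_helix(30, n_frames = 120, thermal_sd = 5, seed = 43)
  ev_in <- data.frame(resno = c(5, 12, 20), start = c(20, 40, 70),
                      duration = c(25, 30, 40))
  fl <- inject_flips(h, ev_in)
  bb <- backbone_dihedrals(fl$trajectory)
  det <- detect_flips(dihedral_sum_profile(bb$phi, bb$psi))
  enter <- det[det$to == "flipped", ]
  exit <- det[det$from == "flipped", ]
  expect_equal(nrow(enter), 3)
  expect_equal(nrow(exit), 3)
  expect_setequal(paste(enter$resno, enter$frame),
                  paste(ev_in$resno, ev_in$start))
  expect_setequal(paste(exit$resno, exit$frame),
                  paste(ev_in$resno, ev_in$start + ev_in$duration))
})

test_that("helicity is 1 inside a helix, 0 in an extended chain", {
  h <- make_ideal_helix(12, n_frames = 4)
  bb <- backbone_dihedrals(h$trajectory)
  hp <- helicity_profile(bb$phi, bb$psi)
  expect_true(all(hp$fraction[hp$resno %in% 2:11] == 1))

  ext <- build_backbone(matrix(180, 2, 12), matrix(180, 2, 12))
  bbe <- backbone_dihedrals(ext)
  hpe <- helicity_profile(bbe$phi, bbe$psi)
  expect_true(all(hpe$fraction == 0, na.rm = TRUE))
})

test_that("a 1:1 helix/extended mixture gives helicity exactly 0.5", {
  n <- 10
  pm <- matrix(rep(c(-57, 180), each = n), 2, n, byrow = TRUE)
  sm <- matrix(rep(c(-47, 180), each = n), 2, n, byrow = TRUE)
  traj <- build_backbone(pm, sm)
  bb <- backbone_dihedrals(traj)
  hp <- helicity_profile(bb$phi, bb$psi)
  expect_equal(unique(hp$fraction[hp$resno %in% 2:(n - 1)]), 0.5)
})

test_that("helicity fractions are invariant to frame permutation", {
  h <- make_ideal_helix(10, n_frames = 20, thermal_sd = 25, seed = 44)
  bb <- backbone_dihedrals(h$trajectory)
  hp1 <- helicity_profile(bb$phi, bb$psi)
  perm <- with_seed(45, sample(20))
  phi2 <- dihedral_series("phi", bb$phi$resno, bb$phi$values[perm, ])
  psi2 <- dihedral_series("psi", bb$psi$resno, bb$psi$values[perm, ])
  expect_equal(helicity_profile(phi2, psi2)$fraction, hp1$fraction)
})

test_that("external secondary-structure tables parse and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1 1 H", "1 2 H", "2 1 H", "2 2 C"), f)
  hp <- parse_secondary_structure_table(f)
  expect_equal(hp$fraction, c(1, 0.5))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", ""), f2)
  expect_warning(hp2 <- parse_secondary_structure_table(f2), "empty")
  expect_equal(length(hp2$resno), 0)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1 1 H", "2 H"), f3)
  expect_error(parse_secondary_structure_table(f3), "line 2")

  # writer/parser identity on a generated assignment
  set.seed(46)
  tab <- expand.grid(res = 1:5, frame = 1:8)
  tab$state <- sample(c("H", "C"), nrow(tab), replace = TRUE)
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("%d %d %s", tab$res, tab$frame, tab$state), f4)
  hp4 <- parse_secondary_structure_table(f4)
  expect_equal(hp4$fraction,
               as.numeric(tapply(tab$state == "H", tab$res, mean)))
})
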