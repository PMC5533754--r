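test_that("a perfect octahedron has 6 ligands at 90/180 degree angles", {
  s <- make_metal_site(6)
  sh <- coordination_shell(s$trajectory, list(elesy = "CD"))[[1]]
  expect_equal(sh$count, 6)
  expect_equal(length(sh$angles), 15)
  near <- pmin(abs(sh$angles - 90), abs(sh$angles - 180))
  expect_lt(max(near), 1e-6)
  expect_equal(octahedral_score(sh), 1)
})

test_that("a trans-vacant site has 4 ligands and score (6-2)/6", {
  s <- make_metal_site(4)
  sh <- coordination_shell(s$trajectory, list(elesy = "CD"))[[1]]
  expect_equal(sh$count, 4)
  expect_equal(octahedral_score(sh), 4 / 6, tolerance = 1e-9)
})

test_that("ligand sets equal a brute-force distance scan on random clouds", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    xyz <- array(rnorm(n * 3, sd = 2.5), dim = c(1, n, 3))
    xyz[1, 1, ] <- 0  # metal at origin
    atoms <- data.frame(elety = c("CD", sample(c("O", "N", "C"), n - 1,
                                               replace = TRUE)),
                        resid = "X", resno = seq_len(n), chain = "A",
                        elesy = NA, stringsAsFactors = FALSE)
    atoms$elesy <- atoms$elety
    traj <- trajectory(xyz, atoms)
    sh <- coordination_shell(traj, 1L, cutoff = 3.0)[[1]]
    got <- sort(as.integer(rownames(sh$ligands)))
    expect_equal(got, oracle_ligand_set(traj, 1, 1, 3.0))
  }
})

test_that("coordination count is monotone in the cutoff", {
  set.seed(62)
  xyz <- array(rnorm(30, sd = 2), dim = c(1, 10, 3))
  xyz[1, 1, ] <- 0
  atoms <- data.frame(elety = c("CD", rep("O", 9)), resid = "X",
                      resno = 1:10, chain = "A",
                      elesy = c("CD", rep("O", 9)))
  traj <- trajectory(xyz, atoms)
  counts <- vapply(c(1, 2, 3, 4, 6),
                   function(ct) coordination_shell(traj, 1L,
                                                   cutoff = ct)[[1]]$count,
                   0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("octahedricity declines monotonically with angular jitter", {
  scores <- vapply(c(0, 5, 10, 20), function(sd) {
    s <- make_metal_site(6, angular_jitter_sd = sd, n_frames = 25, seed = 63)
    mean(octahedral_score(coordination_shell(s$trajectory,
                                             list(elesy = "CD"))))
  }, 0)
  expect_true(all(diff(scores) < 0))
  expect_equal(scores[1], 1)
})

test_that("score is 1 only for a complete, exact octahedron", {
  s5 <- make_metal_site(5)
  sh5 <- coordination_shell(s5$trajectory, list(elesy = "CD"))[[1]]
  expect_lt(octahedral_score(sh5), 1)
  sj <- make_metal_site(6, angular_jitter_sd = 8, seed = 64)
  shj <- coordination_shell(sj$trajectory, list(elesy = "CD"))[[1]]
  expect_lt(octahedral_score(shj), 1)
  # under 2 ligands the score is undefined
  s2 <- make_metal_site(2)
  sh2 <- coordination_shell(s2$trajectory, list(elesy = "CD"))[[1]]
  sh2$count <- 1L; sh2$angles <- numeric(0); sh2$ligands <- sh2$ligands[1, ]
  expect_true(is.na(octahedral_score(sh2)))
})

test_that("metal selection must resolve to exactly one atom", {
  s <- make_metal_site(6)
  expect_error(coordination_shell(s$trajectory, list(elesy = "O")),
               "exactly 1")
  expect_error(coordination_shell(s$trajectory, list(elesy = "FE")),
               "no atoms")
})

test_that("gate fixtures classify open/closed frames per schedule", {
  sched <- c("closed", "open", "closed", "open", "open")
  g <- make_gate_states(sched)
  gm <- gate_metrics(g$trajectory)
  expect_equal(gm$gate_state, sched)
  expect_true(all(gm$tyr_pocket[sched == "closed"] < 8))
  expect_true(all(gm$met_pocket[sched == "open"] < 7))
  expect_equal(gm$stub_extension[sched == "open"][1], 16)

  all_closed <- make_gate_states(rep("closed", 4))
  expect_true(all(gate_metrics(all_closed$trajectory)$gate_state ==
                    "closed"))
  all_open <- make_gate_states(rep("open", 4))
  expect_true(all(gate_metrics(all_open$trajectory)$gate_state == "open"))
})

test_that("geometry outputs are invariant under rigid motion", {
  g <- make_gate_states(c("closed", "open"))
  gm1 <- gate_metrics(g$trajectory)
  rig <- with_seed(65, random_rigid())
  gm2 <- gate_metrics(apply_rigid(g$trajectory, rig))
  for (col in c("tyr_pocket", "met_pocket", "stub_extension")) {
    expect_equal(gm2[[col]], gm1[[col]], tolerance = 1e-9)
  }
  s <- make_metal_site(6, angular_jitter_sd = 5, seed = 66)
  sc1 <- octahedral_score(coordination_shell(s$trajectory,
                                             list(elesy = "CD"))[[1]])
  sc2 <- octahedral_score(coordination_shell(apply_rigid(s$trajectory, rig),
                                             list(elesy = "CD"))[[1]])
  expect_equal(sc2, sc1, tolerance = 1e-9)
})

test_that("unresolvable gate selections fail naming the selection", {
  g <- make_gate_states("closed")
  sel <- default_gate_selections()
  sel$met_pocket <- list(resno = 999)
  expect_error(gate_metrics(g$trajectory, sel), "met_pocket")
})
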