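test_that("two synthetic blobs resolve into two clusters at the right centers", {
  b <- two_blob_fixture(n = 100, seed = 42)
  cl <- cluster_rotamers(b$chi1, b$chi2)
  expect_equal(nrow(cl$clusters), 2)
  cents <- cl$clusters[, c("centroid_chi1", "centroid_chi2")]
  d_to <- function(target) {
    min(sqrt(circ_dist(cents$centroid_chi1, target[1])^2 +
               circ_dist(cents$centroid_chi2, target[2])^2))
  }
  expect_lt(d_to(c(-60, -60)), 5)
  expect_lt(d_to(c(180, 60)), 5)
  expect_equal(sum(cl$clusters$occupancy) + cl$noise_fraction, 1,
               tolerance = 1e-9)
})

test_that("identical points form one cluster with the point as centroid", {
  cl <- cluster_rotamers(rep(-60, 50), rep(170, 50))
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$occupancy, 1)
  expect_equal(cl$noise_fraction, 0)
  expect_equal(cl$clusters$centroid_chi1, -60)
  expect_equal(cl$clusters$centroid_chi2, 170)
})

test_that("a blob straddling the +/-180 wrap is not split", {
  ang <- with_seed(47, list(chi1 = rnorm(200, -60, 5),
                            chi2 = rnorm(200, 179, 5)))
  cl <- cluster_rotamers(ang$chi1, ang$chi2)
  expect_equal(nrow(cl$clusters), 1)
  expect_lt(circ_dist(cl$clusters$centroid_chi2, 179), 5)
})

test_that("clustering is invariant to full turns and frame permutation", {
  b <- two_blob_fixture(n = 80, seed = 48)
  cl1 <- cluster_rotamers(b$chi1, b$chi2)
  cl2 <- cluster_rotamers(wrap180(b$chi1 + 360), wrap180(b$chi2 + 360))
  expect_equal(cl1$clusters$centroid_chi1, cl2$clusters$centroid_chi1)
  perm <- with_seed(49, sample(length(b$chi1)))
  cl3 <- cluster_rotamers(b$chi1[perm], b$chi2[perm])
  expect_equal(sort(round(cl3$clusters$centroid_chi1, 9)),
               sort(round(cl1$clusters$centroid_chi1, 9)))
  expect_equal(sort(cl3$clusters$n_members), sort(cl1$clusters$n_members))
})

test_that("configuration errors are rejected", {
  expect_error(cluster_rotamers(1:10, 1:10, eps = 0), "eps")
  expect_error(cluster_rotamers(1:10, 1:10, min_members = 0), "min_members")
})

test_that("assign_states labels by nearest centroid within eps", {
  b <- two_blob_fixture(n = 100, seed = 50)
  cl <- cluster_rotamers(b$chi1, b$chi2)
  c1 <- cl$clusters
  # a frame exactly at each centroid gets that cluster's id
  lab <- assign_states(c1$centroid_chi1, c1$centroid_chi2, cl)
  expect_equal(lab, c1$id)
  # a frame far from all centroids is noise
  expect_equal(assign_states(60, -170, cl), 0L)
  # relabelling the training frames reproduces >= 95% of labels
  relab <- assign_states(b$chi1, b$chi2, cl)
  core <- cl$labels > 0
  expect_gte(mean(relab[core] == cl$labels[core]), 0.95)
})

test_that("transition counts tally consecutive label changes", {
  tc <- transition_counts(c(1L, 1L, 2L, 2L, 1L))
  expect_equal(tc$counts["1", "2"], 1L)
  expect_equal(tc$counts["2", "1"], 1L)
  expect_equal(tc$n_changes, 2L)
  expect_true(all(transition_counts(rep(2L, 10))$counts == 0L))
  # noise-involving changes are tallied separately
  tc2 <- transition_counts(c(1L, 0L, 1L, 2L))
  expect_equal(tc2$noise_in, 1L)
  expect_equal(tc2$noise_out, 1L)
  expect_equal(tc2$counts["1", "2"], 1L)
  # never counted across trajectory boundaries
  tc3 <- transition_counts(list(c(1L, 1L), c(2L, 2L)))
  expect_equal(sum(tc3$counts), 0L)
})

test_that("total transitions equal a naive scan on random label sequences", {
  set.seed(51)
  for (i in 1:10) {
    lab <- sample(0:3, 200, replace = TRUE)
    expect_equal(transition_counts(lab)$n_changes, oracle_n_changes(lab))
  }
})

test_that("a two-state chain reproduces its analytic transition law", {
  n <- 10000
  r <- simulate_rotamer_markov(rbind(c(-60, -60), c(60, 60)),
                               rbind(c(0, 0.02), c(0.01, 0)),
                               n, within_state_sd = 5, seed = 52)
  # stationary occupancy 1/3, 2/3 within 3 sigma; the occupancy variance
  # carries the chain autocorrelation factor (1+lambda)/(1-lambda),
  # lambda = 1 - k12 - k21
  p1 <- 1 / 3
  lam <- 1 - 0.02 - 0.01
  sd_occ <- sqrt(p1 * (1 - p1) / n * (1 + lam) / (1 - lam))
  expect_lt(abs(mean(r$states == 1) - p1), 3 * sd_occ)
  tc <- transition_counts(r$states)
  e12 <- (n - 1) * p1 * 0.02
  e21 <- (n - 1) * (1 - p1) * 0.01
  expect_lt(abs(tc$counts["1", "2"] - e12), 3 * sqrt(e12 * (1 - 0.02)))
  expect_lt(abs(tc$counts["2", "1"] - e21), 3 * sqrt(e21 * (1 - 0.01)))
})

test_that("the five-state preset is recovered with centroids within 10 deg", {
  pre <- rotamer_preset_5state()
  r <- simulate_rotamer_markov(pre$states, pre$rates, 4000, seed = 53)
  cl <- cluster_rotamers(r$chi1, r$chi2)
  expect_equal(nrow(cl$clusters), 5)
  for (k in seq_len(5)) {
    d <- sqrt(circ_dist(cl$clusters$centroid_chi1, pre$states[k, 1])^2 +
                circ_dist(cl$clusters$centroid_chi2, pre$states[k, 2])^2)
    expect_lt(min(d), 10)
  }
})
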