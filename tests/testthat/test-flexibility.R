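# Mean structure, RMSF with block averaging, Welch comparison, contact and
# difference maps.

test_that("the mean structure of a static trajectory is the frame itself", {
  topo <- build_chain("Ng-c2")
  fr <- forward_kinematics(topo, const_assignment(topo, 120))
  tr <- frames_traj(topo, list(fr, fr, fr))
  expect_equal(mean_structure(tr), fr, tolerance = 1e-12)
})

test_that("a mirror-displaced pair averages to the midpoint structure", {
  topo <- build_chain("Ng-c2")
  fr <- forward_kinematics(topo, const_assignment(topo, 120))
  delta <- matrix(0, nrow(fr), 3)
  i <- match("Gal6p.CM", topo$atoms$atom_key)
  delta[i, ] <- c(0.05, -0.02, 0.03)
  tr <- frames_traj(topo, list(fr + delta, fr - delta))
  expect_equal(mean_structure(tr, superpose = FALSE), fr,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the mean structure is invariant to a joint rigid motion", {
  topo <- build_chain("Ng-c2")
  tr <- generate_trajectory(topo, n_frames = 20, seed = 5)
  set.seed(6)
  R <- random_rotation(); shift <- c(2, -1, 0.5)
  co2 <- tr$coords
  for (f in 1:20) co2[, , f] <- tr$coords[, , f] %*% t(R) +
      matrix(shift, dim(co2)[1], 3, byrow = TRUE)
  tr2 <- glycan_trajectory(co2, topo)
  m1 <- mean_structure(tr)
  m2 <- mean_structure(tr2)
  expect_lt(superposed_rmsd(m1, m2), 1e-9)
})

test_that("RMSF of a static trajectory is zero", {
  topo <- build_chain("Ng-c2f")
  fr <- forward_kinematics(topo, const_assignment(topo, 140))
  tr <- frames_traj(topo, rep(list(fr), 30), dt_ps = 1000)
  r <- rmsf(tr, window_ns = 10)
  expect_equal(max(r$global$rmsf_nm), 0)
  expect_equal(max(r$windows$rmsf_nm), 0)
})

test_that("a two-point oscillation has RMSF d/2", {
  topo <- build_chain("Ng-c2")
  fr <- forward_kinematics(topo, const_assignment(topo, 120))
  d <- 0.6
  delta <- matrix(0, nrow(fr), 3)
  gal_atoms <- which(topo$atoms$block_id == topo$blocks$block_id[
    match("Gal6p", topo$blocks$label)])
  delta[gal_atoms, 1] <- d / 2
  frames <- rep(list(fr + delta, fr - delta), 10)
  tr <- frames_traj(topo, frames, dt_ps = 1000)
  r <- rmsf(tr, targets = "Gal6p", window_ns = 20, fit = "none")
  expect_equal(r$global$rmsf_nm, d / 2, tolerance = 1e-9)
})

test_that("RMSF is invariant under a joint rigid motion of all frames", {
  topo <- build_chain("Ng-c2f")
  tr <- generate_trajectory(topo, n_frames = 60, seed = 8, dt_ps = 1000)
  set.seed(9)
  R <- random_rotation()
  co2 <- tr$coords
  for (f in seq_len(60)) co2[, , f] <- tr$coords[, , f] %*% t(R) +
      matrix(c(-3, 2, 1), dim(co2)[1], 3, byrow = TRUE)
  tr2 <- glycan_trajectory(co2, topo, dt_ps = 1000)
  r1 <- rmsf(tr, window_ns = 20)
  r2 <- rmsf(tr2, window_ns = 20)
  expect_equal(r1$global$rmsf_nm, r2$global$rmsf_nm, tolerance = 1e-9)
})

test_that("window bookkeeping matches the protocol arithmetic", {
  topo <- build_chain("Ng-c2")
  trajs <- lapply(1:3, function(r)
    generate_trajectory(topo, n_frames = 1000, seed = 1, replica_id = r))
  tr <- bind_replicas(trajs)          # 3 x 10 ns at 10 ps
  r <- rmsf(tr, targets = "Gal6p", window_ns = 1)
  expect_equal(nrow(r$windows), 30L)  # 10 windows per replica
  expect_error(rmsf(tr, targets = "Gal6p", window_ns = 50), "longer than")
  # the reference protocol: 3 x 500 ns with 10 ns windows -> 150 windows
  expect_equal(sampling_plan(3, 500, 10, 10)$total_windows, 150)
})

test_that("global RMSF pools the window values plus between-window spread", {
  topo <- build_chain("Ng-c2")
  tr <- generate_trajectory(topo, n_frames = 600, seed = 12, dt_ps = 1000)
  r <- rmsf(tr, targets = "Gal6p", window_ns = 100, fit = "none")
  com <- t(tr$coords[match("Gal6p.CM", topo$atoms$atom_key), , ])
  wsize <- 100
  wins <- split(seq_len(600), rep(1:6, each = wsize))
  wmeans <- t(vapply(wins, function(i) colMeans(com[i, ]), numeric(3)))
  between <- mean(rowSums((wmeans - matrix(colMeans(com), 6, 3, byrow = TRUE))^2))
  pooled <- sqrt(mean(r$windows$rmsf_nm^2) + between)
  expect_equal(r$global$rmsf_nm, pooled, tolerance = 1e-9)
})

test_that("Welch comparison matches the textbook computation", {
  a <- c(0.61, 0.58, 0.64, 0.60, 0.63)
  b <- c(0.71, 0.69, 0.74, 0.68, 0.70)
  cmp <- compare_rmsf(a, b)
  expect_equal(cmp$t, oracle_welch_t(a, b), tolerance = 1e-12)
  expect_true(cmp$significant)
  same <- compare_rmsf(a, a)
  expect_equal(same$t, 0)
  expect_false(same$significant)
  expect_error(compare_rmsf(a, 0.5), "at least 2")
})

test_that("a planted 3-sigma mean shift is detected at n = 150 per side", {
  set.seed(15)
  hits <- 0
  for (i in 1:5) {
    a <- rnorm(150, 0.70, 0.05)
    b <- rnorm(150, 0.70 + 3 * 0.05 / sqrt(1), 0.05)
    if (compare_rmsf(a, b)$significant) hits <- hits + 1
  }
  expect_equal(hits, 5)
})

test_that("contact maps match the brute-force oracle and are symmetric", {
  topo <- build_chain("Ng-c2")
  tr <- generate_trajectory(topo, n_frames = 8, seed = 20)
  cm <- contact_map(tr)
  expect_equal(cm$matrix, oracle_contact_map(tr), tolerance = 1e-12)
  expect_equal(cm$matrix, t(cm$matrix))
  expect_true(all(cm$matrix >= 0))
  expect_equal(unname(diag(cm$matrix)), rep(0, nrow(cm$matrix)))
})

test_that("difference maps subtract entrywise over shared blocks", {
  topo <- build_chain("Ng-c2Sf")
  trS <- generate_trajectory(topo, n_frames = 6, seed = 30)
  topoN <- desialylate(topo)
  trN <- generate_trajectory(topoN, default_presets("Ng-c2f"), n_frames = 6,
                             seed = 31)
  mS <- contact_map(trS)
  mN <- contact_map(trN)
  zero <- difference_map(mS, mS)
  expect_true(all(zero == 0))
  d1 <- difference_map(mN, mS)
  d2 <- difference_map(mS, mN)
  expect_equal(unclass(d1), -unclass(d2))
  expect_setequal(rownames(d1), topoN$blocks$label)
  # a planted uniform expansion shifts every off-diagonal entry by +0.1
  mX <- mN
  mX$matrix <- mN$matrix + 0.1 - 0.1 * diag(nrow(mN$matrix))
  dX <- difference_map(mX, mN)
  off <- dX[row(dX) != col(dX)]
  expect_equal(unname(off), rep(0.1, length(off)))
  # removing more than NeuAc blocks is not a valid comparison
  mF <- contact_map(generate_trajectory(defucosylate(topo),
                                        default_presets("Ng-c2S"),
                                        n_frames = 6, seed = 32))
  expect_error(difference_map(mF, mN), "non-NeuAc")
})
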