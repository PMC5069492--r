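# Synthetic trajectory generator: mixture sampling, forward kinematics,
# and the chain presets.

test_that("a degenerate single-mode model stays in its basin", {
  m <- dihedral_state_model(160, concentration = 8.2)
  x <- sample_dihedral_path(m, 2000, seed = 1)
  expect_true(all(abs(wrap_angle(x - 160)) < 90))
  expect_equal(unique(attr(x, "modes")), 1L)
})

test_that("an identity switching matrix never leaves the initial mode", {
  m <- dihedral_state_model(c(0, 120), c(0.5, 0.5), switching = diag(2))
  x <- sample_dihedral_path(m, 5000, seed = 3)
  expect_equal(length(unique(attr(x, "modes"))), 1L)
})

test_that("a non-stochastic switching matrix is rejected", {
  m <- dihedral_state_model(c(0, 120), c(0.5, 0.5),
                            switching = matrix(c(1, 1, 0, 0.5), 2, 2))
  expect_error(sample_dihedral_path(m, 10, seed = 1), "row-stochastic")
})

test_that("sampling is reproducible under a fixed seed", {
  m <- dihedral_state_model(c(70, 180), c(0.79, 0.21))
  expect_identical(sample_dihedral_path(m, 1000, seed = 7),
                   sample_dihedral_path(m, 1000, seed = 7))
})

test_that("long-run basin occupancies match the stationary weights", {
  # independent switching so the chi-square sampling theory applies
  m <- dihedral_state_model(c(70, 180), c(0.79, 0.21), correlation_time_ps = 0)
  for (seed in 1:10) {
    x <- sample_dihedral_path(m, 150000, seed = seed)
    counts <- tabulate(attr(x, "modes"), 2)
    expect_gt(suppressWarnings(
      stats::chisq.test(counts, p = c(0.79, 0.21))$p.value), 0.01)
    expect_lt(abs(counts[1] / 150000 - 0.79), 0.02)
  }
})

test_that("forward kinematics reproduces assigned torsions exactly", {
  topo <- build_chain("Ng-c3Sf")
  set.seed(11)
  for (rep in 1:3) {
    a <- random_assignment(topo)
    tr <- assignment_traj(topo, a)
    for (lk in list_linkages(topo)) for (nm in names(lk$dihedral_defs)) {
      got <- dihedral_series(tr, lk$label, nm)$values
      expect_lt(abs(wrap_angle(got - a[[lk$label]][[nm]])), 1e-6)
    }
  }
})

test_that("a missing dihedral assignment is reported with its linkage", {
  topo <- build_chain("Ng-c2")
  a <- const_assignment(topo)
  a[["Man4p(a1-6)Man3"]]$omega <- NULL
  expect_error(forward_kinematics(topo, a), "Man4p\\(a1-6\\)Man3")
})

test_that("the all-trans chain is maximally extended", {
  topo <- build_chain("Ng-c2Sf")
  ext <- function(fr) sqrt(sum((fr["Gal6.CM", ] - fr["Asn.CM", ])^2))
  trans <- ext(forward_kinematics(topo, const_assignment(topo, 180)))
  set.seed(5)
  for (i in 1:20)
    expect_gt(trans, ext(forward_kinematics(topo, random_assignment(topo))))
})

test_that("bond geometry is rigid across generated frames", {
  topo <- build_chain("Ng-c2f")
  tr <- generate_trajectory(topo, n_frames = 50, seed = 2)
  # bonded pairs along each linkage chain keep template lengths exactly
  d <- function(k1, k2) {
    i <- match(k1, topo$atoms$atom_key); j <- match(k2, topo$atoms$atom_key)
    sqrt(colSums((tr$coords[i, , ] - tr$coords[j, , ])^2))
  }
  for (pair in list(c("Man3.C6", "Man3.O6"), c("Man3.O6", "Man4p.C1"),
                    c("Man4p.C1", "Man4p.O5"), c("GlcNAc1.O5", "GlcNAc1.C1"))) {
    len <- d(pair[1], pair[2])
    expect_lt(diff(range(len)), 1e-9)
  }
})

block_id_of_test <- function(topo, label)
  topo$blocks$block_id[match(label, topo$blocks$label)]

test_that("perturbing one torsion moves only the distal subtree", {
  topo <- build_chain("Ng-c2Sf")
  a <- mode_assignment(topo)
  b <- a
  b[["Man4p(a1-6)Man3"]]$omega <- a[["Man4p(a1-6)Man3"]]$omega + 10
  fa <- forward_kinematics(topo, a)
  fb <- forward_kinematics(topo, b)
  moved <- rowSums((fa - fb)^2) > 1e-18
  moved_blocks <- unique(topo$atoms$block_id[moved])
  distal <- c("Man4p", "GlcNAc5p", "Gal6p", "NeuAc7p")
  proximal <- setdiff(topo$blocks$label, distal)
  # proximal blocks (and everything on the alpha1-3 side) stay fixed
  expect_true(all(topo$blocks$label[match(moved_blocks, topo$blocks$block_id)]
                  %in% c(distal, "Man3")))
  # Man3 may only move in its O6 bridge atom, never its ring
  man3_moved <- topo$atoms$atom_name[moved & topo$atoms$block_id ==
                                       block_id_of_test(topo, "Man3")]
  expect_true(all(man3_moved %in% "O6"))
})

test_that("trajectory generation is deterministic and carries the protocol", {
  topo <- build_chain("Ng-c2")
  t1 <- generate_trajectory(topo, n_frames = 100, seed = 9)
  t2 <- generate_trajectory(topo, n_frames = 100, seed = 9)
  expect_identical(t1$coords, t2$coords)
  t3 <- generate_trajectory(topo, n_frames = 100, seed = 10)
  expect_false(identical(t1$coords, t3$coords))
  expect_equal(t1$dt_ps, 10)
  expect_equal(max(t1$time_ps), 99 * 10)
  # a 500 ns replica at 10 ps is 50,000 frames
  expect_equal(sampling_plan()$frames_per_replica, 50000)
})

test_that("generation requires a model for every torsion", {
  topo <- build_chain("Ng-c2")
  pres <- default_presets("Ng-c2")
  pres[["Man4(a1-3)Man3"]] <- NULL
  expect_error(generate_trajectory(topo, pres, n_frames = 5, seed = 1),
               "Man4\\(a1-3\\)Man3")
})

test_that("presets encode the sialylation-dependent mixtures", {
  w <- function(spec, linkage, nm) {
    m <- default_presets(spec)[[linkage]][[nm]]
    vapply(m$modes, `[[`, 0, "weight")
  }
  loc <- function(spec, linkage, nm) {
    m <- default_presets(spec)[[linkage]][[nm]]
    vapply(m$modes, `[[`, 0, "mean")
  }
  expect_equal(loc("Ng-c2Sf", "Man4(a1-3)Man3", "phi"), c(90, 170))
  expect_equal(w("Ng-c2Sf", "Man4(a1-3)Man3", "phi"), c(0.35, 0.65))
  expect_equal(w("Ng-c2f", "Man4(a1-3)Man3", "phi"), c(0.52, 0.48))
  expect_equal(loc("Ng-c2Sf", "Man4p(a1-6)Man3", "psi"), c(70, 180))
  expect_equal(w("Ng-c2Sf", "Man4p(a1-6)Man3", "psi"), c(0.79, 0.21))
  # tri-antennary: the third-antenna linkage loses its +50 mode without SA
  expect_length(loc("Ng-c3Sf", "GlcNAc5pp(b1-4)Man4p", "phi"), 2L)
  expect_length(loc("Ng-c3f", "GlcNAc5pp(b1-4)Man4p", "phi"), 1L)
  # inner-core models identical across sialylation states
  for (l in c("GlcNAc1(b1-N)Asn", "GlcNAc2(b1-4)GlcNAc1", "Man3(b1-4)GlcNAc2"))
    expect_identical(default_presets("Ng-c2Sf")[[l]],
                     default_presets("Ng-c2f")[[l]])
})

test_that("generated torsion statistics match the configured mixture", {
  topo <- build_chain("Ng-c2Sf")
  tr <- generate_replicas(topo, fast_presets("Ng-c2Sf", 100), replicas = 3,
                          n_frames = 5000, seed = 4)
  psi <- dihedral_series(tr, "Man4p(a1-6)Man3", "psi")
  md <- modal_decomposition(angular_histogram(psi, 5))
  expect_equal(nrow(md$modes), 2L)
  expect_lt(abs(md$modes$fraction[1] - 0.79), 0.05)
  expect_lt(abs(wrap_angle(md$modes$location[1] - 70)), 10)
})
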