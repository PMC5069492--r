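# Superposed RMSD, GROMOS clustering, cutoff selection, state labelling and
# transition counting.

test_that("superposed RMSD is zero on itself and under rigid motion", {
  set.seed(17)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(superposed_rmsd(A, A), 0)
  R <- random_rotation()
  B <- A %*% t(R) + matrix(c(1.2, -0.7, 3.1), 10, 3, byrow = TRUE)
  expect_lt(superposed_rmsd(A, B), 1e-9)
  expect_error(superposed_rmsd(A, B[1:5, ]), "matching atom counts")
})

test_that("superposed RMSD matches the quaternion oracle and is symmetric", {
  set.seed(19)
  for (i in 1:25) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_lt(abs(superposed_rmsd(A, B) - oracle_pair_rmsd(A, B)), 1e-6)
    expect_lt(abs(superposed_rmsd(A, B) - superposed_rmsd(B, A)), 1e-9)
  }
})

test_that("identical frames collapse to a single cluster", {
  topo <- build_chain("Ng-c2")
  tr <- assignment_traj(topo, const_assignment(topo), reps = 12L)
  cl <- gromos_cluster(tr, 0.1)
  expect_equal(length(cl$sizes), 1L)
  expect_equal(cl$sizes, 12L)
  expect_equal(unique(cl$assignments), 1L)
})

test_that("well-separated bundles are recovered with their planted sizes", {
  set.seed(23)
  pb <- planted_bundles(c(30, 15, 5))
  D <- rmsd_matrix(pb$coords)
  res <- glycotraj:::gromos_cluster_matrix(D, 0.1)
  expect_equal(length(res$sizes), 3L)
  expect_equal(res$sizes, c(30L, 15L, 5L))
  # recovered partition matches the planted one exactly
  expect_equal(length(unique(paste(res$assignments, pb$truth))), 3L)
})

test_that("clustering matches the brute-force oracle on random frame sets", {
  set.seed(29)
  for (i in 1:20) {
    nf <- sample(10:50, 1)
    co <- random_frames(nf)
    cutoff <- runif(1, 0.15, 0.5)
    D <- rmsd_matrix(co)
    got <- glycotraj:::gromos_cluster_matrix(D, cutoff)
    ref <- oracle_gromos(co, cutoff)
    # same partition (cluster numbering may differ: compare co-membership)
    expect_equal(outer(got$assignments, got$assignments, `==`),
                 outer(as.integer(ref), as.integer(ref), `==`))
    expect_equal(sum(got$sizes), nf)
    expect_equal(sort(got$sizes, decreasing = TRUE), got$sizes)
  }
})

test_that("the selected cutoff is the smallest satisfying the coverage rule", {
  set.seed(37)
  # 8 resolved bundles keep top-5 coverage below 90%; the rule is only met
  # once the cutoff grows past the planted inter-bundle scale
  pb <- planted_bundles(c(20, 15, 15, 12, 12, 10, 8, 8),
                        jitter = 0.005, sep = 0.15)
  D <- rmsd_matrix(pb$coords)
  tr <- list(coords = pb$coords)
  class(tr) <- "glycan_trajectory"
  cutoff <- select_cutoff(tr, D = D)
  cov_at <- function(cut) {
    r <- glycotraj:::gromos_cluster_matrix(D, cut)
    sum(r$sizes[seq_len(min(5, length(r$sizes)))]) / nrow(D)
  }
  expect_gt(cutoff, 0.05)
  expect_gte(cov_at(cutoff), 0.90)
  expect_lt(cov_at(cutoff - 0.01), 0.90)
  # a single tight bundle is fully covered at the smallest grid value
  one <- planted_bundles(20, jitter = 0.001)
  trm <- list(coords = one$coords); class(trm) <- "glycan_trajectory"
  expect_equal(select_cutoff(trm), 0.05)
  expect_error(select_cutoff(trm, grid = numeric(0)), "coverage")
})

test_that("constructed folded and extended frames get the expected labels", {
  topo <- build_chain("Ng-c2Sf")
  base <- mode_assignment(topo)
  tweak <- function(psi, omega, g5psi = NULL) {
    a <- base
    a[["Man4p(a1-6)Man3"]]$psi <- psi
    a[["Man4p(a1-6)Man3"]]$omega <- omega
    if (!is.null(g5psi)) a[["GlcNAc5p(b1-2)Man4p"]]$psi <- g5psi
    forward_kinematics(topo, a)
  }
  # alpha1-6 antenna folded along the trunk on the front side
  folded <- tweak(-160, 180, 60)
  # folded on the rear side
  rear <- tweak(-140, -160, 60)
  # extended roughly perpendicular to the trunk
  extended <- tweak(180, -60)
  tr <- frames_traj(topo, list(folded, rear, extended))
  st <- label_states(tr)
  expect_equal(st$labels, c("broken_wing", "back_folded", "bird"))
  expect_equal(sum(st$fractions), 1)
  # sanity of the constructed geometry against the published thresholds
  of <- orient_frame(extended, topo)$coords
  expect_gt(radial_distance(of["Gal6p.CM", 1:2]), 1.0)
  off <- orient_frame(folded, topo)$coords
  expect_lt(radial_distance(off["Gal6p.CM", 1:2]), 0.8)
})

test_that("state fractions sum to one on generated data", {
  topo <- build_chain("Ng-c2f")
  tr <- generate_replicas(topo, replicas = 2, n_frames = 300, seed = 3)
  st <- label_states(tr)
  expect_equal(sum(st$fractions), 1)
  expect_equal(length(st$labels), 600L)
  expect_true(all(rowSums(st$by_replica) - 1 < 1e-12))
})

test_that("transition counting follows the debounce contract", {
  expect_equal(count_transitions(rep("bird", 50)), 0L)
  expect_equal(count_transitions(c("broken_wing", "broken_wing", "bird",
                                   "bird", "broken_wing", "broken_wing")), 2L)
  # relabelling A<->B leaves the count unchanged
  s <- c("bird", "broken_wing", "bird", "bird", "broken_wing")
  expect_equal(count_transitions(s, c("broken_wing", "bird")),
               count_transitions(s, c("bird", "broken_wing")))
  expect_error(count_transitions(s, c("bird", "flying")), "unknown states")
  expect_error(count_transitions(s, debounce = 0), "debounce")
})

test_that("planted Markov switch counts are recovered exactly at debounce 1", {
  m <- dihedral_state_model(c(0, 120), c(0.5, 0.5), correlation_time_ps = 500)
  for (seed in 1:5) {
    x <- sample_dihedral_path(m, 20000, seed = seed)
    path <- attr(x, "modes")
    truth <- sum(diff(path) != 0)
    labels <- c("broken_wing", "bird")[path]
    expect_equal(count_transitions(labels, c("broken_wing", "bird")), truth)
  }
})

test_that("transition counts never cross replica boundaries", {
  labels <- c("bird", "broken_wing", "bird", "broken_wing")
  replica <- c(1L, 1L, 2L, 2L)
  expect_equal(count_transitions(labels, replica = replica), 2L)
  expect_equal(count_transitions(labels, replica = rep(1L, 4)), 3L)
})

test_that("transition counts are non-increasing in the debounce", {
  m <- dihedral_state_model(c(0, 120), c(0.7, 0.3), correlation_time_ps = 100)
  x <- sample_dihedral_path(m, 10000, seed = 44)
  labels <- c("broken_wing", "bird")[attr(x, "modes")]
  counts <- vapply(c(1, 2, 5, 10, 50), function(d)
    count_transitions(labels, debounce = d), 0L)
  expect_true(all(diff(counts) <= 0))
})
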