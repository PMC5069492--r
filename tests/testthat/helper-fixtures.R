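# Shared fixture builders.  All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# Full dihedral assignment with every free torsion at the given constant.
const_assignment <- function(topo, value = 180) {
  a <- lapply(list_linkages(topo), function(lk) {
    v <- list(phi = value, psi = value)
    if (!is.null(lk$dihedral_defs$omega)) v$omega <- value
    v
  })
  names(a) <- vapply(list_linkages(topo), `[[`, "", "label")
  a
}

# Assignment with all torsions at the dominant preset mode of the chain.
mode_assignment <- function(topo) {
  pres <- default_presets(topo$spec)
  a <- const_assignment(topo)
  for (l in names(a)) for (nm in names(a[[l]])) {
    m <- pres[[l]][[nm]]
    w <- vapply(m$modes, `[[`, 0, "weight")
    a[[l]][[nm]] <- m$modes[[which.max(w)]]$mean
  }
  a
}

# Random free-torsion assignment.
random_assignment <- function(topo) {
  a <- const_assignment(topo)
  for (l in names(a)) for (nm in names(a[[l]]))
    a[[l]][[nm]] <- runif(1, -180, 180)
  a
}

# Single-frame trajectory from an assignment.
assignment_traj <- function(topo, assignment, reps = 1L) {
  fr <- forward_kinematics(topo, assignment)
  co <- array(rep(fr, reps), c(nrow(fr), 3L, reps))
  glycan_trajectory(co, topo)
}

# Stack explicit frames (list of matrices) into a trajectory.
frames_traj <- function(topo, frames, dt_ps = 10, replica = 1L) {
  co <- array(unlist(frames), c(nrow(frames[[1]]), 3L, length(frames)))
  glycan_trajectory(co, topo, dt_ps = dt_ps, replica = replica)
}

# Presets with a shorter switching correlation time (well-mixed sampling for
# recovery checks on small frame counts).
fast_presets <- function(spec, tau_ps = 200) {
  p <- default_presets(spec)
  for (l in names(p)) for (nm in names(p[[l]]))
    p[[l]][[nm]]$correlation_time_ps <- tau_ps
  p
}

# Random unstructured frame set (not a glycan) for clustering oracles.
random_frames <- function(n_frames, n_atoms = 8, spread = 0.3) {
  array(rnorm(n_atoms * 3 * n_frames, sd = spread), c(n_atoms, 3L, n_frames))
}

# Planted bundle trajectory: k tight clusters of frames with the given
# sizes, built by jittering k base shapes that are themselves perturbations
# (scale `sep`) of one common random shape.
planted_bundles <- function(sizes, n_atoms = 10, jitter = 0.01, sep = 0.5) {
  k <- length(sizes)
  base0 <- matrix(rnorm(n_atoms * 3), n_atoms, 3)
  bases <- lapply(seq_len(k), function(i)
    base0 + matrix(rnorm(n_atoms * 3, sd = sep), n_atoms, 3))
  frames <- list()
  truth <- integer(0)
  for (i in seq_len(k)) for (j in seq_len(sizes[i])) {
    frames[[length(frames) + 1L]] <-
      bases[[i]] + matrix(rnorm(n_atoms * 3, sd = jitter), n_atoms, 3)
    truth <- c(truth, i)
  }
  ord <- sample(seq_along(frames))
  list(coords = array(unlist(frames[ord]), c(n_atoms, 3L, length(frames))),
       truth = truth[ord])
}
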