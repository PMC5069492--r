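## Synthetic coarse-grained trajectory generator.
##
## Each free glycosidic torsion follows a mixture of angular modes (wrapped
## Gaussian within a mode) with first-order Markov switching between modes at
## the stored-frame resolution.  Cartesian frames are produced by forward
## kinematics over the topology tree with a fixed rigid geometry template, so
## all conformational variability enters through the torsions.

## Rigid geometry template (free parameters of the coarse model; nm, degrees)
FK_TEMPLATE <- list(
  r_ring = 0.25,      # ring triangle side (O5-C1, C1-O5' spans)
  r_attach = 0.15,    # ring anchor -> attachment carbon
  r_glyco = 0.14,     # C-O bonds across the glycosidic bridge
  theta_attach = 109.47,
  theta_glyco = 113,
  theta_ring = 60,    # apex angle of the ring triangle
  tau_ring = 180,     # ring closure stays in the backbone plane
  ## attachment direction per substitution position: distinct fixed torsions
  ## separate branches while keeping the 4-linked backbone near-trans
  tau_attach = c("N" = 180, "2" = 120, "3" = 160, "4" = 180, "6" = 60)
)

#' One angular mode of a torsion mixture
#'
#' @param mean mode location in degrees, wrapped to `(-180, 180]`.
#' @param concentration inverse-variance dispersion (von Mises kappa-like):
#'   within-mode samples are wrapped Gaussian with sd `1/sqrt(concentration)`
#'   radians.  The default 8.2 corresponds to a ~20 degree sd.
#' @param weight stationary occupancy fraction of the mode.
#' @return an `angular_mode` object.
#' @export
angular_mode <- function(mean, concentration = 8.2, weight = 1) {
  stopifnot(concentration > 0, weight >= 0, weight <= 1)
  structure(list(mean = wrap_angle(mean), concentration = concentration,
                 weight = weight), class = "angular_mode")
}

#' Mixture-with-switching model for one torsion
#'
#' @param means mode locations (degrees).
#' @param weights stationary mode weights (must sum to 1).
#' @param concentration per-mode dispersion, recycled (see [angular_mode()]).
#' @param correlation_time_ps relaxation time of the mode-switching process.
#'   `0` gives independent sampling from the stationary weights.
#' @param switching optional explicit row-stochastic switching matrix; when
#'   given it overrides the matrix derived from `correlation_time_ps` (its
#'   stationary distribution should equal `weights`).
#' @return a `dihedral_state_model`.
#' @export
dihedral_state_model <- function(means, weights = rep(1 / length(means), length(means)),
                                 concentration = 8.2,
                                 correlation_time_ps = 5000,
                                 switching = NULL) {
  stopifnot(length(means) == length(weights))
  if (abs(sum(weights) - 1) > 1e-9) stop("mode weights must sum to 1")
  concentration <- rep_len(concentration, length(means))
  modes <- mapply(angular_mode, means, concentration, weights, SIMPLIFY = FALSE)
  structure(list(modes = modes, correlation_time_ps = correlation_time_ps,
                 switching = switching), class = "dihedral_state_model")
}

model_means <- function(m) vapply(m$modes, `[[`, 0, "mean")
model_weights <- function(m) vapply(m$modes, `[[`, 0, "weight")
model_sds_deg <- function(m) rad2deg(1 / sqrt(vapply(m$modes, `[[`, 0, "concentration")))

#' Mode-switching matrix of a model at a given frame spacing
#'
#' The default switching process is a linear relaxation towards the
#' stationary weights `w`: `P = (1 - a) I + a 1 w'` with
#' `a = 1 - exp(-dt/tau)`, whose stationary distribution is exactly `w`.
#'
#' @param model a `dihedral_state_model`.
#' @param dt_ps frame spacing in ps.
#' @return a row-stochastic matrix over the modes.
#' @export
switching_matrix <- function(model, dt_ps = 10) {
  if (!is.null(model$switching)) return(model$switching)
  w <- model_weights(model)
  k <- length(w)
  tau <- model$correlation_time_ps
  a <- if (tau <= 0) 1 else 1 - exp(-dt_ps / tau)
  (1 - a) * diag(k) + a * matrix(w, k, k, byrow = TRUE)
}

check_stochastic <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < -1e-12) ||
      any(abs(rowSums(P) - 1) > 1e-9))
    stop("switching matrix is not row-stochastic")
}

#' Sample a torsion time series from a state model
#'
#' Draws a Markov mode path at the frame resolution, then adds wrapped
#' Gaussian within-mode noise.  The realised mode path is attached as
#' attribute `"modes"` (1-based mode indices) for generator-truth checks.
#'
#' @param model a `dihedral_state_model`.
#' @param n_frames number of frames (>= 1).
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @param dt_ps frame spacing used to derive the switching matrix.
#' @return numeric vector of angles in degrees in `(-180, 180]`.
#' @export
sample_dihedral_path <- function(model, n_frames, seed = NULL, dt_ps = 10) {
  stopifnot(inherits(model, "dihedral_state_model"), n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  P <- switching_matrix(model, dt_ps)
  check_stochastic(P)
  w <- model_weights(model)
  k <- length(w)
  init <- if (k == 1L) 1L else sample.int(k, 1L, prob = w)
  path <- if (n_frames == 1L) init else
    cpp_markov_path(P, init, runif(n_frames - 1L))
  means <- model_means(model)
  sds <- model_sds_deg(model)
  ang <- wrap_angle(means[path] + rnorm(n_frames, 0, sds[path]))
  attr(ang, "modes") <- as.integer(path)
  ang
}

## flatten "linkage -> dihedral -> value" nested list checks
check_assignment <- function(topo, assignment) {
  for (lk in topo$linkages) {
    a <- assignment[[lk$label]]
    for (nm in names(lk$dihedral_defs)) {
      if (is.null(a) || is.null(a[[nm]]))
        stop("missing dihedral assignment for ", nm, " of linkage '",
             lk$label, "'")
    }
  }
}

## Vectorised forward kinematics: angles is a nested list
## linkage label -> list(phi=, psi=, omega=) of per-frame vectors (recycled).
## Returns coords array n_atoms x 3 x n_frames.
fk_batch <- function(topo, angles, n = NULL) {
  check_assignment(topo, angles)
  if (is.null(n))
    n <- max(vapply(angles, function(a) max(lengths(a)), 1L))
  tpl <- FK_TEMPLATE
  pos <- vector("list", nrow(topo$atoms))
  names(pos) <- topo$atoms$atom_key
  bput <- function(block_id, atom, m) pos[[atom_row(topo, block_id, atom)]] <<- m
  bget <- function(block_id, atom) pos[[atom_row(topo, block_id, atom)]]
  rep_row <- function(v) matrix(v, n, 3, byrow = TRUE)

  ## root ring triangle in a canonical pose
  r <- tpl$r_ring
  root <- topo$root
  bput(root, "O5", rep_row(c(0, 0, 0)))
  bput(root, "C1", rep_row(c(r, 0, 0)))
  bput(root, "C5", rep_row(c(r / 2, r * sin(pi / 3), 0)))
  bput(root, "CM", (bget(root, "O5") + bget(root, "C1") + bget(root, "C5")) / 3)

  for (lk in topo$linkages) {
    p <- lk$parent_block; c_ <- lk$child_block
    tok <- linkage_pos(lk$linkage_code)
    cx <- paste0("C", tok); ox <- paste0("O", tok)
    a <- angles[[lk$label]]
    phi <- rep_len(a$phi, n); psi <- rep_len(a$psi, n)
    bput(p, cx, nerf_place(bget(p, "C1"), bget(p, "O5"), bget(p, "C5"),
                           tpl$r_attach, tpl$theta_attach,
                           tpl$tau_attach[[tok]]))
    tau_o <- if (has_omega(lk$linkage_code)) rep_len(a$omega, n) else 180
    bput(p, ox, nerf_place(bget(p, "O5"), bget(p, "C5"), bget(p, cx),
                           tpl$r_glyco, tpl$theta_attach, tau_o))
    bput(c_, "C1", nerf_place(bget(p, "C5"), bget(p, cx), bget(p, ox),
                              tpl$r_glyco, tpl$theta_glyco, psi))
    bput(c_, "O5", nerf_place(bget(p, cx), bget(p, ox), bget(c_, "C1"),
                              tpl$r_ring, tpl$theta_attach, phi))
    bput(c_, "C5", nerf_place(bget(p, ox), bget(c_, "C1"), bget(c_, "O5"),
                              tpl$r_ring, tpl$theta_ring, tpl$tau_ring))
    bput(c_, "CM", (bget(c_, "C1") + bget(c_, "O5") + bget(c_, "C5")) / 3)
  }

  out <- array(NA_real_, dim = c(nrow(topo$atoms), 3L, n))
  for (i in seq_along(pos)) out[i, , ] <- t(pos[[i]])
  out
}

#' Build one Cartesian frame from a dihedral assignment
#'
#' Extends the chain over the topology tree with the fixed rigid-geometry
#' template, placing every pseudo-atom so that each linkage's measured
#' phi/psi(/omega) torsion equals the assigned value.
#'
#' @param topo a `glycan_topology`.
#' @param assignment nested list: linkage label -> `list(phi=, psi=, omega=)`
#'   in degrees (omega only for 1-6/2-6 linkages).
#' @return `n_atoms x 3` coordinate matrix (nm), atom keys as row names.
#' @export
forward_kinematics <- function(topo, assignment) {
  co <- fk_batch(topo, assignment, n = 1L)
  m <- co[, , 1L]
  rownames(m) <- topo$atoms$atom_key
  m
}

#' Generate a synthetic replica trajectory
#'
#' Samples every free torsion of every linkage from its state model and runs
#' forward kinematics for all frames.  The replica seed is derived as
#' `seed + replica_id`, so a set of replicas generated from one base seed is
#' reproducible and mutually independent.
#'
#' @param topo a `glycan_topology`.
#' @param models nested list linkage label -> dihedral name ->
#'   `dihedral_state_model`; defaults to [default_presets()] for the chain's
#'   spec.
#' @param n_frames frames per replica (default 50,000: 500 ns at 10 ps).
#' @param dt_ps frame spacing (ps).
#' @param seed base integer seed.
#' @param replica_id integer replica id.
#' @return a `glycan_trajectory`; the realised mode paths are kept in
#'   `$mode_paths` for generator-truth checks.
#' @export
generate_trajectory <- function(topo, models = NULL, n_frames = 50000,
                                dt_ps = 10, seed = 1, replica_id = 1L) {
  stopifnot(inherits(topo, "glycan_topology"), n_frames >= 1)
  if (is.null(models)) {
    if (is.null(topo$spec)) stop("models required for a custom topology")
    models <- default_presets(topo$spec)
  }
  set.seed(seed + replica_id)
  angles <- list()
  mode_paths <- list()
  for (lk in topo$linkages) {
    mset <- models[[lk$label]]
    if (is.null(mset)) stop("missing state model for linkage '", lk$label, "'")
    a <- list()
    for (nm in names(lk$dihedral_defs)) {
      if (is.null(mset[[nm]]))
        stop("missing state model for ", nm, " of linkage '", lk$label, "'")
      v <- sample_dihedral_path(mset[[nm]], n_frames, seed = NULL, dt_ps = dt_ps)
      a[[nm]] <- as.numeric(v)
      mode_paths[[paste0(lk$label, ":", nm)]] <- attr(v, "modes")
    }
    angles[[lk$label]] <- a
  }
  co <- fk_batch(topo, angles, n = n_frames)
  traj <- glycan_trajectory(co, topo, dt_ps = dt_ps, replica = replica_id)
  traj$mode_paths <- mode_paths
  traj
}

#' Generate a set of independent replicas
#'
#' @inheritParams generate_trajectory
#' @param replicas number of replicas (default 3).
#' @return pooled `glycan_trajectory` over all replicas.
#' @export
generate_replicas <- function(topo, models = NULL, replicas = 3L,
                              n_frames = 50000, dt_ps = 10, seed = 1) {
  trajs <- lapply(seq_len(replicas), function(r)
    generate_trajectory(topo, models, n_frames = n_frames, dt_ps = dt_ps,
                        seed = seed, replica_id = r))
  pooled <- bind_replicas(trajs)
  pooled$mode_paths <- lapply(
    stats::setNames(nm = names(trajs[[1]]$mode_paths)),
    function(k) unlist(lapply(trajs, function(t) t$mode_paths[[k]]),
                       use.names = FALSE))
  pooled
}

## preset shorthands: stable unimodal torsions are stiffer (~10 degree sd)
## than the flexible multimodal ones (~20 degree sd, the package default)
.m1 <- function(mean, ...) dihedral_state_model(mean, 1, concentration = 33, ...)
.m2 <- function(means, weights, ...) dihedral_state_model(means, weights, ...)

#' Default per-linkage torsion presets for a chain variant
#'
#' Encodes the characteristic angular statistics of each glycosidic linkage:
#' stable unimodal inner-core torsions that do not depend on sialylation;
#' a bimodal phi on Man4(a1-3)Man3 at +90/+170 degrees whose weights invert
#' on desialylation (0.35/0.65 sialylated vs 0.52/0.48 non-sialylated for
#' bi-antennary chains); a bimodal psi on Man4p(a1-6)Man3 at +70/+180
#' degrees with 79%/21% occupancy when sialylated; and, for tri-antennary
#' chains, a bimodal-to-unimodal phi on GlcNAc5pp(b1-4)Man4p (+50/-165
#' degrees collapsing to -165 on desialylation).  Unstated torsions default
#' to stable unimodal modes.  All modes use the default ~20 degree
#' within-mode sd and a 5 ns switching correlation time.
#'
#' @param spec a [chain_spec()] or abbreviation string.
#' @return nested list: linkage label -> dihedral name ->
#'   `dihedral_state_model`.
#' @export
default_presets <- function(spec) {
  if (is.character(spec)) spec <- chain_spec(spec)
  S <- spec$sialylated
  tri <- spec$n_antennas == 3L
  p <- list()
  p[["GlcNAc1(b1-N)Asn"]]      <- list(phi = .m1(-80), psi = .m1(180))
  if (spec$fucosylated)
    p[["Fuc1p(a1-6)GlcNAc1"]]  <- list(phi = .m1(-70),
                                       psi = if (S) .m1(100) else .m1(80),
                                       omega = .m1(180))
  p[["GlcNAc2(b1-4)GlcNAc1"]]  <- list(phi = .m1(-80), psi = .m1(120))
  p[["Man3(b1-4)GlcNAc2"]]     <- list(phi = .m1(-80), psi = .m1(120))
  p[["Man4(a1-3)Man3"]] <- list(
    phi = if (tri) {
      if (S) .m2(c(90, 170), c(0.80, 0.20)) else .m2(c(90, 170), c(0.60, 0.40))
    } else {
      if (S) .m2(c(90, 170), c(0.35, 0.65)) else .m2(c(90, 170), c(0.52, 0.48))
    },
    psi = .m1(20))
  p[["GlcNAc5(b1-2)Man4"]]     <- list(phi = .m1(160), psi = .m1(160))
  p[["Gal6(b1-4)GlcNAc5"]]     <- list(phi = .m1(-80),
                                       psi = if (S) .m1(120) else .m1(100))
  p[["Man4p(a1-6)Man3"]] <- list(
    phi = .m1(-90),
    psi = if (S) .m2(c(70, 180), c(0.79, 0.21)) else .m2(c(70, 180), c(0.60, 0.40)),
    omega = .m1(-60))
  p[["GlcNAc5p(b1-2)Man4p"]]   <- list(phi = .m1(160), psi = .m1(160))
  p[["Gal6p(b1-4)GlcNAc5p"]]   <- list(phi = .m1(-80), psi = .m1(120))
  if (tri) {
    p[["GlcNAc5pp(b1-4)Man4p"]] <- list(
      phi = if (S) .m2(c(50, -165), c(0.40, 0.60)) else .m1(-165),
      psi = .m1(120))
    p[["Gal6pp(b1-4)GlcNAc5pp"]] <- list(phi = .m1(-80), psi = .m1(120))
  }
  if (S) {
    neu <- list(phi = .m1(-60), psi = .m1(180), omega = .m1(-60))
    p[["NeuAc7(a2-6)Gal6"]] <- neu
    p[["NeuAc7p(a2-6)Gal6p"]] <- neu
    if (tri) p[["NeuAc7pp(a2-6)Gal6pp"]] <- neu
  }
  p
}
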