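## Trajectory container: an ordered stack of pseudo-atom coordinate frames
## with uniform time spacing, tied to the topology that defines atom order.

#' Construct a glycan trajectory
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (nm); atom order must
#'   match `topology$atoms`.
#' @param topology the `glycan_topology` the coordinates refer to.
#' @param dt_ps time between stored frames in ps.
#' @param replica integer replica id, either a scalar or one value per frame.
#' @param time_ps optional explicit frame times; defaults to
#'   `(0:(n-1)) * dt_ps` restarting at each replica.
#' @return an object of class `glycan_trajectory`.
#' @export
glycan_trajectory <- function(coords, topology, dt_ps = 10, replica = 1L,
                              time_ps = NULL) {
  stopifnot(inherits(topology, "glycan_topology"))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("atom count (", dim(coords)[1], ") does not match topology (",
         nrow(topology$atoms), ")")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  nf <- dim(coords)[3]
  if (length(replica) == 1L) replica <- rep.int(as.integer(replica), nf)
  if (length(replica) != nf) stop("replica must be scalar or one per frame")
  if (is.null(time_ps)) {
    time_ps <- numeric(nf)
    for (r in unique(replica)) {
      i <- which(replica == r)
      time_ps[i] <- (seq_along(i) - 1) * dt_ps
    }
  }
  structure(list(coords = coords, topology = topology, dt_ps = dt_ps,
                 replica = as.integer(replica), time_ps = time_ps),
            class = "glycan_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `glycan_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an atom coordinate matrix
#' @param traj a `glycan_trajectory`.
#' @param i frame index.
#' @return `n_atoms x 3` matrix (nm) with atom keys as row names.
#' @export
get_frame <- function(traj, i) {
  m <- traj$coords[, , i, drop = TRUE]
  dim(m) <- c(dim(traj$coords)[1], 3L)
  rownames(m) <- traj$topology$atoms$atom_key
  m
}

#' Concatenate replicas into one pooled trajectory
#'
#' @param ... `glycan_trajectory` objects over the same topology (or a single
#'   list of them).  Replica ids must be distinct.
#' @return a pooled `glycan_trajectory`; per-frame replica ids are kept so
#'   windowed and transition analyses never cross replica boundaries.
#' @export
bind_replicas <- function(...) {
  trajs <- list(...)
  if (length(trajs) == 1L && !inherits(trajs[[1]], "glycan_trajectory"))
    trajs <- trajs[[1]]
  stopifnot(length(trajs) >= 1L)
  a1 <- trajs[[1]]$topology$atoms$atom_key
  for (tr in trajs) {
    stopifnot(inherits(tr, "glycan_trajectory"))
    if (!identical(tr$topology$atoms$atom_key, a1))
      stop("replicas use different topologies")
    if (tr$dt_ps != trajs[[1]]$dt_ps) stop("replicas have different dt")
  }
  coords <- array(unlist(lapply(trajs, `[[`, "coords"), use.names = FALSE),
                  dim = c(length(a1), 3L,
                          sum(vapply(trajs, n_frames, 1L))))
  rep_id <- unlist(lapply(trajs, `[[`, "replica"), use.names = FALSE)
  if (anyDuplicated(unique(unlist(lapply(trajs, function(t) unique(t$replica))))))
    stop("replica ids must be distinct")
  tm <- unlist(lapply(trajs, `[[`, "time_ps"), use.names = FALSE)
  glycan_trajectory(coords, trajs[[1]]$topology, dt_ps = trajs[[1]]$dt_ps,
                    replica = rep_id, time_ps = tm)
}

#' Subset frames of a trajectory
#' @param traj a `glycan_trajectory`.
#' @param idx frame indices to keep (in order).
#' @return the subsetted `glycan_trajectory`.
#' @export
subset_frames <- function(traj, idx) {
  glycan_trajectory(traj$coords[, , idx, drop = FALSE], traj$topology,
                    dt_ps = traj$dt_ps, replica = traj$replica[idx],
                    time_ps = traj$time_ps[idx])
}

## Centre (CM pseudo-atom) series of one block: n_frames x 3
block_com <- function(traj, label) {
  i <- atom_row(traj$topology, block_id_of(traj$topology, label), "CM")
  t(traj$coords[i, , , drop = TRUE])
}

## CM of a single frame matrix for one block
frame_block_com <- function(frame, topo, label) {
  frame[atom_row(topo, block_id_of(topo, label), "CM"), ]
}

#' @export
print.glycan_trajectory <- function(x, ...) {
  cat("glycan_trajectory:", n_frames(x), "frames x", dim(x$coords)[1],
      "pseudo-atoms, dt =", x$dt_ps, "ps,",
      length(unique(x$replica)), "replica(s)\n")
  invisible(x)
}
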