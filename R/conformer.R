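## GROMOS conformer clustering with automatic cutoff selection, named
## conformational-state labelling of the alpha1-6 antenna, and transition
## counting.

#' Minimal RMSD between two frames after optimal superposition
#'
#' Least-RMSD rigid superposition (optimal rotation and translation, Kabsch)
#' followed by the root-mean-square deviation over all pseudo-atoms.
#'
#' @param frameA,frameB `n_atoms x 3` coordinate matrices (nm) with matching
#'   atom order.
#' @return RMSD in nm; symmetric in its arguments.
#' @export
superposed_rmsd <- function(frameA, frameB) {
  if (!is.matrix(frameA) || !is.matrix(frameB) ||
      nrow(frameA) != nrow(frameB))
    stop("frames must be matrices with matching atom counts")
  cpp_pair_rmsd(frameA, frameB)
}

#' All-pairs superposed RMSD matrix of a trajectory
#'
#' @param traj a `glycan_trajectory`, or a bare `n_atoms x 3 x n_frames`
#'   coordinate array.
#' @return symmetric `n_frames x n_frames` matrix of minimal RMSDs (nm).
#' @export
rmsd_matrix <- function(traj) {
  co <- if (inherits(traj, "glycan_trajectory")) traj$coords else traj
  stopifnot(is.array(co), length(dim(co)) == 3L)
  cpp_rmsd_matrix(co)
}

## neighbour-counting clustering on a precomputed distance matrix
gromos_cluster_matrix <- function(D, cutoff) {
  nf <- nrow(D)
  adj <- D <= cutoff
  assignments <- integer(nf)
  centers <- integer(0)
  remaining <- seq_len(nf)
  k <- 0L
  while (length(remaining) > 0L) {
    sub <- adj[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub)
    if (max(counts) == 1) {
      ## every remaining frame is a singleton: extract in index order
      for (f in remaining) {
        k <- k + 1L
        assignments[f] <- k
        centers[k] <- f
      }
      break
    }
    i <- which.max(counts)            # ties: lowest frame index wins
    members <- remaining[sub[i, ]]
    k <- k + 1L
    assignments[members] <- k
    centers[k] <- remaining[i]
    remaining <- remaining[!sub[i, ]]
  }
  sizes <- tabulate(assignments, nbins = k)
  ## report clusters in size order (stable on ties: extraction order)
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k); remap[ord] <- seq_len(k)
  list(assignments = remap[assignments], centers = centers[ord],
       sizes = sizes[ord])
}

#' GROMOS conformer clustering
#'
#' Neighbour-counting algorithm: repeatedly take the unassigned frame with
#' the most neighbours within `cutoff` (superposed RMSD) as a cluster centre
#' together with its neighbours, remove them, and continue until every frame
#' is assigned.  Ties in neighbour count are broken towards the lowest frame
#' index, making the result deterministic.
#'
#' @param traj a `glycan_trajectory` (replicas are clustered jointly).
#' @param cutoff RMSD cutoff in nm.
#' @param D optional precomputed RMSD matrix (from [rmsd_matrix()]).
#' @return a `cluster_result`: per-frame `assignments`, cluster `centers`
#'   (representative frame indices), `sizes`, and the `cutoff`; clusters are
#'   numbered by size descending.
#' @export
gromos_cluster <- function(traj, cutoff, D = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is.null(D)) D <- rmsd_matrix(traj)
  if (nrow(D) == 0L) stop("empty trajectory")
  res <- gromos_cluster_matrix(D, cutoff)
  stopifnot(all(res$assignments > 0L), sum(res$sizes) == nrow(D))
  structure(c(res, list(cutoff = cutoff, n_frames = nrow(D))),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$sizes), "clusters over", x$n_frames,
      "frames (cutoff", x$cutoff, "nm)\n")
  k <- min(5L, length(x$sizes))
  cat("  top", k, "sizes:", paste(x$sizes[seq_len(k)], collapse = ", "),
      sprintf("(coverage %.1f%%)", 100 * sum(x$sizes[seq_len(k)]) / x$n_frames),
      "\n")
  invisible(x)
}

#' Coverage of the largest clusters
#'
#' @param result a `cluster_result`.
#' @param top_n number of clusters to pool (default 5).
#' @return fraction of frames in the `top_n` largest clusters.
#' @export
cluster_coverage <- function(result, top_n = 5L) {
  sum(result$sizes[seq_len(min(top_n, length(result$sizes)))]) / result$n_frames
}

#' Select the clustering cutoff by the coverage rule
#'
#' Returns the smallest cutoff on a grid for which the five largest GROMOS
#' clusters cover at least 90% of the frames.
#'
#' @param traj a `glycan_trajectory`.
#' @param grid candidate cutoffs in nm (default 0.05-1.0 by 0.01).
#' @param top_n,coverage the coverage rule (default: 5 clusters, 90%).
#' @param D optional precomputed RMSD matrix.
#' @return the selected cutoff in nm.
#' @export
select_cutoff <- function(traj, grid = seq(0.05, 1.0, by = 0.01),
                          top_n = 5L, coverage = 0.90, D = NULL) {
  if (is.null(D)) D <- rmsd_matrix(traj)
  if (nrow(D) == 0L) stop("empty trajectory")
  best <- 0
  for (cutoff in sort(grid)) {
    res <- gromos_cluster_matrix(D, cutoff)
    cov <- sum(res$sizes[seq_len(min(top_n, length(res$sizes)))]) / nrow(D)
    if (cov >= coverage) return(cutoff)
    best <- max(best, cov)
  }
  stop(sprintf(
    "no grid cutoff reaches %.0f%% coverage in the first %d clusters (best %.1f%%)",
    100 * coverage, top_n, 100 * best))
}

STATE_LEVELS <- c("broken_wing", "bird", "back_folded", "intermediate")

#' Label frames with named conformational states
#'
#' Classifies every frame by the position of the alpha1-6 antenna relative
#' to the inner core, in the oriented frame of the umbrella projection
#' (trunk along +z): `broken_wing` when the terminal Gal of the alpha1-6
#' antenna sits at small planar radial distance on the front half-plane
#' (along the trunk), `back_folded` when it sits at small radial distance on
#' the rear half-plane, `bird` when it sits far out with the antenna roughly
#' perpendicular to the trunk, and `intermediate` otherwise.
#'
#' @param traj a `glycan_trajectory` whose topology has an alpha1-6 antenna.
#' @param r_core radial threshold (nm) separating along-trunk from extended
#'   positions (default 0.8).
#' @param bird_angle allowed antenna-to-trunk angle range (degrees) for the
#'   `bird` state (default `c(45, 135)`).
#' @return a `state_series`: per-frame labels, pooled occupancy fractions,
#'   per-replica fractions, and the replica ids.
#' @export
label_states <- function(traj, r_core = 0.8, bird_angle = c(45, 135)) {
  topo <- traj$topology
  if (is.null(topo$antennas$ant2)) stop("topology has no alpha1-6 antenna")
  gal <- terminal_gal(topo, "ant2")
  tr <- orientation_transforms(traj)
  galp <- oriented_block_positions(traj, gal, tr)
  man4p <- oriented_block_positions(traj, "Man4p", tr)
  r <- sqrt(galp[, 1]^2 + galp[, 2]^2)
  v <- galp - man4p
  ang <- rad2deg(acos(pmin(1, pmax(-1, v[, 3] / sqrt(rowSums(v^2))))))
  lab <- rep("intermediate", n_frames(traj))
  near <- r <= r_core
  lab[near & galp[, 2] <= 0] <- "broken_wing"
  lab[near & galp[, 2] > 0] <- "back_folded"
  lab[!near & ang >= bird_angle[1] & ang <= bird_angle[2]] <- "bird"
  state_series(lab, traj$replica)
}

state_series <- function(labels, replica = rep(1L, length(labels))) {
  stopifnot(length(labels) == length(replica))
  frac <- function(l) {
    tab <- table(factor(l, levels = union(STATE_LEVELS, unique(l))))
    f <- as.numeric(tab) / length(l)
    names(f) <- names(tab)
    f
  }
  by_rep <- do.call(rbind, lapply(split(labels, replica), frac))
  structure(list(labels = labels, fractions = frac(labels),
                 by_replica = by_rep, replica = as.integer(replica)),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat("state_series over", length(x$labels), "frames\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Count transitions between two conformational states
#'
#' Counts crossings between states A and B where the newly entered state
#' persists for at least `debounce` frames; excursions shorter than the
#' debounce, and visits to other states, do not interrupt a dwell.  Counts
#' are accumulated per replica and summed, never across replica boundaries.
#'
#' @param states a `state_series`, or a character vector of labels (then
#'   `replica` may be given).
#' @param pair the two state labels to monitor (default bird/broken wing).
#' @param debounce minimum persistence in frames (>= 1).
#' @param replica per-frame replica ids when `states` is a plain vector.
#' @return integer transition count.
#' @export
count_transitions <- function(states, pair = c("broken_wing", "bird"),
                              debounce = 1L, replica = NULL) {
  if (inherits(states, "state_series")) {
    labels <- states$labels
    replica <- states$replica
  } else {
    labels <- as.character(states)
    if (is.null(replica)) replica <- rep(1L, length(labels))
  }
  if (debounce < 1) stop("debounce must be >= 1")
  if (length(pair) != 2L || anyDuplicated(pair))
    stop("pair must name two distinct states")
  known <- union(STATE_LEVELS, unique(labels))
  if (!all(pair %in% known))
    stop("unknown states: ", paste(setdiff(pair, known), collapse = ", "))
  count_one <- function(l) {
    l <- l[l %in% pair]          # other states do not interrupt a dwell
    r <- rle(l)
    v <- r$values[r$lengths >= debounce]
    if (length(v) < 2L) 0L else sum(v[-1L] != v[-length(v)])
  }
  sum(vapply(split(labels, replica), count_one, 0L))
}
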