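## Umbrella projection: orient each frame (root at the origin, inner core
## along +z, branch plane fixed), project antenna-terminal galactose centres
## onto the xy plane, build occupancy maps with spot detection, and
## correlate antenna-end distances with glycosidic torsions.

## Orientation of one frame from three block centres:
## - translate the root (Asn) centre to the origin;
## - rotate the inner-core vector (GlcNAc1 centre -> Man3 centre) onto +z;
## - rotate about z so the branch reference vector (Man4 centre - Man4p
##   centre) lies in the +x half of the xz plane.
## Returns list(origin, R) with oriented = (x - origin) %*% t(R).
frame_orientation <- function(asn, g1, m3, m4, m4p) {
  origin <- asn
  u <- m3 - g1
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("degenerate geometry: inner-core vector has zero length")
  R1 <- rotation_between(u / nu, c(0, 0, 1))
  w <- as.vector(R1 %*% (m4 - m4p))
  nw <- sqrt(sum(w[1:2]^2))
  if (nw < 1e-9) stop("degenerate geometry: branch vector parallel to z")
  ca <- w[1] / nw; sa <- w[2] / nw
  R2 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  list(origin = origin, R = R2 %*% R1)
}

## Per-frame orientations for a whole trajectory.
orientation_transforms <- function(traj) {
  topo <- traj$topology
  need <- c("Man4", "Man4p")
  if (!all(need %in% topo$blocks$label))
    stop("topology lacks the branch mannoses needed for orientation")
  asn <- block_com(traj, topo$blocks$label[match(topo$root, topo$blocks$block_id)])
  g1 <- block_com(traj, "GlcNAc1")
  m3 <- block_com(traj, "Man3")
  m4 <- block_com(traj, "Man4")
  m4p <- block_com(traj, "Man4p")
  nf <- n_frames(traj)
  Rs <- array(NA_real_, c(3, 3, nf))
  for (i in seq_len(nf)) {
    tr <- tryCatch(frame_orientation(asn[i, ], g1[i, ], m3[i, ], m4[i, ], m4p[i, ]),
                   error = function(e) stop("frame ", i, ": ", conditionMessage(e)))
    Rs[, , i] <- tr$R
  }
  list(origin = asn, R = Rs)
}

## Oriented centre positions of one block for all frames: n_frames x 3.
oriented_block_positions <- function(traj, label, transforms = NULL) {
  if (is.null(transforms)) transforms <- orientation_transforms(traj)
  com <- block_com(traj, label) - transforms$origin
  out <- matrix(NA_real_, nrow(com), 3)
  for (i in seq_len(nrow(com))) out[i, ] <- transforms$R[, , i] %*% com[i, ]
  out
}

#' Orient one frame for the umbrella projection
#'
#' Applies the rigid orientation transform: root block centre at the origin,
#' inner-core direction (GlcNAc1 centre to Man3 centre) along +z, and the
#' branch reference vector (Man4 centre minus Man4p centre) in the +x half
#' of the xz plane, so the alpha1-3 antenna populates x > 0.
#'
#' @param frame `n_atoms x 3` coordinate matrix (nm), or an `oriented_frame`
#'   (the transform is idempotent).
#' @param topo the `glycan_topology`.
#' @return an `oriented_frame`: `coords` plus the `transform` record
#'   (`origin` translation and 3x3 `rotation`).
#' @export
orient_frame <- function(frame, topo) {
  if (inherits(frame, "oriented_frame")) frame <- frame$coords
  stopifnot(is.matrix(frame), ncol(frame) == 3)
  com <- function(lab) frame_block_com(frame, topo, lab)
  root_lab <- topo$blocks$label[match(topo$root, topo$blocks$block_id)]
  tr <- frame_orientation(com(root_lab), com("GlcNAc1"), com("Man3"),
                          com("Man4"), com("Man4p"))
  oriented <- sweep(frame, 2, tr$origin) %*% t(tr$R)
  rownames(oriented) <- rownames(frame)
  structure(list(coords = oriented,
                 transform = list(origin = tr$origin, rotation = tr$R)),
            class = "oriented_frame")
}

#' Project antenna tips onto the oriented xy plane
#'
#' For every frame and every antenna, the (x, y) position of the terminal
#' galactose centre in the oriented frame: the area the antenna shadows on a
#' hypothetical protein surface under the glycan.
#'
#' @param traj a `glycan_trajectory`.
#' @param antennas antenna names (default: all antennas of the topology).
#' @return data frame with columns `frame`, `replica`, `antenna`, `block`,
#'   `x`, `y` (nm).
#' @export
project_antennas <- function(traj, antennas = NULL) {
  topo <- traj$topology
  if (is.null(antennas)) antennas <- names(topo$antennas)
  tr <- orientation_transforms(traj)
  out <- lapply(antennas, function(a) {
    gal <- terminal_gal(topo, a)
    p <- oriented_block_positions(traj, gal, tr)
    data.frame(frame = seq_len(n_frames(traj)), replica = traj$replica,
               antenna = a, block = gal, x = p[, 1], y = p[, 2])
  })
  do.call(rbind, out)
}

#' Radial distance of planar points from the origin
#'
#' @param point a length-2 `(x, y)` vector or a 2-column matrix of points
#'   (nm).
#' @return `sqrt(x^2 + y^2)`, one value per point.
#' @examples
#' radial_distance(c(0.7, -0.8))   # 1.06 to 2 d.p.
#' @export
radial_distance <- function(point) {
  if (is.null(dim(point))) {
    stopifnot(length(point) == 2L)
    point <- matrix(point, 1L)
  }
  sqrt(point[, 1]^2 + point[, 2]^2)
}

#' Occupancy map and spot detection for projected antenna positions
#'
#' Bins the projected points on a square grid, finds the connected regions
#' of bins whose density exceeds a floor, takes each region as a candidate
#' spot with its points' mean position as centroid, then assigns every frame
#' to the nearest spot centroid within `assign_radius` (frames farther from
#' every spot stay unassigned: the "spread" fraction).  Spot occupancy
#' fractions are assigned frames over total frames.
#'
#' @param points 2-column matrix or data frame of projected `(x, y)` points
#'   (nm), e.g. one antenna's rows from [project_antennas()].
#' @param bin_nm grid bin size in nm (default 0.1).
#' @param assign_radius frame-to-spot assignment radius in nm (default 0.4).
#' @param floor_frac density floor as a fraction of all frames (default
#'   0.01): bins below it do not seed spots.
#' @return an `umbrella_map`: the occupancy `grid`, detected `spots`
#'   (centroid x/y, occupancy fraction, radial distance, frames), the
#'   per-frame spot `assignment` (NA = spread), and the parameters.
#' @export
occupancy_spots <- function(points, bin_nm = 0.1, assign_radius = 0.4,
                            floor_frac = 0.01) {
  if (bin_nm <= 0) stop("bin size must be positive")
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 1L)
  n <- nrow(points)
  xb <- seq(floor(min(points[, 1]) / bin_nm) * bin_nm - bin_nm,
            ceiling(max(points[, 1]) / bin_nm) * bin_nm + bin_nm, by = bin_nm)
  yb <- seq(floor(min(points[, 2]) / bin_nm) * bin_nm - bin_nm,
            ceiling(max(points[, 2]) / bin_nm) * bin_nm + bin_nm, by = bin_nm)
  ix <- findInterval(points[, 1], xb, rightmost.closed = TRUE)
  iy <- findInterval(points[, 2], yb, rightmost.closed = TRUE)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  counts <- matrix(0L, nx, ny)
  for (k in seq_len(n)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  above <- counts >= max(1, floor_frac * n)

  ## connected components (8-neighbourhood) of above-floor bins
  comp <- matrix(0L, nx, ny)
  ncomp <- 0L
  for (sx in seq_len(nx)) for (sy in seq_len(ny)) {
    if (!above[sx, sy] || comp[sx, sy] != 0L) next
    ncomp <- ncomp + 1L
    queue <- list(c(sx, sy)); comp[sx, sy] <- ncomp
    while (length(queue) > 0L) {
      cur <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dx in -1:1) for (dy in -1:1) {
        qx <- cur[1] + dx; qy <- cur[2] + dy
        if (qx >= 1 && qx <= nx && qy >= 1 && qy <= ny &&
            above[qx, qy] && comp[qx, qy] == 0L) {
          comp[qx, qy] <- ncomp
          queue[[length(queue) + 1L]] <- c(qx, qy)
        }
      }
    }
  }

  point_comp <- comp[cbind(ix, iy)]
  spots <- NULL
  if (ncomp > 0L) {
    spots <- do.call(rbind, lapply(seq_len(ncomp), function(k) {
      ink <- point_comp == k
      data.frame(x = mean(points[ink, 1]), y = mean(points[ink, 2]))
    }))
    ## assign every frame to the nearest centroid within the radius
    d2 <- outer(points[, 1], spots$x, `-`)^2 + outer(points[, 2], spots$y, `-`)^2
    nearest <- max.col(-d2, ties.method = "first")
    ok <- d2[cbind(seq_len(n), nearest)] <= assign_radius^2
    assignment <- ifelse(ok, nearest, NA_integer_)
    spots$fraction <- as.numeric(tabulate(assignment[ok], nbins = ncomp)) / n
    spots$radial_nm <- radial_distance(cbind(spots$x, spots$y))
    spots$n_frames <- as.integer(tabulate(assignment[ok], nbins = ncomp))
    ord <- order(-spots$fraction)
    spots <- spots[ord, , drop = FALSE]
    rownames(spots) <- NULL
    assignment <- match(assignment, ord)
  } else {
    spots <- data.frame(x = numeric(0), y = numeric(0), fraction = numeric(0),
                        radial_nm = numeric(0), n_frames = integer(0))
    assignment <- rep(NA_integer_, n)
  }
  structure(list(
    points = points,
    grid = list(x_breaks = xb, y_breaks = yb, counts = counts,
                fraction = counts / n),
    spots = spots,
    assignment = assignment,
    bin_nm = bin_nm, assign_radius = assign_radius, floor_frac = floor_frac
  ), class = "umbrella_map")
}

#' @export
print.umbrella_map <- function(x, ...) {
  cat("umbrella_map:", nrow(x$points), "points,", nrow(x$spots), "spot(s),",
      sprintf("spread %.1f%%", 100 * mean(is.na(x$assignment))), "\n")
  if (nrow(x$spots) > 0) print(round(x$spots[, 1:4], 3))
  invisible(x)
}

#' Distance of an antenna tip from the inner core
#'
#' 3D distance between the antenna's terminal galactose centre and the
#' centre of the inner core (mean of the GlcNAc1, GlcNAc2 and Man3 block
#' centres); rigid-motion invariant, so no orientation is needed.
#'
#' @param traj a `glycan_trajectory`.
#' @param antenna antenna name (e.g. `"ant2"`).
#' @return numeric vector of distances (nm), one per frame.
#' @export
antenna_distance <- function(traj, antenna) {
  topo <- traj$topology
  gal <- block_com(traj, terminal_gal(topo, antenna))
  core_labels <- topo$blocks$label[match(topo$inner_core, topo$blocks$block_id)]
  core <- Reduce(`+`, lapply(core_labels, function(l) block_com(traj, l))) /
    length(core_labels)
  sqrt(rowSums((gal - core)^2))
}

#' Spearman rank correlation between a distance and a torsion series
#'
#' Rank correlation with average ranks on ties; the p-value uses the
#' large-sample normal approximation `z = rho * sqrt(n - 1)`.  Because
#' torsions are circular, the angle series is by default re-centred about
#' its circular mean before ranking, which moves the `+/-180` cut away from
#' the populated basins (a basin straddling the cut would otherwise be split
#' into the two ends of the rank scale).
#'
#' @param distance numeric vector (nm), e.g. from [antenna_distance()].
#' @param angle numeric vector of torsions (degrees) or a
#'   `dihedral_series`; must have the same length.
#' @param recenter re-centre the angles about their circular mean before
#'   ranking (default `TRUE`; set `FALSE` to rank the raw wrapped values).
#' @return list with `rho`, `p_value` and `n`.
#' @export
correlate_distance_dihedral <- function(distance, angle, recenter = TRUE) {
  angle <- series_values(angle)
  if (length(distance) != length(angle)) stop("series lengths differ")
  n <- length(distance)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(distance) == 0 || sd(angle) == 0)
    stop("constant series: correlation undefined")
  if (recenter) angle <- wrap_angle(angle - circular_mean(angle))
  rho <- stats::cor(rank(distance), rank(angle))
  z <- rho * sqrt(n - 1)
  list(rho = rho, p_value = 2 * pnorm(-abs(z)), n = n)
}
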