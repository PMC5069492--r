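## Glycosidic torsion measurement, circular histograms, modal decomposition
## (watershed basin assignment on the circle) and distribution comparison.

#' Measure one torsion of one linkage over a trajectory
#'
#' @param traj a `glycan_trajectory`.
#' @param linkage a linkage label (e.g. `"Man4p(a1-6)Man3"`) or a linkage
#'   object from [list_linkages()].
#' @param name `"phi"`, `"psi"` or `"omega"` (omega only for 1-6/2-6
#'   linkages).
#' @return a `dihedral_series`: per-frame angles in degrees in
#'   `(-180, 180]`, with the linkage/dihedral identity and replica ids.
#' @export
dihedral_series <- function(traj, linkage, name = c("phi", "psi", "omega")) {
  name <- match.arg(name)
  topo <- traj$topology
  if (is.character(linkage)) linkage <- get_linkage(topo, linkage)
  quad <- linkage$dihedral_defs[[name]]
  if (is.null(quad))
    stop("linkage '", linkage$label, "' (", linkage$linkage_code,
         ") has no ", name, " torsion")
  pts <- lapply(quad, function(q) {
    i <- atom_row(topo, q$block_id, q$atom_name)
    t(traj$coords[i, , , drop = TRUE])
  })
  vals <- compute_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  structure(list(linkage = linkage$label, dihedral = name, values = vals,
                 replica = traj$replica),
            class = "dihedral_series")
}

series_values <- function(x) {
  if (inherits(x, "dihedral_series")) x$values else as.numeric(x)
}

#' Normalised circular histogram of an angle series
#'
#' @param series a `dihedral_series` or numeric vector of angles (degrees;
#'   any representation, values are wrapped).
#' @param bin_width bin width in degrees; must divide 360.
#' @return an `angular_histogram`: bin breaks/mids on `(-180, 180]` and bin
#'   masses summing to 1.
#' @export
angular_histogram <- function(series, bin_width = 5) {
  v <- wrap_angle(series_values(series))
  if (length(v) == 0) stop("empty angle series")
  if (bin_width <= 0 || abs(360 / bin_width - round(360 / bin_width)) > 1e-9)
    stop("bin_width must be a positive divisor of 360")
  nb <- round(360 / bin_width)
  ## bins are (-180, -180 + w], ..., (180 - w, 180]
  idx <- ceiling((v + 180) / bin_width)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = nb)
  structure(list(
    breaks = seq(-180, 180, by = bin_width),
    mids = seq(-180 + bin_width / 2, 180 - bin_width / 2, by = bin_width),
    mass = counts / length(v),
    bin_width = bin_width,
    n = length(v)
  ), class = "angular_histogram")
}

circular_mean <- function(deg, w = rep(1, length(deg))) {
  th <- deg2rad(deg)
  wrap_angle(rad2deg(atan2(sum(w * sin(th)), sum(w * cos(th)))))
}

## indices i..j walking forward around a circle of nb bins
circ_span <- function(i, j, nb) {
  if (i <= j) i:j else c(i:nb, 1:j)
}

#' Decompose a circular histogram into modes and basins
#'
#' Finds the local maxima of the (lightly smoothed) histogram, drops peaks
#' below a relative prominence floor, places basin boundaries at the deepest
#' minima between adjacent peaks (circular watershed) and reports each
#' basin's occupancy fraction and circular-mean location.
#'
#' @param hist an `angular_histogram`.
#' @param min_peak_frac peaks whose (smoothed) height is below this fraction
#'   of the tallest peak are not counted as modes.
#' @param boundaries optional fixed basin boundaries (degrees) overriding the
#'   watershed.
#' @return a `modal_decomposition`: `modes` data frame (location, fraction,
#'   sorted by fraction descending) and the basin `boundaries` in degrees.
#' @export
modal_decomposition <- function(hist, min_peak_frac = 0.03, boundaries = NULL) {
  stopifnot(inherits(hist, "angular_histogram"))
  m <- hist$mass
  nb <- length(m)
  if (sum(m) == 0) stop("empty histogram")
  if (abs(sum(m) - 1) > 1e-9) stop("histogram is not normalised")

  if (!is.null(boundaries)) {
    bks <- sort(wrap_angle(boundaries))
    r <- findInterval(hist$mids, bks)
    r[r == 0L] <- length(bks)   # wrap: below first boundary joins above last
    basins <- unname(split(seq_len(nb), r))
  } else {
    ## light circular smoothing for peak finding only
    s <- (m + m[c(nb, 1:(nb - 1))] + m[c(2:nb, 1)]) / 3
    left <- s[c(nb, 1:(nb - 1))]; right <- s[c(2:nb, 1)]
    peaks <- which(s > left & s >= right & s > 0)
    if (length(peaks) == 0) peaks <- which.max(s)
    peaks <- peaks[s[peaks] >= min_peak_frac * max(s[peaks])]
    if (length(peaks) <= 1L) {
      basins <- list(seq_len(nb))
    } else {
      peaks <- sort(peaks)
      np <- length(peaks)
      cuts <- integer(np)   # boundary bin: last bin of the basin of peak i
      for (i in seq_len(np)) {
        nxt <- peaks[if (i == np) 1L else i + 1L]
        between <- circ_span(peaks[i], nxt, nb)
        between <- between[-c(1L, length(between))]
        cuts[i] <- if (length(between) == 0) peaks[i] else
          between[which.min(s[between])]
      }
      basins <- vector("list", np)
      for (i in seq_len(np)) {
        prev <- cuts[if (i == 1L) np else i - 1L]
        start <- if (prev == nb) 1L else prev + 1L
        basins[[i]] <- circ_span(start, cuts[i], nb)
      }
    }
  }

  modes <- do.call(rbind, lapply(basins, function(b) {
    frac <- sum(m[b])
    loc <- if (frac > 0) circular_mean(hist$mids[b], m[b]) else
      circular_mean(hist$mids[b])
    data.frame(location = loc, fraction = frac)
  }))
  modes <- modes[order(-modes$fraction), , drop = FALSE]
  rownames(modes) <- NULL
  bnd <- if (length(basins) > 1L && is.null(boundaries))
    sort(vapply(basins, function(b) hist$breaks[b[length(b)] + 1L], 0))
  else if (!is.null(boundaries)) sort(wrap_angle(boundaries)) else numeric(0)
  structure(list(modes = modes, boundaries = bnd, bin_width = hist$bin_width),
            class = "modal_decomposition")
}

#' Compare two angular distributions
#'
#' Reports the total-variation distance between two histograms on the same
#' binning and, after decomposing both, the per-mode occupancy shift with
#' modes matched by nearest circular location.
#'
#' @param histA,histB `angular_histogram` objects with identical binning.
#' @param ... passed to [modal_decomposition()].
#' @return a list with `tv_distance` in `[0, 1]` and a `mode_shifts` data
#'   frame (location and fraction in A, matched location and fraction in B,
#'   and the fraction shift B - A).
#' @export
compare_distributions <- function(histA, histB, ...) {
  stopifnot(inherits(histA, "angular_histogram"),
            inherits(histB, "angular_histogram"))
  if (!isTRUE(all.equal(histA$breaks, histB$breaks)))
    stop("histograms use different binning")
  tv <- 0.5 * sum(abs(histA$mass - histB$mass))
  da <- modal_decomposition(histA, ...)$modes
  db <- modal_decomposition(histB, ...)$modes
  circ_dist <- function(a, b) abs(wrap_angle(a - b))
  shifts <- do.call(rbind, lapply(seq_len(nrow(da)), function(i) {
    j <- which.min(circ_dist(da$location[i], db$location))
    data.frame(location_a = da$location[i], fraction_a = da$fraction[i],
               location_b = db$location[j], fraction_b = db$fraction[j],
               shift = db$fraction[j] - da$fraction[i])
  }))
  list(tv_distance = tv, mode_shifts = shifts)
}

#' @export
print.modal_decomposition <- function(x, ...) {
  cat("modal_decomposition:", nrow(x$modes), "mode(s)\n")
  print(round(x$modes, 3))
  invisible(x)
}
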