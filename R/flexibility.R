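## RMSF of antenna-terminal galactose centres with 10-ns block averaging,
## Welch comparison between chains, and block-level contact / difference
## maps.

## Superpose every frame onto a reference (fit on `fit_idx` atoms, transform
## applied to all atoms).  Returns the fitted coordinate array.
superpose_all <- function(traj, ref, fit_idx = NULL) {
  co <- traj$coords
  nf <- dim(co)[3]
  if (is.null(fit_idx)) fit_idx <- seq_len(dim(co)[1])
  if (length(fit_idx) == 0L) return(co)   # fit = "none"
  out <- co
  refF <- ref[fit_idx, , drop = FALSE]
  for (i in seq_len(nf)) {
    fr <- co[, , i]
    tr <- kabsch_transform(fr[fit_idx, , drop = FALSE], refF)
    out[, , i] <- apply_transform(fr, tr)
  }
  out
}

fit_indices <- function(topo, fit = c("all", "inner_core", "none")) {
  fit <- match.arg(fit)
  switch(fit,
         all = seq_len(nrow(topo$atoms)),
         inner_core = which(topo$atoms$block_id %in% topo$inner_core),
         none = integer(0))
}

#' Mean structure of a trajectory
#'
#' Per-atom mean coordinates after rigid superposition of every frame onto a
#' progressively refined reference: frames are first fitted to the initial
#' frame and averaged, then refitted to that average and averaged again
#' (two-pass).
#'
#' @param traj a `glycan_trajectory`.
#' @param fit fit group: `"all"` pseudo-atoms (default) or `"inner_core"`.
#' @param superpose set `FALSE` to average raw coordinates without fitting
#'   (useful when frames are already aligned).
#' @return `n_atoms x 3` reference coordinate matrix (nm).
#' @export
mean_structure <- function(traj, fit = "all", superpose = TRUE) {
  if (n_frames(traj) == 0L) stop("empty trajectory")
  if (!superpose) {
    m <- apply(traj$coords, c(1, 2), mean)
    rownames(m) <- traj$topology$atoms$atom_key
    return(m)
  }
  idx <- fit_indices(traj$topology, fit)
  ref <- get_frame(traj, 1L)
  for (pass in 1:2) {
    fitted <- superpose_all(traj, ref, idx)
    ref <- apply(fitted, c(1, 2), mean)
  }
  rownames(ref) <- traj$topology$atoms$atom_key
  ref
}

#' RMSF of block centres with block averaging
#'
#' Superposes all frames onto the mean structure, then computes, for each
#' target block, the root-mean-square fluctuation of its centre about the
#' mean position -- globally and within consecutive non-overlapping time
#' windows (block averaging; windows are aligned to replica starts and a
#' partial trailing window is dropped).  Three 500-ns replicas with 10-ns
#' windows give 150 window values per target.
#'
#' @param traj a `glycan_trajectory`.
#' @param targets block labels (default: the terminal Gal of every antenna).
#' @param window_ns block-averaging window length in ns (default 10).
#' @param fit fit group for the superposition: `"all"` (default),
#'   `"inner_core"`, or `"none"` for frames that are already aligned.
#' @return an `rmsf_result`: `global` data frame (block, rmsf_nm), `windows`
#'   data frame (block, replica, window, rmsf_nm), and the window length.
#' @export
rmsf <- function(traj, targets = NULL, window_ns = 10, fit = "all") {
  topo <- traj$topology
  if (is.null(targets))
    targets <- vapply(names(topo$antennas), function(a) terminal_gal(topo, a), "")
  invisible(block_id_of(topo, targets))   # validate labels
  wf <- round(window_ns * 1000 / traj$dt_ps)
  if (any(tabulate(factor(traj$replica)) < wf))
    stop("window (", window_ns, " ns) is longer than a replica")
  ref <- mean_structure(traj, fit = fit)
  fitted <- superpose_all(traj, ref, fit_indices(topo, fit))
  cm_row <- vapply(targets, function(b) atom_row(topo, block_id_of(topo, b), "CM"), 0L)
  glob <- data.frame(block = targets, rmsf_nm = NA_real_)
  windows <- list()
  for (t in seq_along(targets)) {
    com <- t(fitted[cm_row[t], , , drop = TRUE])      # n_frames x 3
    dev <- sweep(com, 2, colMeans(com))
    glob$rmsf_nm[t] <- sqrt(mean(rowSums(dev^2)))
    for (r in unique(traj$replica)) {
      i <- which(traj$replica == r)
      nwin <- length(i) %/% wf
      for (w in seq_len(nwin)) {
        j <- i[((w - 1) * wf + 1):(w * wf)]
        d <- sweep(com[j, , drop = FALSE], 2, colMeans(com[j, , drop = FALSE]))
        windows[[length(windows) + 1L]] <-
          data.frame(block = targets[t], replica = r, window = w,
                     rmsf_nm = sqrt(mean(rowSums(d^2))))
      }
    }
  }
  structure(list(global = glob, windows = do.call(rbind, windows),
                 window_ns = window_ns),
            class = "rmsf_result")
}

#' @export
print.rmsf_result <- function(x, ...) {
  cat("rmsf_result (", x$window_ns, "ns windows,",
      nrow(x$windows) / max(1, nrow(x$global)), "windows per block )\n")
  print(transform(x$global, rmsf_nm = round(rmsf_nm, 4)))
  invisible(x)
}

#' Compare two sets of window RMSF values
#'
#' Two-sided unequal-variance (Welch) t-test between the block-averaged
#' window RMSF values of two chains.
#'
#' @param windowsA,windowsB numeric vectors of window RMSF values (nm).
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `p_value`, `significant`, and the group sizes.
#' @export
compare_rmsf <- function(windowsA, windowsB, alpha = 0.05) {
  if (length(windowsA) < 2L || length(windowsB) < 2L)
    stop("need at least 2 window values per side")
  tt <- t.test(windowsA, windowsB, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha,
       n = c(length(windowsA), length(windowsB)), alpha = alpha)
}

#' Block-level contact map
#'
#' Entry (i, j) is the mean over frames of the smallest pseudo-atom distance
#' between blocks i and j in that frame (the CM centre marker is excluded).
#' The diagonal is zero by convention.
#'
#' @param traj a `glycan_trajectory`.
#' @return a `contact_map`: symmetric matrix (nm) with block labels as
#'   dimnames, plus the residue names for difference-map matching.
#' @export
contact_map <- function(traj) {
  topo <- traj$topology
  if (n_frames(traj) == 0L) stop("empty trajectory")
  labs <- topo$blocks$label
  nb <- length(labs)
  atom_sets <- lapply(topo$blocks$block_id, function(b)
    which(topo$atoms$block_id == b & topo$atoms$atom_name != "CM"))
  M <- matrix(0, nb, nb, dimnames = list(labs, labs))
  nf <- n_frames(traj)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      mind <- rep(Inf, nf)
      for (ai in atom_sets[[i]]) {
        pa <- traj$coords[ai, , , drop = TRUE]
        for (aj in atom_sets[[j]]) {
          d2 <- colSums((pa - traj$coords[aj, , , drop = TRUE])^2)
          mind <- pmin(mind, d2)
        }
      }
      M[i, j] <- M[j, i] <- mean(sqrt(mind))
    }
  }
  structure(list(matrix = M, labels = labs,
                 residues = topo$blocks$residue_name),
            class = "contact_map")
}

#' Difference between two contact maps
#'
#' Entrywise `mapA - mapB` over the blocks common to both maps.  The two
#' maps may differ only by NeuAc blocks (the desialylation edit); any other
#' mismatch is an error.  With the desialylated chain as `mapA`, positive
#' entries mark block pairs whose distance grew after removal of the sialic
#' acids.
#'
#' @param mapA,mapB `contact_map` objects.
#' @return signed matrix over the shared blocks (class `difference_map`).
#' @export
difference_map <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "contact_map"), inherits(mapB, "contact_map"))
  extra <- c(setdiff(mapA$labels, mapB$labels), setdiff(mapB$labels, mapA$labels))
  res <- c(mapA$residues[match(extra, mapA$labels)],
           mapB$residues[match(extra, mapB$labels)])
  if (any(stats::na.omit(res) != "NeuAc"))
    stop("maps differ by non-NeuAc blocks: ",
         paste(extra[which(res != "NeuAc")], collapse = ", "))
  shared <- intersect(mapA$labels, mapB$labels)
  D <- mapA$matrix[shared, shared] - mapB$matrix[shared, shared]
  class(D) <- c("difference_map", class(D))
  D
}
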