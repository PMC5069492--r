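## Trajectory file I/O (multi-model PDB and a plain CSV dialect) and run
## configuration.  Internal units are nm/ps; the PDB boundary converts to
## and from Angstrom.

PDB_RESNAME <- c(GlcNAc = "NAG", Man = "MAN", Gal = "GAL", NeuAc = "SIA",
                 Fuc = "FUC", Asn = "ASN")

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL per frame; pseudo-atoms are written as HETATM records with the
#' standard monosaccharide residue codes (NAG, MAN, GAL, SIA, FUC, ASN), the
#' block id as residue number, and coordinates in Angstrom.
#'
#' @param traj a `glycan_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  topo <- traj$topology
  at <- topo$atoms
  res <- PDB_RESNAME[topo$blocks$residue_name[match(at$block_id, topo$blocks$block_id)]]
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- get_frame(traj, f) * 10   # nm -> Angstrom
    writeLines(sprintf("HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_len(nrow(at)), at$atom_name, res, at$block_id,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' @param path PDB file with one MODEL per frame.
#' @param topology the `glycan_topology` the file refers to; atom names and
#'   order must match.
#' @param dt_ps frame spacing to attach (ps).
#' @param replica replica id to attach.
#' @return a `glycan_trajectory` (coordinates converted to nm).
#' @export
read_trajectory_pdb <- function(path, topology, dt_ps = 10, replica = 1L) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) stop("no MODEL records in ", path)
  is_atom <- grepl("^(HETATM|ATOM  )", lines)
  model_of <- findInterval(seq_along(lines), model_starts)
  keep <- is_atom & model_of > 0L
  counts <- tabulate(model_of[keep], nbins = length(model_starts))
  na <- nrow(topology$atoms)
  bad <- which(counts != na)
  if (length(bad) > 0L)
    stop("MODEL ", bad[1], " has ", counts[bad[1]], " atoms, expected ", na)
  rec <- lines[keep]
  num <- function(a, b) as.numeric(substr(rec, a, b))
  x <- num(31, 38); y <- num(39, 46); z <- num(47, 54)
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    badline <- which(keep)[which(is.na(x) | is.na(y) | is.na(z))[1]]
    stop("malformed coordinate record at line ", badline)
  }
  names_in <- trimws(substr(rec[seq_len(na)], 13, 16))
  if (!identical(names_in, topology$atoms$atom_name))
    stop("atom names/order do not match the topology")
  co <- array(c(rbind(x, y, z)), dim = c(3, na, length(model_starts)))
  co <- aperm(co, c(2, 1, 3)) / 10   # Angstrom -> nm
  glycan_trajectory(co, topology, dt_ps = dt_ps, replica = replica)
}

#' Write a trajectory in the plain CSV dialect
#'
#' Long-format text: one row per atom per frame with columns
#' `frame,time_ps,replica,block,atom,x,y,z` (nm), preceded by `#` header
#' lines recording the format and `dt_ps`.
#'
#' @param traj a `glycan_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  topo <- traj$topology
  at <- topo$atoms
  nf <- n_frames(traj)
  na <- nrow(at)
  block <- topo$blocks$label[match(at$block_id, topo$blocks$block_id)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# glycotraj-trajectory v1",
               paste0("# dt_ps: ", traj$dt_ps),
               "frame,time_ps,replica,block,atom,x,y,z"), con)
  for (f in seq_len(nf)) {
    xyz <- get_frame(traj, f)
    writeLines(sprintf("%d,%s,%d,%s,%s,%.9f,%.9f,%.9f",
                       f, format(traj$time_ps[f]), traj$replica[f],
                       block, at$atom_name, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a trajectory in the plain CSV dialect
#'
#' @param path file written by [write_trajectory_csv()] (or hand-written in
#'   the same layout).
#' @param topology the matching `glycan_topology`.
#' @return a `glycan_trajectory`.
#' @export
read_trajectory_csv <- function(path, topology) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  dt <- sub("^# dt_ps:\\s*", "", grep("^# dt_ps:", hdr, value = TRUE))
  dt <- if (length(dt) == 1L) as.numeric(dt) else 10
  tab <- read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  need <- c("frame", "time_ps", "replica", "block", "atom", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  na <- nrow(topology$atoms)
  frames <- sort(unique(tab$frame))
  if (nrow(tab) != na * length(frames))
    stop("atom count drift: ", nrow(tab), " rows for ", length(frames),
         " frames x ", na, " atoms")
  tab <- tab[order(tab$frame), ]
  key <- paste0(tab$block, ".", tab$atom)
  if (!identical(key[seq_len(na)], topology$atoms$atom_key))
    stop("atom keys/order do not match the topology")
  co <- array(NA_real_, c(na, 3L, length(frames)))
  co[, 1, ] <- matrix(tab$x, na); co[, 2, ] <- matrix(tab$y, na)
  co[, 3, ] <- matrix(tab$z, na)
  rep_id <- tab$replica[seq(1L, nrow(tab), by = na)]
  tm <- tab$time_ps[seq(1L, nrow(tab), by = na)]
  glycan_trajectory(co, topology, dt_ps = dt, replica = rep_id, time_ps = tm)
}

#' Read a trajectory file
#'
#' @param path file path.
#' @param topology the matching `glycan_topology`.
#' @param format `"pdb"` (multi-model PDB) or `"csv"`; guessed from the file
#'   extension by default.
#' @param ... passed to the format-specific reader.
#' @return a `glycan_trajectory`.
#' @export
read_trajectory <- function(path, topology, format = NULL, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "csv"
  switch(match.arg(format, c("pdb", "csv")),
         pdb = read_trajectory_pdb(path, topology, ...),
         csv = read_trajectory_csv(path, topology, ...))
}

#' Run configuration for the analysis pipeline
#'
#' Defaults mirror the reference sampling protocol: 3 replicas of 500 ns
#' stored every 10 ps (50,000 frames per replica), 10-ns RMSF windows, 5
#' degree histogram bins, 0.1 nm umbrella bins, and a 0.3 nm cluster cutoff
#' (set `cluster_cutoff = "auto"` for the smallest-cutoff coverage rule).
#'
#' @param chain chain abbreviation (see [chain_spec()]).
#' @param compare_desialylated also run the desialylated counterpart and
#'   emit difference outputs.
#' @param replicas number of replicas.
#' @param n_frames frames per replica.
#' @param dt_ps frame spacing (ps).
#' @param seed base seed; every random draw in the run derives from it.
#' @param cluster_cutoff RMSD cutoff in nm, or `"auto"`.
#' @param cluster_max_frames clustering is done on at most this many frames,
#'   taken with a uniform stride (the RMSD matrix is quadratic in this).
#' @param rmsf_window_ns,hist_bin_deg,umbrella_bin_nm,assign_radius_nm,debounce_frames
#'   analysis parameters (see the respective functions).
#' @param output_dir where [run_pipeline()] writes its files.
#' @return a validated `run_config` list.
#' @export
run_config <- function(chain = "Ng-c2Sf", compare_desialylated = TRUE,
                       replicas = 3L, n_frames = 50000L, dt_ps = 10,
                       seed = 1L, cluster_cutoff = 0.3,
                       cluster_max_frames = 1200L, rmsf_window_ns = 10,
                       hist_bin_deg = 5, umbrella_bin_nm = 0.1,
                       assign_radius_nm = 0.4, debounce_frames = 1L,
                       output_dir = "glycotraj-run") {
  cfg <- list(chain = chain, compare_desialylated = compare_desialylated,
              replicas = as.integer(replicas), n_frames = as.integer(n_frames),
              dt_ps = dt_ps, seed = as.integer(seed),
              cluster_cutoff = cluster_cutoff,
              cluster_max_frames = as.integer(cluster_max_frames),
              rmsf_window_ns = rmsf_window_ns, hist_bin_deg = hist_bin_deg,
              umbrella_bin_nm = umbrella_bin_nm,
              assign_radius_nm = assign_radius_nm,
              debounce_frames = as.integer(debounce_frames),
              output_dir = output_dir)
  invisible(chain_spec(chain))
  num <- c("replicas", "n_frames", "dt_ps", "rmsf_window_ns", "hist_bin_deg",
           "umbrella_bin_nm", "assign_radius_nm", "debounce_frames",
           "cluster_max_frames")
  for (f in num) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    stop("config field '", f, "' must be positive")
  if (!identical(cfg$cluster_cutoff, "auto") &&
      (!is.numeric(cfg$cluster_cutoff) || cfg$cluster_cutoff <= 0))
    stop("cluster_cutoff must be positive or \"auto\"")
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' Fields not present in the file keep their [run_config()] defaults.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## Deterministic fingerprint of a config (polynomial byte hash of its
## canonical JSON form); stamped into every output file header.
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(unclass(config)[sort(names(config))],
                                     auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
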