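## Block-level representation of branched N-glycan chains.
##
## A topology is a tree of monosaccharide blocks joined by glycosidic
## linkages.  Each block carries a small set of named pseudo-atoms: a ring
## triangle (O5 ring oxygen, C1 anomeric carbon, C5 exocyclic anchor), a CM
## centre marker (centroid of the triangle), and, per outgoing linkage, an
## attachment carbon/oxygen pair (e.g. C6/O6 for a 1-6 linkage).  Dihedral
## quadruples are stored as data on the linkage, so a different torsion
## convention is a topology edit, not a code change.
##
## Labels are ASCII-safe: a prime is written "p" (Man4p for Man4'), a double
## prime "pp" (Gal6pp).  The pretty unicode form is kept as display metadata.

CHAIN_VARIANTS <- data.frame(
  abbreviation = c("Ng-c2Sf", "Ng-c2f", "Ng-c2S", "Ng-c2",
                   "Ng-c3Sf", "Ng-c3f", "Ng-c3S", "Ng-c3"),
  n_antennas   = c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L),
  fucosylated  = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
  sialylated   = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

#' Chain variant specification
#'
#' Looks up one of the eight supported chain variants, named by the standard
#' abbreviations: `Ng-c2[S][f]` for bi-antennary and `Ng-c3[S][f]` for
#' tri-antennary chains, where `S` marks sialylation (a terminal NeuAc on
#' every antenna) and `f` core fucosylation (Fuc alpha1-6 on GlcNAc1).
#'
#' @param abbreviation one of `"Ng-c2Sf"`, `"Ng-c2f"`, `"Ng-c2S"`, `"Ng-c2"`,
#'   `"Ng-c3Sf"`, `"Ng-c3f"`, `"Ng-c3S"`, `"Ng-c3"`.
#' @return an object of class `chain_spec` with fields `abbreviation`,
#'   `n_antennas`, `fucosylated`, `sialylated`.
#' @export
chain_spec <- function(abbreviation) {
  i <- match(abbreviation, CHAIN_VARIANTS$abbreviation)
  if (is.na(i))
    stop("unknown chain abbreviation: '", abbreviation, "' (expected one of ",
         paste(CHAIN_VARIANTS$abbreviation, collapse = ", "), ")")
  structure(as.list(CHAIN_VARIANTS[i, ]), class = "chain_spec")
}

## abbreviation from the three flags (inverse of the table lookup)
abbreviation_for <- function(n_antennas, fucosylated, sialylated) {
  hit <- CHAIN_VARIANTS$n_antennas == n_antennas &
    CHAIN_VARIANTS$fucosylated == fucosylated &
    CHAIN_VARIANTS$sialylated == sialylated
  CHAIN_VARIANTS$abbreviation[hit]
}

linkage_display <- function(code) {
  code <- sub("^a", "α", code)
  sub("^b", "β", code)
}

label_display <- function(label) {
  out <- sub("pp$", "″", label)
  ifelse(grepl("″$", out), out, sub("p$", "′", out))
}

## position token of a linkage code: "a1-6" -> "6", "b1-N" -> "N"
linkage_pos <- function(code) sub("^.*-", "", code)

## codes carrying an omega torsion (exocyclic 6-position attachments)
has_omega <- function(code) linkage_pos(code) == "6"

## Block table of one chain variant: one row per block, parent by label.
variant_block_table <- function(n_antennas, fucosylated, sialylated) {
  rows <- list(
    c("Asn",      "Asn",    NA,         NA),
    c("GlcNAc1",  "GlcNAc", "Asn",      "b1-N"),
    if (fucosylated) c("Fuc1p", "Fuc", "GlcNAc1", "a1-6"),
    c("GlcNAc2",  "GlcNAc", "GlcNAc1",  "b1-4"),
    c("Man3",     "Man",    "GlcNAc2",  "b1-4"),
    c("Man4",     "Man",    "Man3",     "a1-3"),
    c("GlcNAc5",  "GlcNAc", "Man4",     "b1-2"),
    c("Gal6",     "Gal",    "GlcNAc5",  "b1-4"),
    if (sialylated) c("NeuAc7", "NeuAc", "Gal6", "a2-6"),
    c("Man4p",    "Man",    "Man3",     "a1-6"),
    c("GlcNAc5p", "GlcNAc", "Man4p",    "b1-2"),
    c("Gal6p",    "Gal",    "GlcNAc5p", "b1-4"),
    if (sialylated) c("NeuAc7p", "NeuAc", "Gal6p", "a2-6"),
    if (n_antennas == 3L) c("GlcNAc5pp", "GlcNAc", "Man4p",     "b1-4"),
    if (n_antennas == 3L) c("Gal6pp",    "Gal",    "GlcNAc5pp", "b1-4"),
    if (n_antennas == 3L && sialylated) c("NeuAc7pp", "NeuAc", "Gal6pp", "a2-6")
  )
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- c("label", "residue_name", "parent_label", "linkage_code")
  tab
}

## Construct a full glycan_topology from a block table.  Assigns sequential
## block ids in table order, derives pseudo-atoms, linkage dihedral
## quadruples, inner core, antennas, and a reference frame (all free
## dihedrals at 180 degrees) giving each block its local coordinates.
topology_from_blocks <- function(block_table, spec = NULL) {
  tab <- block_table
  rownames(tab) <- NULL
  tab$block_id <- seq_len(nrow(tab))
  if (anyDuplicated(tab$label))
    stop("block labels must be unique within a topology")
  tab$display_label <- label_display(tab$label)

  parent_id <- tab$block_id[match(tab$parent_label, tab$label)]
  if (sum(is.na(parent_id)) != 1L)
    stop("topology must have exactly one root block")
  root <- tab$block_id[is.na(parent_id)]

  linkages <- vector("list", nrow(tab) - 1L)
  k <- 0L
  for (i in seq_len(nrow(tab))) {
    if (is.na(parent_id[i])) next
    k <- k + 1L
    code <- tab$linkage_code[i]
    pos <- linkage_pos(code)
    p <- parent_id[i]; c_ <- tab$block_id[i]
    cx <- paste0("C", pos); ox <- paste0("O", pos)
    quad <- function(...) {
      q <- list(...)
      lapply(q, function(a) list(block_id = a[[1]], atom_name = a[[2]]))
    }
    dihedrals <- list(
      phi = quad(list(c_, "O5"), list(c_, "C1"), list(p, ox), list(p, cx)),
      psi = quad(list(c_, "C1"), list(p, ox), list(p, cx), list(p, "C5"))
    )
    if (has_omega(code))
      dihedrals$omega <- quad(list(p, ox), list(p, cx), list(p, "C5"), list(p, "O5"))
    linkages[[k]] <- structure(list(
      parent_block = p,
      child_block = c_,
      linkage_code = code,
      label = paste0(tab$label[i], "(", code, ")", tab$parent_label[i]),
      display_label = paste0(tab$display_label[i], "(", linkage_display(code),
                             ")", tab$display_label[match(p, tab$block_id)]),
      dihedral_defs = dihedrals
    ), class = "glycosidic_linkage")
  }
  ## root-first (breadth-first) linkage order
  ord <- order(match(vapply(linkages, `[[`, 1L, "parent_block"), tab$block_id),
               match(vapply(linkages, `[[`, 1L, "child_block"), tab$block_id))
  linkages <- linkages[ord]

  ## pseudo-atom table: ring triangle + centre, then attachment pairs
  atoms <- list()
  for (i in seq_len(nrow(tab))) {
    nm <- c("O5", "C1", "C5", "CM")
    kids <- which(parent_id == tab$block_id[i])
    for (j in kids) {
      pos <- linkage_pos(tab$linkage_code[j])
      nm <- c(nm, paste0("C", pos), paste0("O", pos))
    }
    if (anyDuplicated(nm))
      stop("block '", tab$label[i], "' has two children at the same position")
    atoms[[i]] <- data.frame(block_id = tab$block_id[i], atom_name = nm,
                             stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)
  atoms$atom_key <- paste0(tab$label[atoms$block_id], ".", atoms$atom_name)

  inner_core <- tab$block_id[match(c("GlcNAc1", "GlcNAc2", "Man3"), tab$label)]

  antenna_paths <- list(
    ant1 = c("Man4", "GlcNAc5", "Gal6", "NeuAc7"),
    ant2 = c("Man4p", "GlcNAc5p", "Gal6p", "NeuAc7p"),
    ant3 = c("Man4p", "GlcNAc5pp", "Gal6pp", "NeuAc7pp")
  )
  antennas <- lapply(antenna_paths, function(p) {
    ids <- tab$block_id[match(p, tab$label)]
    ids[!is.na(ids)]
  })
  antennas <- antennas[vapply(antennas, length, 1L) >= 2L]

  topo <- structure(list(
    blocks = tab[, c("block_id", "label", "display_label", "residue_name",
                     "parent_label", "linkage_code")],
    atoms = atoms,
    linkages = linkages,
    root = root,
    inner_core = inner_core,
    antennas = antennas,
    spec = spec
  ), class = "glycan_topology")

  ## reference frame (all free dihedrals trans) -> per-block local coordinates
  ref <- forward_kinematics(topo, trans_assignment(topo))
  topo$reference <- ref
  topo
}

trans_assignment <- function(topo) {
  a <- lapply(topo$linkages, function(lk) {
    v <- list(phi = 180, psi = 180)
    if (!is.null(lk$dihedral_defs$omega)) v$omega <- 180
    v
  })
  names(a) <- vapply(topo$linkages, `[[`, "", "label")
  a
}

#' Build a glycan chain topology
#'
#' Constructs the block-level topology of one of the eight chain variants:
#' the chitobiose/mannose inner core (GlcNAc1-GlcNAc2-Man3) carrying an
#' alpha1-3 antenna (Man4-GlcNAc5-Gal6), an alpha1-6 antenna
#' (Man4p-GlcNAc5p-Gal6p), optionally a third antenna on Man4p
#' (GlcNAc5pp beta1-4), optional terminal NeuAc alpha2-6 caps on each Gal,
#' and optional core fucosylation (Fuc1p alpha1-6 on GlcNAc1).  The chain is
#' rooted at an Asn attachment block.
#'
#' @param spec a [chain_spec()] or an abbreviation string such as
#'   `"Ng-c2Sf"`.
#' @return a `glycan_topology`: blocks, pseudo-atom table, linkages with
#'   phi/psi(/omega) dihedral quadruples, root, inner core, antenna paths,
#'   and a reference frame with all free dihedrals trans.
#' @examples
#' topo <- build_chain("Ng-c2Sf")
#' nrow(topo$blocks)       # Asn + 12 sugar blocks
#' length(topo$linkages)   # blocks - 1 (tree)
#' @export
build_chain <- function(spec) {
  if (is.character(spec)) spec <- chain_spec(spec)
  if (!inherits(spec, "chain_spec")) stop("spec must be a chain_spec or abbreviation")
  tab <- variant_block_table(spec$n_antennas, spec$fucosylated, spec$sialylated)
  topology_from_blocks(tab, spec = spec)
}

## Remove all blocks of one residue type (must be leaves) and rebuild.
remove_residue <- function(topo, residue, flag) {
  keep <- topo$blocks$residue_name != residue
  if (all(keep)) return(topo)
  victims <- topo$blocks$label[!keep]
  kids <- topo$blocks$parent_label %in% victims
  if (any(kids & keep))
    stop(residue, " blocks with children cannot be removed")
  tab <- topo$blocks[keep, c("label", "residue_name", "parent_label", "linkage_code")]
  spec <- topo$spec
  if (!is.null(spec)) {
    spec[[flag]] <- FALSE
    spec$abbreviation <- abbreviation_for(spec$n_antennas, spec$fucosylated,
                                          spec$sialylated)
  }
  topology_from_blocks(tab, spec = spec)
}

#' Remove terminal sialic acids from a topology
#'
#' Deletes every NeuAc block together with its linkage and the parent-side
#' attachment atoms, leaving the rest of the chain unchanged.  Applied to a
#' built variant this yields exactly the matching non-sialylated variant;
#' on an already non-sialylated chain it is a no-op.
#'
#' @param topo a `glycan_topology`.
#' @return the desialylated `glycan_topology`.
#' @examples
#' identical(desialylate(build_chain("Ng-c2Sf")), build_chain("Ng-c2f"))
#' @export
desialylate <- function(topo) {
  stopifnot(inherits(topo, "glycan_topology"))
  remove_residue(topo, "NeuAc", "sialylated")
}

#' Remove the core fucose from a topology
#'
#' Counterpart of [desialylate()] for the Fuc block.
#'
#' @param topo a `glycan_topology`.
#' @return the defucosylated `glycan_topology`.
#' @export
defucosylate <- function(topo) {
  stopifnot(inherits(topo, "glycan_topology"))
  remove_residue(topo, "Fuc", "fucosylated")
}

#' List the glycosidic linkages of a topology
#'
#' @param topo a `glycan_topology`.
#' @return the linkages in deterministic root-first order.
#' @export
list_linkages <- function(topo) {
  stopifnot(inherits(topo, "glycan_topology"))
  topo$linkages
}

#' Tabular summary of a topology's linkages
#'
#' @param topo a `glycan_topology`.
#' @return a data frame with one row per linkage: label, code, parent and
#'   child block labels, and which torsions (phi/psi/omega) it carries.
#' @export
linkage_table <- function(topo) {
  do.call(rbind, lapply(list_linkages(topo), function(lk) {
    data.frame(
      label = lk$label,
      linkage_code = lk$linkage_code,
      parent = topo$blocks$label[match(lk$parent_block, topo$blocks$block_id)],
      child = topo$blocks$label[match(lk$child_block, topo$blocks$block_id)],
      dihedrals = paste(names(lk$dihedral_defs), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
}

block_id_of <- function(topo, label) {
  id <- topo$blocks$block_id[match(label, topo$blocks$label)]
  if (anyNA(id)) stop("unknown block label: ", paste(label[is.na(id)], collapse = ", "))
  id
}

## Terminal galactose label of one antenna ("ant1", "ant2", "ant3")
terminal_gal <- function(topo, antenna) {
  ids <- topo$antennas[[antenna]]
  if (is.null(ids)) stop("topology has no antenna '", antenna, "'")
  labs <- topo$blocks$label[match(ids, topo$blocks$block_id)]
  gal <- labs[topo$blocks$residue_name[match(ids, topo$blocks$block_id)] == "Gal"]
  if (length(gal) != 1L) stop("antenna '", antenna, "' has no unique Gal block")
  gal
}

## linkage object by label
get_linkage <- function(topo, label) {
  labs <- vapply(topo$linkages, `[[`, "", "label")
  i <- match(label, labs)
  if (is.na(i)) stop("unknown linkage: '", label, "'")
  topo$linkages[[i]]
}

atom_row <- function(topo, block_id, atom_name) {
  i <- which(topo$atoms$block_id == block_id & topo$atoms$atom_name == atom_name)
  if (length(i) != 1L)
    stop("no pseudo-atom '", atom_name, "' in block id ", block_id)
  i
}

#' @export
print.glycan_topology <- function(x, ...) {
  ab <- if (!is.null(x$spec)) x$spec$abbreviation else "custom"
  cat("glycan_topology:", ab, "\n")
  cat("  blocks:", nrow(x$blocks), " linkages:", length(x$linkages),
      " pseudo-atoms:", nrow(x$atoms), "\n")
  cat("  antennas:", paste(names(x$antennas), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a topology to JSON
#'
#' Writes blocks, linkages with their dihedral quadruples, antenna paths and
#' the reference coordinates as a structured JSON file.
#'
#' @param topo a `glycan_topology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  obj <- list(
    format = "glycotraj-topology",
    version = 1L,
    spec = topo$spec[c("abbreviation", "n_antennas", "fucosylated", "sialylated")],
    blocks = topo$blocks[, c("label", "residue_name", "parent_label", "linkage_code")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a topology written by [write_topology()]
#'
#' @param path JSON file path.
#' @return a `glycan_topology`.
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "glycotraj-topology"))
    stop("not a glycotraj topology file: ", path)
  spec <- obj$spec
  if (!is.null(spec) && !is.null(spec$abbreviation)) spec <- chain_spec(spec$abbreviation)
  tab <- as.data.frame(obj$blocks, stringsAsFactors = FALSE)
  topology_from_blocks(tab, spec = spec)
}
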