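#' @name topology
#' @title Topology, frame and trajectory containers
#'
#' @description
#' Lightweight S3 containers shared by every analysis stage:
#' \describe{
#'   \item{`ip_topology`}{atom table (`atoms`) with one row per atom —
#'     columns `index` (0-based), `name`, `element`, `vdw_radius`,
#'     `residue_index`, `residue_name`, `chain`, `segment_class` — plus a
#'     derived residue table (`residues`).}
#'   \item{`ip_frame`}{`frame_index` (0-based), an n x 3 coordinate matrix in
#'     Angstrom and an optional orthorhombic `box` (three lengths, A).}
#'   \item{`ip_trajectory`}{one topology plus an ordered list of frames.}
#' }
#' `segment_class` is one of `protein`, `lipid`, `ion`, `solvent`, `other`,
#' inferred from the residue name.
NULL

.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
          "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL","HSD","HSE",
          "HSP","HID","HIE","HIP","MSE","CYX","GLH","ASH","LYN")
.lipids <- c("POPC","POPE","POPS","DPPC","DOPC","DMPC","POPG","CHL1","CHOL",
             "PSM","POPA",
             # 3-column truncations as written to standard PDB fields
             "POP","DPP","DOP","DMP","CHL")
.ions <- c("CL","CLA","NA","SOD","K","POT","MG","CAL","ZN","CA2","LIT","CES")
.waters <- c("HOH","TIP3","TIP","WAT","SOL","SPC","TIP4")

classify_segment <- function(residue_name) {
  rn <- toupper(trimws(residue_name))
  out <- rep("other", length(rn))
  out[rn %in% .aa3] <- "protein"
  out[rn %in% .lipids] <- "lipid"
  out[rn %in% .ions] <- "ion"
  out[rn %in% .waters] <- "solvent"
  out
}

#' Build a topology from an atom table
#'
#' @param atoms data.frame with columns `name`, `element`, `vdw_radius`,
#'   `residue_index`, `residue_name`, `chain`; `segment_class` and `index`
#'   are filled in when absent.
#' @return an `ip_topology`.
#' @export
ip_topology <- function(atoms) {
  need <- c("name", "element", "vdw_radius", "residue_index", "residue_name",
            "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop_ip("format_error", "atom table lacks column(s): %s",
            paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$vdw_radius)) || any(atoms$vdw_radius <= 0))
    stop_ip("config_error", "all vdW radii must be finite and > 0")
  atoms$index <- seq_len(nrow(atoms)) - 1L
  if (is.null(atoms$segment_class))
    atoms$segment_class <- classify_segment(atoms$residue_name)
  rid <- paste(atoms$chain, atoms$residue_index)
  first <- !duplicated(rid)
  residues <- data.frame(
    residue_index = atoms$residue_index[first],
    residue_name  = atoms$residue_name[first],
    chain         = atoms$chain[first],
    first_atom    = which(first) - 1L,
    n_atoms       = as.integer(table(factor(rid, levels = rid[first]))),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, residues = residues),
            class = "ip_topology")
}

#' @export
print.ip_topology <- function(x, ...) {
  cat(sprintf("ip_topology: %d atoms, %d residues (%s)\n",
              nrow(x$atoms), nrow(x$residues),
              paste(sprintf("%s: %d", names(table(x$atoms$segment_class)),
                            table(x$atoms$segment_class)), collapse = ", ")))
  invisible(x)
}

#' Construct a single coordinate frame
#'
#' @param coords n x 3 numeric matrix (A).
#' @param frame_index 0-based frame index.
#' @param box optional orthorhombic box lengths, length-3 numeric (A).
#' @return an `ip_frame`.
#' @export
ip_frame <- function(coords, frame_index = 0L, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop_ip("format_error", "coordinates must be an n x 3 matrix")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop_ip("format_error", "box must be three positive lengths")
  }
  structure(list(frame_index = as.integer(frame_index),
                 coords = unname(coords), box = box),
            class = "ip_frame")
}

#' Construct a trajectory
#'
#' @param topology an `ip_topology`.
#' @param frames list of `ip_frame`s sharing the topology's atom count;
#'   frame indices are renumbered 0..n-1 in list order.
#' @return an `ip_trajectory`.
#' @export
ip_trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "ip_topology"))
  nat <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != nat)
      stop_ip("topology_error",
              "frame %d has %d atoms; topology has %d",
              i, nrow(frames[[i]]$coords), nat)
    frames[[i]]$frame_index <- i - 1L
  }
  structure(list(topology = topology, frames = frames),
            class = "ip_trajectory")
}

#' @export
print.ip_trajectory <- function(x, ...) {
  cat(sprintf("ip_trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an `ip_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Select atom rows from a topology
#'
#' Returns 1-based row positions into `topology$atoms` matching every
#' criterion supplied (criteria combine with AND; `NULL` means "any").
#'
#' @param topology an `ip_topology`.
#' @param residues integer vector of residue indices, or NULL.
#' @param chain chain identifier(s), or NULL.
#' @param atom_names atom name(s) (e.g. `"CA"`), or NULL.
#' @param segment segment class(es), or NULL.
#' @param elements element symbol(s), or NULL.
#' @return integer vector of atom row positions (possibly empty).
#' @export
select_atoms <- function(topology, residues = NULL, chain = NULL,
                         atom_names = NULL, segment = NULL, elements = NULL) {
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(residues)) keep <- keep & a$residue_index %in% residues
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(atom_names)) keep <- keep & a$name %in% atom_names
  if (!is.null(segment)) keep <- keep & a$segment_class %in% segment
  if (!is.null(elements)) keep <- keep & toupper(a$element) %in% toupper(elements)
  which(keep)
}

# resolve a residue selection to Calpha rows, erroring with the residues
# that have no Calpha
select_calpha <- function(topology, residues, chain = NULL) {
  rows <- select_atoms(topology, residues = residues, chain = chain,
                       atom_names = "CA")
  found <- unique(topology$atoms$residue_index[rows])
  missing <- setdiff(residues, found)
  if (length(missing))
    stop_ip("selection_error", "no CA atom for residue(s): %s",
            paste(missing, collapse = ", "))
  rows
}
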