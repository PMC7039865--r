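#' Read a molecular structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), assigns van der Waals radii and
#' segment classes, and returns the topology together with the first
#' coordinate frame.  When alternate locations are present only the
#' highest-occupancy altloc of each atom is kept (ties: first encountered).
#'
#' @param path PDB file path.
#' @param radius_table element -> radius table from [vdw_radii()].
#' @return list with elements `topology` (an `ip_topology`) and `frame`
#'   (an `ip_frame`; the first MODEL of a multi-model file).
#' @seealso [read_trajectory()], [write_trajectory()]
#' @export
read_structure <- function(path, radius_table = vdw_radii()) {
  validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  atom <- pdb$atom
  keep <- filter_altloc(atom)
  atom <- atom[keep, , drop = FALSE]
  xyz1 <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
  element <- atom$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  element[bad] <- guess_element(atom$elety[bad])
  atoms <- data.frame(
    name = atom$elety,
    element = toupper(trimws(element)),
    vdw_radius = NA_real_,
    residue_index = atom$resno,
    residue_name = atom$resid,
    chain = ifelse(is.na(atom$chain), "A", atom$chain),
    stringsAsFactors = FALSE)
  atoms$vdw_radius <- assign_vdw(atoms$element, radius_table)
  box <- tryCatch({
    abc <- pdb$cryst1$abc
    if (!is.null(abc) && all(is.finite(abc)) && all(abc > 0)) abc else NULL
  }, error = function(e) NULL)
  list(topology = ip_topology(atoms),
       frame = ip_frame(xyz1, frame_index = 0L, box = box))
}

# fail early, with a line number, on ATOM/HETATM records whose coordinate
# field does not parse; also rejects files with no atom records at all
validate_pdb_lines <- function(path) {
  if (!file.exists(path))
    stop_ip("format_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(is_atom))
    stop_ip("format_error", "no ATOM/HETATM records in %s", path)
  for (i in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz))
      stop_ip("format_error", "unparseable coordinates at line %d of %s",
              i, path)
  }
  invisible(TRUE)
}

# keep highest-occupancy altloc per (chain, resno, insert, atom name)
filter_altloc <- function(atom) {
  alt <- atom$alt
  if (all(is.na(alt))) return(rep(TRUE, nrow(atom)))
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_len(nrow(atom)))
  first_of_key <- !duplicated(key[ord])
  keep <- logical(nrow(atom))
  keep[ord[first_of_key]] <- TRUE
  keep
}

#' Read a coordinate trajectory against a known topology
#'
#' Multi-model PDB files and CHARMM/NAMD-style DCD files are supported
#' (chosen by file extension).  Frames are returned in file order with
#' 0-based indices.
#'
#' @param topology an `ip_topology` the frames must match.
#' @param path trajectory file (`.pdb` or `.dcd`).
#' @return an `ip_trajectory`.
#' @export
read_trajectory <- function(topology, path) {
  nat <- nrow(topology$atoms)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    hdr <- dcd_header_info(path)
    if (hdr$natom != nat)
      stop_ip("topology_error",
              "trajectory has %d atoms; topology has %d", hdr$natom, nat)
    if (hdr$truncated)
      stop_ip("format_error",
              "truncated DCD: last complete frame is %d", hdr$n_complete)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    validate_pdb_lines(path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            rm.alt = FALSE, verbose = FALSE))
    keep <- filter_altloc(pdb$atom)
    if (sum(keep) != nat)
      stop_ip("topology_error",
              "trajectory has %d atoms; topology has %d", sum(keep), nat)
    cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                            3 * which(keep)))
    xyz <- pdb$xyz[, cols, drop = FALSE]
  }
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    ip_frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE), frame_index = i - 1L))
  ip_trajectory(topology, frames)
}

# parse the DCD header with base readBin; detects truncated files
dcd_header_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(rlen) || rlen != 84L)
    stop_ip("format_error", "not a DCD file: %s", path)
  tag <- readChar(con, 4)
  if (!identical(tag, "CORD"))
    stop_ip("format_error", "not a coordinate DCD: %s", path)
  icntrl <- readBin(con, "integer", 20, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little")
  tlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, tlen + 4L, origin = "current")
  readBin(con, "integer", 1, size = 4, endian = "little")
  natom <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little")
  header_end <- seek(con, 0L, origin = "current")
  fsize <- file.info(path)$size
  per_frame <- 3 * (8 + 4 * natom) + if (icntrl[11] == 1L) 8 + 48 else 0
  n_complete <- floor((fsize - header_end) / per_frame)
  truncated <- (fsize - header_end) %% per_frame != 0
  list(natom = natom, nframes = icntrl[1], n_complete = n_complete,
       truncated = truncated)
}

#' Write a trajectory to disk
#'
#' `.pdb` paths produce a multi-model PDB (MODEL/ENDMDL); `.dcd` paths a
#' little-endian CHARMM-format DCD.
#'
#' @param trajectory an `ip_trajectory`.
#' @param path output path ending in `.pdb` or `.dcd`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ip_trajectory"))
  xyz <- do.call(rbind, lapply(trajectory$frames, function(f)
    as.vector(t(f$coords))))
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    write_dcd(path, xyz)
  } else {
    a <- trajectory$topology$atoms
    # residue names are truncated to the standard 3-column PDB field;
    # 4-character force-field names (e.g. POPC) would otherwise shift the
    # coordinate columns
    bio3d::write.pdb(file = path, xyz = xyz, resno = a$residue_index,
                     resid = substr(a$residue_name, 1, 3), elety = a$name,
                     chain = substr(a$chain, 1, 1), elesy = a$element)
  }
  invisible(path)
}

# minimal CHARMM-format DCD writer (little endian, no unit cell record)
write_dcd <- function(path, xyz) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- nrow(xyz)
  nat <- ncol(xyz) %/% 3L
  wrec <- function(nbytes, payload) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  wrec(84L, function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(as.integer(icntrl), con, size = 4, endian = "little")
  })
  title <- sprintf("%-80s", "written by ionpath")
  wrec(84L, function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  })
  wrec(4L, function() writeBin(as.integer(nat), con, size = 4,
                               endian = "little"))
  idx <- seq_len(nat)
  for (i in seq_len(nf)) {
    fr <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    for (k in 1:3)
      wrec(4L * nat, function() writeBin(as.numeric(fr[, k]), con, size = 4,
                                         endian = "little"))
  }
  invisible(path)
}

#' Export tunnel spheres as PDB pseudo-atoms
#'
#' One HETATM per sphere; the sphere radius is written in the B-factor
#' column so molecular viewers can render the tunnel envelope.
#'
#' @param tunnels list of tunnels from [search_tunnels()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_tunnel_pdb <- function(tunnels, path) {
  rows <- list()
  n <- 0L
  for (ti in seq_along(tunnels)) {
    sp <- tunnels[[ti]]$spheres
    for (si in seq_len(nrow(sp))) {
      n <- n + 1L
      rows[[n]] <- sprintf(
        "HETATM%5d  O   TUN %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
        n %% 100000L, LETTERS[(ti - 1L) %% 26L + 1L], ti,
        sp$x[si], sp$y[si], sp$z[si], 1, sp$radius[si])
    }
  }
  writeLines(c(unlist(rows), "END"), path)
  invisible(path)
}

#' Write a table as TSV with commented header lines
#'
#' All pipeline outputs are tab-separated tables; `comments` lines are
#' prefixed with `#` so the files remain machine-readable.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param comments character vector of header comment lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
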