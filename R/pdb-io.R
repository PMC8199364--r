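# PDB I/O.  Parsing is delegated to bio3d::read.pdb; records are written
# with our own fixed-column formatter (TER between chains, element column,
# multi-model support).  All internal coordinates are nm; the only A<->nm
# conversion happens here.

element_from_name <- function(name) {
  stripped <- gsub("[0-9']", "", name)
  toupper(substr(stripped, 1L, 1L))
}

validate_pdb_lines <- function(lines, path) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  for (ln in which(is_atom)) {
    l <- lines[ln]
    if (nchar(l) < 54L) {
      stop(sprintf("malformed ATOM record at line %d of %s (too short)", ln, path))
    }
    coords <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                            substr(l, 47, 54))))
    if (any(is.na(coords))) {
      stop(sprintf("malformed ATOM record at line %d of %s (bad coordinate field)",
                   ln, path))
    }
  }
  invisible(TRUE)
}

model_atom_counts <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(integer())
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
  mapply(function(s, e) sum(grepl("^(ATOM  |HETATM)", lines[s:e])), starts, ends)
}

system_from_bio3d <- function(atom, xyz_row) {
  alt <- atom$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  if (any(!is.na(atom$insert) & atom$insert != "")) {
    stop("insertion codes are not supported")
  }
  atom <- atom[keep, , drop = FALSE]
  chain <- atom$chain
  chain[is.na(chain) | chain == ""] <- "X"
  element <- atom$elesy
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- element_from_name(atom$elety[missing_el])
  idx <- which(keep)
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  xyz <- matrix(xyz_row[cols], ncol = 3L, byrow = TRUE) / 10  # A -> nm
  atoms <- data.frame(serial = atom$eleno, name = atom$elety, element = element,
                      res_index = atom$resno, res_name = atom$resid,
                      chain_id = chain, stringsAsFactors = FALSE)
  molecular_system(atoms, xyz)
}

#' Read a PDB file into a molecular system
#'
#' Coordinates are converted from Angstrom (PDB convention) to nm.
#' Alternate-location indicators other than blank/'A' are dropped; insertion
#' codes are rejected.  For a multi-model file only the first model is
#' returned (use [read_trajectory()] for all models).
#'
#' @param path path to a PDB file.
#' @return a `molecular_system`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  system_from_bio3d(pdb$atom, pdb$xyz[1L, ])
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks must share one topology (same atoms in the same
#' order).  A file without MODEL records is read as a single-frame
#' trajectory.
#'
#' @param path path to a (multi-model) PDB file.
#' @param times optional frame times (ns); overrides `dt`.
#' @param dt optional uniform frame spacing (ns); default 1 ns per frame
#'   starting at 0.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, times = NULL, dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  counts <- model_atom_counts(lines)
  if (length(counts) > 1L && length(unique(counts)) != 1L) {
    stop("topology mismatch: MODEL blocks contain ",
         paste(unique(counts), collapse = ", "), " atoms")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nm <- nrow(pdb$xyz)
  topo <- system_from_bio3d(pdb$atom, pdb$xyz[1L, ])
  alt <- pdb$atom$alt
  keep <- which(is.na(alt) | alt == "" | alt == "A")
  cols <- as.vector(rbind(3L * keep - 2L, 3L * keep - 1L, 3L * keep))
  frames <- lapply(seq_len(nm), function(k) {
    matrix(pdb$xyz[k, cols], ncol = 3L, byrow = TRUE) / 10
  })
  if (is.null(times)) {
    step <- if (is.null(dt)) 1 else dt
    times <- (seq_len(nm) - 1L) * step
  }
  trajectory(topo, frames, times)
}

format_atom_line <- function(serial, name, res_name, chain_id, res_index, xyz_A,
                             element) {
  aname <- if (nchar(name) < 4L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, aname, res_name, chain_id, res_index,
          xyz_A[1L], xyz_A[2L], xyz_A[3L], 1, 0, element)
}

system_record_lines <- function(system, xyz = NULL) {
  if (is.null(xyz)) xyz <- system$xyz
  a <- system$atoms
  xyz_A <- xyz * 10
  lines <- character(0L)
  for (ch in system$chains) {
    rows <- which(a$chain_id == ch)
    lines <- c(lines,
               vapply(rows, function(i) {
                 format_atom_line(a$serial[i], a$name[i], a$res_name[i],
                                  a$chain_id[i], a$res_index[i], xyz_A[i, ],
                                  a$element[i])
               }, character(1L)),
               "TER")
  }
  lines
}

#' Write a molecular system to a PDB file
#'
#' Fixed-column ATOM records in Angstrom, a TER record after each chain and
#' a terminating END record.
#'
#' @param system a `molecular_system`.
#' @param path output path.
#' @export
write_pdb <- function(system, path) {
  stopifnot(inherits(system, "molecular_system"))
  writeLines(c(system_record_lines(system), "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  blocks <- lapply(seq_along(traj$frames), function(k) {
    c(sprintf("MODEL %8d", k),
      system_record_lines(traj$topology, traj$frames[[k]]),
      "ENDMDL")
  })
  writeLines(c(unlist(blocks), "END"), path)
  invisible(path)
}

#' Read a region annotation table
#'
#' Plain-text whitespace-separated table with header columns `chain`,
#' `res_start`, `res_end`, `label`, `hydrophobic`.
#'
#' @param path path to the annotation file.
#' @return a `region_annotation`.
#' @export
read_annotation <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "chain"] <- "chain_id"
  tab$hydrophobic <- as.logical(tab$hydrophobic)
  region_annotation(tab)
}

#' Write a region annotation table
#'
#' Inverse of [read_annotation()]: contiguous equal-label runs are collapsed
#' back to ranges.
#'
#' @param annotation a `region_annotation`.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  rows <- list()
  for (ch in unique(annotation$chain_id)) {
    sub <- annotation[annotation$chain_id == ch, ]
    sub <- sub[order(sub$res_index), ]
    run_key <- paste(sub$label, sub$hydrophobic)
    grp <- cumsum(c(TRUE, run_key[-1L] != run_key[-nrow(sub)]))
    for (g in unique(grp)) {
      s <- sub[grp == g, ]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, res_start = min(s$res_index), res_end = max(s$res_index),
        label = s$label[1L], hydrophobic = s$hydrophobic[1L],
        stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, rows), path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
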