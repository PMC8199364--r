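#' helixtraj: trajectory analysis of alpha-helical bundle proteins
#'
#' Tools for the structural analysis of molecular-dynamics trajectories of
#' four-alpha-helical bundle proteins (helical hairpin dimers and loopless
#' four-helix tetramers): superposed deviation metrics (RMSD, relative
#' deviation between thermal conditions, per-residue RMSF), geometric
#' hydrogen-bond detection and classification, hydrophobic C-beta contact
#' distributions, backbone torsion / Ramachandran analysis, alpha-helix
#' geometry metrics, and block-averaged summaries.  A synthetic builder
#' constructs ideal bundles from backbone internal coordinates and generates
#' noisy trajectories with known ground truth so every analysis stage can be
#' validated against analytic expectations.
#'
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.table write.csv write.table packageVersion
#' @keywords internal
"_PACKAGE"

# Region labels recognised in annotations.
REGION_LABELS <- c("N_TAIL", "HELIX1", "LOOP", "HELIX2", "C_TAIL", "HELIX")

# Default hydrophobic residue classification (configurable downstream).
HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP")

# Atomic masses (u) for the elements the package handles.
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

WATER_RESNAMES <- c("HOH", "SOL", "WAT")

#' Molecular system container
#'
#' A molecular system is an ordered set of atoms grouped into residues and
#' chains, with Cartesian coordinates in nanometres and an optional
#' orthorhombic periodic box.
#'
#' @param atoms data.frame with columns `serial` (integer >= 1), `name`
#'   (atom name, e.g. "CA"), `element` (element symbol), `res_index`
#'   (1-based residue index within its chain), `res_name` (3-letter code),
#'   `chain_id` (single character).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @param box optional numeric length-3 vector of box edge lengths in nm.
#' @return object of class `molecular_system` with elements `atoms`, `xyz`,
#'   `chains` (ordered unique chain ids) and `box`.
#' @export
molecular_system <- function(atoms, xyz, box = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  required <- c("serial", "name", "element", "res_index", "res_name", "chain_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("molecular_system needs at least one atom")
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L) {
    stop("xyz must be an n_atoms x 3 matrix matching the atoms table")
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$name <- as.character(atoms$name)
  atoms$res_name <- as.character(atoms$res_name)
  atoms$element <- as.character(atoms$element)
  atoms$res_index <- as.integer(atoms$res_index)
  atoms$serial <- as.integer(atoms$serial)
  key <- paste(atoms$chain_id, atoms$res_index, atoms$name)
  if (anyDuplicated(key)) {
    stop("(chain_id, res_index, name) must be unique; first duplicate: ",
         key[duplicated(key)][1L])
  }
  chains <- unique(atoms$chain_id)
  # residue indices within each chain must be contiguous and ascending
  for (ch in chains) {
    ri <- atoms$res_index[atoms$chain_id == ch]
    u <- unique(ri)
    if (any(diff(u) < 0L)) stop("residue indices not ascending in chain ", ch)
    if (!identical(u, seq(u[1L], u[length(u)]))) {
      stop("residue indices not contiguous in chain ", ch)
    }
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be 3 positive finite edge lengths (nm)")
    }
  }
  rownames(xyz) <- NULL
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz, chains = chains, box = box),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain_id", "res_index")]))
  cat(sprintf("<molecular_system> %d atoms, %d residues, chains: %s%s\n",
              nrow(x$atoms), nres, paste(x$chains, collapse = ","),
              if (is.null(x$box)) "" else
                sprintf(", box %.2fx%.2fx%.2f nm", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

n_atoms <- function(system) nrow(system$atoms)

#' Per-residue table of a system
#'
#' @param system a `molecular_system`.
#' @return data.frame with one row per residue: `chain_id`, `res_index`,
#'   `res_name`, ordered as in the system.
#' @export
residue_table <- function(system) {
  a <- system$atoms
  keep <- !duplicated(paste(a$chain_id, a$res_index))
  out <- a[keep, c("chain_id", "res_index", "res_name")]
  rownames(out) <- NULL
  out
}

is_water_atom <- function(atoms) atoms$res_name %in% WATER_RESNAMES

#' Trajectory container
#'
#' Ordered coordinate frames over a fixed topology, with strictly increasing
#' timestamps in nanoseconds.
#'
#' @param topology a `molecular_system` providing atom identities (its own
#'   coordinates are frame 0 metadata only and are not part of the frames).
#' @param frames list of n_atoms x 3 coordinate matrices (nm).
#' @param times numeric vector of frame times (ns), strictly increasing;
#'   defaults to `0:(n_frames-1)`.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL) {
  if (!inherits(topology, "molecular_system")) stop("topology must be a molecular_system")
  if (!is.list(frames) || length(frames) == 0L) stop("frames must be a non-empty list")
  na <- n_atoms(topology)
  frames <- lapply(seq_along(frames), function(k) {
    f <- as.matrix(frames[[k]])
    if (nrow(f) != na || ncol(f) != 3L) {
      stop(sprintf("frame %d has %d atoms; topology has %d (topology mismatch)",
                   k, nrow(f), na))
    }
    if (!all(is.finite(f))) stop(sprintf("frame %d contains non-finite coordinates", k))
    storage.mode(f) <- "double"
    dimnames(f) <- NULL
    f
  })
  if (is.null(times)) times <- as.numeric(seq_along(frames) - 1L)
  if (length(times) != length(frames)) stop("times and frames lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %.3f..%.3f ns\n",
              length(x$frames), n_atoms(x$topology),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Per-residue region annotation
#'
#' Structural labels (N_TAIL / HELIX1 / LOOP / HELIX2 / C_TAIL / HELIX) and
#' hydrophobicity flags over contiguous residue ranges.  Labels must
#' partition each annotated chain's residues without gaps, and a chain
#' carrying HELIX1/HELIX2 must have a non-empty LOOP between them.
#'
#' @param ranges data.frame with columns `chain_id`, `res_start`, `res_end`,
#'   `label`, `hydrophobic` (logical; may be NA meaning "classify by residue
#'   name downstream").
#' @return object of class `region_annotation`: per-residue data.frame with
#'   columns `chain_id`, `res_index`, `label`, `hydrophobic`.
#' @export
region_annotation <- function(ranges) {
  required <- c("chain_id", "res_start", "res_end", "label")
  if (!all(required %in% names(ranges))) {
    stop("annotation ranges need columns chain_id, res_start, res_end, label")
  }
  if (is.null(ranges$hydrophobic)) ranges$hydrophobic <- NA
  bad <- setdiff(unique(ranges$label), REGION_LABELS)
  if (length(bad) > 0L) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    if (r$res_end < r$res_start) stop("res_end < res_start in annotation row ", i)
    data.frame(chain_id = as.character(r$chain_id),
               res_index = seq(r$res_start, r$res_end),
               label = as.character(r$label),
               hydrophobic = as.logical(r$hydrophobic),
               stringsAsFactors = FALSE)
  })
  per_res <- do.call(rbind, rows)
  for (ch in unique(per_res$chain_id)) {
    sub <- per_res[per_res$chain_id == ch, ]
    ri <- sort(sub$res_index)
    if (anyDuplicated(ri)) stop("overlapping annotation ranges in chain ", ch)
    if (!identical(ri, seq(ri[1L], ri[length(ri)]))) {
      stop("annotation leaves gaps in chain ", ch)
    }
    labs <- sub$label[order(sub$res_index)]
    if (all(c("HELIX1", "HELIX2") %in% labs)) {
      between <- labs[seq(max(which(labs == "HELIX1")) + 1L,
                          min(which(labs == "HELIX2")) - 1L)]
      if (!any(between == "LOOP")) {
        stop("chain ", ch, " has HELIX1 and HELIX2 but no LOOP between them")
      }
    }
  }
  per_res <- per_res[order(match(per_res$chain_id, unique(per_res$chain_id)),
                           per_res$res_index), ]
  rownames(per_res) <- NULL
  structure(per_res, class = c("region_annotation", "data.frame"))
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation> %d residues, chains: %s\n",
              nrow(x), paste(unique(x$chain_id), collapse = ",")))
  invisible(NextMethod())
}

#' Helix residue ranges from an annotation
#'
#' @param annotation a `region_annotation`.
#' @return data.frame with columns `chain_id`, `label`, `res_start`,
#'   `res_end`, `helix_id` (e.g. "A1" for HELIX1 of chain A, "A" for a
#'   single-HELIX chain), one row per annotated helix.
#' @export
helix_ranges <- function(annotation) {
  hx <- annotation[annotation$label %in% c("HELIX", "HELIX1", "HELIX2"), ]
  if (nrow(hx) == 0L) return(data.frame(chain_id = character(), label = character(),
                                        res_start = integer(), res_end = integer(),
                                        helix_id = character(), stringsAsFactors = FALSE))
  key <- paste(hx$chain_id, hx$label)
  out <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- hx[key == k, ]
    data.frame(chain_id = sub$chain_id[1L], label = sub$label[1L],
               res_start = min(sub$res_index), res_end = max(sub$res_index),
               stringsAsFactors = FALSE)
  }))
  out$helix_id <- ifelse(out$label == "HELIX", out$chain_id,
                         paste0(out$chain_id, sub("HELIX", "", out$label)))
  out <- out[order(out$chain_id, out$res_start), ]
  rownames(out) <- NULL
  out
}

#' Hydrophobic flags resolved per residue
#'
#' Uses annotation flags where set, falling back to a residue-name
#' classification where the flag is NA.
#'
#' @param system a `molecular_system`.
#' @param annotation a `region_annotation` or NULL.
#' @param residue_set character vector of hydrophobic 3-letter codes used
#'   for the fallback classification.
#' @return per-residue data.frame `chain_id`, `res_index`, `hydrophobic`.
#' @export
hydrophobic_flags <- function(system, annotation = NULL,
                              residue_set = HYDROPHOBIC_RESIDUES) {
  res <- residue_table(system)
  res$hydrophobic <- res$res_name %in% residue_set
  if (!is.null(annotation)) {
    key_sys <- paste(res$chain_id, res$res_index)
    key_ann <- paste(annotation$chain_id, annotation$res_index)
    m <- match(key_sys, key_ann)
    flagged <- !is.na(m) & !is.na(annotation$hydrophobic[m])
    res$hydrophobic[flagged] <- annotation$hydrophobic[m[flagged]]
  }
  res[, c("chain_id", "res_index", "hydrophobic")]
}
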