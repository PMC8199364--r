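# Atom selection.  A selection is an ordered set of references
# (chain_id, res_index, name) into a molecular system, stored with the
# resolved row indices.  Order is deterministic: chain order of the system,
# then residue index, then atom order within the residue (file order).

BACKBONE_ATOMS <- c("N", "H", "CA", "C", "O")
WATER_ATOMS <- c("OW", "O", "HW1", "HW2", "H1", "H2")

new_selection <- function(system, idx) {
  idx <- as.integer(idx)
  a <- system$atoms[idx, , drop = FALSE]
  refs <- data.frame(chain_id = a$chain_id, res_index = a$res_index,
                     name = a$name, stringsAsFactors = FALSE)
  rownames(refs) <- NULL
  structure(list(refs = refs, index = idx), class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> %d atoms (%s)\n", length(x$index),
              paste(unique(x$refs$name), collapse = ",")))
  invisible(x)
}

#' @export
length.atom_selection <- function(x) length(x$index)

#' Resolve a selection against a (possibly different) system
#'
#' References are matched by (chain_id, res_index, name); all must resolve.
#'
#' @param selection an `atom_selection`.
#' @param system a `molecular_system` sharing the referenced atoms.
#' @return integer atom row indices into `system`.
#' @export
resolve_selection <- function(selection, system) {
  key_sys <- paste(system$atoms$chain_id, system$atoms$res_index, system$atoms$name)
  key_sel <- paste(selection$refs$chain_id, selection$refs$res_index,
                   selection$refs$name)
  m <- match(key_sel, key_sys)
  if (anyNA(m)) {
    stop("selection reference does not resolve: ", key_sel[which(is.na(m))[1L]])
  }
  m
}

#' Select atoms from a molecular system
#'
#' Deterministic, order-stable atom selection by atom class, chain, region
#' and tail/head exclusion rules.  The exclusion rule `"tail7"` removes the
#' last 7 residues of each selected chain and `"head4"` the first 4 (the
#' conventions used when comparing helical-bundle C-alpha sets whose termini
#' are flexible or unresolved).
#'
#' @param system a `molecular_system`.
#' @param atoms atom class: `"CA"`, `"CB"`, `"backbone"` (N, H, CA, C, O),
#'   `"water"`, or a character vector of explicit atom names.
#' @param chains chains to include (default: all protein chains for protein
#'   atom classes, water chains for `"water"`).
#' @param annotation optional `region_annotation` used with `region`.
#' @param region optional region label(s) to restrict to (e.g. `"HELIX1"`).
#' @param exclude character vector of exclusion rules among `"tail7"`,
#'   `"head4"`.
#' @return an `atom_selection`.
#' @export
select_atoms <- function(system, atoms = "CA", chains = NULL,
                         annotation = NULL, region = NULL, exclude = NULL) {
  a <- system$atoms
  water <- is_water_atom(a)
  if (identical(atoms, "water")) {
    keep_name <- water
  } else {
    names_wanted <- switch(atoms[1L],
                           CA = "CA", CB = "CB", backbone = BACKBONE_ATOMS,
                           atoms)
    if (length(atoms) > 1L) names_wanted <- atoms
    keep_name <- !water & a$name %in% names_wanted
  }
  if (is.null(chains)) {
    chains <- unique(a$chain_id[keep_name])
  } else {
    unknown <- setdiff(chains, system$chains)
    if (length(unknown) > 0L) {
      stop("unknown chain(s) in selection spec: ", paste(unknown, collapse = ", "))
    }
  }
  keep <- keep_name & a$chain_id %in% chains
  if (!is.null(region)) {
    if (is.null(annotation)) stop("region selection requires an annotation")
    bad <- setdiff(region, REGION_LABELS)
    if (length(bad) > 0L) stop("unknown region label(s): ", paste(bad, collapse = ", "))
    ann <- annotation[annotation$label %in% region, ]
    key_sys <- paste(a$chain_id, a$res_index)
    keep <- keep & key_sys %in% paste(ann$chain_id, ann$res_index)
  }
  if (!is.null(exclude)) {
    bad <- setdiff(exclude, c("tail7", "head4"))
    if (length(bad) > 0L) stop("unknown exclusion rule(s): ", paste(bad, collapse = ", "))
    for (ch in chains) {
      in_ch <- a$chain_id == ch & !water
      if (!any(in_ch)) next
      ri <- range(a$res_index[in_ch])
      drop <- rep(FALSE, nrow(a))
      if ("tail7" %in% exclude) {
        drop <- drop | (in_ch & a$res_index > ri[2L] - 7L)
      }
      if ("head4" %in% exclude) {
        drop <- drop | (in_ch & a$res_index < ri[1L] + 4L)
      }
      keep <- keep & !drop
    }
  }
  idx <- which(keep)
  # deterministic order: chain order as in the system, then residue, then
  # file order of atoms within the residue
  ord <- order(match(a$chain_id[idx], system$chains), a$res_index[idx], idx)
  new_selection(system, idx[ord])
}

#' Coordinates of a selection in one frame
#'
#' @param selection an `atom_selection`.
#' @param source a `molecular_system`, a coordinate matrix, or a
#'   `trajectory` (with `frame` given).
#' @param frame frame number when `source` is a trajectory.
#' @return m x 3 coordinate matrix (nm).
#' @export
selection_coords <- function(selection, source, frame = NULL) {
  if (inherits(source, "trajectory")) {
    if (is.null(frame)) stop("frame index required for a trajectory source")
    return(source$frames[[frame]][selection$index, , drop = FALSE])
  }
  if (inherits(source, "molecular_system")) {
    return(source$xyz[selection$index, , drop = FALSE])
  }
  as.matrix(source)[selection$index, , drop = FALSE]
}
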