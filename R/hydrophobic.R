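# Hydrophobic-contact analysis: cross-set radial distribution functions
# between C-beta atoms of hydrophobic residues and hydrophobic
# centre-of-mass distances.

#' Hydrophobic C-beta selections grouped per chain or per chain pair
#'
#' Selects the C-beta atoms of hydrophobic residues and groups them per
#' chain (hairpin-dimer mode: interchain contacts) or per chain pair AB vs
#' CD (four-chain tetramer mode: interpair contacts).
#'
#' @param system a `molecular_system`.
#' @param annotation optional `region_annotation` carrying hydrophobic
#'   flags; residues with NA flags fall back to the residue-name
#'   classification.
#' @param grouping `"per_chain"` or `"per_pair"`.
#' @param residue_set hydrophobic residue codes for the fallback
#'   classification.
#' @return named list of `atom_selection`s (one per group).
#' @export
hydrophobic_selection <- function(system, annotation = NULL,
                                  grouping = c("per_chain", "per_pair"),
                                  residue_set = HYDROPHOBIC_RESIDUES) {
  grouping <- match.arg(grouping)
  flags <- hydrophobic_flags(system, annotation, residue_set)
  a <- system$atoms
  prot_chains <- unique(a$chain_id[!is_water_atom(a)])
  if (grouping == "per_pair" && length(prot_chains) != 4L) {
    stop("per_pair grouping requires exactly 4 protein chains")
  }
  groups <- if (grouping == "per_chain") {
    setNames(as.list(prot_chains), prot_chains)
  } else {
    list(AB = prot_chains[1:2], CD = prot_chains[3:4])
  }
  key_flag <- paste(flags$chain_id, flags$res_index)
  out <- lapply(groups, function(chs) {
    hydro <- flags$hydrophobic &
      flags$chain_id %in% chs
    keys <- key_flag[hydro]
    idx <- which(a$name == "CB" & paste(a$chain_id, a$res_index) %in% keys)
    new_selection(system, idx)
  })
  if (all(vapply(out, length, integer(1L)) == 0L)) {
    warning("no hydrophobic C-beta atoms selected")
  }
  out
}

min_image_dist2 <- function(dxyz, box) {
  for (j in 1:3) {
    dxyz[, j] <- dxyz[, j] - box[j] * round(dxyz[, j] / box[j])
  }
  rowSums(dxyz^2)
}

cross_distances <- function(xa, xb, box = NULL) {
  na <- nrow(xa); nb <- nrow(xb)
  d <- matrix(0, na, nb)
  if (is.null(box)) {
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    d2[d2 < 0] <- 0
    return(sqrt(d2))
  }
  for (i in seq_len(na)) {
    d[i, ] <- sqrt(min_image_dist2(sweep(xb, 2L, xa[i, ]), box))
  }
  d
}

#' Cross-set radial distribution function
#'
#' g(r) is the histogram of A-B distances (minimum image when periodic)
#' normalised by the ideal-gas expectation N_A N_B 4 pi r^2 dr / V,
#' averaged over frames.  For uniformly random points g(r) -> 1.
#'
#' @param traj a `trajectory` (or a `molecular_system` for one frame).
#' @param set_a,set_b disjoint `atom_selection`s.
#' @param bin_width histogram bin width (nm).
#' @param r_max maximum distance (nm); defaults to min(2, half the minimum
#'   box edge) and must not exceed half the box edge when periodic.
#' @param periodic use the minimum-image convention (requires a box).
#' @param box override box edge lengths (nm); defaults to the topology box.
#'   A box (or explicit `volume`) is required for normalisation even when
#'   not periodic.
#' @param volume normalisation volume (nm^3); defaults to the box volume.
#' @return object of class `rdf_result`: list with `r` (bin centres), `g`,
#'   `counts` (total pair counts per bin), `bin_width`, `r_max`,
#'   `n_frames`.
#' @export
rdf <- function(traj, set_a, set_b, bin_width = 0.01, r_max = NULL,
                periodic = FALSE, box = NULL, volume = NULL) {
  if (inherits(traj, "molecular_system")) {
    traj <- trajectory(traj, list(traj$xyz))
  }
  if (length(intersect(set_a$index, set_b$index)) > 0L) {
    stop("set_a and set_b must be disjoint for a cross-set rdf")
  }
  if (length(set_a) == 0L || length(set_b) == 0L) stop("empty selection")
  if (is.null(box)) box <- traj$topology$box
  if (periodic && is.null(box)) stop("periodic rdf requires a box")
  if (is.null(r_max)) {
    r_max <- if (!is.null(box)) min(2, min(box) / 2) else 2
  }
  if (periodic && r_max > min(box) / 2 + 1e-9) {
    stop("r_max must not exceed half the minimum box edge")
  }
  if (is.null(volume)) {
    if (is.null(box)) stop("rdf normalisation needs a box or explicit volume")
    volume <- prod(box)
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max - 1e-12) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  nf <- n_frames(traj)
  for (k in seq_len(nf)) {
    xa <- traj$frames[[k]][set_a$index, , drop = FALSE]
    xb <- traj$frames[[k]][set_b$index, , drop = FALSE]
    d <- as.numeric(cross_distances(xa, xb, if (periodic) box else NULL))
    d <- d[d < r_max]
    if (length(d) > 0L) {
      h <- findInterval(d, edges, rightmost.closed = TRUE)
      tab <- tabulate(h, nbins = nb)
      counts <- counts + tab
    }
  }
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  widths <- diff(edges)
  shell <- 4 * pi * centers^2 * widths
  expected <- length(set_a) * length(set_b) * shell / volume
  g <- counts / (nf * expected)
  structure(list(r = centers, g = g, counts = counts, bin_width = bin_width,
                 r_max = r_max, n_frames = nf),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf("<rdf_result> %d bins to %.2f nm; first max g=%.2f at r=%.3f nm\n",
              length(x$r), x$r_max, x$g[pk], x$r[pk]))
  invisible(x)
}

#' Distance between the centres of two atom sets
#'
#' Geometric (default) or mass-weighted centres; all-C-beta sets have equal
#' masses, so the geometric centre is the conventional choice.
#'
#' @param system a `molecular_system` (or coordinate matrix with `xyz`).
#' @param set_a,set_b non-empty `atom_selection`s.
#' @param mass_weighted weight by atomic mass.
#' @param xyz optional coordinate override (one trajectory frame).
#' @return distance in nm.
#' @export
cm_distance <- function(system, set_a, set_b, mass_weighted = FALSE,
                        xyz = NULL) {
  if (length(set_a) == 0L || length(set_b) == 0L) stop("empty selection")
  if (is.null(xyz)) xyz <- system$xyz
  centre <- function(sel) {
    x <- xyz[sel$index, , drop = FALSE]
    if (!mass_weighted) return(colMeans(x))
    el <- system$atoms$element[sel$index]
    w <- ATOMIC_MASSES[el]
    w[is.na(w)] <- mean(ATOMIC_MASSES)
    colSums(x * w) / sum(w)
  }
  vec_norm(centre(set_a) - centre(set_b))
}

#' Centre-distance time series over a trajectory
#'
#' @param traj a `trajectory`.
#' @param set_a,set_b `atom_selection`s.
#' @param mass_weighted weight by atomic mass.
#' @return `deviation_series`-like list with `times` and `values` (nm),
#'   suitable for [block_average()].
#' @export
cm_distance_series <- function(traj, set_a, set_b, mass_weighted = FALSE) {
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    cm_distance(traj$topology, set_a, set_b, mass_weighted,
                xyz = traj$frames[[k]])
  }, numeric(1L))
  list(times = traj$times, values = vals)
}
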