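# Backbone torsions, Ramachandran region classification and per-helix
# circular-mean torsion summaries.

#' Dihedral angle of four points
#'
#' IUPAC sign convention; result in degrees wrapped to (-180, 180].
#' Returns NA for degenerate (collinear) geometries.
#'
#' @param a,b,c,d numeric length-3 coordinates.
#' @return angle in degrees, or NA if undefined.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vec_norm(n1) < 1e-10 || vec_norm(n2) < 1e-10) return(NA_real_)
  m1 <- cross3(n1, unit(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

# wrap to (-180, 180]
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180 & !is.na(w)] <- 180
  w
}

#' Circular mean of angles in degrees
#'
#' Result wrapped to (-180, 180]; invariant under adding 360 to any input.
#'
#' @param x angles (deg); NAs removed.
#' @return circular mean (deg).
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  rad <- x * pi / 180
  wrap_angle(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
}

# population std of angles about their circular mean, via wrapped residuals
circular_std <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  m <- circular_mean(x)
  sqrt(mean(wrap_angle(x - m)^2))
}

#' Backbone phi/psi torsions of one chain
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i) and psi(i) = N(i)-CA(i)-C(i)-N(i+1);
#' undefined at the respective chain termini (NA), and NA where a backbone
#' atom is missing or the geometry is degenerate.
#'
#' @param system a `molecular_system`.
#' @param chain_id chain to analyse.
#' @param xyz optional coordinate matrix overriding the system coordinates
#'   (e.g. one trajectory frame).
#' @return data.frame with columns `chain_id`, `res_index`, `phi`, `psi`.
#' @export
backbone_torsions <- function(system, chain_id, xyz = NULL) {
  if (is.null(xyz)) xyz <- system$xyz
  a <- system$atoms
  in_ch <- a$chain_id == chain_id & !is_water_atom(a)
  if (!any(in_ch)) stop("no protein atoms in chain ", chain_id)
  res_idx <- sort(unique(a$res_index[in_ch]))
  n <- length(res_idx)
  if (n < 2L) stop("chain ", chain_id, " has fewer than 2 residues")
  atom_row <- function(ri, nm) {
    w <- which(in_ch & a$res_index == ri & a$name == nm)
    if (length(w) == 1L) w else NA_integer_
  }
  Nr <- vapply(res_idx, atom_row, integer(1L), nm = "N")
  CAr <- vapply(res_idx, atom_row, integer(1L), nm = "CA")
  Cr <- vapply(res_idx, atom_row, integer(1L), nm = "C")
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L && !anyNA(c(Cr[i - 1L], Nr[i], CAr[i], Cr[i]))) {
      phi[i] <- dihedral_angle(xyz[Cr[i - 1L], ], xyz[Nr[i], ],
                               xyz[CAr[i], ], xyz[Cr[i], ])
    }
    if (i < n && !anyNA(c(Nr[i], CAr[i], Cr[i], Nr[i + 1L]))) {
      psi[i] <- dihedral_angle(xyz[Nr[i], ], xyz[CAr[i], ],
                               xyz[Cr[i], ], xyz[Nr[i + 1L], ])
    }
  }
  data.frame(chain_id = chain_id, res_index = res_idx, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' Ramachandran region definitions
#'
#' Disjoint (phi, psi) rectangles (degrees) for the alpha-helix, beta-strand
#' and left-handed-alpha regions; everything else is OTHER.  Intervals are
#' half-open `[min, max)` except that an upper bound of 180 is inclusive.
#' Disjointness is verified at construction.
#'
#' @param alpha,beta,left_alpha matrices with columns
#'   `phi_min, phi_max, psi_min, psi_max`, one row per rectangle.
#' @return object of class `rama_regions`.
#' @export
rama_regions <- function(
    alpha = matrix(c(-180, 0, -120, 50), nrow = 1L),
    beta = matrix(c(-180, -20, 50, 180,
                    -180, -20, -180, -150), nrow = 2L, byrow = TRUE),
    left_alpha = matrix(c(0, 180, -20, 90), nrow = 1L)) {
  regions <- list(ALPHA = alpha, BETA = beta, LEFT_ALPHA = left_alpha)
  regions <- lapply(regions, function(m) {
    m <- matrix(as.numeric(m), ncol = 4L)
    colnames(m) <- c("phi_min", "phi_max", "psi_min", "psi_max")
    m
  })
  # verify pairwise disjointness of rectangles across regions
  rects <- do.call(rbind, regions)
  owner <- rep(names(regions), vapply(regions, nrow, integer(1L)))
  overlap1d <- function(lo1, hi1, lo2, hi2) max(lo1, lo2) < min(hi1, hi2)
  nr <- nrow(rects)
  if (nr > 1L) {
    for (i in seq_len(nr - 1L)) for (j in seq(i + 1L, nr)) {
      if (owner[i] != owner[j] &&
          overlap1d(rects[i, 1L], rects[i, 2L], rects[j, 1L], rects[j, 2L]) &&
          overlap1d(rects[i, 3L], rects[i, 4L], rects[j, 3L], rects[j, 4L])) {
        stop("Ramachandran regions ", owner[i], " and ", owner[j], " overlap")
      }
    }
  }
  structure(regions, class = "rama_regions")
}

in_interval <- function(x, lo, hi) (x >= lo & x < hi) | (hi == 180 & x == 180)

#' Classify a (phi, psi) pair into a Ramachandran region
#'
#' @param phi,psi torsions in degrees (may be vectors).
#' @param regions a [rama_regions()].
#' @return character vector of labels among ALPHA, BETA, LEFT_ALPHA, OTHER.
#' @export
classify_rama <- function(phi, psi, regions = rama_regions()) {
  stopifnot(inherits(regions, "rama_regions"), length(phi) == length(psi))
  out <- rep("OTHER", length(phi))
  for (lab in names(regions)) {
    m <- regions[[lab]]
    hit <- rep(FALSE, length(phi))
    for (r in seq_len(nrow(m))) {
      hit <- hit | (in_interval(phi, m[r, 1L], m[r, 2L]) &
                    in_interval(psi, m[r, 3L], m[r, 4L]))
    }
    out[hit & out == "OTHER"] <- lab
  }
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}

collect_torsions <- function(traj, chains = NULL) {
  system <- traj$topology
  if (is.null(chains)) {
    chains <- unique(system$atoms$chain_id[!is_water_atom(system$atoms)])
  }
  do.call(rbind, lapply(seq_len(n_frames(traj)), function(k) {
    do.call(rbind, lapply(chains, function(ch) {
      tt <- backbone_torsions(system, ch, xyz = traj$frames[[k]])
      tt$frame <- k
      tt$time <- traj$times[k]
      tt
    }))
  }))
}

#' Ramachandran region percentages over a trajectory
#'
#' Percentages of all defined (phi, psi) pairs (all residues, all frames in
#' the analysis window) falling in each region; they sum to 100 exactly.
#' Per-frame percentages are also block-averaged for error bars.
#'
#' @param traj a `trajectory`.
#' @param regions a [rama_regions()].
#' @param window trailing analysis window (ns); NULL = full trajectory.
#' @param n_blocks number of blocks for the per-frame summaries.
#' @return list with `percent` (named vector summing to 100), `counts`,
#'   and `blocks` (per-region [block_average()] results of the per-frame
#'   percentage series; NULL when the window holds fewer than `n_blocks`
#'   frames).
#' @export
region_percentages <- function(traj, regions = rama_regions(), window = NULL,
                               n_blocks = 5L) {
  tors <- collect_torsions(traj)
  if (!is.null(window)) {
    t_end <- max(traj$times)
    tors <- tors[tors$time >= t_end - window, ]
  }
  ok <- !is.na(tors$phi) & !is.na(tors$psi)
  if (!any(ok)) stop("no defined (phi, psi) pairs in the analysis window")
  lab <- classify_rama(tors$phi[ok], tors$psi[ok], regions)
  levels_all <- c(names(regions), "OTHER")
  counts <- vapply(levels_all, function(l) sum(lab == l), numeric(1L))
  percent <- 100 * counts / sum(counts)
  blocks <- NULL
  frames <- sort(unique(tors$frame[ok]))
  if (length(frames) >= n_blocks) {
    per_frame <- t(vapply(frames, function(k) {
      sel <- ok & tors$frame == k
      lk <- classify_rama(tors$phi[sel], tors$psi[sel], regions)
      100 * vapply(levels_all, function(l) mean(lk == l), numeric(1L))
    }, numeric(length(levels_all))))
    times_f <- traj$times[frames]
    blocks <- lapply(seq_along(levels_all), function(j) {
      block_average(per_frame[, j], times = times_f, n_blocks = n_blocks)
    })
    names(blocks) <- levels_all
  }
  list(percent = percent, counts = counts, blocks = blocks)
}

#' Time map of one residue's (phi, psi) trajectory
#'
#' Records (time, phi, psi) per frame and the occupied footprint on a
#' (phi, psi) grid, quantifying how broadly the residue explores torsion
#' space.
#'
#' @param traj a `trajectory`.
#' @param chain_id,res_index residue to map.
#' @param grid grid resolution in degrees (default 5).
#' @return list with `map` (data.frame time/phi/psi), `footprint_cells`,
#'   `footprint_area_deg2` and `grid`.
#' @export
torsion_time_map <- function(traj, chain_id, res_index, grid = 5) {
  system <- traj$topology
  recs <- lapply(seq_len(n_frames(traj)), function(k) {
    tt <- backbone_torsions(system, chain_id, xyz = traj$frames[[k]])
    row <- tt[tt$res_index == res_index, ]
    if (nrow(row) == 0L) stop("residue ", res_index, " not found in chain ", chain_id)
    data.frame(time = traj$times[k], phi = row$phi, psi = row$psi)
  })
  map <- do.call(rbind, recs)
  if (all(is.na(map$phi))) stop("phi undefined for residue ", res_index,
                                " of chain ", chain_id, " (chain-first residue)")
  if (all(is.na(map$psi))) stop("psi undefined for residue ", res_index,
                                " of chain ", chain_id, " (chain-last residue)")
  ok <- !is.na(map$phi) & !is.na(map$psi)
  cells <- unique(paste(floor(map$phi[ok] / grid), floor(map$psi[ok] / grid)))
  list(map = map, footprint_cells = length(cells),
       footprint_area_deg2 = length(cells) * grid^2, grid = grid)
}

#' Per-helix mean backbone torsions with block-averaged errors
#'
#' Two-stage averaging: the circular mean of all defined (phi, psi) pairs
#' along each helix at each frame, then block time-averaging over the
#' trailing window; the error is the spread of the block means.
#'
#' @param traj a `trajectory`.
#' @param annotation a `region_annotation` with helix ranges.
#' @param window trailing analysis window (ns); NULL = full trajectory.
#' @param n_blocks number of blocks.
#' @return data.frame, one row per helix: `helix_id`, `phi_mean`, `phi_err`,
#'   `psi_mean`, `psi_err`.
#' @export
helix_mean_torsions <- function(traj, annotation, window = NULL, n_blocks = 5L) {
  hr <- helix_ranges(annotation)
  if (nrow(hr) == 0L) stop("annotation contains no helix ranges")
  if (!is.null(window) && window > diff(range(traj$times))) {
    stop("analysis window exceeds the trajectory span")
  }
  system <- traj$topology
  out <- lapply(seq_len(nrow(hr)), function(h) {
    rng <- seq(hr$res_start[h], hr$res_end[h])
    per_frame <- t(vapply(seq_len(n_frames(traj)), function(k) {
      tt <- backbone_torsions(system, hr$chain_id[h], xyz = traj$frames[[k]])
      tt <- tt[tt$res_index %in% rng, ]
      c(circular_mean(tt$phi), circular_mean(tt$psi))
    }, numeric(2L)))
    bphi <- block_average(per_frame[, 1L], times = traj$times, window = window,
                          n_blocks = n_blocks, circular = TRUE)
    bpsi <- block_average(per_frame[, 2L], times = traj$times, window = window,
                          n_blocks = n_blocks, circular = TRUE)
    data.frame(helix_id = hr$helix_id[h],
               phi_mean = bphi$mean, phi_err = bphi$error,
               psi_mean = bpsi$mean, psi_err = bpsi$error,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
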