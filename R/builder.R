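# Synthetic structure and trajectory builder.  Chains are grown from
# backbone internal coordinates (bond lengths, bond angles, phi/psi/omega
# torsions) by sequential natural-extension-reference-frame placement, so
# every generated structure has exactly known ground-truth geometry.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Standard peptide backbone geometry
#'
#' Bond lengths in nm and bond angles in degrees used by the chain builder.
#' Defaults are standard peptide-geometry values; the carbonyl O and C-beta
#' placement parameters are included so a full backbone + C-beta residue can
#' be constructed.
#'
#' @param b_n_ca,b_ca_c,b_c_n backbone bond lengths N-CA, CA-C, C-N (nm).
#' @param a_n_ca_c,a_ca_c_n,a_c_n_ca backbone bond angles (deg).
#' @param omega peptide-bond torsion (deg); 180 is the trans conformation.
#' @param b_c_o,a_ca_c_o carbonyl O bond length (nm) and CA-C-O angle (deg).
#' @param b_ca_cb,a_n_ca_cb C-beta bond length (nm) and N-CA-CB angle (deg).
#' @param b_n_h amide N-H bond length (nm), used for H reconstruction.
#' @return object of class `backbone_geometry`.
#' @export
backbone_geometry <- function(b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329,
                              a_n_ca_c = 111.2, a_ca_c_n = 116.2,
                              a_c_n_ca = 121.7, omega = 180,
                              b_c_o = 0.1231, a_ca_c_o = 120.5,
                              b_ca_cb = 0.1530, a_n_ca_cb = 110.5,
                              b_n_h = 0.100) {
  g <- list(b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n,
            a_n_ca_c = a_n_ca_c, a_ca_c_n = a_ca_c_n, a_c_n_ca = a_c_n_ca,
            omega = omega, b_c_o = b_c_o, a_ca_c_o = a_ca_c_o,
            b_ca_cb = b_ca_cb, a_n_ca_cb = a_n_ca_cb, b_n_h = b_n_h)
  lens <- c(g$b_n_ca, g$b_ca_c, g$b_c_n)
  angs <- c(g$a_n_ca_c, g$a_ca_c_n, g$a_c_n_ca)
  if (any(lens <= 0.1 | lens >= 0.2)) stop("backbone bond lengths must lie in (0.1, 0.2) nm")
  if (any(angs <= 90 | angs >= 140)) stop("backbone bond angles must lie in (90, 140) deg")
  structure(g, class = "backbone_geometry")
}

vec_norm <- function(v) sqrt(sum(v * v))
unit <- function(v) v / vec_norm(v)
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Place atom D bonded to C, with bond angle B-C-D and torsion A-B-C-D
# (IUPAC sign convention, matching dihedral_angle()).
place_atom <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  bc <- unit(c_ - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c_ + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

normalize_torsions <- function(torsions, n) {
  if (is.list(torsions)) torsions <- do.call(rbind, lapply(torsions, as.numeric))
  torsions <- as.matrix(torsions)
  if (ncol(torsions) != 2L || nrow(torsions) != n) {
    stop("torsions must provide one (phi, psi) pair per residue")
  }
  torsions
}

#' Build a peptide chain from backbone torsions
#'
#' Grows backbone atoms N, CA, C, O (and CB for non-glycine residues) by
#' sequential internal-coordinate construction.  The first residue's phi and
#' the last residue's psi are undefined at the termini and ignored.
#' C-beta is placed so the improper torsion N-CA-C-CB measures about
#' -122.6 deg in the IUPAC sign convention, the L-amino-acid chirality
#' observed in crystal structures.
#'
#' @param sequence character vector of 3-letter residue codes.
#' @param torsions n x 2 matrix (or list of pairs) of (phi, psi) in degrees.
#' @param geometry a [backbone_geometry()].
#' @param chain_id chain label for the built chain.
#' @return a `molecular_system`.
#' @export
build_chain <- function(sequence, torsions, geometry = backbone_geometry(),
                        chain_id = "A") {
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, AA3)
  if (length(bad) > 0L) stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  n <- length(sequence)
  if (n < 2L) stop("chain needs at least 2 residues")
  tor <- normalize_torsions(torsions, n)
  g <- geometry

  N <- matrix(NA_real_, n, 3L)
  CA <- matrix(NA_real_, n, 3L)
  C <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  ang <- (180 - g$a_n_ca_c) * pi / 180
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    psi_i <- tor[i, 2L]
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, psi_i)
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], g$b_n_ca,
                               g$a_c_n_ca, g$omega)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ], g$b_ca_c,
                              g$a_n_ca_c, tor[i + 1L, 1L])
  }
  # carbonyl O: sp2, anti to the next N about the CA-C bond; the terminal
  # residue (undefined psi) uses 180 deg by convention
  O <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    psi_eff <- if (i < n) tor[i, 2L] else 0
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                         psi_eff + 180)
  }
  # C-beta: tetrahedral off CA, improper torsion N-CA-C-CB = +122.6 deg
  CB <- matrix(NA_real_, n, 3L)
  has_cb <- sequence != "GLY"
  for (i in which(has_cb)) {
    CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], g$b_ca_cb, g$a_n_ca_cb,
                          -122.6)
  }

  rows <- list()
  coords <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    names_i <- c("N", "CA", "C", "O", if (has_cb[i]) "CB")
    xyz_i <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ], if (has_cb[i]) CB[i, ])
    rows[[i]] <- data.frame(
      serial = serial + seq_along(names_i), name = names_i,
      element = substr(names_i, 1L, 1L), res_index = i,
      res_name = sequence[i], chain_id = chain_id, stringsAsFactors = FALSE)
    coords[[i]] <- xyz_i
    serial <- serial + length(names_i)
  }
  molecular_system(do.call(rbind, rows), do.call(rbind, coords))
}

IDEAL_HELIX_TORSIONS <- c(-60, -50)
EXTENDED_TORSIONS <- c(-80, 80)

# Loop torsions (phi, psi) that fold the chain back so the two helices of a
# hairpin chain run roughly antiparallel; chosen once by a grid search over
# turn motifs and frozen (see the methods vignette).
HAIRPIN_LOOP_TORSIONS <- matrix(c(
   23,  -4,
 -105,  14,
   51,  94,
   87,  29,
 -165, 117,
 -136,  55,
  -33, -90,
  -61,   9,
  -91, -32), ncol = 2L, byrow = TRUE)

heptad_sequence <- function(n, loop_range = NULL) {
  polar <- c("GLU", "GLN", "LYS", "ASN", "SER")
  seqs <- character(n)
  for (i in seq_len(n)) {
    pos <- (i - 1L) %% 7L
    seqs[i] <- if (pos == 0L) "LEU" else if (pos == 3L) "ALA"
               else polar[(i %% length(polar)) + 1L]
  }
  if (!is.null(loop_range)) {
    # a leucine/aspartate/alanine loop centre echoing helical-hairpin loops
    mid <- floor(mean(loop_range))
    pick <- intersect((mid - 1L):(mid + 2L), loop_range)
    seqs[pick] <- rep(c("LEU", "ASP", "ALA", "ASP"), length.out = length(pick))
  }
  seqs
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
         nrow = 3L, byrow = TRUE)
}

rotation_aligning <- function(v, target) {
  v <- unit(v); target <- unit(target)
  c_ <- sum(v * target)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any perpendicular axis
    p <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about_axis(cross3(v, p), 180))
  }
  axis <- cross3(v, target)
  rotation_about_axis(axis, acos(c_) * 180 / pi)
}

wtrop_layout <- function(chain_length, loop_length) {
  if (loop_length < 1L) stop("loop_length must be >= 1 for wtrop_like bundles")
  h1_end <- 24L
  loop_end <- h1_end + loop_length
  tail_start <- chain_length - 6L
  if (loop_end >= tail_start - 4L) stop("chain too short for the requested loop")
  list(n_tail = c(1L, 2L), helix1 = c(3L, h1_end),
       loop = c(h1_end + 1L, loop_end),
       helix2 = c(loop_end + 1L, tail_start - 1L),
       c_tail = c(tail_start, chain_length))
}

#' Build an ideal alpha-helical bundle with its region annotation
#'
#' `wtrop_like` builds a helical-hairpin dimer: 2 chains, each two helices
#' joined by a loop, with short N-tails and flexible 7-residue C-tails
#' (default 63 residues per chain, helix1 = 3-24, loop = 25-33).
#' `rm6_like` builds a loopless four-helix tetramer: 4 chains of one long
#' helix each (default 58 residues per chain).  Chains are placed on a
#' square lattice of side `separation` with antiparallel alternation.
#'
#' @param kind `"wtrop_like"` or `"rm6_like"`.
#' @param chain_length residues per chain (63 / 58 by default).
#' @param loop_length loop residues for `wtrop_like` (default 9, the loop
#'   region plus its nearest neighbours).
#' @param separation lattice spacing between chain axes (nm).
#' @param geometry a [backbone_geometry()].
#' @return list with elements `system` (a `molecular_system`) and
#'   `annotation` (a `region_annotation` with hydrophobic flags).
#' @export
build_bundle <- function(kind = c("wtrop_like", "rm6_like"),
                         chain_length = NULL, loop_length = 9L,
                         separation = 1.0, geometry = backbone_geometry()) {
  kind <- match.arg(kind)
  if (is.null(chain_length)) chain_length <- if (kind == "wtrop_like") 63L else 58L
  n_chains <- if (kind == "wtrop_like") 2L else 4L

  if (kind == "wtrop_like") {
    lay <- wtrop_layout(chain_length, loop_length)
    seqs <- heptad_sequence(chain_length, loop_range = seq(lay$loop[1L], lay$loop[2L]))
    tor <- matrix(rep(IDEAL_HELIX_TORSIONS, chain_length), ncol = 2L, byrow = TRUE)
    ext_rows <- c(seq(lay$n_tail[1L], lay$n_tail[2L]),
                  seq(lay$c_tail[1L], lay$c_tail[2L]))
    tor[ext_rows, ] <- matrix(rep(EXTENDED_TORSIONS, length(ext_rows)),
                              ncol = 2L, byrow = TRUE)
    loop_rows <- seq(lay$loop[1L], lay$loop[2L])
    loop_tor <- HAIRPIN_LOOP_TORSIONS[
      round(seq(1L, nrow(HAIRPIN_LOOP_TORSIONS), length.out = length(loop_rows))), ,
      drop = FALSE]
    tor[loop_rows, ] <- loop_tor
    ann_ranges <- data.frame(
      chain_id = "A",
      res_start = c(lay$n_tail[1L], lay$helix1[1L], lay$loop[1L],
                    lay$helix2[1L], lay$c_tail[1L]),
      res_end = c(lay$n_tail[2L], lay$helix1[2L], lay$loop[2L],
                  lay$helix2[2L], lay$c_tail[2L]),
      label = c("N_TAIL", "HELIX1", "LOOP", "HELIX2", "C_TAIL"),
      stringsAsFactors = FALSE)
    axis_range <- seq(lay$helix1[1L], lay$helix1[2L])
  } else {
    seqs <- heptad_sequence(chain_length)
    tor <- matrix(rep(IDEAL_HELIX_TORSIONS, chain_length), ncol = 2L, byrow = TRUE)
    ann_ranges <- data.frame(chain_id = "A", res_start = 1L,
                             res_end = chain_length, label = "HELIX",
                             stringsAsFactors = FALSE)
    axis_range <- seq_len(chain_length)
  }

  proto <- build_chain(seqs, tor, geometry, chain_id = "A")
  # orient the (first) helix axis along z and centre the chain
  ca_idx <- which(proto$atoms$name == "CA" & proto$atoms$res_index %in% axis_range)
  axis <- fit_axis(proto$xyz[ca_idx, , drop = FALSE])
  R_align <- rotation_aligning(axis$direction, c(0, 0, 1))
  xyz0 <- proto$xyz %*% t(R_align)
  xyz0 <- sweep(xyz0, 2L, colMeans(xyz0))

  offsets <- switch(as.character(n_chains),
                    "2" = rbind(c(0, 0, 0), c(separation, 0, 0)),
                    "4" = rbind(c(0, 0, 0), c(separation, 0, 0),
                                c(0, separation, 0), c(separation, separation, 0)))
  flip <- rotation_about_axis(c(1, 0, 0), 180)
  atoms_all <- list(); xyz_all <- list(); ann_all <- list()
  serial <- 0L
  for (k in seq_len(n_chains)) {
    ch <- LETTERS[k]
    xyz_k <- if (k %% 2L == 0L) xyz0 %*% t(flip) else xyz0
    xyz_k <- sweep(xyz_k, 2L, offsets[k, ], "+")
    a_k <- proto$atoms
    a_k$chain_id <- ch
    a_k$serial <- serial + seq_len(nrow(a_k))
    serial <- serial + nrow(a_k)
    atoms_all[[k]] <- a_k
    xyz_all[[k]] <- xyz_k
    r_k <- ann_ranges
    r_k$chain_id <- ch
    ann_all[[k]] <- r_k
  }
  system <- molecular_system(do.call(rbind, atoms_all), do.call(rbind, xyz_all))
  ranges <- do.call(rbind, ann_all)
  ranges$hydrophobic <- NA
  annotation <- region_annotation(ranges)
  flags <- hydrophobic_flags(system)
  key_ann <- paste(annotation$chain_id, annotation$res_index)
  annotation$hydrophobic <- flags$hydrophobic[
    match(key_ann, paste(flags$chain_id, flags$res_index))]
  list(system = system, annotation = annotation)
}

#' Noise model for synthetic trajectories
#'
#' Frames are the reference conformation (or a linear drift towards a
#' target) plus i.i.d. Gaussian displacements with per-coordinate standard
#' deviation sigma_i for all atoms of residue i.  The same seed always
#' yields the same trajectory.
#'
#' @param sigma per-residue displacement amplitude (nm): a scalar applied
#'   to every residue or a vector with one value per residue of the system
#'   (in residue order).
#' @param drift_target optional `molecular_system` with identical topology;
#'   frames interpolate linearly from the reference to it.
#' @param seed integer RNG seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma, drift_target = NULL, seed = 1L) {
  sigma <- as.numeric(sigma)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  structure(list(sigma = sigma, drift_target = drift_target,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Per-residue sigma profile from a region annotation
#'
#' Assigns displacement amplitudes by structural region, emulating the
#' larger thermal fluctuations of tails and loops relative to helices.
#'
#' @param annotation a `region_annotation`.
#' @param helix,loop,tail sigma (nm) for helix, loop and tail residues.
#' @param scale overall multiplier (use > 1 for a hotter tier).
#' @return numeric vector, one sigma per annotated residue in order.
#' @export
sigma_profile <- function(annotation, helix = 0.01, loop = 0.03, tail = 0.05,
                          scale = 1) {
  s <- ifelse(annotation$label %in% c("HELIX", "HELIX1", "HELIX2"), helix,
              ifelse(annotation$label == "LOOP", loop, tail))
  s * scale
}

#' Generate a synthetic trajectory
#'
#' @param system reference `molecular_system`.
#' @param n_frames number of frames (>= 1).
#' @param noise a [noise_model()].
#' @param dt frame spacing (ns).
#' @return a `trajectory`; reproducible for a fixed noise seed.
#' @export
generate_trajectory <- function(system, n_frames, noise, dt = 0.1) {
  stopifnot(inherits(system, "molecular_system"), inherits(noise, "noise_model"))
  if (n_frames < 1L) stop("n_frames must be >= 1")
  res <- residue_table(system)
  sigma <- noise$sigma
  if (length(sigma) == 1L) sigma <- rep(sigma, nrow(res))
  if (length(sigma) != nrow(res)) {
    stop("sigma must be scalar or one value per residue (", nrow(res), ")")
  }
  res_key <- paste(system$atoms$chain_id, system$atoms$res_index)
  sigma_atom <- sigma[match(res_key, paste(res$chain_id, res$res_index))]
  target <- noise$drift_target
  if (!is.null(target)) {
    if (!identical(dim(target$xyz), dim(system$xyz))) {
      stop("drift target topology differs from the reference")
    }
  }
  na <- n_atoms(system)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(noise$seed)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    base <- if (is.null(target) || n_frames == 1L) system$xyz else {
      w <- (k - 1) / (n_frames - 1)
      (1 - w) * system$xyz + w * target$xyz
    }
    disp <- matrix(rnorm(na * 3L, sd = rep(sigma_atom, 3L)), ncol = 3L)
    frames[[k]] <- base + disp
  }
  trajectory(system, frames, times = (seq_len(n_frames) - 1L) * dt)
}

#' Place rigid three-site waters in a box
#'
#' Waters (residue name SOL; atoms OW, HW1, HW2 with O-H 0.1 nm and an
#' H-O-H angle of 109.47 deg) are placed with uniformly random positions and
#' orientations, rejecting candidates whose O-O distance to any accepted
#' water falls below `min_dist`.
#'
#' @param box numeric length-3 box edge lengths (nm).
#' @param n_waters number of waters.
#' @param min_dist minimum O-O separation (nm).
#' @param seed RNG seed.
#' @param max_tries attempts per water before giving up.
#' @return a `molecular_system` (chain "W") with `box` set.
#' @export
place_waters <- function(box, n_waters, min_dist = 0.26, seed = 1L,
                         max_tries = 2000L) {
  box <- as.numeric(box)
  stopifnot(length(box) == 3L, n_waters >= 1L)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  half_ang <- (109.47 / 2) * pi / 180
  oh <- 0.100
  o_pos <- matrix(NA_real_, n_waters, 3L)
  placed <- 0L
  atoms <- list(); coords <- list()
  for (w in seq_len(n_waters)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- runif(3L) * box
      if (placed == 0L ||
          min(sqrt(rowSums(sweep(o_pos[seq_len(placed), , drop = FALSE],
                                 2L, cand)^2))) >= min_dist) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("water placement failed after %d tries (%d of %d placed)",
                   max_tries, placed, n_waters))
    }
    placed <- placed + 1L
    o_pos[placed, ] <- cand
    # random orientation from a random rotation matrix
    q <- rnorm(4L); q <- q / vec_norm(q)
    R <- matrix(c(1 - 2 * (q[3L]^2 + q[4L]^2), 2 * (q[2L] * q[3L] - q[4L] * q[1L]), 2 * (q[2L] * q[4L] + q[3L] * q[1L]),
                  2 * (q[2L] * q[3L] + q[4L] * q[1L]), 1 - 2 * (q[2L]^2 + q[4L]^2), 2 * (q[3L] * q[4L] - q[2L] * q[1L]),
                  2 * (q[2L] * q[4L] - q[3L] * q[1L]), 2 * (q[3L] * q[4L] + q[2L] * q[1L]), 1 - 2 * (q[2L]^2 + q[3L]^2)),
                nrow = 3L, byrow = TRUE)
    h1 <- cand + (R %*% (oh * c(sin(half_ang), 0, cos(half_ang))))[, 1L]
    h2 <- cand + (R %*% (oh * c(-sin(half_ang), 0, cos(half_ang))))[, 1L]
    atoms[[placed]] <- data.frame(
      serial = (placed - 1L) * 3L + 1:3, name = c("OW", "HW1", "HW2"),
      element = c("O", "H", "H"), res_index = placed, res_name = "SOL",
      chain_id = "W", stringsAsFactors = FALSE)
    coords[[placed]] <- rbind(cand, h1, h2)
  }
  molecular_system(do.call(rbind, atoms), do.call(rbind, coords), box = box)
}

#' Merge molecular systems (e.g. protein + water shell)
#'
#' @param ... `molecular_system` objects with disjoint chain ids.
#' @param box box of the merged system (default: first non-NULL input box).
#' @return a `molecular_system`.
#' @export
merge_systems <- function(..., box = NULL) {
  systems <- list(...)
  all_chains <- unlist(lapply(systems, function(s) s$chains))
  if (anyDuplicated(all_chains)) stop("chain ids must be disjoint across systems")
  atoms <- do.call(rbind, lapply(systems, function(s) s$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  xyz <- do.call(rbind, lapply(systems, function(s) s$xyz))
  if (is.null(box)) {
    boxes <- Filter(Negate(is.null), lapply(systems, function(s) s$box))
    if (length(boxes) > 0L) box <- boxes[[1L]]
  }
  molecular_system(atoms, xyz, box = box)
}
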