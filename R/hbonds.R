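# Geometric hydrogen-bond detection and the censuses built on it.
# Donors are backbone amide N-H groups (with the H reconstructed from
# standard planar amide geometry when absent, as in crystal structures) and
# water O-H groups; acceptors are backbone carbonyl O and water O.

#' Geometric hydrogen-bond criterion
#'
#' A donor-acceptor pair is hydrogen bonded when the donor-acceptor
#' distance and the hydrogen-donor-acceptor angle both fall below the
#' cutoffs.  Defaults follow the common MD-analysis convention
#' (0.35 nm, 30 deg).
#'
#' @param max_da_distance donor-acceptor distance cutoff (nm), in (0, 1).
#' @param max_hda_angle H-donor-acceptor angle cutoff (deg), in (0, 90).
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_distance = 0.35, max_hda_angle = 30) {
  if (max_da_distance <= 0 || max_da_distance >= 1) {
    stop("distance cutoff must lie in (0, 1) nm")
  }
  if (max_hda_angle <= 0 || max_hda_angle >= 90) {
    stop("angle cutoff must lie in (0, 90) deg")
  }
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle),
            class = "hbond_criterion")
}

# Donor/acceptor inventory for a topology; computed once and reused across
# frames.  Each donor row is one D-H group (a water O contributes two).
hbond_inventory <- function(system) {
  a <- system$atoms
  water <- is_water_atom(a)
  donors <- list()
  warn_res <- character(0L)

  # protein amide donors: residues after the chain's first, excluding Pro
  prot_chains <- unique(a$chain_id[!water])
  for (ch in prot_chains) {
    rows_ch <- which(a$chain_id == ch & !water)
    res_ids <- sort(unique(a$res_index[rows_ch]))
    find_atom <- function(ri, nm) {
      w <- rows_ch[a$res_index[rows_ch] == ri & a$name[rows_ch] == nm]
      if (length(w) >= 1L) w[1L] else NA_integer_
    }
    for (ri in res_ids[-1L]) {
      res_name <- a$res_name[rows_ch[a$res_index[rows_ch] == ri][1L]]
      if (res_name == "PRO") next
      n_row <- find_atom(ri, "N")
      h_row <- find_atom(ri, "H")
      ca_row <- find_atom(ri, "CA")
      cprev_row <- find_atom(ri - 1L, "C")
      if (is.na(n_row)) next
      if (is.na(h_row) && (is.na(ca_row) || is.na(cprev_row))) {
        warn_res <- c(warn_res, paste0(ch, ":", ri))
        next
      }
      donors[[length(donors) + 1L]] <- data.frame(
        d_row = n_row, h_row = h_row, ca_row = ca_row, cprev_row = cprev_row,
        water = FALSE, stringsAsFactors = FALSE)
    }
  }
  # water donors
  if (any(water)) {
    w_res <- unique(paste(a$chain_id[water], a$res_index[water]))
    for (key in w_res) {
      rows_w <- which(water & paste(a$chain_id, a$res_index) == key)
      o_row <- rows_w[a$name[rows_w] %in% c("OW", "O")][1L]
      h_rows <- rows_w[grepl("^H", a$name[rows_w])]
      if (is.na(o_row) || length(h_rows) == 0L) next
      for (h in h_rows) {
        donors[[length(donors) + 1L]] <- data.frame(
          d_row = o_row, h_row = h, ca_row = NA_integer_,
          cprev_row = NA_integer_, water = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(warn_res) > 0L) {
    warning("missing heavy atoms for amide-H reconstruction; skipped residue(s): ",
            paste(warn_res, collapse = ", "))
  }
  donors <- if (length(donors) > 0L) do.call(rbind, donors) else
    data.frame(d_row = integer(), h_row = integer(), ca_row = integer(),
               cprev_row = integer(), water = logical())
  acc_rows <- which((!water & a$name == "O") | (water & a$name %in% c("OW", "O")))
  list(donors = donors, acceptors = acc_rows, acceptor_water = water[acc_rows])
}

reconstruct_h <- function(xyz, n_row, ca_row, cprev_row, b_n_h = 0.100) {
  n <- xyz[n_row, ]
  u1 <- unit(xyz[cprev_row, ] - n)
  u2 <- unit(xyz[ca_row, ] - n)
  n + b_n_h * unit(-(u1 + u2))
}

#' Detect hydrogen bonds in one frame
#'
#' Reports one record per donor-acceptor pair satisfying the criterion
#' (where both water hydrogens qualify, the smaller-angle one is kept).
#' Covalently adjacent pairs (a donor N with its own or the preceding
#' residue's carbonyl O; a water O with itself) are excluded.
#'
#' @param system a `molecular_system` (topology).
#' @param criterion an [hbond_criterion()].
#' @param xyz optional coordinate matrix for one trajectory frame.
#' @param inventory precomputed [hbond_inventory] (internal reuse).
#' @return data.frame with columns `donor_row`, `acceptor_row` (atom row
#'   indices), `h_name`, `distance` (nm), `angle` (deg), `class`
#'   ("PP"/"PW"/"WW"), `span` ("interchain"/"intrachain" for PP, NA
#'   otherwise).
#' @export
find_hbonds <- function(system, criterion = hbond_criterion(), xyz = NULL,
                        inventory = NULL) {
  if (is.null(xyz)) xyz <- system$xyz
  if (is.null(inventory)) inventory <- hbond_inventory(system)
  don <- inventory$donors
  acc <- inventory$acceptors
  empty <- data.frame(donor_row = integer(), acceptor_row = integer(),
                      h_name = character(), distance = numeric(),
                      angle = numeric(), class = character(),
                      span = character(), stringsAsFactors = FALSE)
  if (nrow(don) == 0L || length(acc) == 0L) return(empty)
  a <- system$atoms

  h_xyz <- matrix(NA_real_, nrow(don), 3L)
  for (i in seq_len(nrow(don))) {
    h_xyz[i, ] <- if (!is.na(don$h_row[i])) xyz[don$h_row[i], ] else
      reconstruct_h(xyz, don$d_row[i], don$ca_row[i], don$cprev_row[i])
  }
  d_xyz <- xyz[don$d_row, , drop = FALSE]
  a_xyz <- xyz[acc, , drop = FALSE]

  # donor-acceptor distance matrix
  d2 <- outer(rowSums(d_xyz^2), rowSums(a_xyz^2), "+") -
    2 * d_xyz %*% t(a_xyz)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  cand <- which(dist <= criterion$max_da_distance, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)

  recs <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    d_row <- don$d_row[i]; a_row <- acc[j]
    if (d_row == a_row) next
    # covalent-neighbourhood exclusions
    if (!don$water[i] && !inventory$acceptor_water[j] &&
        a$chain_id[d_row] == a$chain_id[a_row] &&
        a$res_index[a_row] %in% c(a$res_index[d_row], a$res_index[d_row] - 1L)) next
    if (don$water[i] && a$chain_id[d_row] == a$chain_id[a_row] &&
        a$res_index[d_row] == a$res_index[a_row]) next
    v_h <- h_xyz[i, ] - d_xyz[i, ]
    v_a <- a_xyz[j, ] - d_xyz[i, ]
    cosang <- sum(v_h * v_a) / (vec_norm(v_h) * vec_norm(v_a))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    if (ang > criterion$max_hda_angle) next
    cls <- if (don$water[i] && inventory$acceptor_water[j]) "WW"
           else if (!don$water[i] && !inventory$acceptor_water[j]) "PP"
           else "PW"
    span <- if (cls == "PP") {
      if (a$chain_id[d_row] == a$chain_id[a_row]) "intrachain" else "interchain"
    } else NA_character_
    recs[[length(recs) + 1L]] <- data.frame(
      donor_row = d_row, acceptor_row = a_row,
      h_name = if (!is.na(don$h_row[i])) a$name[don$h_row[i]] else "H*",
      distance = dist[i, j], angle = ang, class = cls, span = span,
      stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  # one record per donor-acceptor pair: keep the smallest angle
  key <- paste(out$donor_row, out$acceptor_row)
  out <- out[order(key, out$angle), ]
  out <- out[!duplicated(paste(out$donor_row, out$acceptor_row)), ]
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond census over a trajectory
#'
#' Per-frame counts by class, block-averaged: total / interchain /
#' intrachain protein-protein (P-P), protein-water (P-W), and water-water
#' per water molecule, the latter attributing each W-W bond to both partner
#' waters (2 N_WW / N_waters).  Also reports the intrachain hydrogen bonds
#' per protein residue.  Water classes are absent (NULL) when the system
#' has no water.
#'
#' @param traj a `trajectory`.
#' @param criterion an [hbond_criterion()].
#' @param window trailing analysis window (ns); NULL = full trajectory.
#' @param n_blocks number of blocks.
#' @return object of class `hbond_census`: list with `per_frame`
#'   (data.frame of counts), `pp`, `pp_interchain`, `pp_intrachain`
#'   ([block_average()] results), `pw`, `ww_per_water` (NULL without
#'   water), `intrachain_per_residue`, `n_waters`, `n_residues`.
#' @export
hbond_census <- function(traj, criterion = hbond_criterion(), window = NULL,
                         n_blocks = 5L) {
  system <- traj$topology
  inv <- hbond_inventory(system)
  a <- system$atoms
  n_waters <- length(unique(paste(a$chain_id, a$res_index)[is_water_atom(a)]))
  n_residues <- nrow(residue_table(system)) - n_waters
  per_frame <- do.call(rbind, lapply(seq_len(n_frames(traj)), function(k) {
    hb <- find_hbonds(system, criterion, xyz = traj$frames[[k]], inventory = inv)
    data.frame(frame = k, time = traj$times[k],
               pp = sum(hb$class == "PP"),
               pp_interchain = sum(hb$class == "PP" & hb$span == "interchain"),
               pp_intrachain = sum(hb$class == "PP" & hb$span == "intrachain"),
               pw = sum(hb$class == "PW"),
               ww = sum(hb$class == "WW"))
  }))
  ba <- function(v) block_average(v, times = per_frame$time, window = window,
                                  n_blocks = n_blocks)
  has_water <- n_waters > 0L
  pp_intra <- ba(per_frame$pp_intrachain)
  structure(list(
    per_frame = per_frame,
    pp = ba(per_frame$pp),
    pp_interchain = ba(per_frame$pp_interchain),
    pp_intrachain = pp_intra,
    pw = if (has_water) ba(per_frame$pw) else NULL,
    ww_per_water = if (has_water) ba(2 * per_frame$ww / n_waters) else NULL,
    intrachain_per_residue = pp_intra$mean / n_residues,
    n_waters = n_waters, n_residues = n_residues),
    class = "hbond_census")
}

#' @export
print.hbond_census <- function(x, ...) {
  cat(sprintf("<hbond_census> <P-P> %.2f +/- %.2f (inter %.2f, intra %.2f)",
              x$pp$mean, x$pp$error, x$pp_interchain$mean, x$pp_intrachain$mean))
  if (!is.null(x$pw)) {
    cat(sprintf("; <P-W> %.2f; <W-W>/W %.3f", x$pw$mean, x$ww_per_water$mean))
  }
  cat("\n")
  invisible(x)
}

# helper: O(i) -> N(i+4) bonds inside one helix range for one frame
count_i_i4 <- function(system, xyz, chain_id, res_range, criterion) {
  a <- system$atoms
  in_ch <- a$chain_id == chain_id & !is_water_atom(a)
  atom_row <- function(ri, nm) {
    w <- which(in_ch & a$res_index == ri & a$name == nm)
    if (length(w) >= 1L) w[1L] else NA_integer_
  }
  lo <- min(res_range); hi <- max(res_range)
  if (hi - lo + 1L < 5L) return(0L)
  count <- 0L
  for (i in seq(lo, hi - 4L)) {
    o_row <- atom_row(i, "O")
    n_row <- atom_row(i + 4L, "N")
    ca_row <- atom_row(i + 4L, "CA")
    c_row <- atom_row(i + 3L, "C")
    h_row <- atom_row(i + 4L, "H")
    if (anyNA(c(o_row, n_row))) next
    d <- vec_norm(xyz[o_row, ] - xyz[n_row, ])
    if (d > criterion$max_da_distance) next
    h <- if (!is.na(h_row)) xyz[h_row, ] else {
      if (anyNA(c(ca_row, c_row))) next
      reconstruct_h(xyz, n_row, ca_row, c_row)
    }
    v_h <- h - xyz[n_row, ]
    v_a <- xyz[o_row, ] - xyz[n_row, ]
    ang <- acos(pmin(1, pmax(-1, sum(v_h * v_a) /
                               (vec_norm(v_h) * vec_norm(v_a))))) * 180 / pi
    if (ang <= criterion$max_hda_angle) count <- count + 1L
  }
  count
}

#' Helical i -> i+4 hydrogen-bond counts per helix
#'
#' Counts backbone bonds from the carbonyl O of residue i to the amide N-H
#' of residue i+4, with both residues inside the same annotated helix,
#' per frame, then block-averages per helix.
#'
#' @param traj a `trajectory`.
#' @param annotation a `region_annotation` with helix ranges.
#' @param criterion an [hbond_criterion()].
#' @param window trailing analysis window (ns); NULL = full trajectory.
#' @param n_blocks number of blocks.
#' @return data.frame: `helix_id`, `n_res`, `mean`, `error`.
#' @export
helix_i_to_i4 <- function(traj, annotation, criterion = hbond_criterion(),
                          window = NULL, n_blocks = 5L) {
  hr <- helix_ranges(annotation)
  if (nrow(hr) == 0L) stop("annotation contains no helix ranges")
  system <- traj$topology
  out <- lapply(seq_len(nrow(hr)), function(h) {
    rng <- seq(hr$res_start[h], hr$res_end[h])
    if (length(rng) < 5L) {
      warning("helix ", hr$helix_id[h], " has fewer than 5 residues; count is 0")
    }
    counts <- vapply(seq_len(n_frames(traj)), function(k) {
      as.numeric(count_i_i4(system, traj$frames[[k]], hr$chain_id[h], rng,
                            criterion))
    }, numeric(1L))
    b <- block_average(counts, times = traj$times, window = window,
                       n_blocks = n_blocks)
    data.frame(helix_id = hr$helix_id[h], n_res = length(rng),
               mean = b$mean, error = b$error, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Loop-to-helix hydrogen-bond table with bridge flags
#'
#' For every loop residue and every annotated helix, the block-averaged
#' number of hydrogen bonds per frame in which the loop residue
#' participates in either donor or acceptor role with an atom of that helix
#' (water excluded).  A loop residue is flagged as a bridge for its own
#' chain when its mean count to BOTH helices of that chain exceeds
#' `threshold`.
#'
#' @param traj a `trajectory`.
#' @param annotation a `region_annotation` containing LOOP (and HELIX1 /
#'   HELIX2) labels.
#' @param criterion an [hbond_criterion()].
#' @param threshold bridge-flag threshold on the mean count (default 0.05).
#' @param window trailing analysis window (ns); NULL = full trajectory.
#' @param n_blocks number of blocks.
#' @return list with `table` (data.frame `chain_id`, `res_index`,
#'   `res_name`, `helix_id`, `mean`, `error`) and `bridges` (data.frame
#'   `chain_id`, `res_index`, `bridge`).
#' @export
loop_bridge_table <- function(traj, annotation, criterion = hbond_criterion(),
                              threshold = 0.05, window = NULL, n_blocks = 5L) {
  if (!any(annotation$label == "LOOP")) {
    stop("annotation has no LOOP region (loopless topology)")
  }
  hr <- helix_ranges(annotation)
  system <- traj$topology
  inv <- hbond_inventory(system)
  a <- system$atoms
  loops <- annotation[annotation$label == "LOOP", ]
  res_tab <- residue_table(system)
  loop_keys <- paste(loops$chain_id, loops$res_index)

  # per frame, per (loop residue x helix) count matrix
  nf <- n_frames(traj)
  counts <- array(0, dim = c(length(loop_keys), nrow(hr), nf))
  for (k in seq_len(nf)) {
    hb <- find_hbonds(system, criterion, xyz = traj$frames[[k]], inventory = inv)
    hb <- hb[hb$class == "PP", , drop = FALSE]
    if (nrow(hb) == 0L) next
    d_key <- paste(a$chain_id[hb$donor_row], a$res_index[hb$donor_row])
    a_key <- paste(a$chain_id[hb$acceptor_row], a$res_index[hb$acceptor_row])
    for (li in seq_along(loop_keys)) {
      as_donor <- d_key == loop_keys[li]
      as_acceptor <- a_key == loop_keys[li]
      if (!any(as_donor | as_acceptor)) next
      partner_row <- ifelse(as_donor, hb$acceptor_row, hb$donor_row)
      sel <- which(as_donor | as_acceptor)
      for (s in sel) {
        pr <- partner_row[s]
        hit <- which(hr$chain_id == a$chain_id[pr] &
                     hr$res_start <= a$res_index[pr] &
                     hr$res_end >= a$res_index[pr])
        if (length(hit) == 1L) counts[li, hit, k] <- counts[li, hit, k] + 1
      }
    }
  }
  rows <- list()
  for (li in seq_along(loop_keys)) {
    rn <- res_tab$res_name[match(loop_keys[li],
                                 paste(res_tab$chain_id, res_tab$res_index))]
    for (h in seq_len(nrow(hr))) {
      b <- block_average(counts[li, h, ], times = traj$times, window = window,
                         n_blocks = n_blocks)
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = loops$chain_id[li], res_index = loops$res_index[li],
        res_name = rn, helix_id = hr$helix_id[h],
        mean = b$mean, error = b$error, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  bridges <- do.call(rbind, lapply(seq_along(loop_keys), function(li) {
    ch <- loops$chain_id[li]
    own <- tab$chain_id == ch & tab$res_index == loops$res_index[li] &
      tab$helix_id %in% hr$helix_id[hr$chain_id == ch]
    data.frame(chain_id = ch, res_index = loops$res_index[li],
               bridge = sum(tab$mean[own] > threshold) >= 2L,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, bridges = bridges)
}
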