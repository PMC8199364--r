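# Fixtures are built in code: ideal helices from the chain builder, a
# closed-form parametric helix as the independent geometry oracle, and
# small hand-placed systems for hydrogen-bond geometry.

ideal_helix_chain <- function(n = 20, phi = -60, psi = -50, res = "ALA",
                              chain_id = "A") {
  build_chain(rep(res, n), matrix(rep(c(phi, psi), n), ncol = 2, byrow = TRUE),
              chain_id = chain_id)
}

# Closed-form alpha-helix C-alpha trace: the oracle the axis/metric code is
# checked against.  radius nm, pitch nm, residues per turn.
parametric_helix <- function(n = 24, radius = 0.23, pitch = 0.54,
                             res_per_turn = 3.6) {
  i <- seq_len(n) - 1
  ang <- 2 * pi * i / res_per_turn
  cbind(radius * cos(ang), radius * sin(ang), pitch * i / res_per_turn)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]), 2 * (q[2] * q[4] + q[3] * q[1]),
           2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[2] * q[1]),
           2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]), 1 - 2 * (q[2]^2 + q[3]^2)),
         nrow = 3, byrow = TRUE)
}

# Two rigid waters whose oxygens are `d` nm apart; when `aligned`, one O-H
# of the first water points straight along the O-O vector (a textbook
# hydrogen-bond geometry).
two_waters <- function(d = 0.28, aligned = TRUE) {
  half <- (109.47 / 2) * pi / 180
  o1 <- c(0, 0, 0)
  if (aligned) {
    h1a <- o1 + 0.1 * c(1, 0, 0)
    h1b <- o1 + 0.1 * c(cos(2 * half), sin(2 * half), 0)
  } else {
    h1a <- o1 + 0.1 * c(0, 0, 1)                       # perpendicular to O-O
    h1b <- o1 + 0.1 * c(0, sin(2 * half), cos(2 * half))
  }
  o2 <- c(d, 0, 0)
  # second water's hydrogens point away from water 1
  h2a <- o2 + 0.1 * c(cos(half), sin(half), 0)
  h2b <- o2 + 0.1 * c(cos(half), -sin(half), 0)
  atoms <- data.frame(
    serial = 1:6, name = rep(c("OW", "HW1", "HW2"), 2),
    element = rep(c("O", "H", "H"), 2),
    res_index = rep(1:2, each = 3), res_name = "SOL", chain_id = "W",
    stringsAsFactors = FALSE)
  molecular_system(atoms, rbind(o1, h1a, h1b, o2, h2a, h2b))
}

# Minimal protein-like system from explicit atom placements.
bare_system <- function(names, res_index, chain_id, xyz, res_name = "ALA") {
  atoms <- data.frame(serial = seq_along(names), name = names,
                      element = substr(names, 1, 1),
                      res_index = res_index,
                      res_name = rep_len(res_name, length(names)),
                      chain_id = chain_id, stringsAsFactors = FALSE)
  molecular_system(atoms, xyz)
}

static_trajectory <- function(system, n = 4, dt = 0.1) {
  trajectory(system, rep(list(system$xyz), n), times = (seq_len(n) - 1) * dt)
}

# Independent brute-force hydrogen-bond enumeration used as the oracle for
# the detection code: scans every backbone N(H, reconstructed) / carbonyl O
# pair with its own distance and angle computation.
brute_force_backbone_hbonds <- function(system, xyz = NULL,
                                        max_d = 0.35, max_ang = 30) {
  if (is.null(xyz)) xyz <- system$xyz
  a <- system$atoms
  found <- list()
  for (ch in unique(a$chain_id)) {
    res_ids <- sort(unique(a$res_index[a$chain_id == ch]))
    row <- function(ri, nm) {
      w <- which(a$chain_id == ch & a$res_index == ri & a$name == nm)
      if (length(w)) w[1] else NA_integer_
    }
    for (di in res_ids[-1]) {
      nr <- row(di, "N"); car <- row(di, "CA"); cpr <- row(di - 1, "C")
      if (anyNA(c(nr, car, cpr))) next
      u1 <- xyz[cpr, ] - xyz[nr, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- xyz[car, ] - xyz[nr, ]; u2 <- u2 / sqrt(sum(u2^2))
      hdir <- -(u1 + u2); hdir <- hdir / sqrt(sum(hdir^2))
      for (ch2 in unique(a$chain_id)) for (ai in sort(unique(a$res_index[a$chain_id == ch2]))) {
        if (ch2 == ch && ai %in% c(di, di - 1)) next
        or <- which(a$chain_id == ch2 & a$res_index == ai & a$name == "O")
        if (length(or) != 1) next
        v <- xyz[or, ] - xyz[nr, ]
        dist <- sqrt(sum(v^2))
        if (dist > max_d) next
        ang <- acos(min(1, max(-1, sum(hdir * v) / dist))) * 180 / pi
        if (ang <= max_ang) {
          found[[length(found) + 1]] <- data.frame(
            donor_chain = ch, donor_res = di, acceptor_chain = ch2,
            acceptor_res = ai, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(found)) do.call(rbind, found) else
    data.frame(donor_chain = character(), donor_res = integer(),
               acceptor_chain = character(), acceptor_res = integer())
}
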