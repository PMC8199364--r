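test_that("a textbook water pair is detected; a distant pair is not", {
  w <- two_waters(d = 0.28, aligned = TRUE)
  hb <- find_hbonds(w)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$class, "WW")
  expect_equal(hb$distance, 0.28, tolerance = 1e-9)
  expect_lt(hb$angle, 1e-6)
  expect_equal(nrow(find_hbonds(two_waters(d = 0.50, aligned = TRUE))), 0)
  # misaligned hydrogens fail the angle cut even at bonding distance
  expect_equal(nrow(find_hbonds(two_waters(d = 0.28, aligned = FALSE))), 0)
})

test_that("criterion constructor validates its ranges", {
  expect_error(hbond_criterion(max_da_distance = 1.2), "distance")
  expect_error(hbond_criterion(max_hda_angle = 95), "angle")
})

test_that("an ideal helix has exactly the O(i)->N(i+4) bond set", {
  ch <- ideal_helix_chain(20)
  hb <- find_hbonds(ch)
  expect_equal(nrow(hb), 16)                       # n - 4
  a <- ch$atoms
  offs <- a$res_index[hb$donor_row] - a$res_index[hb$acceptor_row]
  expect_true(all(offs == 4))
  expect_true(all(a$name[hb$donor_row] == "N"))
  expect_true(all(a$name[hb$acceptor_row] == "O"))
  # brute-force enumeration oracle agrees pair-for-pair
  bf <- brute_force_backbone_hbonds(ch)
  expect_equal(nrow(bf), 16)
  got <- sort(paste(a$res_index[hb$donor_row], a$res_index[hb$acceptor_row]))
  expect_equal(got, sort(paste(bf$donor_res, bf$acceptor_res)))
})

test_that("detected bonds satisfy the criterion on independent re-measurement", {
  b <- build_bundle("wtrop_like")
  tr <- generate_trajectory(b$system, 3, noise_model(0.01, seed = 21))
  crit <- hbond_criterion()
  for (k in seq_len(3)) {
    hb <- find_hbonds(b$system, crit, xyz = tr$frames[[k]])
    expect_true(all(hb$distance <= crit$max_da_distance))
    expect_true(all(hb$angle <= crit$max_hda_angle))
    # and the frame's bond set matches the brute-force oracle
    bf <- brute_force_backbone_hbonds(b$system, xyz = tr$frames[[k]])
    expect_equal(nrow(hb[hb$class == "PP", ]), nrow(bf))
  }
})

test_that("enlarging the distance cutoff never decreases the count", {
  ch <- ideal_helix_chain(15)
  tr <- generate_trajectory(ch, 4, noise_model(0.02, seed = 31))
  for (k in 1:4) {
    counts <- vapply(c(0.25, 0.30, 0.35, 0.45), function(d) {
      nrow(find_hbonds(ch, hbond_criterion(max_da_distance = d),
                       xyz = tr$frames[[k]]))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("census classes partition and water bookkeeping is per molecule", {
  # protein + waters
  prot <- build_bundle("wtrop_like")$system
  w <- place_waters(c(3, 3, 3), 60, min_dist = 0.3, seed = 8)
  w$box <- NULL
  sys <- merge_systems(prot, w)
  tr <- generate_trajectory(sys, 4, noise_model(0.005, seed = 2))
  cs <- hbond_census(tr, n_blocks = 2)
  expect_equal(cs$n_waters, 60)
  expect_equal(cs$n_residues, 126)
  # exact partition per frame
  expect_equal(cs$per_frame$pp,
               cs$per_frame$pp_interchain + cs$per_frame$pp_intrachain)
  expect_equal(cs$intrachain_per_residue, cs$pp_intrachain$mean / 126)
  # protein-only census reports water classes as absent
  trp <- generate_trajectory(prot, 4, noise_model(0.005, seed = 3))
  csp <- hbond_census(trp, n_blocks = 2)
  expect_null(csp$pw)
  expect_null(csp$ww_per_water)
  expect_gte(csp$pp$mean, 0)
  # a single bonded water pair: <W-W>/W = 2 * 1 / 2 = 1
  tw <- two_waters(0.28)
  trw <- static_trajectory(tw, 4)
  csw <- hbond_census(trw, n_blocks = 2)
  expect_equal(csw$ww_per_water$mean, 1.0)
})

test_that("helical i->i+4 counts follow the helix ranges", {
  ch <- ideal_helix_chain(20)
  ann <- region_annotation(data.frame(chain_id = "A", res_start = 1,
                                      res_end = 20, label = "HELIX"))
  tr <- static_trajectory(ch, 4)
  h <- helix_i_to_i4(tr, ann, n_blocks = 2)
  expect_equal(h$mean, 16)
  expect_equal(h$error, 0)
  # counts are bounded by length - 4
  expect_lte(h$mean, h$n_res - 4)
  # short helix: zero with a warning
  ann4 <- region_annotation(data.frame(chain_id = "A", res_start = c(1, 5),
                                       res_end = c(4, 20),
                                       label = c("HELIX", "C_TAIL")))
  expect_warning(h4 <- helix_i_to_i4(tr, ann4, n_blocks = 2), "fewer than 5")
  expect_equal(h4$mean, 0)
})

test_that("displacing helix residues removes exactly their bonds", {
  ch <- ideal_helix_chain(20)
  ann <- region_annotation(data.frame(chain_id = "A", res_start = 1,
                                      res_end = 20, label = "HELIX"))
  xyz <- ch$xyz
  out <- ch$atoms$res_index %in% 5:8
  xyz[out, ] <- xyz[out, ] + 1.0     # push residues 5-8 1 nm outward
  tr <- trajectory(ch, list(xyz, xyz), times = c(0, 1))
  h <- helix_i_to_i4(tr, ann, n_blocks = 2)
  bf <- brute_force_backbone_hbonds(ch, xyz = xyz)
  expect_equal(h$mean, nrow(bf))
  # bonds lost are exactly those involving residues 5-8 as O(i) or N(i+4)
  lost <- sum(vapply(1:16, function(i) any(c(i, i + 4) %in% 5:8), logical(1)))
  expect_equal(h$mean, 16 - lost)
})

test_that("loop bridge table flags residues bonded to both helices", {
  # hand-placed chain: helix1 1-6, loop 7-8, helix2 9-14.  Residue 7's
  # carbonyl O sits between the reconstructed amide H of residue 3 (helix1)
  # and of residue 11 (helix2), accepting from both; everything else is
  # parked far apart.
  n_res <- 14
  names <- rep(c("N", "CA", "C", "O"), n_res)
  res_index <- rep(1:n_res, each = 4)
  far <- function(i) c(5 * i, 10, 0)  # parking positions
  xyz <- matrix(NA_real_, n_res * 4, 3)
  for (i in 1:n_res) {
    base <- far(i)
    xyz[(i - 1) * 4 + 1:4, ] <- rbind(base, base + c(0.15, 0, 0),
                                      base + c(0.3, 0, 0),
                                      base + c(0.3, 0.12, 0))
  }
  row <- function(i, nm) (i - 1) * 4 + match(nm, c("N", "CA", "C", "O"))
  # donor residue 3: N at origin-ish with C(2) and CA(3) behind it so the
  # reconstructed H points along +x
  P <- c(0.29, 0, 0)
  xyz[row(3, "N"), ] <- c(0, 0, 0)
  xyz[row(2, "C"), ] <- c(-0.147 / sqrt(2), 0.147 / sqrt(2), 0)
  xyz[row(3, "CA"), ] <- c(-0.146 / sqrt(2), -0.146 / sqrt(2), 0)
  # donor residue 11 mirrored on the other side of P, H points along -x
  xyz[row(11, "N"), ] <- c(0.58, 0, 0)
  xyz[row(10, "C"), ] <- c(0.58 + 0.147 / sqrt(2), 0.147 / sqrt(2), 0)
  xyz[row(11, "CA"), ] <- c(0.58 + 0.146 / sqrt(2), -0.146 / sqrt(2), 0)
  # loop residue 7's O at P
  xyz[row(7, "O"), ] <- P
  sys <- bare_system(names, res_index, "A", xyz)
  ann <- region_annotation(data.frame(
    chain_id = "A", res_start = c(1, 7, 9), res_end = c(6, 8, 14),
    label = c("HELIX1", "LOOP", "HELIX2")))
  tr <- static_trajectory(sys, 4)
  lb <- loop_bridge_table(tr, ann, n_blocks = 2)
  t7 <- lb$table[lb$table$res_index == 7, ]
  expect_equal(sort(t7$mean[t7$helix_id %in% c("A1", "A2")]), c(1, 1))
  expect_true(lb$bridges$bridge[lb$bridges$res_index == 7])
  expect_false(any(lb$bridges$bridge[lb$bridges$res_index != 7]))
  # push the loop O away: every entry empties, no bridges
  xyz2 <- xyz
  xyz2[row(7, "O"), ] <- P + c(0, 0, 2)
  sys2 <- bare_system(names, res_index, "A", xyz2)
  lb2 <- loop_bridge_table(static_trajectory(sys2, 4), ann, n_blocks = 2)
  expect_true(all(lb2$table$mean == 0))
  expect_false(any(lb2$bridges$bridge))
  # loopless annotations are rejected
  annr <- region_annotation(data.frame(chain_id = "A", res_start = 1,
                                       res_end = 14, label = "HELIX"))
  expect_error(loop_bridge_table(tr, annr), "no LOOP")
})
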