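test_that("dihedral computation matches a brute-force plane-normal formula", {
  brute <- function(a, b, c, d) {
    n1 <- pracma::cross(b - a, c - b)
    n2 <- pracma::cross(c - b, d - c)
    ang <- acos(min(1, max(-1, sum(n1 * n2) /
                             sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
    s <- sign(sum(pracma::cross(n1, n2) * (c - b)))
    if (s < 0) -ang else ang
  }
  set.seed(8)
  for (i in 1:25) {
    p <- matrix(rnorm(12), ncol = 3)
    got <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    want <- brute(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(helixtraj:::wrap_angle(got - want), 0, tolerance = 1e-9)
  }
  # collinear geometry is undefined
  expect_true(is.na(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                   c(3, 0, 0))))
})

test_that("torsions of an ideal helix and a 2-residue chain", {
  ch <- ideal_helix_chain(20)
  tt <- backbone_torsions(ch, "A")
  expect_equal(tt$phi[-1], rep(-60, 19), tolerance = 1e-7)
  expect_equal(tt$psi[-20], rep(-50, 19), tolerance = 1e-7)
  ch2 <- build_chain(c("ALA", "GLY"), matrix(c(-70, 120, -70, 120), 2,
                                             byrow = TRUE))
  t2 <- backbone_torsions(ch2, "A")
  expect_equal(sum(!is.na(t2$phi)), 1)
  expect_equal(sum(!is.na(t2$psi)), 1)
})

test_that("region classification is total, disjoint and hits the anchors", {
  reg <- rama_regions()
  expect_equal(classify_rama(-60, -50, reg), "ALPHA")
  expect_equal(classify_rama(-120, 130, reg), "BETA")
  expect_equal(classify_rama(60, 45, reg), "LEFT_ALPHA")
  expect_equal(classify_rama(150, -120, reg), "OTHER")
  # total over a dense grid, and boundary-stable
  grid <- expand.grid(phi = seq(-180, 180, by = 7.5),
                      psi = seq(-180, 180, by = 7.5))
  lab <- classify_rama(grid$phi, grid$psi, reg)
  expect_true(all(lab %in% c("ALPHA", "BETA", "LEFT_ALPHA", "OTHER")))
  # overlapping custom regions are rejected at load time
  expect_error(rama_regions(alpha = matrix(c(-180, 0, -120, 50), 1),
                            beta = matrix(c(-60, -20, 0, 60), 1)), "overlap")
})

test_that("region percentages sum to 100 and split the two-state fixture", {
  ch <- ideal_helix_chain(15)
  tr <- static_trajectory(ch, 6)
  p <- region_percentages(tr, n_blocks = 3)
  expect_equal(sum(p$percent), 100, tolerance = 1e-9)
  expect_equal(unname(p$percent["ALPHA"]), 100)
  # 22 residues: 10 defined pairs alpha, 10 beta
  tor <- rbind(matrix(rep(c(-60, -50), 11), ncol = 2, byrow = TRUE),
               matrix(rep(c(-120, 130), 11), ncol = 2, byrow = TRUE))
  ch2 <- build_chain(rep("ALA", 22), tor)
  tr2 <- static_trajectory(ch2, 4)
  p2 <- region_percentages(tr2, n_blocks = 2)
  expect_equal(unname(p2$percent["ALPHA"]), 50)
  expect_equal(unname(p2$percent["BETA"]), 50)
  expect_equal(sum(p2$percent), 100, tolerance = 1e-12)
})

test_that("torsion time maps record every frame and grow with noise", {
  ch <- ideal_helix_chain(10)
  tr <- static_trajectory(ch, 8)
  tm <- torsion_time_map(tr, "A", 5)
  expect_equal(nrow(tm$map), 8)
  expect_equal(tm$footprint_cells, 1)
  expect_equal(tm$footprint_area_deg2, 25)
  expect_error(torsion_time_map(tr, "A", 1), "phi undefined")
  # larger noise never shrinks the explored footprint (matched seeds)
  cells <- vapply(c(0.005, 0.05), function(s) {
    trn <- generate_trajectory(ch, 40, noise_model(s, seed = 19))
    torsion_time_map(trn, "A", 5)$footprint_cells
  }, numeric(1))
  expect_gte(cells[2], cells[1])
})

test_that("helix mean torsions use two-stage circular averaging", {
  ch <- ideal_helix_chain(15)
  ann <- region_annotation(data.frame(chain_id = "A", res_start = 1,
                                      res_end = 15, label = "HELIX"))
  tr <- static_trajectory(ch, 6)
  mt <- helix_mean_torsions(tr, ann, n_blocks = 3)
  expect_equal(mt$phi_mean, -60, tolerance = 1e-6)
  expect_equal(mt$psi_mean, -50, tolerance = 1e-6)
  expect_equal(mt$phi_err, 0, tolerance = 1e-9)
  expect_equal(mt$psi_err, 0, tolerance = 1e-9)
  # two pure blocks at a and b: mean (a+b)/2, error |a-b|/2
  cha <- ideal_helix_chain(15, phi = -58, psi = -48)
  chb <- ideal_helix_chain(15, phi = -66, psi = -42)
  tr2 <- trajectory(ch, c(rep(list(cha$xyz), 3), rep(list(chb$xyz), 3)),
                    times = 0:5)
  mt2 <- helix_mean_torsions(tr2, ann, n_blocks = 2)
  expect_equal(mt2$phi_mean, -62, tolerance = 1e-6)
  expect_equal(mt2$phi_err, 4, tolerance = 1e-6)
  expect_equal(mt2$psi_mean, -45, tolerance = 1e-6)
  expect_equal(mt2$psi_err, 3, tolerance = 1e-6)
  expect_error(helix_mean_torsions(tr, ann, window = 99), "window")
})

test_that("circular statistics handle the wrap point", {
  expect_equal(circular_mean(c(179, -179)), 180)
  expect_equal(circular_mean(c(10, 20) + 360), circular_mean(c(10, 20)))
  expect_equal(circular_mean(c(-170, 170)), 180, tolerance = 1e-9)
  b <- block_average(c(179, 179, -179, -179), n_blocks = 2, circular = TRUE)
  expect_equal(b$mean, 180)
  expect_equal(b$error, 1, tolerance = 1e-9)
})
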