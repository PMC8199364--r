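test_that("kabsch_fit recovers exact rigid transforms", {
  set.seed(1)
  x <- matrix(rnorm(30), ncol = 3)
  id <- kabsch_fit(x, x)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-10)
  # 90 degrees about z plus a shift
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  target <- sweep(x %*% t(Rz), 2, c(1, 2, 3), "+")
  tr <- kabsch_fit(x, target)
  expect_lt(max(abs(apply_transform(tr, x) - target)), 1e-10)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
  expect_equal(t(tr$rotation) %*% tr$rotation, diag(3), tolerance = 1e-10)
  expect_error(kabsch_fit(x[1:2, ], x[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "collinear")
})

test_that("kabsch_fit is invariant under simultaneous rigid motion", {
  set.seed(2)
  m <- matrix(rnorm(30), ncol = 3)
  q <- matrix(rnorm(30), ncol = 3)
  base <- kabsch_fit(m, q)
  R <- random_rotation(); t0 <- c(0.3, -1, 2)
  m2 <- sweep(m %*% t(R), 2, t0, "+")
  q2 <- sweep(q %*% t(R), 2, t0, "+")
  moved <- kabsch_fit(m2, q2)
  # the residual after fitting must be identical
  r1 <- apply_transform(base, m) - q
  r2 <- apply_transform(moved, m2) - q2
  expect_equal(sqrt(mean(r1^2)), sqrt(mean(r2^2)), tolerance = 1e-10)
})

test_that("rmsd_series obeys the translation and superposition contracts", {
  ch <- ideal_helix_chain(12)
  sel <- select_atoms(ch, "CA")
  # uniform translation, no fit: rmsd = |t| = 0.5 nm
  shift <- ch$xyz + matrix(rep(c(0.3, 0.4, 0), each = nrow(ch$xyz)), ncol = 3)
  tr <- trajectory(ch, list(shift, shift), times = c(0, 1))
  expect_equal(rmsd_series(tr, ch, sel, fit = FALSE)$values, c(0.5, 0.5),
               tolerance = 1e-12)
  # rigid rotation removed by fitting
  set.seed(3)
  frames <- lapply(1:4, function(k) {
    sweep(ch$xyz %*% t(random_rotation()), 2, rnorm(3), "+")
  })
  tr2 <- trajectory(ch, frames)
  expect_lt(max(rmsd_series(tr2, ch, sel, fit = TRUE)$values), 1e-9)
  # fitted rmsd never exceeds unfitted rmsd
  tr3 <- generate_trajectory(ch, 10, noise_model(0.05, seed = 5))
  f_on <- rmsd_series(tr3, ch, sel, fit = TRUE)$values
  f_off <- rmsd_series(tr3, ch, sel, fit = FALSE)$values
  expect_true(all(f_on <= f_off + 1e-12))
  expect_error(rmsd_series(tr3, ch, select_atoms(ch, atoms = "OXT")),
               "empty selection")
})

test_that("relative deviation (%D) contract: zero, arithmetic, scale invariance", {
  mk <- function(v) structure(list(times = seq_along(v), values = v,
                                   fitted = TRUE, n_atoms = 1),
                              class = "deviation_series")
  s <- mk(c(0.1, 0.2, 0.3))
  expect_equal(percent_increase(s, s)$values, rep(0, 3))
  # the magnitude scale of a strong thermal contrast: 0.324 vs 0.1 -> 224%
  p <- percent_increase(mk(rep(0.324, 3)), mk(rep(0.1, 3)))
  expect_equal(p$values, rep(2.24, 3), tolerance = 1e-12)
  expect_equal(p$mean, 2.24, tolerance = 1e-12)
  # scale invariance under c > 0
  p2 <- percent_increase(mk(7 * c(0.324, 0.324, 0.324)), mk(7 * rep(0.1, 3)))
  expect_equal(p2$values, p$values, tolerance = 1e-12)
  # zero reference points are excluded and counted
  expect_warning(pz <- percent_increase(mk(c(0.2, 0.2)), mk(c(0, 0.1))),
                 "undefined")
  expect_equal(pz$n_undefined, 1)
  expect_true(is.na(pz$values[1]))
  expect_equal(pz$mean, 1)
  expect_error(percent_increase(mk(1:3 / 10), mk(1:4 / 10)), "time grid")
})

test_that("rmsf: static zero, explicit chain averaging, reference modes", {
  ch <- ideal_helix_chain(10)
  sel <- select_atoms(ch, "CA")
  tr <- static_trajectory(ch, 5)
  expect_equal(rmsf_per_residue(tr, sel)$rmsf, rep(0, 10))
  expect_error(rmsf_per_residue(static_trajectory(ch, 1), sel), "2 frames")
  # chain averaging is (u + v) / 2
  b <- build_bundle("wtrop_like")
  trb <- generate_trajectory(b$system, 30, noise_model(0.02, seed = 9))
  selb <- select_atoms(b$system, "CA")
  per_chain <- rmsf_per_residue(trb, selb, chain_average = FALSE)
  avg <- rmsf_per_residue(trb, selb, chain_average = TRUE)
  u <- per_chain$rmsf[per_chain$chain_id == "A"]
  v <- per_chain$rmsf[per_chain$chain_id == "B"]
  expect_equal(avg$rmsf, (u + v) / 2, tolerance = 1e-12)
  # first_frame reference reproduces the literal fluctuation definition
  r_ff <- rmsf_per_residue(trb, selb, reference = "first_frame")
  r_tm <- rmsf_per_residue(trb, selb, reference = "time_mean")
  expect_true(mean(r_ff$rmsf) >= mean(r_tm$rmsf))
})

test_that("mean rmsd^2 over frames equals mean rmsf^2 over atoms (no fit)", {
  ch <- ideal_helix_chain(8)
  sel <- select_atoms(ch, "CA")
  tr <- generate_trajectory(ch, 25, noise_model(0.04, seed = 13))
  rmsd2 <- mean(rmsd_series(tr, ch, sel, fit = FALSE)$values^2)
  rmsf2 <- mean(rmsf_per_residue(tr, sel, reference = ch,
                                 superpose = FALSE)$rmsf^2)
  expect_equal(rmsd2, rmsf2, tolerance = 1e-10)
})
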