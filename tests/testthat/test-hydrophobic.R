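make_point_sets <- function(na, nb, box, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(
    serial = 1:(na + nb), name = "CB", element = "C",
    res_index = c(1:na, 1:nb), res_name = "LEU",
    chain_id = rep(c("A", "B"), c(na, nb)), stringsAsFactors = FALSE)
  molecular_system(atoms, matrix(runif((na + nb) * 3), ncol = 3) %*% diag(box),
                   box = box)
}

test_that("rdf of uniform random points approaches the ideal-gas limit", {
  box <- c(4, 4, 4)
  sys <- make_point_sets(40, 40, box, seed = 5)
  set.seed(6)
  frames <- lapply(1:80, function(k) matrix(runif(80 * 3), ncol = 3) %*% diag(box))
  tr <- trajectory(sys, frames)
  sa <- select_atoms(sys, "CB", chains = "A")
  sb <- select_atoms(sys, "CB", chains = "B")
  g <- rdf(tr, sa, sb, bin_width = 0.1, r_max = 2, periodic = TRUE)
  sel <- g$r >= 0.5
  se <- 1 / sqrt(pmax(g$counts[sel], 1))
  expect_true(all(abs(g$g[sel] - 1) <= 3 * se))
})

test_that("rdf is symmetric and localises a fixed pair distance", {
  box <- c(3, 3, 3)
  sys <- make_point_sets(6, 6, box, seed = 2)
  tr <- trajectory(sys, list(sys$xyz))
  sa <- select_atoms(sys, "CB", chains = "A")
  sb <- select_atoms(sys, "CB", chains = "B")
  g_ab <- rdf(tr, sa, sb, bin_width = 0.05, r_max = 1.4, periodic = TRUE)
  g_ba <- rdf(tr, sb, sa, bin_width = 0.05, r_max = 1.4, periodic = TRUE)
  expect_equal(g_ab$g, g_ba$g)
  expect_error(rdf(tr, sa, sa, periodic = TRUE), "disjoint")
  expect_error(rdf(tr, sa, sb, r_max = 2, periodic = TRUE), "half")
  # two single points 0.73 nm apart: all mass in the bin containing 0.73
  one <- make_point_sets(1, 1, box)
  one$xyz <- rbind(c(1, 1, 1), c(1.73, 1, 1))
  tr1 <- trajectory(one, list(one$xyz))
  s1 <- select_atoms(one, "CB", chains = "A")
  s2 <- select_atoms(one, "CB", chains = "B")
  g1 <- rdf(tr1, s1, s2, bin_width = 0.05, r_max = 1.4, periodic = TRUE)
  expect_equal(sum(g1$counts), 1)
  expect_equal(g1$r[g1$counts == 1], 0.725, tolerance = 0.05)
})

test_that("the coordination integral is stable under bin-width doubling", {
  box <- c(4, 4, 4)
  sys <- make_point_sets(30, 30, box, seed = 9)
  set.seed(10)
  frames <- lapply(1:20, function(k) matrix(runif(60 * 3), ncol = 3) %*% diag(box))
  tr <- trajectory(sys, frames)
  sa <- select_atoms(sys, "CB", chains = "A")
  sb <- select_atoms(sys, "CB", chains = "B")
  coord_int <- function(g) {
    rho <- 30 / prod(box)
    sum(g$g * 4 * pi * g$r^2 * rho * g$bin_width)
  }
  g1 <- rdf(tr, sa, sb, bin_width = 0.05, r_max = 2, periodic = TRUE)
  g2 <- rdf(tr, sa, sb, bin_width = 0.10, r_max = 2, periodic = TRUE)
  expect_equal(coord_int(g1), coord_int(g2), tolerance = 0.02)
})

test_that("minimum-image distances respect the periodic bound", {
  box <- c(2, 2, 2)
  set.seed(4)
  xa <- matrix(runif(30), ncol = 3) %*% diag(box)
  xb <- matrix(runif(30), ncol = 3) %*% diag(box)
  d <- helixtraj:::cross_distances(xa, xb, box)
  expect_lte(max(d), sqrt(3) / 2 * max(box) + 1e-12)
})

test_that("centre distances match hand arithmetic and translations", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
               c(2, 2, 2), c(3, 2, 2), c(2, 3, 2))
  sys <- bare_system(rep("CB", 6), res_index = 1:6,
                     chain_id = rep(c("A", "B"), each = 3), xyz,
                     res_name = "LEU")
  sa <- select_atoms(sys, "CB", chains = "A")
  sb <- select_atoms(sys, "CB", chains = "B")
  # centroids (1/3, 1/3, 0) and (7/3, 7/3, 2): distance sqrt(4+4+4)=2*sqrt(3)
  expect_equal(cm_distance(sys, sa, sb), 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(cm_distance(sys, sa, sa), 0)
  # pure translation of one set by (1,0,0)
  sys2 <- sys
  sys2$xyz[4:6, ] <- sys$xyz[1:3, ] + matrix(rep(c(1, 0, 0), 3),
                                             ncol = 3, byrow = TRUE)
  expect_equal(cm_distance(sys2, sa, sb), 1.0, tolerance = 1e-12)
  expect_error(cm_distance(sys, sa, select_atoms(sys, atoms = "OXT")), "empty")
})

test_that("hydrophobic selections group per chain and per pair", {
  b <- build_bundle("wtrop_like")
  sels <- hydrophobic_selection(b$system, b$annotation, "per_chain")
  expect_equal(names(sels), c("A", "B"))
  expect_true(all(vapply(sels, length, integer(1)) > 0))
  expect_true(all(b$system$atoms$name[sels$A$index] == "CB"))
  r <- build_bundle("rm6_like")
  sp <- hydrophobic_selection(r$system, r$annotation, "per_pair")
  expect_equal(names(sp), c("AB", "CD"))
  expect_setequal(unique(sp$AB$refs$chain_id), c("A", "B"))
  expect_setequal(unique(sp$CD$refs$chain_id), c("C", "D"))
  expect_error(hydrophobic_selection(b$system, b$annotation, "per_pair"),
               "4 protein chains")
  # all-polar system: empty selections with a warning
  polar <- build_chain(rep("SER", 6),
                       matrix(rep(c(-60, -50), 6), ncol = 2, byrow = TRUE))
  expect_warning(s0 <- hydrophobic_selection(polar), "no hydrophobic")
  expect_equal(length(s0$A), 0)
})

test_that("first rdf peak decays as contact noise grows", {
  # tight contact fixture: two CB grids 0.5 nm apart, jittered
  mk_contact <- function(sigma, seed) {
    grid <- as.matrix(expand.grid(x = (0:3) * 0.6, y = (0:3) * 0.6, z = 0))
    xa <- grid; xb <- grid
    xb[, 3] <- 0.5
    sys <- bare_system(rep("CB", 32), res_index = c(1:16, 1:16),
                       chain_id = rep(c("A", "B"), each = 16),
                       rbind(xa, xb), res_name = "LEU")
    set.seed(seed)
    frames <- lapply(1:40, function(k) sys$xyz + matrix(rnorm(96, sd = sigma),
                                                        ncol = 3))
    trajectory(sys, frames)
  }
  peak <- vapply(c(0.01, 0.05, 0.10), function(s) {
    tr <- mk_contact(s, seed = 17)
    sa <- select_atoms(tr$topology, "CB", chains = "A")
    sb <- select_atoms(tr$topology, "CB", chains = "B")
    g <- rdf(tr, sa, sb, bin_width = 0.04, r_max = 1.2, volume = 3^3)
    max(g$g)
  }, numeric(1))
  expect_true(all(diff(peak) < 0))
})
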