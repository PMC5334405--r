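# Euler rotation, shape/charge discretization, dielectric

test_that("rotate_euler matches the closed-form rotation matrix", {
  set.seed(11)
  xyz <- matrix(rnorm(30, sd = 4), ncol = 3)
  s <- new_structure(data.frame(serial = 1:10, name = "CA", resname = "ALA",
                                chain = "A", resseq = 1:10, icode = "",
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                element = "C", charge = 0))
  expect_equal(coords(rotate_euler(s, c(0, 0, 0))), coords(s))
  expect_equal(coords(rotate_euler(s, c(360, 0, 0))), coords(s),
               tolerance = 1e-9)

  th <- 48 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cen <- colMeans(xyz)
  expected <- sweep(sweep(xyz, 2, cen) %*% t(Rz), 2, cen, "+")
  got <- coords(rotate_euler(s, c(48, 0, 0)))
  expect_equal(got, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(colMeans(got)), unname(cen), tolerance = 1e-9)
})

test_that("rotation preserves pairwise distances (rigid body)", {
  set.seed(12)
  for (rep in 1:5) {
    xyz <- matrix(rnorm(24, sd = 3), ncol = 3)
    s <- new_structure(data.frame(serial = 1:8, name = "CA", resname = "GLY",
                                  chain = "A", resseq = 1:8, icode = "",
                                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                  element = "C", charge = 0))
    ang <- runif(3, 0, 360) * c(1, 0.5, 1)
    r <- rotate_euler(s, ang)
    expect_equal(c(dist(coords(r))), c(dist(xyz)), tolerance = 1e-9)
  }
})

test_that("shape discretization matches brute-force occupancy", {
  s <- new_structure(data.frame(serial = 1L, name = "P", resname = "A",
                                chain = "R", resseq = 1L, icode = "",
                                x = 0.3, y = -0.2, z = 0.1,
                                element = "P", charge = 0))
  spec <- grid_spec(1, 10, c(-4.5, -4.5, -4.5))
  g <- discretize_shape(s, spec, "ligand")
  occ <- brute_occupancy(coords(s), 1.8, spec)
  expect_identical(g$values == 1, occ)
  expect_true(all(g$values %in% c(0, 1)))
})

test_that("receptor surface layer follows the erosion rule on a toy sphere", {
  # solid ball of atoms: boundary cells get surface weight, none of the
  # boundary carries the core penalty
  pts <- expand.grid(x = seq(-4, 4, 1.5), y = seq(-4, 4, 1.5),
                     z = seq(-4, 4, 1.5))
  pts <- pts[sqrt(rowSums(pts^2)) <= 5, ]
  s <- new_structure(data.frame(serial = seq_len(nrow(pts)), name = "CA",
                                resname = "ALA", chain = "A",
                                resseq = seq_len(nrow(pts)), icode = "",
                                x = pts$x, y = pts$y, z = pts$z,
                                element = "C", charge = 0))
  spec <- grid_spec(1, 24, c(-11.5, -11.5, -11.5))
  g <- discretize_shape(s, spec, "receptor", surface_thickness = 1.5,
                        surface_weight = 1, core_penalty = -15)
  occ <- g$values != 0
  n <- spec$n
  # erosion oracle: occupied cell with an empty cell center within 1.5
  offsets <- subset(expand.grid(i = -1:1, j = -1:1, k = -1:1),
                    (i != 0 | j != 0 | k != 0) & sqrt(i^2 + j^2 + k^2) <= 1.5)
  for (cell in sample(which(occ), 200)) {
    ijk <- arrayInd(cell, dim(occ))
    near_empty <- FALSE
    for (o in seq_len(nrow(offsets))) {
      p <- ijk + as.integer(offsets[o, ])
      if (any(p < 1 | p > n) || !occ[p[1], p[2], p[3]]) near_empty <- TRUE
    }
    expect_equal(g$values[cell], if (near_empty) 1 else -15)
  }
  expect_gt(sum(g$values == -15), 0)
  expect_error(discretize_shape(s, grid_spec(1, 8, c(-4, -4, -4)), "receptor"),
               "grid extent")
})

test_that("dielectric is the documented continuous piecewise form", {
  expect_equal(dielectric(6), 4)
  expect_equal(dielectric(8), 80)
  expect_equal(dielectric(7), 42)
  expect_equal(dielectric(0), 4)
  expect_equal(dielectric(100), 80)
  r <- seq(0, 12, by = 0.01)
  expect_true(all(diff(dielectric(r)) >= 0))
})

test_that("charge grids follow Coulomb with clamped soft core", {
  one <- function(q, x) {
    s <- new_structure(data.frame(serial = 1L, name = "N1", resname = "U",
                                  chain = "R", resseq = 1L, icode = "",
                                  x = x[1], y = x[2], z = x[3],
                                  element = "N", charge = q))
    s
  }
  spec <- grid_spec(1, 24, c(-11, -11, -11))
  g <- discretize_charge(one(1, c(0, 0, 0)), spec, "receptor")
  # probe cell at exactly (10, 0, 0): phi = 1 / (80 * 10)
  idx <- c(10 - spec$origin[1] + 1, 0 - spec$origin[2] + 1, 0 - spec$origin[3] + 1)
  expect_equal(g$values[idx[1], idx[2], idx[3]], 1 / (80 * 10),
               tolerance = 1e-12)
  # soft core: the cell at the atom uses r = 2
  at <- -spec$origin + 1
  expect_equal(g$values[at[1], at[2], at[3]], 1 / (dielectric(2) * 2))
  # beyond the cutoff the potential is exactly zero (corner cell, r ~ 19)
  expect_equal(g$values[1, 1, 1], 0)
})

test_that("ligand charge grid conserves total charge; potential is linear", {
  tc <- make_toy_complex(4)
  rna <- suppressMessages(assign_charges(tc$rna, quiet = TRUE))
  spec <- auto_grid_spec(tc$protein, rna, 1)
  g <- discretize_charge(rna, spec, "ligand")
  expect_equal(sum(g$values), sum(rna$atoms$charge), tolerance = 1e-6)

  # linearity in charges
  a1 <- rna; a1$atoms$charge <- seq_len(n_atoms(rna)) %% 3 - 1
  a2 <- rna; a2$atoms$charge <- rev(a1$atoms$charge)
  a12 <- rna; a12$atoms$charge <- a1$atoms$charge + a2$atoms$charge
  p1 <- suppressWarnings(discretize_charge(a1, spec, "receptor"))$values
  p2 <- suppressWarnings(discretize_charge(a2, spec, "receptor"))$values
  p12 <- suppressWarnings(discretize_charge(a12, spec, "receptor"))$values
  expect_equal(p12, p1 + p2, tolerance = 1e-9)
})

test_that("occupancy is covariant under whole-cell translations", {
  tc <- make_toy_complex(5)
  rna <- tc$rna
  spec <- auto_grid_spec(tc$protein, rna, 1)
  occ <- rpcdock:::occupancy_grid(rna, spec)
  shifted <- set_coords(rna, sweep(coords(rna), 2, c(3, 0, 0), "+"))
  occ2 <- rpcdock:::occupancy_grid(shifted, spec)
  n <- spec$n
  expect_identical(occ2[4:n, , ], occ[1:(n - 3), , ])
})
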