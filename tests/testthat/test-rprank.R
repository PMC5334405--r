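# Residue-base pair extraction, RMSD matching, training, decoy scoring

two_atom_complex <- function(sep) {
  atoms <- rbind(
    data.frame(serial = 1:5, name = c("N", "CA", "C", "O", "CB"),
               resname = "ALA", chain = "A", resseq = 1L, icode = "",
               x = c(-1.2, 0, 1.3, 1.4, 0.2), y = c(0.9, 0, 0.7, 1.9, -0.8),
               z = c(0, 0, 0, 0.3, 1.2), element = c("N", "C", "C", "O", "C"),
               charge = 0),
    data.frame(serial = 6:9, name = c("P", "C4'", "C1'", "N9"),
               resname = "A", chain = "R", resseq = 1L, icode = "",
               x = 1.3 + sep + c(0, 1.1, 2.2, 3.2), y = c(0.7, 1, 1.4, 2),
               z = c(0, 0.4, 0.8, 1), element = c("P", "C", "C", "N"),
               charge = 0))
  new_structure(atoms)
}

test_that("extract_pairs applies the inclusive 10 A boundary", {
  # closest atom pair is protein C at (1.3, 0.7, 0) and rna P at
  # (1.3 + sep, 0.7, 0): the minimum heavy-atom distance is exactly sep
  expect_length(extract_pairs(two_atom_complex(10.0), "A", "R"), 1)
  expect_length(extract_pairs(two_atom_complex(10.1), "A", "R"), 0)
  expect_length(extract_pairs(two_atom_complex(50), "A", "R"), 0)
})

test_that("extract_pairs agrees with the generator manifest", {
  for (sd in 1:3) {
    tc <- make_toy_complex(sd)
    cplx <- combine_structures(tc$protein, tc$rna)
    pairs <- extract_pairs(cplx, "A", "R", cutoff = 10)
    expect_equal(length(pairs), tc$manifest$n_pairs)
  }
})

test_that("pair_rmsd is a superposition metric within a type class", {
  cplx <- two_atom_complex(3)
  p <- extract_pairs(cplx, "A", "R")[[1]]
  expect_equal(pair_rmsd(p, p), 0, tolerance = 1e-12)

  # a rigidly moved copy superposes to zero
  moved <- cplx
  R <- euler_matrix(33, 70, 120)
  moved <- set_coords(moved, sweep(coords(moved) %*% t(R), 2, c(5, -3, 8), "+"))
  q <- extract_pairs(moved, "A", "R")[[1]]
  expect_equal(pair_rmsd(p, q), 0, tolerance = 1e-6)

  other <- q; other$base_type <- "U"
  expect_true(is.na(pair_rmsd(p, other)))

  # symmetry and non-negativity over fixture pairs
  ts <- make_pair_training_set(c(2, 2), seed = 3)
  ps <- unlist(lapply(ts, function(x) extract_pairs(x[[1]], x[[2]], x[[3]])),
               recursive = FALSE)
  for (i in 1:3) for (j in (i + 1):4) {
    rij <- pair_rmsd(ps[[i]], ps[[j]])
    expect_gte(rij, 0)
    expect_equal(rij, pair_rmsd(ps[[j]], ps[[i]]), tolerance = 1e-9)
  }
})

test_that("kabsch-based pair RMSD matches an exhaustive rotation search", {
  set.seed(31)
  P <- matrix(rnorm(15, sd = 3), ncol = 3)
  Q <- matrix(rnorm(15, sd = 3), ncol = 3)
  direct <- kabsch_superpose(P, Q)$rmsd
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  cost <- function(R) sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  starts <- replicate(3000, random_rotation(), simplify = FALSE)
  costs <- vapply(starts, cost, numeric(1))
  refine <- function(R0) {
    best_R <- R0; best <- cost(R0)
    step <- 15
    while (step > 1e-4) {
      improved <- FALSE
      for (i in 1:40) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        th <- rnorm(1, 0, step) * pi / 180
        K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
        R <- (diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K) %*% best_R
        v <- cost(R)
        if (v < best) { best <- v; best_R <- R; improved <- TRUE }
      }
      if (!improved) step <- step / 2
    }
    best
  }
  best <- min(vapply(starts[order(costs)[1:8]], refine, numeric(1)))
  expect_lte(direct, best + 1e-9)
  expect_equal(direct, best, tolerance = 1e-3)
})

test_that("training recovers planted clusters and count-based energies", {
  ts <- make_pair_training_set(c(9, 3, 3), seed = 1)
  lib <- train_potential(ts)
  ns <- vapply(lib$standard_pairs, function(p) p$n_members, integer(1))
  es <- vapply(lib$standard_pairs, function(p) p$energy, numeric(1))
  expect_equal(ns, c(9L, 3L, 3L))
  expect_equal(es, c(-log(9 / 5), -log(3 / 5), -log(3 / 5)), tolerance = 1e-12)
  expect_equal(which.min(es), which.max(ns))
  # partition property: cluster sizes sum to the training pair count
  expect_equal(sum(ns), lib$meta$n_training_pairs)

  # a single cluster carries energy -ln(1) = 0
  lib1 <- train_potential(make_pair_training_set(c(4), seed = 2))
  expect_equal(vapply(lib1$standard_pairs, function(p) p$energy, numeric(1)), 0)

  # duplicating the training set doubles counts but keeps energies
  ts2 <- c(ts, ts)
  lib2 <- train_potential(ts2)
  ns2 <- vapply(lib2$standard_pairs, function(p) p$n_members, integer(1))
  es2 <- vapply(lib2$standard_pairs, function(p) p$energy, numeric(1))
  expect_equal(ns2, 2L * ns)
  expect_equal(es2, es, tolerance = 1e-12)

  expect_error(train_potential(list()), "no residue-base pairs")
})

test_that("decoy scoring sums matched energies under the strict 6 A rule", {
  ts <- make_pair_training_set(c(9, 3, 3), seed = 1)
  lib <- train_potential(ts)

  fx <- make_scoring_fixture(lib, c(1, 2))
  expect_equal(score_complex(fx$structure, "A", "R", lib),
               fx$expected_energy, tolerance = 1e-12)

  fx3 <- make_scoring_fixture(lib, c(1, 2, 3))
  expect_equal(score_complex(fx3$structure, "A", "R", lib),
               fx3$expected_energy, tolerance = 1e-12)

  # an extra pair beyond 6 A from every standard pair contributes nothing
  fxu <- make_scoring_fixture(lib, c(1, 2), add_unmatched = TRUE)
  expect_equal(score_complex(fxu$structure, "A", "R", lib),
               fxu$expected_energy, tolerance = 1e-12)

  # no pair within range at all scores zero
  far <- make_scoring_fixture(lib, integer(0), add_unmatched = TRUE)
  expect_equal(score_complex(far$structure, "A", "R", lib), 0)
})

test_that("scoring is invariant under a global rigid transform", {
  ts <- make_pair_training_set(c(5, 2), seed = 4)
  lib <- train_potential(ts)
  fx <- make_scoring_fixture(lib, c(1, 2))
  base <- score_complex(fx$structure, "A", "R", lib)
  set.seed(32)
  for (rep in 1:3) {
    R <- random_rotation()
    moved <- set_coords(fx$structure,
                        sweep(coords(fx$structure) %*% t(R), 2,
                              rnorm(3, sd = 20), "+"))
    expect_equal(score_complex(moved, "A", "R", lib), base, tolerance = 1e-9)
  }
})

test_that("score_list writes name/energy lines and errors on bad input", {
  ts <- make_pair_training_set(c(3, 2), seed = 5)
  lib <- train_potential(ts)
  fx <- make_scoring_fixture(lib, c(1, 2))
  td <- withr::local_tempdir()
  write_pdb(fx$structure, file.path(td, "complex1.pdb"))
  write_pdb(fx$structure, file.path(td, "complex2.pdb"))
  listf <- file.path(td, "list")
  writeLines(c("complex1.pdb A R", "complex2.pdb A R"), listf)
  outf <- file.path(td, "RMSD.score")
  res <- score_list(listf, lib, outf)
  lines <- readLines(outf)
  expect_length(lines, 2)
  parts <- strsplit(lines[1], " +")[[1]]
  expect_equal(parts[1], "complex1.pdb")
  expect_equal(as.numeric(parts[2]), res$energy[1], tolerance = 1e-3)
  expect_equal(res$energy[1], res$energy[2])

  writeLines(c("complex1.pdb A R", "only-two fields"), listf)
  expect_error(score_list(listf, lib, outf), "line 2")
  writeLines("missing.pdb A R", listf)
  expect_error(score_list(listf, lib, outf), "missing.pdb")

  writeLines(character(0), listf)
  score_list(listf, lib, outf)
  expect_length(readLines(outf), 0)
})

test_that("pair library JSON serialization round-trips", {
  ts <- make_pair_training_set(c(9, 3, 3), seed = 1)
  lib <- train_potential(ts)
  f <- withr::local_tempfile(fileext = ".json")
  write_pair_library(lib, f)
  back <- read_pair_library(f)
  expect_equal(length(back$standard_pairs), length(lib$standard_pairs))
  for (i in seq_along(lib$standard_pairs)) {
    expect_equal(back$standard_pairs[[i]]$energy,
                 lib$standard_pairs[[i]]$energy)
    expect_equal(back$standard_pairs[[i]]$coords,
                 lib$standard_pairs[[i]]$coords, ignore_attr = TRUE)
  }
  fx <- make_scoring_fixture(lib, c(1, 3))
  expect_equal(score_complex(fx$structure, "A", "R", back),
               score_complex(fx$structure, "A", "R", lib))
})
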