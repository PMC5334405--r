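# Residue mapping, superposition, CAPRI-style metrics, decoy analysis

test_that("map_residues builds identity maps and handles truncations", {
  tc <- make_toy_complex(1)
  cplx <- combine_structures(tc$protein, tc$rna)
  m <- map_residues(cplx, cplx)
  expect_equal(m$native_key, m$decoy_key)
  idx <- rpcdock:::residue_index(cplx)
  expect_equal(nrow(m), length(idx))

  # decoy missing its 2 N-terminal protein residues: exactly those drop out
  trunc <- cplx
  trunc$atoms <- trunc$atoms[!(trunc$atoms$chain == "A" &
                                 trunc$atoms$resseq <= 2), , drop = FALSE]
  m2 <- map_residues(cplx, trunc)
  expect_equal(nrow(m2), nrow(m) - 2)
  expect_false(any(grepl("^A\\|1\\|", m2$native_key)))
  expect_false(any(grepl("^A\\|2\\|", m2$native_key)))
})

test_that("alignment scores match an independent global aligner", {
  skip_if_not_installed("Biostrings")
  set.seed(41)
  alphabet <- c("A", "C", "G", "U")
  sub <- matrix(-1, 4, 4, dimnames = list(alphabet, alphabet))
  diag(sub) <- 1
  for (rep in 1:5) {
    s1 <- sample(alphabet, 30, TRUE)
    s2 <- sample(alphabet, 30, TRUE)
    ours <- rpcdock:::nw_align(s1, s2)$score
    ref <- Biostrings::pairwiseAlignment(
      paste(s1, collapse = ""), paste(s2, collapse = ""),
      substitutionMatrix = sub, gapOpening = 5, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("map_residues rejects low-identity chain pairings", {
  fx <- make_contact_fixture(6, 6, 0)
  other <- fx$native
  other$atoms$resname[other$atoms$chain == "R"] <- "U"
  other$atoms$name[other$atoms$name == "N9"] <- "N1"
  expect_error(map_residues(fx$native, other), "identity")
})

test_that("kabsch_superpose recovers exact transforms and is optimal", {
  set.seed(42)
  P <- matrix(rnorm(30, sd = 5), ncol = 3)
  id <- kabsch_superpose(P, P)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)

  R <- random_rotation(); tv <- rnorm(3, sd = 10)
  Q <- apply_transform(P, R, tv)
  fit <- kabsch_superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  Q2 <- matrix(rnorm(30, sd = 5), ncol = 3)
  best_random <- min(vapply(1:1000, function(i) {
    Rr <- random_rotation()
    sqrt(mean(rowSums((sweep(P, 2, colMeans(P)) %*% t(Rr) -
                         sweep(Q2, 2, colMeans(Q2)))^2)))
  }, numeric(1)))
  expect_lte(kabsch_superpose(P, Q2)$rmsd, best_random)

  expect_error(kabsch_superpose(P[1:2, ], Q2[1:2, ]), "3 points")
})

test_that("receptor and ligand RMSD follow the receptor-frame definition", {
  tc <- make_toy_complex(2)
  nat <- combine_structures(tc$protein, tc$rna)
  m <- map_residues(nat, nat)
  expect_equal(unname(receptor_ligand_rmsd(nat, nat, m)), c(0, 0),
               tolerance = 1e-9)

  ds <- make_decoy_set(tc, list(list(translation = c(5, 0, 0))))
  dec <- combine_structures(tc$protein, ds$decoys[[1]])
  rl <- receptor_ligand_rmsd(nat, dec, m)
  expect_equal(unname(rl["r_rmsd"]), 0, tolerance = 1e-9)
  expect_equal(unname(rl["l_rmsd"]), 5, tolerance = 1e-6)

  # generator closed form for a random rigid perturbation
  set.seed(43)
  tr <- list(rotation = random_rotation(), translation = rnorm(3))
  ds2 <- make_decoy_set(tc, list(tr))
  dec2 <- combine_structures(tc$protein, ds2$decoys[[1]])
  rl2 <- receptor_ligand_rmsd(nat, dec2, m)
  expect_equal(unname(rl2["l_rmsd"]), ds2$manifest$l_rmsd, tolerance = 1e-6)
})

test_that("interface RMSD matches direct superposition on the interface set", {
  tc <- make_toy_complex(3)
  nat <- combine_structures(tc$protein, tc$rna)
  m <- map_residues(nat, nat)
  expect_equal(interface_rmsd(nat, nat, m), 0, tolerance = 1e-9)

  ds <- make_decoy_set(tc, list(list(translation = c(2, 0, 0))))
  dec <- combine_structures(tc$protein, ds$decoys[[1]])
  got <- interface_rmsd(nat, dec, m)
  # oracle: single Kabsch call on the concatenated mapped interface atoms
  cp <- rpcdock:::contact_pairs(nat, 10)
  keys <- unique(c(cp$res_key, cp$nt_key))
  sub <- m[m$native_key %in% keys, ]
  bb <- rpcdock:::mapped_backbone(nat, dec, sub)
  expect_equal(got, kabsch_superpose(bb$Q, bb$P)$rmsd, tolerance = 1e-9)

  # enlarging the cutoff never shrinks the interface residue set
  k1 <- unique(unlist(rpcdock:::contact_pairs(nat, 8)))
  k2 <- unique(unlist(rpcdock:::contact_pairs(nat, 12)))
  expect_true(all(k1 %in% k2))
})

test_that("contact fractions are exact on planted decoys", {
  fx <- make_contact_fixture(20, 14, 6)
  m <- map_residues(fx$native, fx$decoy)
  cf <- contact_fractions(fx$native, fx$decoy, m)
  expect_equal(unname(cf["fnat"]), 0.70)
  expect_equal(unname(cf["fnon"]), 0.30)

  self <- contact_fractions(fx$native, fx$native, map_residues(fx$native, fx$native))
  expect_equal(unname(self), c(1, 0))

  # far-shifted ligand: no decoy contacts at all
  tc <- make_toy_complex(4)
  nat <- combine_structures(tc$protein, tc$rna)
  ds <- make_decoy_set(tc, list(list(translation = c(100, 0, 0))))
  dec <- combine_structures(tc$protein, ds$decoys[[1]])
  m2 <- map_residues(nat, dec)
  cf2 <- contact_fractions(nat, dec, m2)
  expect_equal(unname(cf2), c(0, 0))

  # fnat plus the lost fraction is one on any decoy
  ds3 <- make_decoy_set(tc, list(list(translation = c(1.5, 0.5, 0))))
  dec3 <- combine_structures(tc$protein, ds3$decoys[[1]])
  cf3 <- contact_fractions(nat, dec3, m2)
  expect_equal(unname(cf3["fnat"]), ds3$manifest$fnat, tolerance = 1e-12)
})

test_that("metrics are invariant under a joint rigid transform", {
  tc <- make_toy_complex(5)
  nat <- combine_structures(tc$protein, tc$rna)
  ds <- make_decoy_set(tc, list(list(translation = c(2, 1, 0))))
  dec <- combine_structures(tc$protein, ds$decoys[[1]])
  m <- map_residues(nat, dec)
  base_rl <- receptor_ligand_rmsd(nat, dec, m)
  base_ir <- interface_rmsd(nat, dec, m)
  base_cf <- contact_fractions(nat, dec, m)

  set.seed(44)
  R <- random_rotation(); tv <- rnorm(3, sd = 30)
  dec2 <- set_coords(dec, apply_transform(coords(dec), R, tv))
  expect_equal(receptor_ligand_rmsd(nat, dec2, m), base_rl, tolerance = 1e-6)
  expect_equal(interface_rmsd(nat, dec2, m), base_ir, tolerance = 1e-6)
  expect_equal(contact_fractions(nat, dec2, m), base_cf)
})

test_that("analyze_decoys writes the step-wise metrics table", {
  tc <- make_toy_complex(1)
  td <- withr::local_tempdir()
  write_pdb(tc$protein, file.path(td, "prot.pdb"))
  write_pdb(tc$rna, file.path(td, "rna.pdb"))
  # record 1 is the native pose; 2 and 3 are shifted
  recs <- data.frame(rotation_index = 1L, score = c(3, 2, 1),
                     tx = c(0L, 2L, 5L), ty = 0L, tz = 0L,
                     alpha = 0, beta = 0, gamma = 0)
  write_gdata(recs, file.path(td, "dock.out"))
  par <- list(
    "RPDock.resfile" = "dock.out", "RPDock.max_matches" = "3",
    "native.receptor_pdb_filename" = "prot.pdb",
    "native.ligand_pdb_filename" = "rna.pdb",
    "native.receptor.chainid" = "A", "native.ligand.chainid" = "R",
    "decoy.receptor_pdb_filename" = "prot.pdb",
    "decoy.ligand_pdb_filename" = "rna.pdb",
    "decoy.receptor.chainid" = "A", "decoy.ligand.chainid" = "R",
    "rmsd.output" = "out.rmsd.dat")
  metrics <- analyze_decoys(par, dir = td)
  lines <- readLines(file.path(td, "out.rmsd.dat"))
  expect_equal(lines[1], "#Decoy R_rmsd L_rmsd I_rms fnat fnon")
  expect_length(lines, 4)
  row1 <- as.numeric(strsplit(lines[2], " ")[[1]])
  expect_equal(row1, c(1, 0, 0, 0, 1, 0), tolerance = 1e-6)
  expect_equal(metrics$l_rmsd[3], 5, tolerance = 1e-3)
  expect_true(all(metrics$fnat <= 1 & metrics$fnat >= 0))

  # rerun is byte-identical
  before <- readLines(file.path(td, "out.rmsd.dat"))
  analyze_decoys(par, dir = td)
  expect_identical(readLines(file.path(td, "out.rmsd.dat")), before)

  par$`RPDock.max_matches` <- "9"
  expect_error(analyze_decoys(par, dir = td), "exceeds")
})
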