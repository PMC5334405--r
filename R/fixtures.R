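# Deterministic synthetic structures: an idealized helical-lattice protein
# and an RNA arc hugging it at a fixed radial gap, so the generated pose is
# the geometric-complementarity optimum and every downstream stage can be
# validated against manifest quantities computed by direct geometry here.
# Lattice geometry is intentionally idealized (no Ramachandran/pucker
# realism): the pipeline's math is purely geometric.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# rows of an atom table from a named list of coordinates
atom_rows <- function(coords_list, resname, chain, resseq, serial0) {
  nm <- names(coords_list)
  m <- do.call(rbind, coords_list)
  data.frame(serial = serial0 + seq_along(nm), name = nm,
             resname = resname, chain = chain, resseq = resseq, icode = "",
             x = m[, 1], y = m[, 2], z = m[, 3],
             element = .guess_element(nm), charge = 0,
             stringsAsFactors = FALSE)
}

# local (radial u, tangent t, vertical w) frame at azimuth phi (degrees)
cyl_frame <- function(phi) {
  p <- phi * pi / 180
  list(u = c(cos(p), sin(p), 0), t = c(-sin(p), cos(p), 0), w = c(0, 0, 1))
}

off <- function(origin, fr, du, dt, dw) origin + du * fr$u + dt * fr$t + dw * fr$w

# protein: chain threaded through a cubic lattice (1.8 A spacing) slab
# whose top face carries a carved trench closed at both ends, plus floor
# knobs under the raised bases. Because walls, caps and knobs are part of
# one solid mass, every deep penetration anywhere reaches core cells and
# pays the clash penalty; atom naming is correct per residue, geometry
# deliberately idealized.
toy_protein <- function(n_res, n_nt, res_names) {
  spacing <- 1.8
  half_len <- (n_nt - 1) * 2.6 / 2 + 2.6   # trench half-length (with caps)
  kx <- ceiling((half_len + 3.6) / spacing)
  g <- expand.grid(ix = -kx:kx, iy = -4:4, iz = 0:3)
  pts <- cbind(g$ix * spacing, g$iy * spacing, -0.9 - g$iz * spacing)
  carved <- abs(pts[, 1]) < half_len & abs(pts[, 2]) < 3.4 & pts[, 3] > -3.6
  # checkerboard pits on the top face away from the trench lip: a rigid
  # flat tile cannot seat closely anywhere except inside the trench
  cap_x <- spacing * ceiling(half_len / spacing)
  on_top <- pts[, 3] > -1.0
  off_lip <- abs(pts[, 2]) > 3.7 | abs(pts[, 1]) > cap_x + 0.1
  pitted <- on_top & off_lip & ((g$ix + g$iy) %% 2L == 1L)
  pts <- pts[!(carved | pitted), , drop = FALSE]
  ord <- order(pts[, 3], pts[, 2], pts[, 1])
  pts <- pts[ord, , drop = FALSE]
  n_sites <- 5L * (nrow(pts) %/% 5L)
  pts <- pts[seq_len(n_sites), , drop = FALSE]
  n_res_total <- n_sites %/% 5L
  names_all <- c(res_names, rep("ALA", max(0L, n_res_total - length(res_names))))
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_res_total)) {
    ats <- lapply(1:5, function(a) pts[(i - 1L) * 5L + a, ])
    names(ats) <- c("N", "CA", "C", "O", "CB")
    rows[[i]] <- atom_rows(ats, names_all[i], "A", i, serial)
    serial <- serial + 5L
  }
  resseq <- n_res_total
  for (j in seq_len(n_nt)) {               # floor knobs under raised bases
    if (j %% 3 != 2) next
    xj <- (j - 1) * 2.6 - (n_nt - 1) * 1.3
    ats <- list(N = c(xj, 0, -3.7), CA = c(xj, 0, -2.4),
                C = c(xj, 1.0, -3.2), O = c(xj, -1.0, -3.2))
    resseq <- resseq + 1L
    rows[[length(rows) + 1]] <- atom_rows(ats, "GLY", "A", resseq, serial)
    serial <- serial + 4L
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, source = "toy_protein")
}

# RNA: straight strand lying in the trench, each base ring flat against
# the floor at a fixed gap with the low-profile backbone on top; every
# third base (j = 2, 5, ...) is raised over a floor knob (non-palindromic
# pattern), and a slow per-nucleotide ring twist plus the mixed
# purine/pyrimidine ring sizes make the generated orientation the unique
# snug fit
toy_rna <- function(n_nt, nt_names, twist0, gap = 2.0, floor_z = -4.5) {
  rows <- list()
  serial <- 0L
  d <- c(0, 0, 1)                          # up, out of the trench
  e1 <- c(1, 0, 0)                         # along the trench
  e2 <- c(0, 1, 0)
  for (j in seq_len(n_nt)) {
    xj <- (j - 1) * 2.6 - (n_nt - 1) * 1.3
    tw <- (twist0 + (j - 1) * 20) * pi / 180
    f1 <- cos(tw) * e1 + sin(tw) * e2
    f2 <- -sin(tw) * e1 + cos(tw) * e2
    raised <- (j %% 3) == 2
    center <- c(xj, 0, floor_z + gap + if (raised) 1.2 else 0)
    ring_names <- .BASE_RING_ATOMS[[nt_names[j]]]
    m <- length(ring_names)
    ats <- list()
    for (a in seq_len(m)) {
      ang <- 2 * pi * (a - 1) / m
      ats[[ring_names[a]]] <- center + 1.3 * (cos(ang) * f1 + sin(ang) * f2)
    }
    # low-profile backbone stacked over the ring center with lateral
    # extent capped below the wall clearance: the nucleotide is a flat
    # tile whose only snug face is the base side, so flipped placements
    # cannot pack as closely and nothing pokes into the trench walls
    ats[["C1'"]] <- center + 1.2 * d + 1.2 * f1
    ats[["O4'"]] <- center + 2.4 * d - 0.9 * f1
    ats[["C2'"]] <- center + 1.7 * d + 1.3 * f1 - 0.6 * f2
    ats[["O2'"]] <- center + 1.4 * d + 0.9 * f1 - 1.1 * f2
    ats[["C4'"]] <- center + 2.2 * d + 0.5 * f1 + 0.4 * f2
    ats[["C3'"]] <- center + 2.6 * d + 0.9 * f2
    ats[["O3'"]] <- center + 2.9 * d + 1.4 * f2
    ats[["C5'"]] <- center + 2.8 * d - 0.9 * f2
    ats[["O5'"]] <- center + 3.3 * d - 1.3 * f2
    ats[["P"]] <- center + 3.8 * d - 0.9 * f2
    rows[[j]] <- atom_rows(ats, nt_names[j], "R", j, serial)
    serial <- serial + length(ats)
  }
  new_structure(do.call(rbind, rows), source = "toy_rna")
}

# direct-geometry residue/nucleotide minimum distances (manifest oracle,
# independent of the analysis module)
direct_contacts <- function(protein, rna, cutoff) {
  pk <- residue_keys(protein$atoms)
  nk <- residue_keys(rna$atoms)
  px <- coords(protein); nx <- coords(rna)
  out <- list()
  for (rkey in unique(pk)) {
    pi_ <- px[pk == rkey, , drop = FALSE]
    for (tkey in unique(nk)) {
      ni <- nx[nk == tkey, , drop = FALSE]
      dmin <- sqrt(min(outer(rowSums(pi_^2), rowSums(ni^2), "+") -
                         2 * pi_ %*% t(ni)))
      if (dmin <= cutoff) out[[length(out) + 1]] <- c(rkey, tkey, dmin)
    }
  }
  if (length(out) == 0) {
    return(data.frame(res_key = character(0), nt_key = character(0),
                      dmin = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(res_key = m[, 1], nt_key = m[, 2], dmin = as.numeric(m[, 3]),
             stringsAsFactors = FALSE)
}

#' Generate a deterministic toy protein/RNA complex
#'
#' Builds an idealized lattice protein slab (chain A) with a carved trench
#' and an RNA strand (chain R) nested in it base-side down, so the
#' generated placement is the native pose and, by construction, the
#' geometric-complementarity optimum (solid walls, closed ends and a
#' knobs-into-holes base-height pattern penalize every rigid-body
#' alternative). The manifest records, by direct geometry: the contact
#' list (residue/nucleotide minimum heavy-atom distance <= 5 A), the pair
#' list at 10 A, and the closed-form ligand RMSD for a standard
#' perturbation. The same seed always yields byte-identical structures.
#'
#' @param seed Integer RNG seed (drives residue/base identities and the
#'   strand twist phase).
#' @param n_res Number of seed-sampled residue identities (>= 5); the slab
#'   adds further ALA/GLY residues as needed.
#' @param n_nt Number of nucleotides (>= 3).
#' @return List with `protein`, `rna` (`rpc_structure`), `native_pose`
#'   (zero-rotation, zero-translation pose record) and `manifest` (list:
#'   `contacts`, `n_contacts`, `pairs`, `n_pairs`, `l_rmsd_shift_5x = 5`,
#'   atom/chain counts).
#' @export
make_toy_complex <- function(seed, n_res = 10, n_nt = 5) {
  stopifnot(n_res >= 5, n_nt >= 3)
  with_seed(seed, {
    res_names <- sample(setdiff(.STANDARD_AA, "GLY"), n_res, replace = TRUE)
    nt_names <- sample(.STANDARD_NT, n_nt, replace = TRUE)
    twist0 <- stats::runif(1, 0, 360)
    prot <- toy_protein(n_res, n_nt, res_names)
    rna <- toy_rna(n_nt, nt_names, twist0 = twist0)
    contacts <- direct_contacts(prot, rna, 5)
    pairs <- direct_contacts(prot, rna, 10)
    native_pose <- data.frame(rotation_index = 0L, score = NA_real_,
                              tx = 0L, ty = 0L, tz = 0L,
                              alpha = 0, beta = 0, gamma = 0)
    list(protein = prot, rna = rna, native_pose = native_pose,
         manifest = list(
           seed = seed, n_res = n_res, n_nt = n_nt,
           n_protein_atoms = n_atoms(prot), n_rna_atoms = n_atoms(rna),
           contacts = contacts, n_contacts = nrow(contacts),
           pairs = pairs, n_pairs = nrow(pairs),
           l_rmsd_shift_5x = 5))
  })
}

#' Generate decoys from a toy complex by rigid RNA transforms
#'
#' Each decoy is the native complex with one rigid transform applied to
#' the RNA (rotation about the RNA centroid, then translation). The
#' manifest's `l_rmsd` is computed in closed form from the transform and
#' the RNA backbone coordinates (the receptor never moves, so the
#' receptor-frame ligand RMSD is the direct displacement RMSD); `fnat`
#' comes from direct contact recomputation.
#'
#' @param native Output of [make_toy_complex()].
#' @param transforms List of `list(rotation = 3x3, translation = length-3)`
#'   rigid transforms.
#' @return List with `decoys` (list of RNA `rpc_structure`s) and
#'   `manifest` (data.frame `decoy`, `l_rmsd`, `fnat`).
#' @export
make_decoy_set <- function(native, transforms) {
  bb_rows <- normalize_atom_name(native$rna$atoms$name) %in% .RNA_BB
  x0 <- coords(native$rna)
  cen <- colMeans(x0)
  nat_contacts <- paste(native$manifest$contacts$res_key,
                        native$manifest$contacts$nt_key)
  decoys <- list()
  man <- list()
  for (i in seq_along(transforms)) {
    tr <- transforms[[i]]
    R <- tr$rotation %||% diag(3)
    tv <- tr$translation %||% c(0, 0, 0)
    x1 <- sweep(sweep(x0, 2, cen) %*% t(R), 2, cen + tv, "+")
    dec <- set_coords(native$rna, x1)
    l_rmsd <- sqrt(mean(rowSums((x1[bb_rows, , drop = FALSE] -
                                   x0[bb_rows, , drop = FALSE])^2)))
    dc <- direct_contacts(native$protein, dec, 5)
    fnat <- if (nrow(native$manifest$contacts) == 0) NA_real_ else {
      mean(nat_contacts %in% paste(dc$res_key, dc$nt_key))
    }
    decoys[[i]] <- dec
    man[[i]] <- data.frame(decoy = i, l_rmsd = l_rmsd, fnat = fnat)
  }
  list(decoys = decoys, manifest = do.call(rbind, man))
}

# -- planted fixtures for the pair potential ------------------------------

# conformation classes for the 9 reduced-pair atoms laid out on helices:
# differing radius/pitch/turn (and handedness) give mutual superposition
# RMSDs well above the 6 A clustering threshold, which compact realistic
# geometry cannot reach (the reduced pair spans too little). Class "far"
# sits ~7 A from every planted class: the unmatched decoy pair.
.PAIR_CLASS_PARAMS <- list(
  c1 = c(hand = 1, r = 4.5, pitch = 1.2, turn = 40),
  c2 = c(hand = 1, r = 2.0, pitch = 3.6, turn = 110),
  c3 = c(hand = 1, r = 5.5, pitch = 0.4, turn = 85),
  far = c(hand = -1, r = 5.95, pitch = 0.22, turn = 144.8))

pair_class_coords <- function(class) {
  p <- .PAIR_CLASS_PARAMS[[class]]
  t(sapply(0:8, function(k) {
    a <- p[["hand"]] * k * p[["turn"]] * pi / 180
    c(p[["r"]] * cos(a), p[["r"]] * sin(a), k * p[["pitch"]])
  }))
}

# single ALA + adenosine "pair unit" whose 9 reduced atoms carry the class
# geometry (residue = points 1-5, nucleotide = points 6-9)
pair_unit_atoms <- function(class, origin = c(0, 0, 0), resseq = 1L,
                            jitter = NULL) {
  xyz <- pair_class_coords(class)
  if (!is.null(jitter)) xyz <- xyz + jitter
  xyz <- sweep(xyz, 2, origin, "+")
  res_xyz <- lapply(1:5, function(a) xyz[a, ])
  names(res_xyz) <- c("N", "CA", "C", "O", "CB")
  nt_xyz <- lapply(6:9, function(a) xyz[a, ])
  names(nt_xyz) <- c("P", "C4'", "C1'", "N9")
  rbind(atom_rows(res_xyz, "ALA", "A", resseq, 0L),
        atom_rows(nt_xyz, "A", "R", resseq, 5L))
}

#' Synthetic training population with planted cluster sizes
#'
#' Builds single-pair complexes of one (residue type, base type) class in
#' three distinct conformation classes whose mutual superposition RMSD
#' exceeds the clustering threshold, with small within-class jitter, in
#' cluster-size order (first `sizes[1]` complexes belong to cluster 1,
#' etc.). Greedy leader clustering at 6 A therefore recovers exactly the
#' planted clusters.
#'
#' @param sizes Integer cluster sizes (up to 3 clusters, default
#'   `c(9, 3, 3)`).
#' @param seed RNG seed for the within-cluster jitter.
#' @return List of `list(structure, protein_chains, rna_chains)` entries
#'   suitable for [train_potential()].
#' @export
make_pair_training_set <- function(sizes = c(9, 3, 3), seed = 1) {
  stopifnot(length(sizes) <= 3, all(sizes >= 1))
  classes <- c("c1", "c2", "c3")
  with_seed(seed, {
    out <- list()
    for (ci in seq_along(sizes)) {
      for (k in seq_len(sizes[ci])) {
        jit <- matrix(stats::runif(9 * 3, -0.12, 0.12), ncol = 3)
        atoms <- pair_unit_atoms(classes[ci], jitter = jit)
        out[[length(out) + 1]] <-
          list(new_structure(atoms, "training_unit"), "A", "R")
      }
    }
    out
  })
}

#' Planted decoy for exact potential-score checks
#'
#' Assembles a complex from rigid copies of chosen standard pairs of a
#' trained library (so each extracted pair matches its source at RMSD 0)
#' placed far apart, optionally plus one extra pair whose conformation is
#' beyond the match threshold from every standard pair. The expected score
#' is the exact sum of the copied standard energies.
#'
#' @param lib A `pair_library` trained on [make_pair_training_set()]
#'   geometry.
#' @param cluster_ids Which standard pairs to copy.
#' @param add_unmatched Also plant one far-off-conformation pair.
#' @return List with `structure`, `protein_chains`, `rna_chains`,
#'   `expected_energy`.
#' @export
make_scoring_fixture <- function(lib, cluster_ids = c(1, 2),
                                 add_unmatched = FALSE) {
  rows <- list()
  expected <- 0
  spacing <- 60
  for (i in seq_along(cluster_ids)) {
    sp <- lib$standard_pairs[[cluster_ids[i]]]
    shift <- c((i - 1) * spacing, 0, 0)
    m <- sweep(sp$coords, 2, shift, "+")
    res_xyz <- lapply(seq_len(5), function(a) m[a, ])
    names(res_xyz) <- c("N", "CA", "C", "O", "CB")
    gly_n <- if (sp$base_type %in% .PURINES) "N9" else "N1"
    nt_xyz <- lapply(6:9, function(a) m[a, ])
    names(nt_xyz) <- c("P", "C4'", "C1'", gly_n)
    rows[[length(rows) + 1]] <-
      rbind(atom_rows(res_xyz, sp$res_type, "A", i, 0L),
            atom_rows(nt_xyz, sp$base_type, "R", i, 5L))
    expected <- expected + sp$energy
  }
  if (add_unmatched) {
    # the "far" conformation class sits ~7 A from every planted class, so
    # the strict <6 A rule leaves it unscored
    atoms <- pair_unit_atoms("far",
                             origin = c(length(cluster_ids) * spacing, 0, 0),
                             resseq = length(cluster_ids) + 1L)
    rows[[length(rows) + 1]] <- atoms
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  list(structure = new_structure(atoms, "scoring_fixture"),
       protein_chains = "A", rna_chains = "R",
       expected_energy = expected)
}

#' Planted contact-count fixture
#'
#' Builds a native and a decoy complex over isolated "contact stations"
#' (residues 20 A apart, one nucleotide per station) with exactly
#' controlled residue-nucleotide contact sets: the native has `n_native`
#' contacts; the decoy keeps `n_kept` of them and gains `n_new` contacts
#' with previously uncontacted residues, so
#' `fnat = n_kept / n_native` and `fnon = n_new / (n_kept + n_new)`
#' exactly.
#'
#' @param n_native,n_kept,n_new Contact counts (defaults 20, 14, 6).
#' @return List with `native`, `decoy` (`rpc_structure` complexes),
#'   `fnat`, `fnon`.
#' @export
make_contact_fixture <- function(n_native = 20, n_kept = 14, n_new = 6) {
  stopifnot(n_kept + n_new <= n_native)
  n_res <- n_native + n_new
  res_at <- function(i, serial0) {
    x <- i * 20
    atom_rows(list(N = c(x - 1.2, 0.9, 0), CA = c(x, 0, 0),
                   C = c(x + 1.3, 0.7, 0), O = c(x + 1.4, 1.9, 0.3),
                   CB = c(x + 0.2, -0.8, 1.2)),
              "ALA", "A", i, serial0)
  }
  nt_at <- function(i, station, serial0) {
    x <- station * 20
    atom_rows(list(P = c(x, 0.5, 6.5), "O5'" = c(x + 0.6, 0.2, 5.4),
                   "C5'" = c(x + 0.4, -0.3, 4.4), "C4'" = c(x, 0, 3.4),
                   "C1'" = c(x + 1.2, 0.4, 2.8), N9 = c(x + 1.0, 0.2, 1.4)),
              "A", "R", i, serial0)
  }
  build <- function(stations) {
    rows <- lapply(seq_len(n_res), function(i) res_at(i, 0L))
    rows <- c(rows, lapply(seq_along(stations),
                           function(j) nt_at(j, stations[j], 0L)))
    atoms <- do.call(rbind, rows)
    atoms$serial <- seq_len(nrow(atoms))
    new_structure(atoms, "contact_fixture")
  }
  native_st <- seq_len(n_native)
  decoy_st <- c(seq_len(n_kept),                       # kept contacts
                n_native + seq_len(n_new),             # new contacts
                rep(NA, n_native - n_kept - n_new))
  # lost contacts: park those nucleotides far from every residue
  lost <- which(is.na(decoy_st))
  decoy_st[lost] <- -(seq_along(lost) + 2)             # negative stations
  list(native = build(native_st), decoy = build(decoy_st),
       fnat = n_kept / n_native, fnon = n_new / (n_kept + n_new))
}

#' Planted aromatic-base stacking fixture
#'
#' Builds a complex with exactly `k` PHE-ring/base-ring pairs whose ring
#' centroids sit 5.0 A apart, plus one distant non-stacking pair, so the
#' stacking bonus equals `k * bonus`.
#'
#' @param k Number of planted stacked pairs.
#' @return List with `structure`, `protein_chains`, `rna_chains`, `k`.
#' @export
make_stacking_fixture <- function(k = 2) {
  ring6 <- function(center, names6, radius = 1.39) {
    out <- list()
    for (a in seq_len(6)) {
      th <- 2 * pi * (a - 1) / 6
      out[[names6[a]]] <- center + c(radius * cos(th), radius * sin(th), 0)
    }
    out
  }
  rows <- list()
  for (i in seq_len(k)) {
    base0 <- c((i - 1) * 40, 0, 0)
    phe <- c(ring6(base0, c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
             list(N = base0 + c(-3, 0, 0), CA = base0 + c(-2.4, 1.2, 0),
                  C = base0 + c(-3.4, 2.2, 0), O = base0 + c(-3.1, 3.4, 0),
                  CB = base0 + c(-1.2, 0.5, 0.8)))
    rows[[length(rows) + 1]] <- atom_rows(phe, "PHE", "A", i, 0L)
    urange <- c("N1", "C2", "N3", "C4", "C5", "C6")
    base_ats <- c(ring6(base0 + c(0, 0, 5.0), urange),
                  list("C1'" = base0 + c(2.8, 0, 5.4),
                       "C4'" = base0 + c(4.2, 0.8, 5.6),
                       P = base0 + c(5.6, 1.4, 6.2),
                       "O5'" = base0 + c(5.0, 0.6, 6.0)))
    rows[[length(rows) + 1]] <- atom_rows(base_ats, "U", "R", i, 0L)
  }
  # one far, non-aromatic residue and no partner base near it
  rows[[length(rows) + 1]] <-
    atom_rows(list(N = c(-60, 0, 0), CA = c(-59, 1, 0), C = c(-58, 0.5, 0),
                   O = c(-58, -0.7, 0), CB = c(-59.2, 1.8, 1.1)),
              "ALA", "A", k + 1L, 0L)
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  list(structure = new_structure(atoms, "stacking_fixture"),
       protein_chains = "A", rna_chains = "R", k = k)
}
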