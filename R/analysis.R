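# Decoy assessment against a native complex: receptor/ligand/interface
# RMSDs and native-contact fractions, with sequence-alignment residue
# mapping between bound (native) and unbound (docked) structures.

.PROT_BB <- c("N", "CA", "C", "O")
.RNA_BB <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

# Needleman-Wunsch global alignment with affine gaps (Gotoh). A gap of
# length L costs gap_open + L * gap_extend.
nw_align <- function(s1, s2, match = 1, mismatch = -1,
                     gap_open = -5, gap_extend = -1) {
  n1 <- length(s1); n2 <- length(s2)
  NEG <- -1e9
  M <- matrix(NEG, n1 + 1, n2 + 1)
  X <- matrix(NEG, n1 + 1, n2 + 1)  # gap in s2 (s1 char vs -)
  Y <- matrix(NEG, n1 + 1, n2 + 1)  # gap in s1 (- vs s2 char)
  M[1, 1] <- 0
  for (i in 2:(n1 + 1)) X[i, 1] <- gap_open + (i - 1) * gap_extend
  for (j in 2:(n2 + 1)) Y[1, j] <- gap_open + (j - 1) * gap_extend
  for (i in 2:(n1 + 1)) {
    for (j in 2:(n2 + 1)) {
      sub <- if (s1[i - 1] == s2[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- max(M[i - 1, j] + gap_open + gap_extend,
                     X[i - 1, j] + gap_extend)
      Y[i, j] <- max(M[i, j - 1] + gap_open + gap_extend,
                     Y[i, j - 1] + gap_extend)
    }
  }
  score <- max(M[n1 + 1, n2 + 1], X[n1 + 1, n2 + 1], Y[n1 + 1, n2 + 1])
  # traceback
  i <- n1; j <- n2
  state <- which.max(c(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1]))
  pairs <- matrix(0L, 0, 2)
  while (i > 0 || j > 0) {
    if (state == 1 && i > 0 && j > 0) {
      pairs <- rbind(c(i, j), pairs)
      sub <- if (s1[i] == s2[j]) match else mismatch
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which.max(prev)
      if (abs(prev[state] + sub - M[i + 1, j + 1]) > 1e-9) state <- 1
      i <- i - 1; j <- j - 1
    } else if (state == 2 && i > 0) {
      from_m <- M[i, j + 1] + gap_open + gap_extend
      state <- if (abs(from_m - X[i + 1, j + 1]) < 1e-9) 1 else 2
      i <- i - 1
    } else if (state == 3 && j > 0) {
      from_m <- M[i + 1, j] + gap_open + gap_extend
      state <- if (abs(from_m - Y[i + 1, j + 1]) < 1e-9) 1 else 3
      j <- j - 1
    } else if (i > 0) {
      state <- 2
    } else {
      state <- 3
    }
  }
  list(score = score, pairs = pairs)
}

residue_sequence <- function(s) {
  idx <- residue_index(s)
  keys <- names(idx)
  resnames <- vapply(idx, function(i) s$atoms$resname[i[1]], character(1))
  letters1 <- ifelse(resnames %in% names(.AA1), .AA1[resnames],
                     ifelse(resnames %in% .STANDARD_NT, resnames, "X"))
  list(keys = keys, letters = unname(letters1))
}

#' Map residues between a native and a decoy structure
#'
#' Chains are paired in order of appearance; each pairing must agree in
#' molecule type. One-letter sequences are globally aligned
#' (Needleman-Wunsch, match +1, mismatch -1, gap open -5, extend -1);
#' aligned non-gap columns become residue correspondences. Alignment
#' identity (identical / aligned columns) below `min_identity` is an error.
#'
#' @param native,decoy `rpc_structure` objects.
#' @param min_identity Minimum acceptable identity fraction (default 0.3).
#' @return A data.frame (`native_key`, `decoy_key`, `moltype`) of
#'   one-to-one residue correspondences.
#' @export
map_residues <- function(native, decoy, min_identity = 0.3) {
  nch <- chain_ids(native); dch <- chain_ids(decoy)
  if (length(nch) != length(dch)) {
    stop("chain count mismatch: native has ", length(nch),
         ", decoy has ", length(dch))
  }
  maps <- list()
  for (k in seq_along(nch)) {
    sn <- select_chains(native, nch[k])
    sd <- select_chains(decoy, dch[k])
    mt_n <- classify_molecule(sn); mt_d <- classify_molecule(sd)
    if (mt_n != mt_d) {
      stop("molecule type mismatch for chain pairing ", nch[k], "/", dch[k])
    }
    qn <- residue_sequence(sn); qd <- residue_sequence(sd)
    al <- nw_align(qn$letters, qd$letters)
    if (nrow(al$pairs) == 0) stop("no aligned residues for chain ", nch[k])
    ident <- mean(qn$letters[al$pairs[, 1]] == qd$letters[al$pairs[, 2]])
    if (ident < min_identity) {
      stop(sprintf("alignment identity %.1f%% below minimum %.1f%% (chains %s/%s)",
                   100 * ident, 100 * min_identity, nch[k], dch[k]))
    }
    maps[[k]] <- data.frame(native_key = qn$keys[al$pairs[, 1]],
                            decoy_key = qd$keys[al$pairs[, 2]],
                            moltype = mt_n, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(maps, list(make.row.names = FALSE)))
}

# matched backbone coordinate pairs over a set of mapped residues
mapped_backbone <- function(native, decoy, map) {
  kn <- residue_keys(native$atoms)
  kd <- residue_keys(decoy$atoms)
  P <- list(); Q <- list()
  for (r in seq_len(nrow(map))) {
    rows_n <- which(kn == map$native_key[r])
    rows_d <- which(kd == map$decoy_key[r])
    bb <- if (map$moltype[r] == "rna") .RNA_BB else .PROT_BB
    nm_n <- normalize_atom_name(native$atoms$name[rows_n])
    nm_d <- normalize_atom_name(decoy$atoms$name[rows_d])
    common <- intersect(intersect(bb, nm_n), nm_d)
    if (length(common) == 0) next
    P[[length(P) + 1]] <-
      as.matrix(native$atoms[rows_n[match(common, nm_n)], c("x", "y", "z")])
    Q[[length(Q) + 1]] <-
      as.matrix(decoy$atoms[rows_d[match(common, nm_d)], c("x", "y", "z")])
  }
  list(P = do.call(rbind, P), Q = do.call(rbind, Q))
}

#' Receptor and ligand RMSD of a decoy complex
#'
#' `r_rmsd`: RMSD of mapped protein backbone atoms (N, CA, C, O) after
#' optimal superposition on them. `l_rmsd`: the complexes are superposed on
#' the protein backbone, then the RMSD of mapped RNA backbone atoms (P,
#' O5', C5', C4', C3', O3') is measured without refitting (ligand in the
#' receptor frame).
#'
#' @param native_cplx,decoy_cplx `rpc_structure` complexes.
#' @param map Residue map from [map_residues()].
#' @return Named numeric vector `c(r_rmsd, l_rmsd)`, Angstrom.
#' @export
receptor_ligand_rmsd <- function(native_cplx, decoy_cplx, map) {
  bbp <- mapped_backbone(native_cplx, decoy_cplx, map[map$moltype == "protein", ])
  if (is.null(bbp$P) || nrow(bbp$P) < 3) stop("fewer than 3 mapped protein backbone atoms")
  fit <- kabsch_superpose(bbp$Q, bbp$P)    # decoy onto native
  bbr <- mapped_backbone(native_cplx, decoy_cplx, map[map$moltype == "rna", ])
  if (is.null(bbr$P) || nrow(bbr$P) < 3) stop("fewer than 3 mapped RNA backbone atoms")
  moved <- apply_transform(bbr$Q, fit$rotation, fit$translation)
  c(r_rmsd = fit$rmsd, l_rmsd = rmsd_raw(bbr$P, moved))
}

# residue-level contacts between protein and RNA parts of a complex:
# returns data.frame(res_key, nt_key) of pairs with min heavy-atom
# distance <= cutoff
contact_pairs <- function(cplx, cutoff) {
  mt <- chain_moltypes(cplx)
  pch <- names(mt)[mt == "protein"]; rch <- names(mt)[mt == "rna"]
  if (length(pch) == 0 || length(rch) == 0) {
    stop("complex needs both a protein and an RNA part")
  }
  prot <- select_chains(cplx, paste(pch, collapse = ""))
  rna <- select_chains(cplx, paste(rch, collapse = ""))
  pa <- prot$atoms[prot$atoms$element != "H", , drop = FALSE]
  na_ <- rna$atoms[rna$atoms$element != "H", , drop = FALSE]
  pk <- residue_keys(pa); nk <- residue_keys(na_)
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  nxyz <- as.matrix(na_[, c("x", "y", "z")])
  pidx <- split(seq_len(nrow(pa)), factor(pk, levels = unique(pk)))
  nidx <- split(seq_len(nrow(na_)), factor(nk, levels = unique(nk)))
  out <- list()
  for (rk in names(pidx)) {
    rows_p <- pidx[[rk]]
    d2 <- outer(rowSums(pxyz[rows_p, , drop = FALSE]^2),
                rowSums(nxyz^2), "+") -
      2 * pxyz[rows_p, , drop = FALSE] %*% t(nxyz)
    dmin_atom <- sqrt(pmax(apply(d2, 2, min), 0))
    for (tk in names(nidx)) {
      if (min(dmin_atom[nidx[[tk]]]) <= cutoff) {
        out[[length(out) + 1]] <- c(rk, tk)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(res_key = character(0), nt_key = character(0)))
  }
  m <- do.call(rbind, out)
  data.frame(res_key = m[, 1], nt_key = m[, 2], stringsAsFactors = FALSE)
}

#' Interface RMSD of a decoy complex
#'
#' Native interface residues are those with any heavy atom within
#' `iface_cutoff` of the partner molecule. The mapped backbone atoms of
#' those residues (both molecules) are superposed between decoy and native,
#' and the RMSD over that same atom set is returned.
#'
#' @param native_cplx,decoy_cplx `rpc_structure` complexes.
#' @param map Residue map from [map_residues()].
#' @param iface_cutoff Interface distance cutoff, Angstrom (default 10).
#' @return Interface RMSD, Angstrom.
#' @export
interface_rmsd <- function(native_cplx, decoy_cplx, map, iface_cutoff = 10) {
  cp <- contact_pairs(native_cplx, iface_cutoff)
  iface_keys <- unique(c(cp$res_key, cp$nt_key))
  if (length(iface_keys) == 0) stop("native interface is empty at cutoff ",
                                    iface_cutoff)
  sub <- map[map$native_key %in% iface_keys, , drop = FALSE]
  bb <- mapped_backbone(native_cplx, decoy_cplx, sub)
  if (is.null(bb$P) || nrow(bb$P) < 3) stop("fewer than 3 mapped interface atoms")
  kabsch_superpose(bb$Q, bb$P)$rmsd
}

#' Native and non-native contact fractions
#'
#' Contacts are (residue, nucleotide) pairs with minimum heavy-atom
#' distance at most `contact_cutoff`. `fnat` is the fraction of native
#' contacts present in the decoy; `fnon` is the fraction of the decoy's
#' contacts that are not native (0 when the decoy has no contacts).
#'
#' @param native_cplx,decoy_cplx `rpc_structure` complexes.
#' @param map Residue map from [map_residues()].
#' @param contact_cutoff Contact distance, Angstrom (default 5).
#' @return Named numeric vector `c(fnat, fnon)`.
#' @export
contact_fractions <- function(native_cplx, decoy_cplx, map,
                              contact_cutoff = 5) {
  nat <- contact_pairs(native_cplx, contact_cutoff)
  if (nrow(nat) == 0) stop("native complex has no contacts at cutoff ",
                           contact_cutoff)
  dec <- contact_pairs(decoy_cplx, contact_cutoff)
  to_native <- stats::setNames(map$native_key, map$decoy_key)
  nat_set <- paste(nat$res_key, nat$nt_key, sep = "~")
  if (nrow(dec) == 0) return(c(fnat = 0, fnon = 0))
  dec_set <- paste(to_native[dec$res_key], to_native[dec$nt_key], sep = "~")
  fnat <- sum(nat_set %in% dec_set) / length(nat_set)
  fnon <- sum(!(dec_set %in% nat_set)) / length(dec_set)
  c(fnat = fnat, fnon = fnon)
}

#' Assess docked decoys against a native complex
#'
#' Drives the full analysis from a parameter set (see the `.par` keys
#' below): reads the G_DATA result file, rebuilds each of the first
#' `RPDock.max_matches` decoys from the docking structures (the grid is
#' re-derived deterministically with [auto_grid_spec()] at
#' `RPDock.grid_step`), maps residues to the native complex by sequence
#' alignment, computes the metrics and writes a whitespace-separated table
#' with header `#Decoy R_rmsd L_rmsd I_rms fnat fnon`.
#'
#' Recognized keys: `RPDock.resfile`, `RPDock.max_matches`,
#' `native.receptor_pdb_filename`, `native.ligand_pdb_filename`,
#' `native.receptor.chainid`, `native.ligand.chainid`,
#' `decoy.receptor_pdb_filename`, `decoy.ligand_pdb_filename`,
#' `decoy.receptor.chainid`, `decoy.ligand.chainid`, `rmsd.output`,
#' and optionally `RPDock.grid_step` (default 1).
#'
#' @param par Named list (e.g. from [parse_par()]) or path to a `.par`
#'   file.
#' @param dir Base directory for relative file names (defaults to the
#'   `.par` file's directory, or `"."`).
#' @return data.frame of metrics, invisibly; the output table is written
#'   as a side effect.
#' @export
analyze_decoys <- function(par, dir = NULL) {
  if (is.character(par) && length(par) == 1) {
    if (is.null(dir)) dir <- dirname(par)
    par <- parse_par(par)
  }
  if (is.null(dir)) dir <- "."
  need <- function(key) {
    v <- par[[key]]
    if (is.null(v)) stop("missing parameter: ", key)
    v
  }
  resolve <- function(f) if (file.exists(f)) f else file.path(dir, f)

  records <- read_gdata(resolve(need("RPDock.resfile")))
  max_matches <- as.integer(need("RPDock.max_matches"))
  if (max_matches > nrow(records)) {
    stop("RPDock.max_matches (", max_matches, ") exceeds record count (",
         nrow(records), ")")
  }
  grid_step <- as.numeric(par[["RPDock.grid_step"]] %||% "1")

  nat_r <- select_chains(read_pdb(resolve(need("native.receptor_pdb_filename"))),
                         need("native.receptor.chainid"))
  nat_l <- select_chains(read_pdb(resolve(need("native.ligand_pdb_filename"))),
                         need("native.ligand.chainid"))
  dec_r <- select_chains(read_pdb(resolve(need("decoy.receptor_pdb_filename"))),
                         need("decoy.receptor.chainid"))
  dec_l <- select_chains(read_pdb(resolve(need("decoy.ligand_pdb_filename"))),
                         need("decoy.ligand.chainid"))

  native_cplx <- suppressMessages(combine_structures(nat_r, nat_l))
  spec <- auto_grid_spec(dec_r, dec_l, step = grid_step)
  base_cplx <- suppressMessages(combine_structures(dec_r, dec_l))
  map <- map_residues(native_cplx, base_cplx)

  rows <- vector("list", max_matches)
  for (i in seq_len(max_matches)) {
    posed <- apply_pose(dec_l, records[i, ], spec)
    dcplx <- suppressMessages(combine_structures(dec_r, posed))
    rl <- receptor_ligand_rmsd(native_cplx, dcplx, map)
    ir <- interface_rmsd(native_cplx, dcplx, map)
    cf <- contact_fractions(native_cplx, dcplx, map)
    rows[[i]] <- data.frame(decoy = i, r_rmsd = rl[["r_rmsd"]],
                            l_rmsd = rl[["l_rmsd"]], i_rms = ir,
                            fnat = cf[["fnat"]], fnon = cf[["fnon"]])
  }
  metrics <- do.call(rbind, rows)
  out_path <- file.path(dir, need("rmsd.output"))
  lines <- c("#Decoy R_rmsd L_rmsd I_rms fnat fnon",
             sprintf("%d %.6g %.6g %.6g %.6g %.6g", metrics$decoy,
                     metrics$r_rmsd, metrics$l_rmsd, metrics$i_rms,
                     metrics$fnat, metrics$fnon))
  writeLines(lines, out_path)
  invisible(metrics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
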