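# Rebuild full-atom complexes from pose records, plus an optional
# aromatic-base stacking rescoring term.

#' Apply a docked pose to a ligand structure
#'
#' Rotates the ligand about its centroid by the record's Euler angles, then
#' translates it by the record's integer grid translation times the grid
#' step. Translations are interpreted modulo the grid (components at or
#' above `n/2` wrap to negative shifts), matching the circular FFT scan,
#' so a zero record leaves the ligand unchanged.
#'
#' @param ligand An `rpc_structure` (at the position used for docking).
#' @param rec One pose record (row of the [dock()] output).
#' @param spec The [grid_spec()] of the scan.
#' @return The posed ligand structure.
#' @export
apply_pose <- function(ligand, rec, spec) {
  t_raw <- c(rec$tx, rec$ty, rec$tz)
  if (any(t_raw < 0 | t_raw >= spec$n)) stop("translation outside grid")
  half <- floor(spec$n / 2)
  t_signed <- ((t_raw + half) %% spec$n) - half
  s <- rotate_euler(ligand, c(rec$alpha, rec$beta, rec$gamma))
  set_coords(s, sweep(coords(s), 2, t_signed * spec$step, "+"))
}

#' Build complex PDB files from docked pose records
#'
#' Writes `prefix1.pdb` ... `prefix{n_out}.pdb` in record (score) order,
#' each holding the receptor chains followed by the posed ligand chains
#' (ligand chain IDs colliding with receptor IDs are remapped).
#'
#' @param receptor,ligand `rpc_structure` objects as used for docking.
#' @param records Pose record data.frame (from [dock()] or [read_gdata()]).
#' @param spec The [grid_spec()] of the scan.
#' @param n_out Number of complexes to write (must not exceed the record
#'   count).
#' @param prefix File-name prefix, default `"complex"`.
#' @param dir Output directory.
#' @return Character vector of file paths, invisibly.
#' @export
build_complexes <- function(receptor, ligand, records, spec, n_out,
                            prefix = "complex", dir = ".") {
  if (n_out > nrow(records)) {
    stop("n_out (", n_out, ") exceeds available records (", nrow(records), ")")
  }
  paths <- character(n_out)
  for (i in seq_len(n_out)) {
    posed <- apply_pose(ligand, records[i, ], spec)
    cplx <- suppressMessages(combine_structures(receptor, posed))
    paths[i] <- file.path(dir, paste0(prefix, i, ".pdb"))
    write_pdb(cplx, paths[i])
  }
  invisible(paths)
}

.AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

.BASE_RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C4", "N1", "C2", "N3", "C6"),
  G = c("N9", "C8", "N7", "C5", "C4", "N1", "C2", "N3", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"))

ring_centroids <- function(s, ring_table) {
  idx <- residue_index(s)
  cens <- list()
  for (key in names(idx)) {
    rows <- idx[[key]]
    rn <- s$atoms$resname[rows[1]]
    ring <- ring_table[[rn]]
    if (is.null(ring)) next
    hit <- rows[normalize_atom_name(s$atoms$name[rows]) %in% ring]
    if (length(hit) < 3) next
    cens[[key]] <- colMeans(as.matrix(s$atoms[hit, c("x", "y", "z")]))
  }
  cens
}

#' Aromatic side chain / base stacking bonus
#'
#' Counts (aromatic residue, nucleotide) pairs whose ring centroids lie
#' within `dmax` and returns `bonus` times that count. Aromatic residues
#' are PHE, TYR, TRP, HIS. Intended as an optional rescoring column; it is
#' not part of the default docking score.
#'
#' @param complex An `rpc_structure` holding both molecules.
#' @param protein_chains,rna_chains Concatenated chain ID strings.
#' @param dmax Centroid distance cutoff, Angstrom (default 5.5).
#' @param bonus Score contribution per stacked pair.
#' @return Numeric stacking score (`bonus * n_pairs`).
#' @export
stacking_bonus <- function(complex, protein_chains, rna_chains,
                           dmax = 5.5, bonus = 1) {
  prot <- select_chains(complex, protein_chains)
  rna <- select_chains(complex, rna_chains)
  pc <- ring_centroids(prot, .AROMATIC_RING_ATOMS)
  bc <- ring_centroids(rna, .BASE_RING_ATOMS)
  if (length(pc) == 0 || length(bc) == 0) return(0)
  count <- 0L
  for (p in pc) for (b in bc) {
    if (sqrt(sum((p - b)^2)) <= dmax) count <- count + 1L
  }
  bonus * count
}
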