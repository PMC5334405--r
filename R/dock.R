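# The rigid-body docking driver: sweep a lattice of Euler rotations, FFT
# translation scan at each, keep the best few translations per rotation.

#' Docking parameter set
#'
#' @param receptor_path,ligand_path PDB file paths (protein receptor, RNA
#'   ligand).
#' @param receptor_chains,ligand_chains Concatenated chain IDs (`NULL` =
#'   all chains).
#' @param outfile G_DATA output path (`NULL` = do not write).
#' @param grid_step Grid spacing, Angstrom (1 recommended).
#' @param out_pdb Number of complex PDB files generated by the build stage.
#' @param rotation_step Euler lattice spacing, degrees.
#' @param elec_weight Weight of the electrostatic score term.
#' @param keep_per_rotation Poses retained per rotation (default 3).
#' @param surface_thickness,surface_weight,core_penalty Shape-grid
#'   parameters, see [discretize_shape()].
#' @param elec_cutoff,elec_rmin Potential-grid parameters, see
#'   [discretize_charge()].
#' @param negate_scores Emit scores with flipped sign (printed-style
#'   negative scores); ranking is unaffected.
#' @param pad Grid clearance, Angstrom, see [auto_grid_spec()].
#' @return A `dock_params` list.
#' @export
dock_params <- function(receptor_path, ligand_path,
                        receptor_chains = NULL, ligand_chains = NULL,
                        outfile = NULL, grid_step = 1, out_pdb = 10,
                        rotation_step = 15, elec_weight = 1,
                        keep_per_rotation = 3, surface_thickness = 1.5,
                        surface_weight = 1, core_penalty = -15,
                        elec_cutoff = 12, elec_rmin = 2,
                        negate_scores = FALSE, pad = 2) {
  stopifnot(grid_step > 0, out_pdb >= 0, keep_per_rotation >= 1,
            rotation_step > 0)
  structure(list(receptor_path = receptor_path, ligand_path = ligand_path,
                 receptor_chains = receptor_chains,
                 ligand_chains = ligand_chains, outfile = outfile,
                 grid_step = grid_step, out_pdb = as.integer(out_pdb),
                 rotation_step = rotation_step, elec_weight = elec_weight,
                 keep_per_rotation = as.integer(keep_per_rotation),
                 surface_thickness = surface_thickness,
                 surface_weight = surface_weight,
                 core_penalty = core_penalty, elec_cutoff = elec_cutoff,
                 elec_rmin = elec_rmin, negate_scores = negate_scores,
                 pad = pad),
            class = "dock_params")
}

#' Euler rotation lattice
#'
#' Uniform grid over alpha in \[0, 360), beta in \[0, 180\], gamma in
#' \[0, 360) at the given step, alpha varying fastest.
#'
#' @param step Lattice spacing, degrees.
#' @return data.frame with columns `alpha`, `beta`, `gamma`.
#' @export
rotation_lattice <- function(step) {
  a <- seq(0, 360 - min(step, 360), by = step)
  a <- a[a < 360]
  b <- seq(0, 180, by = step)
  g <- a
  expand.grid(alpha = a, beta = b, gamma = g, KEEP.OUT.ATTRS = FALSE)
}

# load, select and charge one docking partner
prepare_structure <- function(path, chains, expect = NULL) {
  s <- read_pdb(path)
  if (!is.null(chains) && nzchar(chains)) s <- select_chains(s, chains)
  if (!is.null(expect)) {
    got <- classify_molecule(s)
    if (got != expect) {
      warning(basename(path), " classified as ", got, ", expected ", expect)
    }
  }
  suppressMessages(assign_charges(s, quiet = TRUE))
}

#' Run the full rigid-body docking scan
#'
#' For every Euler triple on the rotation lattice the ligand is rotated
#' about its centroid, re-gridded (binary shape + trilinear charge), and
#' scanned over all grid translations by FFT correlation against the fixed
#' receptor grids (surface/core shape + Coulomb potential with
#' distance-dependent dielectric). `keep_per_rotation` poses are retained
#' per rotation on the combined GC + elec_weight * ELEC score; the final
#' list is sorted best-first. Deterministic for fixed parameters.
#'
#' @param p A [dock_params()] object.
#' @return data.frame of pose records (`rotation_index`, `score`, `tx`,
#'   `ty`, `tz`, `alpha`, `beta`, `gamma`), best score first, with the
#'   `grid_spec` used attached as attribute `"spec"`. Written to
#'   `p$outfile` in G_DATA format when set.
#' @export
dock <- function(p) {
  stopifnot(inherits(p, "dock_params"))
  recv <- prepare_structure(p$receptor_path, p$receptor_chains, "protein")
  lig <- prepare_structure(p$ligand_path, p$ligand_chains, "rna")
  spec <- auto_grid_spec(recv, lig, step = p$grid_step, pad = p$pad)

  rs <- discretize_shape(recv, spec, "receptor",
                         surface_thickness = p$surface_thickness,
                         surface_weight = p$surface_weight,
                         core_penalty = p$core_penalty)
  rq <- suppressWarnings(discretize_charge(recv, spec, "receptor",
                                           cutoff = p$elec_cutoff,
                                           r_min = p$elec_rmin))
  FRs <- stats::fft(rs$values)
  FRq <- stats::fft(rq$values)

  lat <- rotation_lattice(p$rotation_step)
  out <- vector("list", nrow(lat))
  N <- length(FRs)
  for (ri in seq_len(nrow(lat))) {
    ang <- c(lat$alpha[ri], lat$beta[ri], lat$gamma[ri])
    ligr <- rotate_euler(lig, ang)
    occ <- occupancy_grid(ligr, spec)
    ls <- array(0, dim(occ)); ls[occ] <- 1
    lq <- suppressWarnings(discretize_charge(ligr, spec, "ligand"))$values
    FL <- fft_real_pair(ls, lq)
    total <- Re(stats::fft(Conj(FL$A) * FRs +
                             p$elec_weight * Conj(FL$B) * FRq,
                           inverse = TRUE)) / N
    top <- top_k_translations(total, p$keep_per_rotation)
    top$rotation_index <- ri
    top$alpha <- ang[1]; top$beta <- ang[2]; top$gamma <- ang[3]
    out[[ri]] <- top
  }
  records <- do.call(rbind, out)
  ord <- order(-records$score, records$rotation_index,
               records$tx, records$ty, records$tz)
  records <- records[ord, c("rotation_index", "score", "tx", "ty", "tz",
                            "alpha", "beta", "gamma")]
  rownames(records) <- NULL
  if (p$negate_scores) records$score <- -records$score
  attr(records, "spec") <- spec
  if (!is.null(p$outfile)) write_gdata(records, p$outfile)
  records
}
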