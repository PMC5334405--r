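# Knowledge-based residue-base pair potential: contacting (residue,
# nucleotide) pairs are the statistical unit. Native pairs are clustered by
# RMSD within each (amino acid, base) type; cluster energies follow
# inverse-Boltzmann counts; decoys score the summed energies of their
# matched pairs.

# reduced-atom templates making cross-conformer RMSD well defined:
# residue 5 points (CB falls back to CA for GLY), nucleotide 4 points
# (P falls back to O5' for a 5'-terminal nucleotide; glycosidic N differs
# between purines and pyrimidines)
.RES_REDUCED <- c("N", "CA", "C", "O", "CB")
.NT_REDUCED_HEAD <- c("P", "O5'")      # first available is used
.NT_REDUCED_TAIL <- c("C4'", "C1'")

reduced_pair_coords <- function(atoms, res_rows, nt_rows) {
  nm_r <- normalize_atom_name(atoms$name[res_rows])
  nm_n <- normalize_atom_name(atoms$name[nt_rows])
  get1 <- function(rows, nms, want) {
    i <- match(want, nms)
    i <- i[!is.na(i)]
    if (length(i) == 0) return(NULL)
    as.numeric(atoms[rows[i[1]], c("x", "y", "z")])
  }
  res <- lapply(c("N", "CA", "C", "O"), function(a) get1(res_rows, nm_r, a))
  cb <- get1(res_rows, nm_r, "CB")
  if (is.null(cb)) cb <- get1(res_rows, nm_r, "CA")
  res <- c(res, list(cb))
  base_type <- atoms$resname[nt_rows[1]]
  gly_n <- if (base_type %in% .PURINES) "N9" else "N1"
  nt <- list(get1(nt_rows, nm_n, .NT_REDUCED_HEAD),
             get1(nt_rows, nm_n, "C4'"),
             get1(nt_rows, nm_n, "C1'"),
             get1(nt_rows, nm_n, gly_n))
  pts <- c(res, nt)
  if (any(vapply(pts, is.null, logical(1)))) return(NULL)
  m <- do.call(rbind, pts)
  sweep(m, 2, colMeans(m))   # canonical local frame: pair centroid at origin
}

new_residue_base_pair <- function(res_type, base_type, coords, source = "") {
  structure(list(res_type = res_type, base_type = base_type,
                 coords = coords, source = source),
            class = "residue_base_pair")
}

#' Extract contacting residue-base pairs from a complex
#'
#' One pair for every (amino-acid residue, nucleotide) whose minimum
#' heavy-atom distance is at most `cutoff` (boundary inclusive). Each pair
#' carries the reduced-atom coordinates (residue N, CA, C, O, CB with CA
#' standing in for GLY's CB; nucleotide P or O5', C4', C1', and N9 for
#' purines / N1 for pyrimidines), centered on the pair centroid. Pairs with
#' incomplete reduced-atom sets are skipped with a warning.
#'
#' @param complex An `rpc_structure`.
#' @param protein_chains,rna_chains Concatenated chain ID strings.
#' @param cutoff Contact distance, Angstrom (default 10).
#' @return List of `residue_base_pair` objects (possibly empty).
#' @export
extract_pairs <- function(complex, protein_chains, rna_chains, cutoff = 10) {
  prot <- select_chains(complex, protein_chains)
  rna <- select_chains(complex, rna_chains)
  pa <- prot$atoms[prot$atoms$element != "H", , drop = FALSE]
  na_ <- rna$atoms[rna$atoms$element != "H", , drop = FALSE]
  if (nrow(pa) == 0 || nrow(na_) == 0) return(list())
  pidx <- split(seq_len(nrow(pa)),
                factor(residue_keys(pa), levels = unique(residue_keys(pa))))
  nidx <- split(seq_len(nrow(na_)),
                factor(residue_keys(na_), levels = unique(residue_keys(na_))))
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  nxyz <- as.matrix(na_[, c("x", "y", "z")])
  out <- list()
  skipped <- 0L
  for (pk in names(pidx)) {
    rows_p <- pidx[[pk]]
    res_type <- pa$resname[rows_p[1]]
    if (!(res_type %in% .STANDARD_AA)) next
    d2 <- outer(rowSums(pxyz[rows_p, , drop = FALSE]^2),
                rowSums(nxyz^2), "+") -
      2 * pxyz[rows_p, , drop = FALSE] %*% t(nxyz)
    dmin_atom <- sqrt(pmax(apply(d2, 2, min), 0))
    for (nk in names(nidx)) {
      rows_n <- nidx[[nk]]
      if (min(dmin_atom[rows_n]) > cutoff) next
      base_type <- na_$resname[rows_n[1]]
      if (!(base_type %in% .STANDARD_NT)) next
      joint <- rbind(pa[rows_p, , drop = FALSE], na_[rows_n, , drop = FALSE])
      m <- reduced_pair_coords(joint, seq_along(rows_p),
                               length(rows_p) + seq_along(rows_n))
      if (is.null(m)) { skipped <- skipped + 1L; next }
      out[[length(out) + 1L]] <-
        new_residue_base_pair(res_type, base_type, m,
                              source = paste(pk, nk, sep = " ~ "))
    }
  }
  if (skipped > 0) {
    warning(skipped, " pair(s) skipped: incomplete reduced-atom set")
  }
  out
}

#' RMSD between two residue-base pairs
#'
#' Pairs of different (residue type, base type) classes are incomparable
#' and return `NA`. Otherwise the RMSD after optimal rigid superposition
#' (Kabsch) of the shared reduced-atom sets.
#'
#' @param a,b `residue_base_pair` objects.
#' @return RMSD in Angstrom, or `NA_real_` if incomparable.
#' @export
pair_rmsd <- function(a, b) {
  if (a$res_type != b$res_type || a$base_type != b$base_type) {
    return(NA_real_)
  }
  kabsch_superpose(a$coords, b$coords)$rmsd
}

#' Train the residue-base pair potential
#'
#' Pools contact pairs from native complexes, then per (residue type, base
#' type) class runs deterministic greedy leader clustering in source order:
#' a pair joins the first existing cluster whose leader is within
#' `cluster_threshold` RMSD, else founds a new cluster. Cluster energies
#' are inverse-Boltzmann in the member counts,
#' `E_c = -ln(n_c / n_bar)` with `n_bar` the mean cluster size within the
#' class, so the most populated cluster gets the lowest energy. Each
#' leader becomes a standard pair carrying its cluster energy.
#'
#' @param native_complexes List of `list(structure, protein_chains,
#'   rna_chains)` entries.
#' @param cluster_threshold Leader RMSD threshold, Angstrom (default 6,
#'   mirroring the scoring match threshold).
#' @param cutoff Pair extraction distance, Angstrom (default 10).
#' @return A `pair_library`.
#' @export
train_potential <- function(native_complexes, cluster_threshold = 6,
                            cutoff = 10) {
  all_pairs <- list()
  for (nc in native_complexes) {
    all_pairs <- c(all_pairs,
                   extract_pairs(nc[[1]], nc[[2]], nc[[3]], cutoff = cutoff))
  }
  if (length(all_pairs) == 0) stop("no residue-base pairs in training set")
  types <- vapply(all_pairs, function(p) paste(p$res_type, p$base_type),
                  character(1))
  std <- list()
  cluster_id <- 0L
  for (ty in unique(types)) {
    members <- all_pairs[types == ty]
    leaders <- list()
    counts <- integer(0)
    for (p in members) {
      joined <- FALSE
      for (ci in seq_along(leaders)) {
        if (pair_rmsd(leaders[[ci]], p) < cluster_threshold) {
          counts[ci] <- counts[ci] + 1L
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        leaders[[length(leaders) + 1L]] <- p
        counts <- c(counts, 1L)
      }
    }
    n_bar <- mean(counts)
    for (ci in seq_along(leaders)) {
      cluster_id <- cluster_id + 1L
      std[[length(std) + 1L]] <- list(
        res_type = leaders[[ci]]$res_type,
        base_type = leaders[[ci]]$base_type,
        energy = -log(counts[ci] / n_bar),
        cluster_id = cluster_id,
        n_members = counts[ci],
        coords = leaders[[ci]]$coords)
    }
  }
  structure(list(standard_pairs = std,
                 meta = list(cutoff = cutoff,
                             cluster_threshold = cluster_threshold,
                             n_training_pairs = length(all_pairs),
                             n_clusters = length(std))),
            class = "pair_library")
}

#' @export
print.pair_library <- function(x, ...) {
  cat(sprintf(paste0("pair_library: %d standard pairs (%d training pairs),",
                     " extraction %.3g A, cluster threshold %.3g A\n"),
              length(x$standard_pairs), x$meta$n_training_pairs,
              x$meta$cutoff, x$meta$cluster_threshold))
  invisible(x)
}

#' Score a decoy complex with a trained pair library
#'
#' Each extracted decoy pair is matched to the nearest standard pair of
#' identical (residue type, base type) class by superposition RMSD; if that
#' RMSD is strictly below `match_threshold` the standard pair's energy is
#' assigned, otherwise 0. The complex energy is the sum over pairs (lower
#' is better).
#'
#' @param complex An `rpc_structure`.
#' @param protein_chains,rna_chains Concatenated chain ID strings.
#' @param lib A [train_potential()] `pair_library`.
#' @param cutoff Pair extraction distance, Angstrom.
#' @param match_threshold Match RMSD threshold, Angstrom (strict, default 6).
#' @return Numeric energy.
#' @export
score_complex <- function(complex, protein_chains, rna_chains, lib,
                          cutoff = 10, match_threshold = 6) {
  stopifnot(inherits(lib, "pair_library"))
  pairs <- extract_pairs(complex, protein_chains, rna_chains, cutoff = cutoff)
  if (length(pairs) == 0) return(0)
  lib_types <- vapply(lib$standard_pairs,
                      function(p) paste(p$res_type, p$base_type), character(1))
  total <- 0
  for (p in pairs) {
    cand <- which(lib_types == paste(p$res_type, p$base_type))
    if (length(cand) == 0) next
    rmsds <- vapply(cand, function(ci) {
      kabsch_superpose(lib$standard_pairs[[ci]]$coords, p$coords)$rmsd
    }, numeric(1))
    best <- which.min(rmsds)
    if (rmsds[best] < match_threshold) {
      total <- total + lib$standard_pairs[[cand[best]]]$energy
    }
  }
  total
}

#' Score a list of complex files
#'
#' The list file holds one complex per line: file name, protein chain IDs,
#' RNA chain IDs, whitespace-separated (e.g. `complex1.pdb V CB`). File
#' names are resolved relative to the list file's directory. Output lines
#' are `name energy` in list order.
#'
#' @param list_path Path to the list file.
#' @param lib A `pair_library`.
#' @param out_path Output score file path.
#' @param ... Passed to [score_complex()].
#' @return data.frame (`name`, `energy`), invisibly; the score file is
#'   written as a side effect.
#' @export
score_list <- function(list_path, lib, out_path, ...) {
  lines <- readLines(list_path)
  base <- dirname(list_path)
  keep <- which(nzchar(trimws(lines)))
  res <- data.frame(name = character(0), energy = numeric(0))
  for (ln in keep) {
    f <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(f) != 3) {
      stop("malformed list line ", ln, " in ", list_path,
           " (expected: name protein_chains rna_chains)")
    }
    path <- if (file.exists(f[1])) f[1] else file.path(base, f[1])
    if (!file.exists(path)) stop("complex file not found: ", f[1])
    cplx <- read_pdb(path)
    e <- score_complex(cplx, f[2], f[3], lib, ...)
    res <- rbind(res, data.frame(name = f[1], energy = e))
  }
  writeLines(sprintf("%s %.4f", res$name, res$energy), out_path)
  invisible(res)
}

#' Serialize a pair library to JSON
#' @param lib A `pair_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_library <- function(lib, path) {
  obj <- list(format = "rpcdock_pair_library", version = 1L,
              meta = lib$meta,
              standard_pairs = lapply(lib$standard_pairs, function(p) {
                list(res_type = p$res_type, base_type = p$base_type,
                     energy = p$energy, cluster_id = p$cluster_id,
                     n_members = p$n_members,
                     coords = as.vector(t(p$coords)))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pair library from JSON
#' @param path Path written by [write_pair_library()].
#' @return A `pair_library`.
#' @export
read_pair_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "rpcdock_pair_library") {
    stop("not a pair library file: ", path)
  }
  sp <- obj$standard_pairs
  pairs <- lapply(seq_len(nrow(sp)), function(i) {
    list(res_type = sp$res_type[i], base_type = sp$base_type[i],
         energy = sp$energy[i], cluster_id = as.integer(sp$cluster_id[i]),
         n_members = as.integer(sp$n_members[i]),
         coords = matrix(unlist(sp$coords[i]), ncol = 3, byrow = TRUE))
  })
  structure(list(standard_pairs = pairs, meta = as.list(obj$meta)),
            class = "pair_library")
}
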