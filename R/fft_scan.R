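# FFT translation scan: the docking score at every grid translation is a
# circular cross-correlation, evaluated for all n^3 shifts at once via the
# convolution theorem.

#' Circular cross-correlation of two equal-size 3-D grids
#'
#' `out[t] = sum_x a[x] * b[x + t]` with indices taken modulo the grid
#' size, computed by forward/inverse FFT.
#'
#' @param a,b Numeric arrays of identical dimensions.
#' @return Numeric array of the same dimensions; entry `[i,j,k]` is the
#'   correlation at translation `(i-1, j-1, k-1)` grid cells.
#' @export
correlate <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid dimension mismatch")
  Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    length(a)
}

# Forward FFTs of two real arrays from one complex transform:
# Z = FFT(a + i b); A(k) = (Z(k) + conj(Z(-k)))/2, B(k) = (Z(k) - conj(Z(-k)))/(2i)
fft_real_pair <- function(a, b) {
  n <- dim(a)
  Z <- stats::fft(a + 1i * b)
  rev_idx <- lapply(n, function(m) c(1L, m:2L))
  Zr <- Conj(Z[rev_idx[[1]], rev_idx[[2]], rev_idx[[3]], drop = FALSE])
  dim(Zr) <- n
  list(A = (Z + Zr) / 2, B = (Z - Zr) / (2i))
}

# direct O(n^6) correlation; independent reference for correlate()
correlate_direct <- function(a, b) {
  n <- dim(a)
  out <- array(0, n)
  for (t3 in 0:(n[3] - 1)) {
    i3 <- ((0:(n[3] - 1) + t3) %% n[3]) + 1
    for (t2 in 0:(n[2] - 1)) {
      i2 <- ((0:(n[2] - 1) + t2) %% n[2]) + 1
      for (t1 in 0:(n[1] - 1)) {
        i1 <- ((0:(n[1] - 1) + t1) %% n[1]) + 1
        out[t1 + 1, t2 + 1, t3 + 1] <- sum(a * b[i1, i2, i3])
      }
    }
  }
  out
}

# k best translations of a score array; ties broken by lexicographic
# translation order (tx, ty, tz)
top_k_translations <- function(total, k) {
  vec <- as.vector(total)
  k <- min(k, length(vec))
  thr <- sort(vec, decreasing = TRUE)[k]
  cand <- which(vec >= thr)
  ijk <- arrayInd(cand, dim(total)) - 1L
  ord <- order(-vec[cand], ijk[, 1], ijk[, 2], ijk[, 3])[seq_len(k)]
  data.frame(score = vec[cand][ord],
             tx = ijk[ord, 1], ty = ijk[ord, 2], tz = ijk[ord, 3])
}

#' Score all translations of one ligand orientation
#'
#' Combined score per translation:
#' `total[t] = GC_corr[t] + elec_weight * ELEC_corr[t]`, where `GC_corr`
#' correlates the ligand shape grid against the receptor surface/core grid
#' and `ELEC_corr` correlates the ligand charge grid against the receptor
#' potential grid. Returns the `k` best translations (largest total;
#' clashes self-penalize through the negative core penalty), ties broken by
#' lexicographic translation order.
#'
#' @param recv_shape,lig_shape `shape_grid` objects sharing one spec.
#' @param recv_elec,lig_elec `charge_grid` objects sharing the same spec.
#' @param elec_weight Weight of the electrostatic term.
#' @param k Number of translations to retain.
#' @return data.frame with columns `score`, `tx`, `ty`, `tz` (grid units).
#' @export
score_rotation <- function(recv_shape, recv_elec, lig_shape, lig_elec,
                           elec_weight = 1, k = 3) {
  specs <- list(recv_shape$spec, recv_elec$spec, lig_shape$spec, lig_elec$spec)
  for (sp in specs[-1]) {
    if (!isTRUE(all.equal(specs[[1]], sp))) stop("grid spec mismatch")
  }
  total <- correlate(lig_shape$values, recv_shape$values) +
    elec_weight * correlate(lig_elec$values, recv_elec$values)
  top_k_translations(total, k)
}

#' Write pose records in G_DATA format
#'
#' One whitespace-separated 11-field line per record: tag `G_DATA`,
#' rotation index, a reserved 0, the docking score (column 4), a reserved 0
#' (column 5), the integer translation vector (columns 6-8, grid units) and
#' the Euler rotation angles in degrees (columns 9-11).
#'
#' @param records data.frame with columns `rotation_index`, `score`, `tx`,
#'   `ty`, `tz`, `alpha`, `beta`, `gamma`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gdata <- function(records, path) {
  lines <- sprintf("G_DATA %d 0 %.2f 0 %d %d %d %.1f %.1f %.1f",
                   records$rotation_index, records$score,
                   records$tx, records$ty, records$tz,
                   records$alpha, records$beta, records$gamma)
  writeLines(lines, path)
  invisible(path)
}

#' Read a G_DATA pose file
#'
#' Inverts [write_gdata()]. Any non-blank line that is not a valid 11-field
#' `G_DATA` record raises an error naming the line number.
#'
#' @param path Path to a G_DATA file.
#' @return data.frame of pose records.
#' @export
read_gdata <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  recs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(f) != 11 || f[1] != "G_DATA") {
      stop("malformed G_DATA line ", ln, " in ", path)
    }
    v <- suppressWarnings(as.numeric(f[2:11]))
    if (any(is.na(v))) stop("malformed G_DATA line ", ln, " in ", path)
    recs[[i]] <- data.frame(rotation_index = as.integer(v[1]),
                            score = v[3],
                            tx = as.integer(v[5]), ty = as.integer(v[6]),
                            tz = as.integer(v[7]),
                            alpha = v[8], beta = v[9], gamma = v[10])
  }
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}
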