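# 3-D grid discretization for the FFT docking scan.
#
# Both molecules share one GridSpec: cubic n^3 lattice, cell centers at
# origin + (i-1)*step along each axis. The receptor shape grid carries
# surface_weight in a surface layer and core_penalty in the interior; the
# ligand shape grid is binary. Electrostatics: the receptor grid holds the
# Coulomb potential with a distance-dependent dielectric, the ligand grid
# holds trilinearly spread partial charges, so their correlation is the
# interaction energy sum.

.VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8)
.VDW_DEFAULT <- 1.7

#' Grid specification
#'
#' @param step Grid spacing in Angstrom (> 0).
#' @param n Cells per axis (FFT-friendly: factors 2, 3, 5 only).
#' @param origin Length-3 coordinate of the first cell center, Angstrom.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(step, n, origin) {
  stopifnot(step > 0, n >= 2, length(origin) == 3, all(is.finite(origin)))
  structure(list(step = step, n = as.integer(n), origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d^3 cells, step %.3g A, origin (%.2f, %.2f, %.2f)\n",
              x$n, x$step, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# smallest integer >= n whose prime factors are all in {2, 3, 5}
next_fft_size <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Automatic grid specification for a docking pair
#'
#' Chooses a cubic grid covering the receptor and the ligand at its input
#' position, padded by the ligand's own extent plus the largest van der
#' Waals radius so that (a) every translation placing the ligand in contact
#' with the receptor fits in the box and (b) the periodic FFT correlation
#' cannot wrap one molecule onto the other. `n` is rounded up to the next
#' FFT-friendly size (factors 2, 3, 5). Deterministic in its inputs, so a
#' later analysis run rebuilds the identical grid.
#'
#' @param receptor,ligand `rpc_structure` objects.
#' @param step Grid spacing, Angstrom.
#' @param pad Extra clearance per side, Angstrom (default 2).
#' @return A `grid_spec`.
#' @export
auto_grid_spec <- function(receptor, ligand, step = 1, pad = 2) {
  rx <- coords(receptor); lx <- coords(ligand)
  rmax <- max(.VDW_RADII, .VDW_DEFAULT)
  lig_cen <- colMeans(lx)
  lig_rad <- max(sqrt(rowSums(sweep(lx, 2, lig_cen)^2))) + rmax
  lo <- pmin(apply(rx, 2, min), apply(lx, 2, min))
  hi <- pmax(apply(rx, 2, max), apply(lx, 2, max))
  # wraparound guard: one period must exceed receptor span + ligand diameter
  span_r <- max(apply(rx, 2, max) - apply(rx, 2, min)) + 2 * rmax
  n_wrap <- (span_r + 2 * lig_rad) / step + 2
  n_cover <- (max(hi - lo) + 2 * (lig_rad + pad)) / step
  n <- next_fft_size(max(n_wrap, n_cover))
  center <- (lo + hi) / 2
  origin <- center - (n - 1) * step / 2
  grid_spec(step, n, origin)
}

atom_radii <- function(s, radii = .VDW_RADII) {
  r <- radii[s$atoms$element]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

check_in_grid <- function(xyz, r, spec) {
  lo <- spec$origin - spec$step / 2
  hi <- spec$origin + (spec$n - 0.5) * spec$step
  ok <- sweep(xyz - r, 2, lo, ">=") & sweep(xyz + r, 2, hi, "<=")
  if (!all(ok)) {
    stop("molecule exceeds grid extent; increase n (need cells beyond ",
         spec$n, ")")
  }
}

# logical occupancy array: cell center within vdW radius of any atom
occupancy_grid <- function(s, spec, radii = .VDW_RADII) {
  n <- spec$n; step <- spec$step; org <- spec$origin
  xyz <- coords(s)
  r <- atom_radii(s, radii)
  check_in_grid(xyz, r, spec)
  occ <- array(FALSE, c(n, n, n))
  ax <- function(k, p, rad) {
    i0 <- max(1L, as.integer(ceiling((p - rad - org[k]) / step)) + 1L)
    i1 <- min(n, as.integer(floor((p + rad - org[k]) / step)) + 1L)
    if (i0 > i1) integer(0) else i0:i1
  }
  for (j in seq_len(nrow(xyz))) {
    p <- xyz[j, ]; rj <- r[j]
    i <- ax(1, p[1], rj); if (length(i) == 0) next
    k2 <- ax(2, p[2], rj); if (length(k2) == 0) next
    k3 <- ax(3, p[3], rj); if (length(k3) == 0) next
    dx2 <- (org[1] + (i - 1) * step - p[1])^2
    dy2 <- (org[2] + (k2 - 1) * step - p[2])^2
    dz2 <- (org[3] + (k3 - 1) * step - p[3])^2
    box <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rj^2
    occ[i, k2, k3] <- occ[i, k2, k3] | box
  }
  occ
}

#' Discretize a structure onto a shape grid
#'
#' A cell is occupied when its center lies within an atom's van der Waals
#' radius. For the receptor, occupied cells whose center is within
#' `surface_thickness` of an empty cell's center (cells beyond the grid
#' count as empty) form the surface layer and carry `surface_weight`;
#' deeper cells carry `core_penalty`. Ligand grids are binary (0/1).
#'
#' @param s An `rpc_structure`.
#' @param spec A [grid_spec()].
#' @param role `"receptor"` or `"ligand"`.
#' @param surface_thickness Surface layer depth, Angstrom.
#' @param surface_weight Value of receptor surface cells.
#' @param core_penalty Value of receptor core cells (negative: clashes
#'   self-penalize).
#' @param radii Named per-element van der Waals radii, Angstrom.
#' @return A `shape_grid`: list with `values` (n^3 array), `role`, `spec`.
#' @export
discretize_shape <- function(s, spec, role = c("receptor", "ligand"),
                             surface_thickness = 1.5, surface_weight = 1,
                             core_penalty = -15, radii = .VDW_RADII) {
  role <- match.arg(role)
  occ <- occupancy_grid(s, spec, radii)
  n <- spec$n
  vals <- array(0, c(n, n, n))
  if (role == "ligand") {
    vals[occ] <- 1
  } else {
    rc <- as.integer(floor(surface_thickness / spec$step))
    near_empty <- array(FALSE, c(n, n, n))
    if (rc >= 1) {
      np <- n + 2L * rc
      empty_pad <- array(TRUE, c(np, np, np))
      inner <- (rc + 1L):(rc + n)
      empty_pad[inner, inner, inner] <- !occ
      for (o1 in -rc:rc) for (o2 in -rc:rc) for (o3 in -rc:rc) {
        if (o1 == 0 && o2 == 0 && o3 == 0) next
        if (sqrt(o1^2 + o2^2 + o3^2) * spec$step > surface_thickness) next
        near_empty <- near_empty |
          empty_pad[inner + o1, inner + o2, inner + o3]
      }
    }
    surf <- occ & near_empty
    vals[surf] <- surface_weight
    vals[occ & !surf] <- core_penalty
  }
  structure(list(values = vals, role = role, spec = spec),
            class = "shape_grid")
}

#' Distance-dependent dielectric
#'
#' Continuous piecewise-linear form: 4 for r <= 6 A, `38 r - 224` for
#' 6 < r < 8 A, 80 for r >= 8 A.
#'
#' @param r Distance(s), Angstrom, >= 0.
#' @return Dimensionless dielectric value(s).
#' @export
dielectric <- function(r) {
  stopifnot(all(r >= 0))
  ifelse(r <= 6, 4, ifelse(r >= 8, 80, 38 * r - 224))
}

#' Discretize partial charges onto a grid
#'
#' Ligand role: each atomic charge is spread over the 8 surrounding cell
#' centers with trilinear weights (total grid charge equals the molecular
#' charge). Receptor role: each cell center gets the Coulomb potential
#' `sum_j q_j / (dielectric(r_j) * r_j)` over receptor atoms within
#' `cutoff`, with `r` clamped below at `r_min` (soft core inside atoms).
#' Internal units: elementary charge and Angstrom.
#'
#' @param s An `rpc_structure` with charges assigned.
#' @param spec A [grid_spec()].
#' @param role `"receptor"` or `"ligand"`.
#' @param cutoff Potential truncation radius, Angstrom.
#' @param r_min Soft-core minimum distance, Angstrom.
#' @return A `charge_grid`: list with `values`, `role`, `spec`.
#' @export
discretize_charge <- function(s, spec, role = c("receptor", "ligand"),
                              cutoff = 12, r_min = 2) {
  role <- match.arg(role)
  n <- spec$n; step <- spec$step; org <- spec$origin
  xyz <- coords(s)
  q <- s$atoms$charge
  vals <- array(0, c(n, n, n))
  if (all(q == 0)) {
    warning("all charges are zero; returning a zero grid")
    return(structure(list(values = vals, role = role, spec = spec),
                     class = "charge_grid"))
  }
  check_in_grid(xyz, 0, spec)
  if (role == "ligand") {
    f <- sweep(xyz, 2, org) / step            # fractional cell coordinates
    i0 <- floor(f)
    w1 <- f - i0                              # weight toward upper neighbor
    i0 <- i0 + 1                              # 1-based lower cell index
    for (j in seq_len(nrow(xyz))) {
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) w1[j, 1] else 1 - w1[j, 1]) *
             (if (dy) w1[j, 2] else 1 - w1[j, 2]) *
             (if (dz) w1[j, 3] else 1 - w1[j, 3])
        ii <- i0[j, 1] + dx; jj <- i0[j, 2] + dy; kk <- i0[j, 3] + dz
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= n && kk >= 1 && kk <= n) {
          vals[ii, jj, kk] <- vals[ii, jj, kk] + q[j] * w
        }
      }
    }
  } else {
    ax <- function(k, p) {
      i0 <- max(1L, as.integer(ceiling((p - cutoff - org[k]) / step)) + 1L)
      i1 <- min(n, as.integer(floor((p + cutoff - org[k]) / step)) + 1L)
      if (i0 > i1) integer(0) else i0:i1
    }
    for (j in seq_len(nrow(xyz))) {
      if (q[j] == 0) next
      p <- xyz[j, ]
      i <- ax(1, p[1]); if (length(i) == 0) next
      k2 <- ax(2, p[2]); if (length(k2) == 0) next
      k3 <- ax(3, p[3]); if (length(k3) == 0) next
      dx2 <- (org[1] + (i - 1) * step - p[1])^2
      dy2 <- (org[2] + (k2 - 1) * step - p[2])^2
      dz2 <- (org[3] + (k3 - 1) * step - p[3])^2
      r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
      inside <- r <= cutoff
      r_eff <- pmax(r, r_min)
      contrib <- q[j] / (dielectric(r_eff) * r_eff)
      contrib[!inside] <- 0
      vals[i, k2, k3] <- vals[i, k2, k3] + contrib
    }
  }
  structure(list(values = vals, role = role, spec = spec),
            class = "charge_grid")
}
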