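# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# Horn's closed-form quaternion superposition: the optimal-rotation RMSD
# follows from the largest eigenvalue of the 4x4 key matrix, with no
# explicit rotation reconstruction.
quaternion_superpose <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  S <- t(P0) %*% Q0
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- eigen(K, symmetric = TRUE, only.values = TRUE)$values[1]
  list(rmsd = sqrt(max(0, sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

# direct occupancy check: cell centers within radius of any atom
brute_occupancy <- function(xyz, radii, spec) {
  n <- spec$n
  ax <- spec$origin[1] + (0:(n - 1)) * spec$step
  ay <- spec$origin[2] + (0:(n - 1)) * spec$step
  az <- spec$origin[3] + (0:(n - 1)) * spec$step
  occ <- array(FALSE, c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    d2 <- (xyz[, 1] - ax[i])^2 + (xyz[, 2] - ay[j])^2 + (xyz[, 3] - az[k])^2
    occ[i, j, k] <- any(d2 <= radii^2)
  }
  occ
}

# direct GC+ELEC overlap score of a posed ligand against receptor grids
rebuild_score <- function(recv_shape, recv_elec, posed_ligand, elec_weight = 1) {
  occ <- rpcdock:::occupancy_grid(posed_ligand, recv_shape$spec)
  ls <- array(0, dim(occ)); ls[occ] <- 1
  lq <- suppressWarnings(discretize_charge(posed_ligand, recv_shape$spec,
                                           "ligand"))$values
  sum(recv_shape$values * ls) + elec_weight * sum(recv_elec$values * lq)
}

# minimal fixed-column PDB writer for handcrafted test inputs
pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     record = "ATOM", altloc = " ", icode = " ", occ = 1,
                     element = substr(gsub("[^A-Za-z]", "", name), 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resseq, icode,
          x, y, z, occ, 0, element)
}
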