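# United-atom partial-charge table. Values follow AMBER-style magnitudes
# with hydrogen charges folded onto their bonded heavy atom (structures are
# typically deposited H-free); one designated atom per residue (CA for amino
# acids, C1' for nucleotides) absorbs the residual so every complete residue
# sums exactly to its formal integer charge.

.charge_env <- new.env(parent = emptyenv())

.AA_FORMAL <- c(ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0,
                GLU = -1, GLY = 0, HIS = 0, ILE = 0, LEU = 0, LYS = 1,
                MET = 0, PHE = 0, PRO = 0, SER = 0, THR = 0, TRP = 0,
                TYR = 0, VAL = 0)
.NT_FORMAL <- c(A = -1, U = -1, G = -1, C = -1)

.SIDECHAIN_Q <- list(
  ALA = c(CB = 0.03),
  ARG = c(CB = 0.00, CG = 0.02, CD = 0.14, NE = -0.23, CZ = 0.81,
          NH1 = 0.03, NH2 = 0.03),
  ASN = c(CB = 0.00, CG = 0.71, OD1 = -0.59, ND2 = -0.08),
  ASP = c(CB = -0.04, CG = 0.80, OD1 = -0.80, OD2 = -0.80),
  CYS = c(CB = 0.10, SG = -0.12),
  GLN = c(CB = 0.00, CG = 0.00, CD = 0.70, OE1 = -0.59, NE2 = -0.08),
  GLU = c(CB = 0.00, CG = -0.04, CD = 0.81, OE1 = -0.82, OE2 = -0.82),
  GLY = c(),
  HIS = c(CB = 0.00, CG = 0.19, ND1 = -0.54, CD2 = 0.10, CE1 = 0.31,
          NE2 = -0.23),
  ILE = c(CB = 0.00, CG1 = 0.00, CG2 = 0.00, CD1 = 0.00),
  LEU = c(CB = 0.00, CG = 0.00, CD1 = 0.00, CD2 = 0.00),
  LYS = c(CB = 0.00, CG = 0.02, CD = 0.00, CE = 0.19, NZ = 0.64),
  MET = c(CB = 0.00, CG = 0.06, SD = -0.27, CE = 0.12),
  PHE = c(CB = 0.00, CG = 0.01, CD1 = 0.00, CD2 = 0.00, CE1 = 0.00,
          CE2 = 0.00, CZ = 0.00),
  PRO = c(CB = 0.00, CG = 0.00, CD = 0.09),
  SER = c(CB = 0.21, OG = -0.23),
  THR = c(CB = 0.27, OG1 = -0.25, CG2 = 0.00),
  TRP = c(CB = 0.00, CG = -0.10, CD1 = 0.10, CD2 = 0.12, NE1 = -0.10,
          CE2 = 0.13, CE3 = 0.00, CZ2 = 0.00, CZ3 = 0.00, CH2 = 0.00),
  TYR = c(CB = 0.00, CG = 0.00, CD1 = 0.00, CD2 = 0.00, CE1 = 0.00,
          CE2 = 0.00, CZ = 0.32, OH = -0.34),
  VAL = c(CB = 0.00, CG1 = 0.00, CG2 = 0.00)
)

# RNA backbone shared by all four ribonucleotides (C1' is the absorber)
.NT_BACKBONE_Q <- c(P = 1.1662, OP1 = -0.776, OP2 = -0.776, "O5'" = -0.4989,
                    "C5'" = 0.0754, "C4'" = 0.1065, "O4'" = -0.3548,
                    "C3'" = 0.2022, "O3'" = -0.5246, "C2'" = 0.1353,
                    "O2'" = -0.2513)

.BASE_Q <- list(
  A = c(N9 = -0.0251, C8 = 0.2006, N7 = -0.6073, C5 = 0.0515, C6 = 0.7009,
        N6 = -0.0800, N1 = -0.7615, C2 = 0.5875, N3 = -0.6997, C4 = 0.3053),
  G = c(N9 = 0.0492, C8 = 0.1374, N7 = -0.5709, C5 = 0.1744, C6 = 0.4770,
        O6 = -0.5597, N1 = -0.1250, C2 = 0.7657, N2 = -0.0590, N3 = -0.6323,
        C4 = 0.1222),
  C = c(N1 = -0.0484, C2 = 0.7538, O2 = -0.6252, N3 = -0.7584, C4 = 0.8185,
        N4 = -0.1230, C5 = -0.3085, C6 = 0.1849),
  U = c(N1 = 0.0418, C2 = 0.4687, O2 = -0.5477, N3 = -0.0801, C4 = 0.5952,
        O4 = -0.5761, C5 = -0.1625, C6 = 0.0214)
)

#' Embedded united-atom charge table
#'
#' Per-(residue, atom) partial charges for the 20 standard amino acids and
#' the 4 ribonucleotides, in elementary-charge units. Hydrogen charges are
#' folded onto their bonded heavy atom, and each complete residue sums
#' exactly to its formal charge (0 for neutral amino acids, +1 ARG/LYS,
#' -1 ASP/GLU, -1 per nucleotide from the phosphate).
#'
#' @return data.frame with columns `resname`, `atom`, `charge`.
#' @export
amber_charge_table <- function() {
  if (!is.null(.charge_env$table)) return(.charge_env$table)
  rows <- list()
  for (aa in names(.AA_FORMAL)) {
    q_n <- if (aa == "PRO") -0.25 else -0.1438   # N+H folded (PRO has no H)
    fixed <- c(N = q_n, C = 0.5973, O = -0.5679, .SIDECHAIN_Q[[aa]])
    q_ca <- .AA_FORMAL[[aa]] - sum(fixed)
    q <- c(fixed, CA = q_ca)
    rows[[aa]] <- data.frame(resname = aa, atom = names(q),
                             charge = unname(q), stringsAsFactors = FALSE)
  }
  for (nt in names(.NT_FORMAL)) {
    fixed <- c(.NT_BACKBONE_Q, .BASE_Q[[nt]])
    q_c1 <- .NT_FORMAL[[nt]] - sum(fixed)
    q <- c(fixed, "C1'" = q_c1)
    rows[[nt]] <- data.frame(resname = nt, atom = names(q),
                             charge = unname(q), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  .charge_env$table <- tab
  tab
}
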