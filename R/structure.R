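#' @title Macromolecular structure container
#'
#' @description An `rpc_structure` holds one macromolecule (or complex) as a
#' flat atom table grouped into chains and residues. Columns: `serial`,
#' `name` (PDB atom name), `resname`, `chain` (single character), `resseq`
#' (author residue number), `icode` (insertion code, `""` if none), `x`,
#' `y`, `z` (Angstrom), `element`, `charge` (elementary charges, 0 until
#' [assign_charges()] is called).
#'
#' @param atoms data.frame with the columns listed above.
#' @param source character scalar, provenance label (usually a file name).
#' @return An object of class `rpc_structure`.
#' @keywords internal
new_structure <- function(atoms, source = "") {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "name", "resname", "chain", "resseq", "icode",
              "x", "y", "z", "element", "charge")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- atoms[needed]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "rpc_structure")
}

# Standard residue vocabularies -------------------------------------------

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
.STANDARD_NT <- c("A", "U", "G", "C")
.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")
.ION_NAMES <- c("NA", "CL", "K", "MG", "ZN", "MN", "FE", "CU", "CO", "NI",
                "CD", "BR", "IOD", "CS", "LI", "SR", "BA")

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

.PURINES <- c("A", "G")
.PYRIMIDINES <- c("U", "C")

# Small accessors ----------------------------------------------------------

#' Atom coordinates as an n x 3 matrix
#' @param s An `rpc_structure`.
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param s An `rpc_structure`.
#' @param xyz Numeric n x 3 matrix.
#' @return The structure with new coordinates.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

#' Number of atoms in a structure
#' @param s An `rpc_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Chain identifiers present in a structure
#' @param s An `rpc_structure`.
#' @return Character vector of chain IDs in order of first appearance.
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' Residue identity keys (chain|resseq|icode|resname), one per atom
#' @param atoms atom table of an `rpc_structure`.
#' @return Character vector, one key per atom row.
#' @keywords internal
residue_keys <- function(atoms) {
  paste(atoms$chain, atoms$resseq, atoms$icode, atoms$resname, sep = "|")
}

#' Per-residue atom index list, in file order
#' @param s An `rpc_structure`.
#' @return Named list of integer row indices, one entry per residue.
#' @keywords internal
residue_index <- function(s) {
  keys <- residue_keys(s$atoms)
  idx <- split(seq_len(nrow(s$atoms)), factor(keys, levels = unique(keys)))
  idx
}

#' Geometric centroid of all atoms
#' @param s An `rpc_structure`.
#' @return Length-3 numeric vector.
#' @export
centroid <- function(s) colMeans(coords(s))

#' @export
print.rpc_structure <- function(x, ...) {
  idx <- residue_index(x)
  cat(sprintf("rpc_structure: %d atoms, %d residues, chains [%s]%s\n",
              n_atoms(x), length(idx), paste(chain_ids(x), collapse = ""),
              if (nzchar(x$source)) paste0(" from ", x$source) else ""))
  invisible(x)
}

# Element inference from PDB atom names (no element column in old files)
.guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  first <- toupper(substr(nm, 1, 1))
  two <- toupper(substr(nm, 1, 2))
  el <- first
  el[two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA")] <-
    two[two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA")]
  el[first == "" | is.na(first)] <- "C"
  el
}

# Reading and writing PDB files -------------------------------------------

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records into an [new_structure()] atom table. Only the
#' first MODEL is kept; alternate locations are resolved to the highest
#' occupancy (ties go to altloc 'A' or blank); HETATM waters and monoatomic
#' ions are dropped; residues that are neither standard amino acids nor
#' standard ribonucleotides are dropped with a warning.
#'
#' @param path Path to a PDB file.
#' @param drop_nonstandard Drop non-standard residues (default `TRUE`).
#' @return An `rpc_structure`.
#' @export
read_pdb <- function(path, drop_nonstandard = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("no ATOM records parsed from ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM records in ", path)

  # first MODEL only: bio3d with multi = FALSE already keeps model 1
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1

  # resolve alternate locations per (residue, atom name): highest occupancy,
  # ties in favor of '' then 'A' then alphabetical
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
    pref <- match(at$alt, c("", "A", sort(unique(at$alt))))
    ord <- order(key, -at$o, pref)
    at <- at[ord[!duplicated(key[ord])], ]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }

  # drop HETATM solvent and ions; other HETATM kept only if standard residue
  is_het <- at$type == "HETATM"
  drop <- is_het & (at$resid %in% c(.WATER_NAMES, .ION_NAMES))
  at <- at[!drop, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)

  res_std <- at$resid %in% c(.STANDARD_AA, .STANDARD_NT)
  if (drop_nonstandard && any(!res_std)) {
    bad <- unique(at$resid[!res_std])
    warning("dropping non-standard residue(s) in ", basename(path), ": ",
            paste(bad, collapse = ", "))
    at <- at[res_std, , drop = FALSE]
    if (nrow(at) == 0) stop("no standard residues in ", path)
  }

  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem[is.na(elem) | elem == ""] <- .guess_element(at$elety[is.na(elem) | elem == ""])

  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = at$elety,
    resname = at$resid,
    chain = at$chain,
    resseq = as.integer(at$resno),
    icode = at$insert,
    x = at$x, y = at$y, z = at$z,
    element = toupper(elem),
    charge = 0,
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  new_structure(atoms, source = basename(path))
}

#' Write a structure to a PDB file
#'
#' Emits standard 80-column ATOM records (3-decimal coordinates) via bio3d.
#'
#' @param s An `rpc_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resseq, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = a$chain, insert = a$icode,
    o = rep(1, nrow(a)), b = rep(0, nrow(a)),
    elesy = a$element))
  invisible(path)
}

#' Select chains from a structure
#'
#' `chain_ids` is a string of concatenated single-character chain
#' identifiers, e.g. `"CB"` selects chains C and B, in that order.
#' Matching is case-sensitive.
#'
#' @param s An `rpc_structure`.
#' @param chain_ids Character scalar of concatenated chain IDs.
#' @return An `rpc_structure` with exactly the requested chains, in request
#'   order. The input is never modified.
#' @export
select_chains <- function(s, chain_ids) {
  stopifnot(is.character(chain_ids), length(chain_ids) == 1, nzchar(chain_ids))
  wanted <- strsplit(chain_ids, "")[[1]]
  have <- chain_ids(s)
  absent <- setdiff(wanted, have)
  if (length(absent) > 0) {
    stop("chain ", paste(absent, collapse = ", "), " not found in ",
         if (nzchar(s$source)) s$source else "structure")
  }
  parts <- lapply(wanted, function(ch) s$atoms[s$atoms$chain == ch, , drop = FALSE])
  new_structure(do.call(rbind, parts), source = s$source)
}

#' Classify a structure as protein, RNA or mixed
#'
#' A structure is `"protein"` if at least 90% of its residues carry standard
#' amino-acid names, `"rna"` if at least 90% carry standard ribonucleotide
#' names, otherwise `"mixed"`.
#'
#' @param s An `rpc_structure`.
#' @return One of `"protein"`, `"rna"`, `"mixed"`.
#' @export
classify_molecule <- function(s) {
  idx <- residue_index(s)
  if (length(idx) == 0) stop("empty structure")
  resnames <- vapply(idx, function(i) s$atoms$resname[i[1]], character(1))
  f_aa <- mean(resnames %in% .STANDARD_AA)
  f_nt <- mean(resnames %in% .STANDARD_NT)
  if (f_aa >= 0.9) "protein" else if (f_nt >= 0.9) "rna" else "mixed"
}

#' Molecule type of each chain
#' @param s An `rpc_structure`.
#' @return Named character vector (chain ID -> protein/rna/mixed).
#' @export
chain_moltypes <- function(s) {
  ids <- chain_ids(s)
  vapply(ids, function(ch) classify_molecule(select_chains(s, ch)),
         character(1))
}

#' Assign partial charges from a charge table
#'
#' Looks each atom up by `(resname, atom name)` in `table` (default: the
#' embedded united-atom AMBER-style table, [amber_charge_table()]). Atoms
#' absent from the table get charge 0 and are counted; the miss count is
#' attached as attribute `"charge_misses"` and reported with a message.
#' Coordinates are untouched.
#'
#' @param s An `rpc_structure`.
#' @param table A charge table data.frame (`resname`, `atom`, `charge`).
#' @param quiet Suppress the miss-count message.
#' @return The structure with the `charge` column filled in.
#' @export
assign_charges <- function(s, table = amber_charge_table(), quiet = FALSE) {
  nm <- normalize_atom_name(s$atoms$name)
  key <- paste(s$atoms$resname, nm, sep = "|")
  tkey <- paste(table$resname, table$atom, sep = "|")
  hit <- match(key, tkey)
  q <- table$charge[hit]
  misses <- sum(is.na(q))
  q[is.na(q)] <- 0
  s$atoms$charge <- q
  attr(s, "charge_misses") <- misses
  if (!quiet && misses > 0) {
    message(misses, " atom(s) missing from charge table; assigned 0")
  }
  s
}

#' Canonicalize PDB atom names (primes vs asterisks, phosphate oxygens)
#' @param name Character vector of atom names.
#' @return Normalized names.
#' @keywords internal
normalize_atom_name <- function(name) {
  nm <- gsub("*", "'", name, fixed = TRUE)
  nm[nm == "O1P"] <- "OP1"
  nm[nm == "O2P"] <- "OP2"
  nm
}

#' Combine two structures into one complex
#'
#' Chain IDs colliding with the first structure are remapped to unused IDs
#' (reported with a message).
#'
#' @param a,b `rpc_structure` objects.
#' @return A combined `rpc_structure`.
#' @export
combine_structures <- function(a, b) {
  taken <- chain_ids(a)
  bids <- chain_ids(b)
  clash <- intersect(bids, taken)
  if (length(clash) > 0) {
    pool <- setdiff(c(LETTERS, letters, as.character(0:9)), c(taken, bids))
    if (length(pool) < length(clash)) stop("no free chain IDs for remapping")
    remap <- stats::setNames(pool[seq_along(clash)], clash)
    message("remapping ligand chain ID(s): ",
            paste(clash, "->", remap, collapse = ", "))
    hit <- b$atoms$chain %in% clash
    b$atoms$chain[hit] <- remap[b$atoms$chain[hit]]
  }
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, source = paste(a$source, b$source, sep = "+"))
}
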