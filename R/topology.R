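# Format-independent topology model: residues, atoms, bonds.
# The 1-based serial residue index is the only identity key everywhere;
# resSeq (the author-assigned number) may repeat or jump and is display-only.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "MSE",
          "CYX", "ASH", "GLH", "LYN")

.AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", HSD = "H", HSE = "H", HSP = "H", HID = "H",
          HIE = "H", HIP = "H", MSE = "M", CYX = "C", ASH = "D", GLH = "E",
          LYN = "K")

.WATER_NAMES <- c("HOH", "WAT", "TIP", "TIP3", "TIP4", "TIP5", "SOL",
                  "SPC", "SPCE", "H2O")

.ION_NAMES <- c("NA", "CL", "SOD", "CLA", "K", "POT", "MG", "ZN", "CAL",
                "LI", "CS", "RB", "BR", "F", "IOD", "NA+", "CL-", "K+",
                "MG2", "ZN2", "CA2")

.NUC_NAMES <- c("A", "U", "G", "C", "DA", "DT", "DG", "DC",
                "ADE", "GUA", "CYT", "THY", "URA", "RA", "RU", "RG", "RC")

# Standard atomic masses (u); used by the center-of-mass distance scheme.
.ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, Na = 22.990, Cl = 35.45,
                     K = 39.098, Mg = 24.305, Zn = 65.38, Ca = 40.078,
                     Fe = 55.845, Se = 78.971, F = 18.998, Br = 79.904,
                     I = 126.904, Li = 6.94, Cs = 132.905)

.ION_ELEMENTS <- c("NA" = "Na", "SOD" = "Na", "NA+" = "Na",
                   "CL" = "Cl", "CLA" = "Cl", "CL-" = "Cl",
                   "K" = "K", "POT" = "K", "K+" = "K",
                   "MG" = "Mg", "MG2" = "Mg", "ZN" = "Zn", "ZN2" = "Zn",
                   "CAL" = "Ca", "CA2" = "Ca", "LI" = "Li", "CS" = "Cs",
                   "BR" = "Br", "F" = "F", "IOD" = "I")

#' Guess an element symbol from an atom name
#'
#' Used when the file format carries no element column (GRO, minimal PDB).
#' Leading digits are stripped ("1HB" is a hydrogen); monoatomic ion residues
#' resolve through a name table so that e.g. atom "NA" in residue "NA" is
#' sodium, not nitrogen.
#'
#' @param name atom name string.
#' @param resname residue name the atom belongs to.
#' @return one-element character vector, e.g. `"C"`, `"Na"`.
#' @keywords internal
guess_element <- function(name, resname = "") {
  nm <- toupper(gsub("[^A-Za-z]", "", sub("^[0-9]+", "", name)))
  rn <- toupper(resname)
  if (rn %in% names(.ION_ELEMENTS) && nzchar(nm)) {
    return(unname(.ION_ELEMENTS[[rn]]))
  }
  if (!nzchar(nm)) return("X")
  first <- substr(nm, 1, 1)
  if (first == "H") return("H")
  two <- substr(nm, 1, 2)
  # two-letter elements that actually occur in biomolecular files
  two_map <- c(SE = "Se", FE = "Fe", MG = "Mg", ZN = "Zn", BR = "Br",
               LI = "Li", CS = "Cs")
  if (two %in% names(two_map)) return(unname(two_map[[two]]))
  first
}

#' Classify a residue name into a molecule class
#'
#' @param name residue name (3-letter or ligand code).
#' @param n_heavy number of heavy atoms in the residue; a single-heavy-atom
#'   residue outside all tables is treated as an ion.
#' @return one of `"protein"`, `"water"`, `"ion"`, `"nucleic"`, `"ligand"`,
#'   `"unknown"`.
#' @keywords internal
molecule_class_of <- function(name, n_heavy = NA_integer_) {
  nm <- toupper(name)
  if (nm %in% .AA3) return("protein")
  if (nm %in% .WATER_NAMES) return("water")
  if (nm %in% .ION_NAMES) return("ion")
  if (nm %in% .NUC_NAMES) return("nucleic")
  if (!is.na(n_heavy) && n_heavy == 1L) return("ion")
  if (nzchar(nm)) return("ligand")
  "unknown"
}

#' Construct a Topology
#'
#' @param atoms data.frame with columns `name`, `element`, `residue`
#'   (1-based residue index). `is_heavy` is derived from `element`.
#' @param residues data.frame with columns `name`, `resSeq`, `chain`
#'   (`NA` when the format has no chain field, e.g. GRO).
#' @param bonds integer matrix with two columns of 1-based atom indices
#'   (unordered pairs), or `NULL`.
#' @return object of class `Topology`.
#' @export
new_topology <- function(atoms, residues, bonds = NULL) {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  if (nrow(atoms) == 0L) stop("empty topology: no atoms")
  atoms$index <- seq_len(nrow(atoms))
  atoms$is_heavy <- atoms$element != "H"
  residues$index <- seq_len(nrow(residues))
  if (is.null(residues$chain)) residues$chain <- NA_character_
  if (!all(atoms$residue %in% residues$index)) {
    stop("atom references a residue index outside the topology")
  }
  # derived per-residue info
  n_heavy <- vapply(residues$index, function(i) {
    sum(atoms$is_heavy[atoms$residue == i])
  }, integer(1))
  residues$molecule_class <- mapply(molecule_class_of, residues$name, n_heavy)
  if (is.null(bonds)) {
    bonds <- matrix(integer(0), ncol = 2)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) &&
        (max(bonds) > nrow(atoms) || min(bonds) < 1L)) {
      stop("bond references an atom index outside the topology")
    }
    bonds <- t(apply(bonds, 1L, sort))
    bonds <- unique(bonds)
  }
  structure(list(atoms = atoms, residues = residues, bonds = bonds),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d residues, %d atoms, %d bonds\n",
              nrow(x$residues), nrow(x$atoms), nrow(x$bonds)))
  cls <- table(x$residues$molecule_class)
  cat("  ", paste(sprintf("%s: %d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' Number of residues / atoms in a Topology
#' @param topology a [Topology].
#' @return integer count.
#' @export
n_residues <- function(topology) nrow(topology$residues)

#' @rdname n_residues
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Atom indices belonging to a residue
#' @param topology a [Topology].
#' @param res_index 1-based residue index.
#' @param heavy_only drop hydrogens.
#' @return integer vector of atom indices.
#' @export
residue_atoms <- function(topology, res_index, heavy_only = FALSE) {
  idx <- which(topology$atoms$residue == res_index)
  if (heavy_only) idx <- idx[topology$atoms$is_heavy[idx]]
  idx
}

# Protein backbone heavy-atom names. Hydrogens bound to these are backbone too.
.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
# name-based fallback for hydrogens when no bonds are available
.BACKBONE_H_RE <- "^(H|H[123]|HN|HT[123]|HA|HA[123]|HXT)$"

#' Classify atoms of a topology as backbone or sidechain
#'
#' Protein residues: backbone is N, CA, C, O, OXT plus their bound hydrogens;
#' everything else is sidechain. Non-protein residues (ligands, ions, waters,
#' nucleic acids) are entirely sidechain, so ligand contacts report as
#' sidechain interactions. The classification is total: every atom falls in
#' exactly one of the two classes.
#'
#' @param topology a [Topology].
#' @return character vector (`"BB"` / `"SC"`), one entry per atom.
#' @export
atom_classes <- function(topology) {
  at <- topology$atoms
  res <- topology$residues
  cls <- rep("SC", nrow(at))
  prot <- res$molecule_class[at$residue] == "protein"
  bb_heavy <- prot & at$is_heavy & toupper(at$name) %in% .BACKBONE_NAMES
  cls[bb_heavy] <- "BB"
  hyd <- prot & !at$is_heavy
  if (any(hyd)) {
    if (nrow(topology$bonds)) {
      bmat <- topology$bonds
      partner <- rep(NA_integer_, nrow(at))
      # hydrogens have exactly one bond partner; take the first listed
      h_idx <- which(hyd)
      for (k in seq_len(nrow(bmat))) {
        i <- bmat[k, 1L]; j <- bmat[k, 2L]
        if (is.na(partner[i]) && hyd[i]) partner[i] <- j
        if (is.na(partner[j]) && hyd[j]) partner[j] <- i
      }
      known <- h_idx[!is.na(partner[h_idx])]
      cls[known] <- ifelse(bb_heavy[partner[known]], "BB", "SC")
      unknown <- h_idx[is.na(partner[h_idx])]
      cls[unknown] <- ifelse(
        grepl(.BACKBONE_H_RE, toupper(at$name[unknown])), "BB", "SC")
    } else {
      cls[hyd] <- ifelse(grepl(.BACKBONE_H_RE, toupper(at$name[hyd])),
                         "BB", "SC")
    }
  }
  cls
}

#' Classify one atom as backbone or sidechain
#'
#' @param topology a [Topology].
#' @param atom_index 1-based atom index.
#' @return `"backbone"` or `"sidechain"`.
#' @export
classify_atom <- function(topology, atom_index) {
  stopifnot(atom_index >= 1L, atom_index <= n_atoms(topology))
  c(BB = "backbone", SC = "sidechain")[[atom_classes(topology)[atom_index]]]
}

#' One-letter code of a residue name
#' @param name residue name(s).
#' @return one-letter code, `"X"` for non-standard names.
#' @export
aa_one <- function(name) {
  out <- .AA1[toupper(name)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Compact display name of a residue
#'
#' Protein residues render as one-letter code + resSeq (`"L394"`); other
#' residues keep their code (`"GDP395"`).
#'
#' @param topology a [Topology].
#' @param res_index residue index (vectorized).
#' @param short use one-letter codes for protein residues.
#' @return character vector.
#' @export
residue_display <- function(topology, res_index, short = TRUE) {
  r <- topology$residues[res_index, , drop = FALSE]
  ifelse(short & r$molecule_class == "protein",
         paste0(aa_one(r$name), r$resSeq),
         paste0(r$name, r$resSeq))
}

#' Residue-level bond graph components
#'
#' Two residues are connected when any bond joins their atoms. Components are
#' the basis of the `bonds` fragmentation heuristic and of the detachment of
#' free molecules (ligands, ions, waters) under the `default` heuristic.
#'
#' @param topology a [Topology].
#' @return integer vector: component id per residue (ids ordered by smallest
#'   member residue).
#' @export
residue_bond_components <- function(topology) {
  n <- n_residues(topology)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(topology$bonds)) {
    ra <- topology$atoms$residue[topology$bonds[, 1L]]
    rb <- topology$atoms$residue[topology$bonds[, 2L]]
    keep <- ra != rb
    for (k in which(keep)) {
      i <- find(ra[k]); j <- find(rb[k])
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}
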