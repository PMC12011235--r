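# PDB reading/writing. Multi-model files are accepted as trajectories
# (MODEL/ENDMDL blocks); coordinates are converted to nanometres internally
# and written back in Angstrom, the PDB unit.

.parse_pdb_float <- function(s, lineno, path) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v))) {
    stop(sprintf("parse error in '%s' at line %d: bad numeric field '%s'",
                 path, lineno[which(is.na(v))[1L]], s[which(is.na(v))[1L]]))
  }
  v
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records, CONECT bonds and CRYST1 box. Residue boundaries
#' are detected from changes in (chain, resSeq, insertion code, residue name)
#' and, in addition, from a repeated atom name, so two residues sharing the
#' same author number are kept distinct. Bonds are the union of CONECT records
#' and a geometric inference on the first model (covalent-range atom pairs
#' within a residue plus the peptide C-N link between consecutive residues).
#'
#' @param path PDB file.
#' @return list with `topology` ([Topology]), `xyz` (frames x atoms x 3 array,
#'   nm), `box` (length-3 nm vector or `NULL`) and `bfactors` (per atom, first
#'   model).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop(sprintf("empty topology: no ATOM records in %s", path))

  box <- NULL
  cry <- which(startsWith(rec, "CRYST1"))
  if (length(cry)) {
    l <- lines[cry[1L]]
    abc <- .parse_pdb_float(c(substr(l, 7, 15), substr(l, 16, 24),
                              substr(l, 25, 33)), rep(cry[1L], 3L), path)
    if (all(abc > 1.0)) box <- abc / 10  # skip the 1x1x1 placeholder cell
  }

  # split atom lines into models
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  atom_rows <- which(is_atom)
  mid <- model_id[atom_rows]
  if (any(is_model) && any(mid == 0L)) mid[mid == 0L] <- 1L
  models <- split(atom_rows, mid)
  first <- models[[1L]]
  n_at <- length(first)
  for (m in seq_along(models)) {
    if (length(models[[m]]) != n_at) {
      stop(sprintf("model %d in '%s' has %d atoms, expected %d",
                   m, path, length(models[[m]]), n_at))
    }
  }

  l1 <- lines[first]
  serial <- suppressWarnings(as.integer(substr(l1, 7, 11)))
  name <- trimws(substr(l1, 13, 16))
  resname <- trimws(substr(l1, 18, 20))
  chain <- substr(l1, 22, 22)
  resseq <- suppressWarnings(as.integer(substr(l1, 23, 26)))
  icode <- substr(l1, 27, 27)
  if (any(is.na(resseq))) {
    stop(sprintf("parse error in '%s' at line %d: bad resSeq field",
                 path, first[which(is.na(resseq))[1L]]))
  }
  element <- trimws(substr(l1, 77, 78))
  element <- ifelse(nzchar(element),
                    paste0(toupper(substr(element, 1, 1)),
                           tolower(substr(element, 2, 2))),
                    mapply(guess_element, name, resname))
  bfactors <- suppressWarnings(as.numeric(substr(l1, 61, 66)))
  bfactors[is.na(bfactors)] <- 0

  # residue boundaries: key change, or an atom name repeating inside a residue
  key <- paste(chain, resseq, icode, resname, sep = "\r")
  res_id <- integer(n_at)
  cur <- 0L
  seen <- character(0)
  for (k in seq_len(n_at)) {
    if (k == 1L || key[k] != key[k - 1L] || name[k] %in% seen) {
      cur <- cur + 1L
      seen <- character(0)
    }
    seen <- c(seen, name[k])
    res_id[k] <- cur
  }
  ridx <- !duplicated(res_id)
  residues <- data.frame(
    name = resname[ridx], resSeq = resseq[ridx],
    chain = ifelse(chain[ridx] == " ", NA_character_, chain[ridx]),
    stringsAsFactors = FALSE)
  atoms <- data.frame(name = name, element = element, residue = res_id,
                      stringsAsFactors = FALSE)

  # coordinates, all models
  nF <- length(models)
  xyz <- array(NA_real_, c(nF, n_at, 3L))
  for (m in seq_len(nF)) {
    lm <- lines[models[[m]]]
    xyz[m, , 1L] <- .parse_pdb_float(substr(lm, 31, 38), models[[m]], path)
    xyz[m, , 2L] <- .parse_pdb_float(substr(lm, 39, 46), models[[m]], path)
    xyz[m, , 3L] <- .parse_pdb_float(substr(lm, 47, 54), models[[m]], path)
  }
  xyz <- xyz / 10  # Angstrom -> nm

  # CONECT bonds (serial -> atom index of first model)
  bonds <- NULL
  con <- which(startsWith(rec, "CONECT"))
  if (length(con)) {
    ser_map <- setNames(seq_len(n_at), serial)
    bl <- list()
    for (k in con) {
      l <- lines[k]
      flds <- suppressWarnings(as.integer(
        substring(l, seq(7, 27, by = 5), seq(11, 31, by = 5))))
      flds <- flds[!is.na(flds)]
      if (length(flds) >= 2L) {
        a <- ser_map[as.character(flds[1L])]
        b <- ser_map[as.character(flds[-1L])]
        ok <- !is.na(a) & !is.na(b)
        if (any(ok)) bl[[length(bl) + 1L]] <- cbind(a, b[ok])
      }
    }
    if (length(bl)) bonds <- do.call(rbind, bl)
  }
  top0 <- new_topology(atoms, residues, bonds)
  geo <- infer_bonds(top0, xyz[1L, , ])
  top <- new_topology(atoms, residues, rbind(top0$bonds, geo))
  list(topology = top, xyz = xyz, box = box, bfactors = bfactors)
}

#' Infer covalent bonds from geometry
#'
#' Template-style inference used for formats without connectivity (GRO) and to
#' complete PDB files without CONECT records: within a residue, atom pairs at
#' covalent range are bonded (< 1.9 A heavy-heavy, < 1.25 A involving
#' hydrogen); between consecutive residues, the peptide C-N bond is added when
#' the distance is below 2.0 A and both residues are protein.
#'
#' @param topology a [Topology].
#' @param frame_xyz atoms x 3 matrix (nm) of the first frame.
#' @return integer bond matrix (two columns).
#' @export
infer_bonds <- function(topology, frame_xyz) {
  at <- topology$atoms
  res <- topology$residues
  out <- list()
  for (r in res$index) {
    idx <- which(at$residue == r)
    if (length(idx) < 2L) next
    d <- as.matrix(stats::dist(frame_xyz[idx, , drop = FALSE]))
    hyd <- !at$is_heavy[idx]
    thr <- outer(hyd, hyd, "|")
    lim <- ifelse(thr, 0.125, 0.19)
    hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) {
      # never bond two hydrogens
      keep <- !(hyd[hit[, 1L]] & hyd[hit[, 2L]])
      hit <- hit[keep, , drop = FALSE]
      if (nrow(hit)) out[[length(out) + 1L]] <-
          cbind(idx[hit[, 1L]], idx[hit[, 2L]])
    }
  }
  # peptide bonds between consecutive protein residues
  n <- nrow(res)
  if (n > 1L) {
    for (r in seq_len(n - 1L)) {
      if (res$molecule_class[r] != "protein" ||
          res$molecule_class[r + 1L] != "protein") next
      ci <- which(at$residue == r & toupper(at$name) == "C")
      ni <- which(at$residue == r + 1L & toupper(at$name) == "N")
      if (length(ci) == 1L && length(ni) == 1L) {
        d <- sqrt(sum((frame_xyz[ci, ] - frame_xyz[ni, ])^2))
        if (d < 0.20) out[[length(out) + 1L]] <- cbind(ci, ni)
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

.fmt_pdb_name <- function(name, element) {
  if (nchar(name) >= 4L) return(substr(name, 1, 4))
  if (nchar(element) == 2L) return(sprintf("%-4s", name))
  sprintf(" %-3s", name)
}

#' Write a Topology (optionally multi-frame) as PDB
#'
#' Coordinates are written in Angstrom; frames beyond the first produce
#' MODEL/ENDMDL blocks. Inter-residue bonds other than the peptide link are
#' emitted as CONECT records so that a read-back reconstructs the bond graph.
#'
#' @param topology a [Topology].
#' @param xyz frames x atoms x 3 array (nm), or atoms x 3 matrix for a single
#'   frame.
#' @param path output file.
#' @param bfactors per-atom numeric vector for the bfactor column (clipped to
#'   the column range -999.99..999.99); default 0.
#' @param occupancy per-atom occupancy; default 1.
#' @param box optional length-3 box (nm) written as CRYST1.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(topology, xyz, path, bfactors = NULL, occupancy = NULL,
                      box = NULL) {
  at <- topology$atoms
  res <- topology$residues
  if (is.matrix(xyz)) xyz <- array(xyz, c(1L, nrow(xyz), ncol(xyz)))
  stopifnot(dim(xyz)[2L] == nrow(at))
  if (is.null(bfactors)) bfactors <- rep(0, nrow(at))
  if (is.null(occupancy)) occupancy <- rep(1, nrow(at))
  bfactors <- pmin(pmax(bfactors, -999.99), 999.99)

  chain <- res$chain[at$residue]
  chain[is.na(chain)] <- " "
  rec <- ifelse(res$molecule_class[at$residue] == "protein",
                "ATOM  ", "HETATM")
  names4 <- mapply(.fmt_pdb_name, at$name, at$element)
  el2 <- sprintf("%2s", toupper(substr(at$element, 1, 2)))

  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90), con)
  }
  nF <- dim(xyz)[1L]
  for (f in seq_len(nF)) {
    if (nF > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %s",
      rec, at$index %% 100000L, names4, substr(res$name[at$residue], 1, 3),
      chain, res$resSeq[at$residue] %% 10000L,
      xyz[f, , 1L] * 10, xyz[f, , 2L] * 10, xyz[f, , 3L] * 10,
      occupancy, bfactors, el2), con)
    if (nF > 1L) writeLines("ENDMDL", con)
  }
  if (nrow(topology$bonds)) {
    ra <- at$residue[topology$bonds[, 1L]]
    rb <- at$residue[topology$bonds[, 2L]]
    inter <- topology$bonds[ra != rb, , drop = FALSE]
    if (nrow(inter)) {
      writeLines(c(sprintf("CONECT%5d%5d", inter[, 1L], inter[, 2L]),
                   sprintf("CONECT%5d%5d", inter[, 2L], inter[, 1L])), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Load a topology from a PDB or GRO file
#'
#' The format is inferred from the extension. For GRO files (no chain field,
#' no connectivity) bonds are inferred from covalent-range geometry plus the
#' peptide C-N criterion, and chain hints are absent.
#'
#' @param path topology file (.pdb or .gro).
#' @return a [Topology].
#' @export
load_topology <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") return(read_pdb(path)$topology)
  if (ext == "gro") return(read_gro(path)$topology)
  stop(sprintf("unsupported topology format '.%s' (expected .pdb or .gro)",
               ext))
}
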