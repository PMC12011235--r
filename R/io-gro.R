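# GRO reading (and writing, used by the fixture generator). The format has no
# chain field and no connectivity: chain hints are absent and bonds are
# inferred from frame-0 geometry (see infer_bonds). Multiple concatenated
# frames in one file are read as a multi-frame block.

#' Read a GRO file
#'
#' @param path GRO file; concatenated frames sharing the atom count are read
#'   as one trajectory block.
#' @return list with `topology` ([Topology], chain hints absent), `xyz`
#'   (frames x atoms x 3, nm) and `box` (length-3 nm vector or `NULL`).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  boxes <- list()
  pos <- 1L
  meta <- NULL
  while (pos + 1L <= length(lines)) {
    n_at <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(n_at) || n_at < 1L) {
      stop(sprintf("parse error in '%s' at line %d: bad atom count",
                   path, pos + 1L))
    }
    if (pos + 1L + n_at + 1L > length(lines)) {
      stop(sprintf("parse error in '%s': truncated frame at line %d",
                   path, pos))
    }
    al <- lines[pos + 1L + seq_len(n_at)]
    resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
    resname <- trimws(substr(al, 6, 10))
    aname <- trimws(substr(al, 11, 15))
    x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
    if (any(is.na(x) | is.na(y) | is.na(z) | is.na(resid))) {
      bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))[1L]
      stop(sprintf("parse error in '%s' at line %d", path, pos + 1L + bad))
    }
    if (is.null(meta)) {
      meta <- list(resid = resid, resname = resname, aname = aname)
    } else if (length(aname) != length(meta$aname)) {
      stop(sprintf("frame at line %d of '%s' has %d atoms, expected %d",
                   pos, path, length(aname), length(meta$aname)))
    }
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    bx <- suppressWarnings(as.numeric(strsplit(
      trimws(lines[pos + 2L + n_at]), "\\s+")[[1L]]))
    boxes[[length(boxes) + 1L]] <- bx
    pos <- pos + n_at + 3L
    if (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }

  # residue boundaries: resid change or repeated atom name
  resid <- meta$resid
  n_at <- length(resid)
  key <- paste(resid, meta$resname, sep = "\r")
  res_id <- integer(n_at)
  cur <- 0L
  seen <- character(0)
  for (k in seq_len(n_at)) {
    if (k == 1L || key[k] != key[k - 1L] || meta$aname[k] %in% seen) {
      cur <- cur + 1L
      seen <- character(0)
    }
    seen <- c(seen, meta$aname[k])
    res_id[k] <- cur
  }
  ridx <- !duplicated(res_id)
  residues <- data.frame(name = meta$resname[ridx], resSeq = resid[ridx],
                         chain = NA_character_, stringsAsFactors = FALSE)
  atoms <- data.frame(
    name = meta$aname,
    element = mapply(guess_element, meta$aname, meta$resname[res_id]),
    residue = res_id, stringsAsFactors = FALSE)

  nF <- length(frames)
  xyz <- array(NA_real_, c(nF, n_at, 3L))
  for (f in seq_len(nF)) xyz[f, , ] <- frames[[f]]

  top0 <- new_topology(atoms, residues)
  top <- new_topology(atoms, residues, infer_bonds(top0, xyz[1L, , ]))
  bx <- boxes[[1L]]
  box <- if (length(bx) >= 3L && all(bx[1:3] > 0)) bx[1:3] else NULL
  list(topology = top, xyz = xyz, box = box)
}

#' Write a single frame as GRO
#'
#' @param topology a [Topology].
#' @param xyz atoms x 3 matrix (nm) or frames x atoms x 3 array (all frames
#'   are written concatenated).
#' @param path output file.
#' @param box length-3 box vector in nm (GRO requires one; defaults to the
#'   coordinate extent plus 2 nm).
#' @param title first line of each frame block.
#' @return `path`, invisibly.
#' @export
write_gro <- function(topology, xyz, path, box = NULL, title = "contactlens") {
  at <- topology$atoms
  res <- topology$residues
  if (is.matrix(xyz)) xyz <- array(xyz, c(1L, nrow(xyz), ncol(xyz)))
  stopifnot(dim(xyz)[2L] == nrow(at))
  if (is.null(box)) box <- apply(xyz, 3L, max) - pmin(0, apply(xyz, 3L, min)) + 2
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(xyz)[1L])) {
    writeLines(title, con)
    writeLines(sprintf("%5d", nrow(at)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       res$resSeq[at$residue] %% 100000L,
                       substr(res$name[at$residue], 1, 5),
                       substr(at$name, 1, 5),
                       at$index %% 100000L,
                       xyz[f, , 1L], xyz[f, , 2L], xyz[f, , 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}
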