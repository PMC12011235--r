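# Single-file ContactGroup archive: a JSON header (topology, fragmentation,
# labels, metadata, block shapes) followed by raw little-endian numeric
# blocks (distances as float64, argmin atom pairs as int32). Self-described
# and versioned; paths are stored as metadata only, so archives move across
# machines. The in-memory ensemble coordinates are not archived: everything
# frequency-related is reproducible from the stored distances.

.CLGRP_MAGIC <- "CLGRP1"

#' Serialize a ContactGroup to a single file
#'
#' @param group a `ContactGroup`.
#' @param path output file (conventional extension: `.clgrp`).
#' @return `path`, invisibly.
#' @export
serialize_group <- function(group, path) {
  stopifnot(inherits(group, "ContactGroup"))
  top <- group$topology
  P <- nrow(group$pairs)
  nT <- length(group$n_frames)
  has_atoms <- P > 0L && !is.null(group$atoms[[1L]][[1L]])
  header <- list(
    version = 1L,
    scheme = group$scheme,
    n_frames = as.integer(group$n_frames),
    files = group$files,
    cutoff = group$cutoff,
    n_nearest = group$n_nearest,
    pairs = list(a = group$pairs$a, b = group$pairs$b),
    has_atoms = has_atoms,
    topology = list(
      atoms = list(name = top$atoms$name, element = top$atoms$element,
                   residue = top$atoms$residue),
      residues = list(name = top$residues$name, resSeq = top$residues$resSeq,
                      chain = top$residues$chain),
      bonds = if (nrow(top$bonds)) list(a = top$bonds[, 1L],
                                        b = top$bonds[, 2L]) else NULL),
    fragmentation = list(method = group$fragmentation$method,
                         names = names(group$fragmentation$fragments),
                         fragments = unname(group$fragmentation$fragments)),
    assignments = if (!is.null(group$assignments)) {
      lapply(group$assignments, function(a) {
        list(scheme = a$scheme,
             res_index = a$table$res_index, label = a$table$label,
             fragment = a$table$fragment, ref_pos = a$table$ref_pos)
      })
    },
    interface_split = group$interface_split,
    anchors = group$anchors)
  hdr <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                                    null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.CLGRP_MAGIC), con)
  writeBin(length(hdr), con, size = 4L, endian = "little")
  writeBin(hdr, con)
  for (p in seq_len(P)) {
    for (tr in seq_len(nT)) {
      writeBin(group$dist[[p]][[tr]], con, size = 8L, endian = "little")
    }
  }
  if (has_atoms) {
    for (p in seq_len(P)) {
      for (tr in seq_len(nT)) {
        writeBin(as.integer(t(group$atoms[[p]][[tr]])), con, size = 4L,
                 endian = "little")
      }
    }
  }
  invisible(path)
}

#' Load a ContactGroup archive
#'
#' Restores distances, labels and metadata bit-exactly. The coordinate
#' ensemble itself is not part of the archive, so operations that need frames
#' (representative-frame PDB export) require re-attaching an ensemble.
#'
#' @param path archive written by [serialize_group()].
#' @return a `ContactGroup`.
#' @export
deserialize_group <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(.CLGRP_MAGIC)))
  if (!identical(magic, .CLGRP_MAGIC)) {
    stop(sprintf(
      "'%s' is not a contactlens group archive (or an incompatible version: found '%s', expected '%s')",
      path, magic, .CLGRP_MAGIC))
  }
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(hlen) || is.na(hlen) || hlen <= 0L) {
    stop(sprintf("integrity error: truncated header in '%s'", path))
  }
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) < hlen) {
    stop(sprintf("integrity error: truncated header in '%s'", path))
  }
  h <- jsonlite::fromJSON(rawToChar(hraw), simplifyVector = TRUE)
  if (!identical(as.integer(h$version), 1L)) {
    stop(sprintf("incompatible archive version %s in '%s'", h$version, path))
  }
  atoms <- data.frame(name = h$topology$atoms$name,
                      element = h$topology$atoms$element,
                      residue = h$topology$atoms$residue,
                      stringsAsFactors = FALSE)
  chain <- h$topology$residues$chain
  if (is.null(chain)) chain <- NA_character_
  residues <- data.frame(name = h$topology$residues$name,
                         resSeq = h$topology$residues$resSeq,
                         chain = chain, stringsAsFactors = FALSE)
  bonds <- if (!is.null(h$topology$bonds)) {
    cbind(h$topology$bonds$a, h$topology$bonds$b)
  }
  top <- new_topology(atoms, residues, bonds)
  frags <- h$fragmentation$fragments
  if (is.matrix(frags)) frags <- lapply(seq_len(nrow(frags)), function(i) frags[i, ])
  fragmentation <- structure(
    list(method = h$fragmentation$method,
         fragments = setNames(lapply(frags, as.integer),
                              h$fragmentation$names)),
    class = "Fragmentation")
  assignments <- NULL
  if (!is.null(h$assignments)) {
    assignments <- lapply(h$assignments, function(a) {
      structure(list(scheme = a$scheme,
                     table = data.frame(res_index = a$res_index,
                                        label = a$label,
                                        fragment = a$fragment,
                                        ref_pos = a$ref_pos,
                                        stringsAsFactors = FALSE),
                     unmapped = integer(0), alignment = NULL,
                     identity = NA_real_),
                class = "LabelAssignment")
    })
  }
  P <- length(h$pairs$a)
  nT <- length(h$n_frames)
  dist <- vector("list", P)
  atoms_l <- vector("list", P)
  for (p in seq_len(P)) {
    dtr <- vector("list", nT)
    for (tr in seq_len(nT)) {
      v <- readBin(con, "double", h$n_frames[tr], size = 8L,
                   endian = "little")
      if (length(v) < h$n_frames[tr]) {
        stop(sprintf("integrity error: truncated distance block in '%s'",
                     path))
      }
      dtr[[tr]] <- v
    }
    dist[[p]] <- dtr
    atoms_l[[p]] <- rep(list(NULL), nT)
  }
  if (isTRUE(h$has_atoms)) {
    for (p in seq_len(P)) {
      for (tr in seq_len(nT)) {
        v <- readBin(con, "integer", 2L * h$n_frames[tr], size = 4L,
                     endian = "little")
        if (length(v) < 2L * h$n_frames[tr]) {
          stop(sprintf("integrity error: truncated atom block in '%s'",
                       path))
        }
        atoms_l[[p]][[tr]] <- matrix(v, ncol = 2L, byrow = TRUE)
      }
    }
  }
  structure(list(pairs = data.frame(a = h$pairs$a, b = h$pairs$b),
                 dist = dist, atoms = atoms_l,
                 topology = top, fragmentation = fragmentation,
                 assignments = assignments, scheme = h$scheme,
                 n_frames = as.integer(h$n_frames), files = h$files,
                 interface_split = if (!is.null(h$interface_split)) {
                   list(A = as.integer(h$interface_split$A),
                        B = as.integer(h$interface_split$B))
                 },
                 anchors = if (!is.null(h$anchors)) as.integer(h$anchors),
                 cutoff = h$cutoff, n_nearest = h$n_nearest,
                 ensemble = NULL),
            class = "ContactGroup")
}
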