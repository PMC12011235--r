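# TrajectoryEnsemble: one topology + an ordered list of coordinate blocks.
# Internally everything is in nanometres.

#' Build a trajectory ensemble
#'
#' @param topology a [Topology].
#' @param xyz_list list of frames x atoms x 3 arrays (nm), one per trajectory.
#' @param box optional length-3 orthorhombic box (nm) shared by all blocks, or
#'   a list of per-trajectory boxes; `NULL` disables minimum-image distances.
#' @param files source filenames (metadata only).
#' @return object of class `TrajectoryEnsemble`.
#' @export
trajectory_ensemble <- function(topology, xyz_list, box = NULL, files = NULL) {
  stopifnot(length(xyz_list) >= 1L)
  for (k in seq_along(xyz_list)) {
    x <- xyz_list[[k]]
    if (is.matrix(x)) xyz_list[[k]] <- x <- array(x, c(1L, nrow(x), ncol(x)))
    if (dim(x)[2L] != n_atoms(topology)) {
      stop(sprintf("trajectory %d has %d atoms, topology has %d",
                   k, dim(x)[2L], n_atoms(topology)))
    }
    if (dim(x)[1L] < 1L) stop(sprintf("trajectory %d has zero frames", k))
  }
  if (!is.null(box) && !is.list(box)) box <- rep(list(box), length(xyz_list))
  if (is.null(files)) files <- sprintf("traj_%d", seq_along(xyz_list))
  structure(list(topology = topology, xyz = xyz_list, box = box,
                 files = files),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf("TrajectoryEnsemble: %d trajectories, frames [%s], %d atoms\n",
              length(x$xyz), paste(nf, collapse = ", "),
              n_atoms(x$topology)))
  invisible(x)
}

#' Frames per trajectory
#' @param ensemble a `TrajectoryEnsemble`.
#' @return integer vector, one entry per trajectory.
#' @export
n_frames <- function(ensemble) {
  vapply(ensemble$xyz, function(x) dim(x)[1L], integer(1))
}

#' Load trajectory files against a topology
#'
#' Supported: multi-model PDB, GRO (including concatenated frames), and DCD
#' when the optional bio3d backend is installed. XTC/TRR have no reader in
#' this toolchain and raise an explicit error. Each file's atom count must
#' match the topology; trajectory order is preserved and coordinates are
#' normalized to nanometres.
#'
#' @param paths character vector of trajectory files.
#' @param topology the shared [Topology].
#' @return a `TrajectoryEnsemble`.
#' @export
load_trajectories <- function(paths, topology) {
  stopifnot(length(paths) >= 1L)
  xyz_list <- list()
  box <- NULL
  for (p in paths) {
    ext <- tolower(tools::file_ext(p))
    blk <- switch(ext,
      pdb = read_pdb(p),
      gro = read_gro(p),
      dcd = {
        if (!requireNamespace("bio3d", quietly = TRUE)) {
          stop("reading DCD requires the 'bio3d' package")
        }
        m <- bio3d::read.dcd(p, verbose = FALSE)
        nf <- nrow(m)
        na <- ncol(m) / 3L
        a <- array(NA_real_, c(nf, na, 3L))
        for (f in seq_len(nf)) a[f, , ] <- matrix(m[f, ], ncol = 3L,
                                                  byrow = TRUE)
        list(xyz = a / 10, box = NULL)  # DCD is in Angstrom
      },
      xtc = ,
      trr = stop(sprintf(
        "no reader backend for '.%s' files is available; convert to multi-model PDB, GRO or DCD",
        ext)),
      stop(sprintf("unsupported trajectory format '.%s'", ext)))
    if (dim(blk$xyz)[2L] != n_atoms(topology)) {
      stop(sprintf("topology mismatch: '%s' has %d atoms, topology has %d",
                   p, dim(blk$xyz)[2L], n_atoms(topology)))
    }
    xyz_list[[length(xyz_list) + 1L]] <- blk$xyz
    if (is.null(box) && !is.null(blk$box)) box <- blk$box
  }
  trajectory_ensemble(topology, xyz_list, box = box, files = paths)
}
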