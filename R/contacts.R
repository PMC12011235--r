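# The core engine: per-frame residue-residue minimum distances under a chosen
# scheme, hard-cutoff contact statistics with per-frame atom-pair bookkeeping,
# and the ContactGroup container that encapsulates all distance-related data
# of one MD setup (any number of trajectories sharing one topology).

# minimum-image displacement for an orthorhombic box (per component)
.min_image <- function(d, L) d - L * round(d / L)

# distance series of one residue pair over one trajectory block.
# Returns list(d = numeric nF (nm), atoms = nF x 2 matrix | NULL).
.pair_block <- function(xyz, idxA, idxB, box = NULL, com = FALSE,
                        mA = NULL, mB = NULL) {
  nF <- dim(xyz)[1L]
  if (com) {
    wA <- mA / sum(mA); wB <- mB / sum(mB)
    d2 <- 0
    for (k in 1:3) {
      cA <- matrix(xyz[, idxA, k], nrow = nF) %*% wA
      cB <- matrix(xyz[, idxB, k], nrow = nF) %*% wB
      dk <- cA - cB
      if (!is.null(box)) dk <- .min_image(dk, box[k])
      d2 <- d2 + dk * dk
    }
    return(list(d = as.vector(sqrt(d2)), atoms = NULL))
  }
  nA <- length(idxA); nB <- length(idxB)
  KA <- rep(idxA, each = nB)
  KB <- rep(idxB, times = nA)
  d2 <- 0
  for (k in 1:3) {
    dk <- matrix(xyz[, KA, k], nrow = nF) - matrix(xyz[, KB, k], nrow = nF)
    if (!is.null(box)) dk <- .min_image(dk, box[k])
    d2 <- d2 + dk * dk
  }
  # ties broken towards the lowest (atom_A, atom_B): columns are ordered
  # lexicographically in (A, B) and max.col takes the first minimum
  kmin <- max.col(-d2, ties.method = "first")
  sel <- cbind(seq_len(nF), kmin)
  list(d = sqrt(d2[sel]),
       atoms = cbind(KA[kmin], KB[kmin]))
}

#' Scheme distance of one residue pair in one frame
#'
#' Minimum over all cross pairs of scheme-selected atoms of the Euclidean
#' distance (minimum-image when a periodic box is present); the `com` scheme
#' returns the distance of the mass-weighted heavy-atom centroids and carries
#' no atom pair.
#'
#' @param frame_xyz atoms x 3 coordinate matrix (nm).
#' @param topology a [Topology].
#' @param pair length-2 vector of residue indices.
#' @param scheme distance scheme, see [scheme_atoms()].
#' @param box optional length-3 orthorhombic box (nm).
#' @return list with `distance` (nm) and `atoms` (length-2 atom-index vector,
#'   `NULL` for `com`).
#' @export
residue_pair_distance <- function(frame_xyz, topology, pair,
                                  scheme = "closest_heavy", box = NULL) {
  scheme <- match.arg(scheme, .SCHEMES)
  classes <- atom_classes(topology)
  idxA <- scheme_atoms(topology, pair[1L], scheme, classes)
  idxB <- scheme_atoms(topology, pair[2L], scheme, classes)
  xyz <- array(frame_xyz, c(1L, nrow(frame_xyz), 3L))
  blk <- .pair_block(xyz, idxA, idxB, box = box, com = scheme == "com",
                     mA = .atom_masses(topology, idxA),
                     mB = .atom_masses(topology, idxB))
  list(distance = blk$d[1L],
       atoms = if (is.null(blk$atoms)) NULL else blk$atoms[1L, ])
}

#' Hard-cutoff contact indicator
#'
#' `1` iff `d <= cutoff`; the boundary is inclusive. Both arguments must be in
#' the same unit.
#'
#' @param d distance(s), non-negative.
#' @param cutoff cutoff, strictly positive.
#' @return integer vector of 0/1.
#' @export
contact_indicator <- function(d, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  if (any(d < 0)) stop("distances must be non-negative")
  as.integer(d <= cutoff)
}

#' Build a ContactGroup
#'
#' Computes the per-frame scheme distances (and, for minimum-based schemes,
#' the atom pair achieving each minimum) for every requested residue pair over
#' every trajectory of the ensemble, and bundles them with the topology,
#' fragmentation, consensus assignments and trajectory metadata.
#'
#' @param ensemble a `TrajectoryEnsemble`.
#' @param pairs two-column matrix / data.frame of residue indices; order
#'   within a pair is irrelevant (stored with a < b), duplicates collapse.
#' @param scheme distance scheme, see [scheme_atoms()].
#' @param fragmentation optional `Fragmentation` (computed with the `default`
#'   heuristic when omitted).
#' @param assignments optional named list of `LabelAssignment`s used for
#'   consensus-tagged labels.
#' @param interface_split optional list with residue-index vectors `A` and `B`
#'   recording a bipartition (set by [contact_interface()]).
#' @param anchors optional anchor residue indices (set by
#'   [residue_neighborhood()]).
#' @return object of class `ContactGroup`.
#' @export
contact_group <- function(ensemble, pairs, scheme = "closest_heavy",
                          fragmentation = NULL, assignments = NULL,
                          interface_split = NULL, anchors = NULL) {
  stopifnot(inherits(ensemble, "TrajectoryEnsemble"))
  scheme <- match.arg(scheme, .SCHEMES)
  top <- ensemble$topology
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (nrow(pairs) && any(pairs[, 1L] == pairs[, 2L])) {
    stop("a residue cannot pair with itself")
  }
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                 pmax(pairs[, 1L], pairs[, 2L]))
  pairs <- unique(pairs)
  if (nrow(pairs) && (min(pairs) < 1L || max(pairs) > n_residues(top))) {
    stop("pair references a residue index outside the topology")
  }
  if (is.null(fragmentation)) fragmentation <- fragment_topology(top)

  classes <- atom_classes(top)
  sel <- new.env(parent = emptyenv())
  get_sel <- function(r) {
    key <- as.character(r)
    if (is.null(sel[[key]])) {
      sel[[key]] <- scheme_atoms(top, r, scheme, classes)
    }
    sel[[key]]
  }
  com <- scheme == "com"
  nT <- length(ensemble$xyz)
  dist <- vector("list", nrow(pairs))
  atoms <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1L]; b <- pairs[p, 2L]
    ia <- get_sel(a); ib <- get_sel(b)
    dtr <- vector("list", nT)
    atr <- vector("list", nT)
    for (tr in seq_len(nT)) {
      blk <- .pair_block(ensemble$xyz[[tr]], ia, ib,
                         box = if (is.null(ensemble$box)) NULL else
                           ensemble$box[[tr]],
                         com = com,
                         mA = if (com) .atom_masses(top, ia),
                         mB = if (com) .atom_masses(top, ib))
      dtr[[tr]] <- blk$d
      atr[tr] <- list(blk$atoms)  # keep NULL slots for the com scheme
    }
    dist[[p]] <- dtr
    atoms[[p]] <- atr
  }
  structure(list(pairs = data.frame(a = pairs[, 1L], b = pairs[, 2L]),
                 dist = dist, atoms = atoms,
                 topology = top, fragmentation = fragmentation,
                 assignments = assignments, scheme = scheme,
                 n_frames = n_frames(ensemble), files = ensemble$files,
                 interface_split = interface_split, anchors = anchors,
                 ensemble = ensemble),
            class = "ContactGroup")
}

#' @export
print.ContactGroup <- function(x, ...) {
  cat(sprintf(
    "ContactGroup: %d pairs, %d trajectories (frames: %s), scheme '%s'\n",
    nrow(x$pairs), length(x$n_frames),
    paste(x$n_frames, collapse = ", "), x$scheme))
  invisible(x)
}

#' Number of contact pairs in a group
#' @param group a `ContactGroup`.
#' @return integer.
#' @export
n_pairs <- function(group) nrow(group$pairs)

#' Subset a ContactGroup to selected pairs
#' @param group a `ContactGroup`.
#' @param keep integer indices of pairs to keep (in the new order).
#' @return a `ContactGroup`.
#' @export
subset_group <- function(group, keep) {
  group$pairs <- group$pairs[keep, , drop = FALSE]
  rownames(group$pairs) <- NULL
  group$dist <- group$dist[keep]
  group$atoms <- group$atoms[keep]
  group
}

#' Display labels of a group's pairs
#' @param group a `ContactGroup`.
#' @param key `"consensus_label"` renders consensus-tagged names (falling back
#'   to plain names); `"residue_name"` renders plain `name+resSeq`.
#' @return two-column character matrix (label_a, label_b).
#' @export
pair_labels <- function(group, key = c("consensus_label", "residue_name")) {
  key <- match.arg(key)
  assign <- if (key == "consensus_label") group$assignments else NULL
  la <- render_residue_label(group$topology, group$pairs$a, assign,
                             fragmentation = group$fragmentation)
  lb <- render_residue_label(group$topology, group$pairs$b, assign,
                             fragmentation = group$fragmentation)
  cbind(label_a = la, label_b = lb)
}

.INTERACTION_TYPES <- c("SC-SC", "SC-BB", "BB-SC", "BB-BB")

#' Contact frequencies of a ContactGroup at a cutoff
#'
#' For each pair, the per-trajectory frequency is the fraction of that
#' trajectory's frames with distance at or below the cutoff, and the global
#' frequency is the frame-count-weighted mean over trajectories (total formed
#' frames over total frames). Both are reported, since the global average can
#' mask per-trajectory outliers. Interaction-type fractions (sidechain /
#' backbone combinations of the per-frame minimum-distance atom pair) are
#' averages over formed frames only.
#'
#' @param group a `ContactGroup`.
#' @param cutoff cutoff in Angstrom (default 4.5).
#' @return object of class `ContactFrequencies`: a list with `freq` (global
#'   F per pair), `per_traj` (pairs x trajectories matrix of f_i), `counts`
#'   (formed-frame counts), `type_fractions` (pairs x 4 matrix over
#'   `r paste(.INTERACTION_TYPES, collapse = ", ")`), `cutoff` (Angstrom),
#'   `n_frames`, and the pair table with display labels.
#' @export
compute_frequencies <- function(group, cutoff = 4.5) {
  stopifnot(inherits(group, "ContactGroup"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive number (Angstrom)")
  }
  if (!nrow(group$pairs)) stop("empty ContactGroup: no pairs to analyze")
  cut_nm <- cutoff / 10
  P <- nrow(group$pairs)
  nT <- length(group$n_frames)
  counts <- matrix(0L, P, nT)
  types <- matrix(0L, P, 4L,
                  dimnames = list(NULL, .INTERACTION_TYPES))
  classes <- atom_classes(group$topology)
  for (p in seq_len(P)) {
    for (tr in seq_len(nT)) {
      formed <- group$dist[[p]][[tr]] <= cut_nm
      counts[p, tr] <- sum(formed)
      am <- group$atoms[[p]][[tr]]
      if (!is.null(am) && any(formed)) {
        ty <- paste(classes[am[formed, 1L]], classes[am[formed, 2L]],
                    sep = "-")
        tt <- table(factor(ty, levels = .INTERACTION_TYPES))
        types[p, ] <- types[p, ] + as.integer(tt)
      }
    }
  }
  per_traj <- sweep(counts, 2L, group$n_frames, "/")
  freq <- rowSums(counts) / sum(group$n_frames)
  formed_tot <- rowSums(counts)
  tf <- types / ifelse(formed_tot > 0, formed_tot, 1)
  has_atoms <- vapply(group$atoms, function(a) !is.null(a[[1L]]), logical(1))
  tf[!has_atoms, ] <- NA_real_
  labs <- pair_labels(group)
  structure(list(freq = freq, per_traj = per_traj, counts = counts,
                 type_fractions = tf, cutoff = cutoff,
                 n_frames = group$n_frames,
                 pairs = data.frame(group$pairs, labs,
                                    stringsAsFactors = FALSE)),
            class = "ContactFrequencies")
}

#' @export
print.ContactFrequencies <- function(x, ...) {
  cat(sprintf("ContactFrequencies at %.2f Ang: %d pairs, sum F = %.2f\n",
              x$cutoff, length(x$freq), sum(x$freq)))
  ord <- order(-x$freq)
  show <- head(ord, 10L)
  for (p in show) {
    cat(sprintf("  %-18s %-18s F = %.4f [%s]\n",
                x$pairs$label_a[p], x$pairs$label_b[p], x$freq[p],
                paste(sprintf("%.2f", x$per_traj[p, ]), collapse = " ")))
  }
  if (length(ord) > 10L) cat(sprintf("  ... %d more\n", length(ord) - 10L))
  invisible(x)
}

#' Per-frame number of formed contacts
#'
#' The value at frame t is the number of the group's pairs with distance at or
#' below the cutoff in that frame. The grand mean of this trace over all
#' frames equals the sum of the global frequencies exactly.
#'
#' @param group a `ContactGroup`.
#' @param cutoff cutoff in Angstrom.
#' @return list of integer vectors, one per trajectory.
#' @export
formed_contacts_timetrace <- function(group, cutoff = 4.5) {
  cut_nm <- cutoff / 10
  nT <- length(group$n_frames)
  out <- vector("list", nT)
  for (tr in seq_len(nT)) {
    acc <- integer(group$n_frames[tr])
    for (p in seq_len(nrow(group$pairs))) {
      acc <- acc + (group$dist[[p]][[tr]] <= cut_nm)
    }
    out[[tr]] <- acc
  }
  out
}

#' Per-residue participation in a group's contacts
#'
#' The participation of residue r is the sum of global frequencies over all
#' pairs containing r; summed over all residues this equals twice the total
#' frequency (each pair contributes to both members).
#'
#' @param freqs a `ContactFrequencies`.
#' @param group the `ContactGroup` the frequencies came from.
#' @return named numeric vector over all topology residues (0 for residues in
#'   no pair).
#' @export
per_residue_participation <- function(freqs, group) {
  part <- numeric(n_residues(group$topology))
  for (p in seq_along(freqs$freq)) {
    part[group$pairs$a[p]] <- part[group$pairs$a[p]] + freqs$freq[p]
    part[group$pairs$b[p]] <- part[group$pairs$b[p]] + freqs$freq[p]
  }
  names(part) <- residue_display(group$topology, seq_along(part))
  part
}

#' Representative frame of a ContactGroup
#'
#' The frame whose pair-distance vector is closest (Euclidean norm) to the
#' ensemble-mean distance vector; ties break towards the earlier (trajectory,
#' frame).
#'
#' @param group a `ContactGroup`.
#' @return list with `traj` and `frame` (1-based) and `rmsd` (nm, distance to
#'   the mean vector divided by sqrt of the number of pairs).
#' @export
select_representative_frame <- function(group) {
  P <- nrow(group$pairs)
  stopifnot(P >= 1L)
  mats <- lapply(seq_along(group$n_frames), function(tr) {
    do.call(cbind, lapply(seq_len(P), function(p) group$dist[[p]][[tr]]))
  })
  all_d <- do.call(rbind, mats)  # total frames x P
  mu <- colMeans(all_d)
  dev <- sqrt(rowSums(sweep(all_d, 2L, mu)^2))
  k <- which.min(dev)  # which.min takes the first minimum: earliest frame
  offsets <- cumsum(c(0L, group$n_frames))
  tr <- findInterval(k - 1L, offsets, rightmost.closed = FALSE)
  list(traj = tr, frame = k - offsets[tr], rmsd = dev[k] / sqrt(P))
}

# ---- selection-driven constructors -----------------------------------------

.resolve_side <- function(ensemble, side, fragmentation, assignments,
                          what = "selection") {
  top <- ensemble$topology
  if (is.numeric(side)) {
    idx <- as.integer(side)
  } else {
    idx <- expand_selection(side, top, fragmentation, assignments)$indices
  }
  if (!length(idx)) stop(sprintf("%s resolved to zero residues", what))
  if (min(idx) < 1L || max(idx) > n_residues(top)) {
    stop(sprintf("%s references residues outside the topology", what))
  }
  sort(unique(idx))
}

# positions within n_nearest along the same bonded chain as any anchor
.bonded_neighbors <- function(topology, anchor, n_nearest) {
  if (n_nearest < 1L) return(integer(0))
  comp <- residue_bond_components(topology)
  cand <- seq_len(n_residues(topology))
  cand[comp == comp[anchor] & abs(cand - anchor) <= n_nearest &
         cand != anchor]
}

#' Contact neighborhood of anchor residues
#'
#' Builds the ContactGroup of an anchor selection against all other residues,
#' excluding trivial bonded sequence neighbors (within `n_nearest` positions
#' along the same bonded chain; these are nearly always in contact by
#' construction). Pairs with zero frequency at the cutoff are dropped; the
#' remainder is truncated per anchor by `ctc_control`.
#'
#' @param ensemble a `TrajectoryEnsemble`.
#' @param anchors selection expression (see [expand_selection()]) or integer
#'   residue indices.
#' @param cutoff cutoff in Angstrom.
#' @param scheme distance scheme.
#' @param n_nearest bonded-sequence neighbors to exclude (default 4).
#' @param ctc_control integer (or any value > 1): keep the top-n pairs per
#'   anchor by global frequency; value in (0, 1]: keep the smallest pair set
#'   capturing that fraction of the anchor's total frequency (integer `1L` is
#'   top-1, double `1.0` is the full set).
#' @param fragmentation optional `Fragmentation`.
#' @param assignments optional named list of `LabelAssignment`s.
#' @return a `ContactGroup` (possibly with zero pairs, which is a valid
#'   report of "no contacts").
#' @export
residue_neighborhood <- function(ensemble, anchors, cutoff = 4.5,
                                 scheme = "closest_heavy", n_nearest = 4L,
                                 ctc_control = 5L, fragmentation = NULL,
                                 assignments = NULL) {
  top <- ensemble$topology
  if (is.null(fragmentation)) fragmentation <- fragment_topology(top)
  anchor_idx <- .resolve_side(ensemble, anchors, fragmentation, assignments,
                              "anchor selection")
  all_res <- seq_len(n_residues(top))
  pair_list <- list()
  for (a in anchor_idx) {
    excl <- c(a, .bonded_neighbors(top, a, n_nearest))
    partners <- setdiff(all_res, excl)
    if (length(partners)) {
      pair_list[[length(pair_list) + 1L]] <- cbind(a, partners)
    }
  }
  pairs <- unique(do.call(rbind, pair_list))
  grp <- contact_group(ensemble, pairs, scheme = scheme,
                       fragmentation = fragmentation,
                       assignments = assignments, anchors = anchor_idx)
  fr <- compute_frequencies(grp, cutoff)
  keep <- integer(0)
  for (a in anchor_idx) {
    mine <- which((grp$pairs$a == a | grp$pairs$b == a) & fr$freq > 0)
    if (!length(mine)) next
    mine <- mine[order(-fr$freq[mine], mine)]
    if (is.integer(ctc_control) || ctc_control > 1) {
      keep <- c(keep, head(mine, as.integer(ctc_control)))
    } else {
      cum <- cumsum(fr$freq[mine])
      n_keep <- which(cum >= ctc_control * sum(fr$freq[mine]))[1L]
      keep <- c(keep, mine[seq_len(n_keep)])
    }
  }
  keep <- sort(unique(keep))
  grp <- subset_group(grp, keep)
  grp$cutoff <- cutoff
  grp$n_nearest <- n_nearest
  grp
}

#' Interface ContactGroup between two residue sets
#'
#' Candidate pairs are the cross product of the two sides only. The two sides
#' must be disjoint and non-empty. The result is truncated by `ctc_control`
#' (default: the smallest pair set capturing 90 percent of the total
#' frequency) and records the bipartition in `interface_split` for
#' participation plots and signed-bfactor heatmaps.
#'
#' @param ensemble a `TrajectoryEnsemble`.
#' @param side_a,side_b selection expressions or integer residue-index
#'   vectors.
#' @param cutoff cutoff in Angstrom.
#' @param scheme distance scheme.
#' @param ctc_control fraction in (0, 1] of total frequency to capture, or an
#'   integer top-n of pairs.
#' @param fragmentation optional `Fragmentation`.
#' @param assignments optional named list of `LabelAssignment`s.
#' @return a `ContactGroup` with `interface_split` set.
#' @export
contact_interface <- function(ensemble, side_a, side_b, cutoff = 4.5,
                              scheme = "closest_heavy", ctc_control = 0.9,
                              fragmentation = NULL, assignments = NULL) {
  top <- ensemble$topology
  if (is.null(fragmentation)) fragmentation <- fragment_topology(top)
  A <- .resolve_side(ensemble, side_a, fragmentation, assignments, "side A")
  B <- .resolve_side(ensemble, side_b, fragmentation, assignments, "side B")
  ov <- intersect(A, B)
  if (length(ov)) {
    stop(sprintf("interface sides overlap in residues: %s",
                 paste(residue_display(top, head(ov, 8L)), collapse = ", ")))
  }
  pairs <- as.matrix(expand.grid(a = A, b = B))
  grp <- contact_group(ensemble, pairs, scheme = scheme,
                       fragmentation = fragmentation,
                       assignments = assignments,
                       interface_split = list(A = A, B = B))
  fr <- compute_frequencies(grp, cutoff)
  ord <- order(-fr$freq, seq_along(fr$freq))
  ord <- ord[fr$freq[ord] > 0]
  if (length(ord)) {
    if (is.integer(ctc_control) || ctc_control > 1) {
      keep <- head(ord, as.integer(ctc_control))
    } else {
      cum <- cumsum(fr$freq[ord])
      keep <- ord[seq_len(which(cum >= ctc_control * sum(fr$freq))[1L])]
    }
  } else {
    keep <- integer(0)
  }
  grp <- subset_group(grp, sort(keep))
  grp$cutoff <- cutoff
  grp
}

#' ContactGroups for user-defined sites
#'
#' @param ensemble a `TrajectoryEnsemble`.
#' @param sites a `Site` or list of `Site`s (see [read_sites()]).
#' @param cutoff cutoff in Angstrom.
#' @param scheme distance scheme.
#' @param fragmentation optional `Fragmentation`.
#' @param assignments optional named list of `LabelAssignment`s.
#' @return named list of `ContactGroup`s, one per site.
#' @export
sites_contacts <- function(ensemble, sites, cutoff = 4.5,
                           scheme = "closest_heavy", fragmentation = NULL,
                           assignments = NULL) {
  if (inherits(sites, "Site")) sites <- list(sites)
  top <- ensemble$topology
  if (is.null(fragmentation)) fragmentation <- fragment_topology(top)
  out <- list()
  for (s in sites) {
    pairs <- resolve_site(s, top, fragmentation, assignments)
    grp <- contact_group(ensemble, pairs, scheme = scheme,
                         fragmentation = fragmentation,
                         assignments = assignments)
    grp$cutoff <- cutoff
    out[[s$name]] <- grp
  }
  out
}
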