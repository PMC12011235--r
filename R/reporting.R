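# Reporting surfaces over ContactGroups: frequency tables (ASCII/CSV/xlsx),
# time-traces, distance distributions, contact and fragment matrices,
# flareplot geometry, signed-bfactor PDB heatmaps, and cross-system
# comparisons. Every operation here is a pure data transform; figure rendering
# is left to the caller so every reported number is independently testable.

#' Ranked frequency table of a ContactGroup
#'
#' Rows are sorted by global frequency (descending, ties by pair index) and
#' carry the per-trajectory frequencies, the interaction-type fractions over
#' formed frames, and a cumulative sum of F.
#'
#' @param freqs a `ContactFrequencies`.
#' @param group the matching `ContactGroup`.
#' @return data.frame with columns rank, label_a, label_b, freq, one
#'   `f_traj<i>` column per trajectory, the four type fractions and `cum_freq`.
#' @export
frequency_table <- function(freqs, group) {
  ord <- order(-freqs$freq, seq_along(freqs$freq))
  pt <- freqs$per_traj[ord, , drop = FALSE]
  colnames(pt) <- sprintf("f_traj%d", seq_len(ncol(pt)))
  tf <- freqs$type_fractions[ord, , drop = FALSE]
  colnames(tf) <- tolower(gsub("-", "_", colnames(tf)))
  out <- data.frame(rank = seq_along(ord),
                    label_a = freqs$pairs$label_a[ord],
                    label_b = freqs$pairs$label_b[ord],
                    freq = freqs$freq[ord],
                    pt, tf,
                    cum_freq = cumsum(freqs$freq[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# provenance header lines common to all text writers
.provenance <- function(group, cutoff, extra = character(0)) {
  c(sprintf("contactlens %s",
            as.character(utils::packageVersion("contactlens"))),
    sprintf("cutoff: %.2f Ang | scheme: %s | trajectories: %d (frames: %s)",
            cutoff, group$scheme, length(group$n_frames),
            paste(group$n_frames, collapse = ", ")),
    if (!is.null(group$n_nearest)) {
      sprintf("n_nearest: %d", group$n_nearest)
    },
    extra)
}

.round_table <- function(tab, digits = 4L) {
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "rank"
  tab[num] <- lapply(tab[num], function(x) round(x, digits))
  tab
}

#' Write a frequency table as fixed-width ASCII
#'
#' All writers ([write_table_ascii()], [write_table_csv()],
#' [write_table_xlsx()]) emit cell-identical numbers at 4 decimals; the text
#' formats carry a provenance header as `#` comment lines.
#'
#' @param tab table from [frequency_table()].
#' @param path output file.
#' @param group the `ContactGroup` (for the provenance header).
#' @param cutoff cutoff in Angstrom (for the provenance header).
#' @return `path`, invisibly.
#' @export
write_table_ascii <- function(tab, path, group, cutoff) {
  tab <- .round_table(tab)
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "rank"
  body <- tab
  body[num] <- lapply(body[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.4f", x))
  })
  widths <- pmax(nchar(names(body)),
                 vapply(body, function(x) max(nchar(as.character(x)), 0L),
                        integer(1)))
  fmt_row <- function(vals) {
    paste(mapply(function(v, w) formatC(as.character(v), width = w),
                 vals, widths), collapse = "  ")
  }
  lines <- c(paste0("# ", .provenance(group, cutoff)),
             fmt_row(names(body)),
             vapply(seq_len(nrow(body)), function(i) {
               fmt_row(unlist(body[i, ], use.names = FALSE))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_table_ascii
#' @export
write_table_csv <- function(tab, path, group, cutoff) {
  tab <- .round_table(tab)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .provenance(group, cutoff)), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_ascii
#' @export
write_table_xlsx <- function(tab, path, group, cutoff) {
  write_xlsx_sheet(.round_table(tab), path, sheet = "frequencies")
}

#' Conventional output file name embedding anchor, cutoff and kind
#'
#' @param kind e.g. `"neighborhood"`, `"interface"`.
#' @param anchor anchor/selection tag (may be empty).
#' @param cutoff cutoff in Angstrom (restated in every artifact name).
#' @param ext file extension without dot.
#' @return file name like `"neighborhood.L394@4.5_Ang.xlsx"`.
#' @export
output_filename <- function(kind, anchor, cutoff, ext) {
  anchor <- gsub("[^A-Za-z0-9@._-]", "_", anchor)
  mid <- if (nzchar(anchor)) paste0(".", anchor) else ""
  sprintf("%s%s@%g_Ang.%s", kind, mid, cutoff, ext)
}

# ---- time traces and distributions ----------------------------------------

#' Centered moving average with contracted edges
#'
#' @param x numeric series.
#' @param window odd integer window; 1 is the identity.
#' @return smoothed series of the same length.
#' @export
smooth_series <- function(x, window = 1L) {
  if (window %% 2L != 1L || window < 1L) {
    stop("smoothing window must be a positive odd integer")
  }
  if (window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)  # contract near the edges
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Raw and smoothed distance time-traces of one pair
#'
#' @param group a `ContactGroup`.
#' @param pair pair index within the group.
#' @param window odd smoothing window; the default is about 1 percent of the
#'   median trajectory length, rounded up to odd.
#' @return list per trajectory with `raw` and `smooth` distance vectors (nm).
#' @export
timetrace_data <- function(group, pair, window = NULL) {
  stopifnot(pair >= 1L, pair <= nrow(group$pairs))
  if (is.null(window)) {
    window <- max(1L, round(stats::median(group$n_frames) * 0.01))
    if (window %% 2L == 0L) window <- window + 1L
  }
  lapply(group$dist[[pair]], function(d) {
    list(raw = d, smooth = smooth_series(d, window))
  })
}

#' Pooled distance distribution of one pair
#'
#' Histogram over all trajectories pooled (the per-trajectory histograms sum
#' to it) plus a violin-ready kernel density.
#'
#' @param group a `ContactGroup`.
#' @param pair pair index.
#' @param bin_width histogram bin width in Angstrom (default 0.25).
#' @return list with `breaks`, `mids`, `counts` (pooled), `per_traj` (counts
#'   matrix), and `density` (x/y from a gaussian KDE, Scott-style bandwidth)
#'   — all distance axes in Angstrom.
#' @export
distance_distribution <- function(group, pair, bin_width = 0.25) {
  stopifnot(bin_width > 0)
  d_ang <- lapply(group$dist[[pair]], function(d) d * 10)
  pooled <- unlist(d_ang)
  top <- max(pooled) + bin_width
  breaks <- seq(0, top + bin_width, by = bin_width)
  cut_all <- findInterval(pooled, breaks, rightmost.closed = TRUE)
  counts <- tabulate(cut_all, nbins = length(breaks) - 1L)
  per_traj <- vapply(d_ang, function(d) {
    tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
             nbins = length(breaks) - 1L)
  }, integer(length(breaks) - 1L))
  dens <- if (length(pooled) > 1L && stats::sd(pooled) > 0) {
    k <- stats::density(pooled, bw = stats::bw.nrd(pooled))
    list(x = k$x, y = k$y)
  } else {
    list(x = pooled[1L], y = 1)
  }
  list(breaks = breaks, mids = breaks[-length(breaks)] + bin_width / 2,
       counts = counts, per_traj = per_traj, density = dens)
}

# ---- matrices --------------------------------------------------------------

#' Symmetric residue-by-residue contact matrix
#'
#' `M[a, b]` is the global frequency of the computed pair (a, b), 0 elsewhere;
#' the diagonal is 0 and row sums equal the per-residue participation.
#'
#' @param freqs a `ContactFrequencies`.
#' @param group the matching `ContactGroup`.
#' @return numeric matrix with residue display names as dimnames.
#' @export
contact_matrix <- function(freqs, group) {
  n <- n_residues(group$topology)
  M <- matrix(0, n, n)
  for (p in seq_along(freqs$freq)) {
    a <- group$pairs$a[p]; b <- group$pairs$b[p]
    M[a, b] <- M[a, b] + freqs$freq[p]
    M[b, a] <- M[b, a] + freqs$freq[p]
  }
  nm <- residue_display(group$topology, seq_len(n))
  dimnames(M) <- list(nm, nm)
  M
}

#' Coarse-grained fragment-by-fragment contact matrix
#'
#' Entry (P, Q) is the sum of pair frequencies with one residue in fragment P
#' and the other in Q; the upper-triangle total (including the diagonal)
#' equals the total frequency.
#'
#' @param freqs a `ContactFrequencies`.
#' @param group the matching `ContactGroup`.
#' @param partition a `Fragmentation` or named list of residue-index sets
#'   covering all residues in the group's pairs (e.g. consensus fragments);
#'   default: the group's fragmentation.
#' @return symmetric numeric matrix with fragment names as dimnames.
#' @export
fragment_matrix <- function(freqs, group, partition = NULL) {
  if (is.null(partition)) partition <- group$fragmentation
  sets <- if (inherits(partition, "Fragmentation")) partition$fragments
    else partition
  owner <- rep(NA_integer_, n_residues(group$topology))
  for (k in seq_along(sets)) owner[sets[[k]]] <- k
  used <- unique(c(group$pairs$a, group$pairs$b))
  if (anyNA(owner[used])) {
    stop("partition does not cover all residues involved in the group's pairs")
  }
  nf <- length(sets)
  M <- matrix(0, nf, nf, dimnames = list(names(sets), names(sets)))
  for (p in seq_along(freqs$freq)) {
    i <- owner[group$pairs$a[p]]; j <- owner[group$pairs$b[p]]
    M[i, j] <- M[i, j] + freqs$freq[p]
    if (i != j) M[j, i] <- M[j, i] + freqs$freq[p]
  }
  M
}

# ---- secondary structure (simple CA-geometry classifier) -------------------

#' Assign coarse secondary structure from CA geometry
#'
#' A deliberately simple classifier for flareplot annotation: residue i is
#' helical (`H`) when the CA(i)-CA(i+3) and CA(i)-CA(i+4) distances fall in
#' the canonical alpha-helical ranges, extended (`B`) when the local
#' CA(i-1)-CA(i+1) span exceeds 0.64 nm, and coil (`C`) otherwise. Distances
#' are only evaluated within bonded chains. The assignment function is
#' pluggable in [flare_layout()].
#'
#' @param topology a [Topology].
#' @param frame_xyz atoms x 3 matrix (nm).
#' @return character vector over residues (`"H"`, `"B"`, `"C"`; `""` for
#'   non-protein residues).
#' @export
secondary_structure <- function(topology, frame_xyz) {
  n <- n_residues(topology)
  comp <- residue_bond_components(topology)
  ca <- matrix(NA_real_, n, 3L)
  for (r in seq_len(n)) {
    k <- which(topology$atoms$residue == r &
                 toupper(topology$atoms$name) == "CA" &
                 topology$atoms$is_heavy)
    if (length(k)) ca[r, ] <- frame_xyz[k[1L], ]
  }
  dca <- function(i, j) {
    if (i < 1L || j > n || comp[i] != comp[j] ||
        anyNA(ca[i, ]) || anyNA(ca[j, ])) return(NA_real_)
    sqrt(sum((ca[i, ] - ca[j, ])^2))
  }
  out <- character(n)
  for (r in seq_len(n)) {
    if (topology$residues$molecule_class[r] != "protein") next
    d3 <- dca(r, r + 3L); d4 <- dca(r, r + 4L)
    d2 <- dca(r - 1L, r + 1L)
    out[r] <- if (!is.na(d3) && !is.na(d4) &&
                  d3 > 0.42 && d3 < 0.60 && d4 > 0.50 && d4 < 0.68) "H"
      else if (!is.na(d2) && d2 > 0.64) "B"
      else "C"
  }
  out
}

# ---- flareplot geometry ----------------------------------------------------

#' Flareplot layout: residues on a circle, frequency-weighted chords
#'
#' Residues are placed in fragment order on the unit circle with an
#' inter-fragment gap; each pair with non-zero frequency becomes a chord with
#' opacity equal to its frequency (clamped to \[0, 1\]). The outer "aura" ring
#' carries any per-residue scalar; by default the interface/neighborhood
#' participation, so the ring equals the bars of the participation plot.
#'
#' @param group a `ContactGroup`.
#' @param freqs a `ContactFrequencies` for the group.
#' @param residues residues to place; default: all residues of every fragment
#'   that contains a pair member.
#' @param aura optional per-residue scalar (same length/order as `residues`);
#'   default: per-residue participation.
#' @param gap inter-fragment gap in radians (default 2 pi / 100).
#' @param ss_fun secondary-structure assignment function
#'   `(topology, frame_xyz) -> letters`; applied to the representative frame
#'   when the group still holds its ensemble, else letters are empty.
#' @return object of class `FlareLayout`: `residues`, `angles` (strictly
#'   increasing), `labels`, `fragments` (name, start/end angle), `chords`
#'   (a, b, opacity), `aura`, `ss`.
#' @export
flare_layout <- function(group, freqs, residues = NULL, aura = NULL,
                         gap = 2 * pi / 100, ss_fun = secondary_structure) {
  frsets <- group$fragmentation$fragments
  if (is.null(residues)) {
    used <- unique(c(group$pairs$a, group$pairs$b))
    inset <- vapply(frsets, function(s) any(used %in% s), logical(1))
    residues <- unlist(frsets[inset], use.names = FALSE)
  }
  residues <- as.integer(residues)
  nr <- length(residues)
  if (!nr) stop("no residues to lay out")
  frname <- fragment_of(group$fragmentation, residues)
  frname[is.na(frname)] <- "(none)"
  # keep the given order; fragment blocks are runs in that order
  blocks <- rle(frname)
  nfr <- length(blocks$values)
  total_gap <- nfr * gap
  if (total_gap >= 2 * pi) stop("gap too large for the number of fragments")
  step <- (2 * pi - total_gap) / nr
  angles <- numeric(nr)
  frag_tab <- data.frame(name = blocks$values, start = NA_real_,
                         end = NA_real_, stringsAsFactors = FALSE)
  pos <- 0
  k <- 1L
  for (bflag in seq_len(nfr)) {
    len <- blocks$lengths[bflag]
    frag_tab$start[bflag] <- pos
    angles[k:(k + len - 1L)] <- pos + (seq_len(len) - 0.5) * step
    pos <- pos + len * step
    frag_tab$end[bflag] <- pos
    pos <- pos + gap
    k <- k + len
  }
  if (!is.null(aura) && length(aura) != nr) {
    stop(sprintf("aura has %d values for %d residues", length(aura), nr))
  }
  if (is.null(aura)) {
    aura <- per_residue_participation(freqs, group)[residues]
  }
  lookup <- match(seq_len(n_residues(group$topology)), residues)
  keep <- which(freqs$freq > 0 &
                  !is.na(lookup[group$pairs$a]) &
                  !is.na(lookup[group$pairs$b]))
  chords <- data.frame(a = lookup[group$pairs$a[keep]],
                       b = lookup[group$pairs$b[keep]],
                       opacity = pmin(pmax(freqs$freq[keep], 0), 1))
  ss <- rep("", nr)
  if (!is.null(group$ensemble) && !is.null(ss_fun) && nrow(group$pairs)) {
    rep_fr <- select_representative_frame(group)
    fx <- group$ensemble$xyz[[rep_fr$traj]][rep_fr$frame, , ]
    ss <- ss_fun(group$topology, fx)[residues]
  }
  structure(list(residues = residues, angles = angles,
                 labels = render_residue_label(group$topology, residues,
                                               group$assignments),
                 fragments = frag_tab, chords = chords,
                 aura = setNames(as.numeric(aura),
                                 residue_display(group$topology, residues)),
                 ss = ss),
            class = "FlareLayout")
}

#' @export
print.FlareLayout <- function(x, ...) {
  cat(sprintf("FlareLayout: %d residues, %d fragments, %d chords\n",
              length(x$residues), nrow(x$fragments), nrow(x$chords)))
  invisible(x)
}

# ---- signed-bfactor heatmap PDB -------------------------------------------

#' Write the representative frame with signed participation as bfactor
#'
#' Every atom's bfactor carries its residue's interface participation, negated
#' on side A and positive on side B of the interface split; residues outside
#' the interface get 0. Values are written at the PDB column precision (2
#' decimals), so a read-back recovers participation to that precision. Loading
#' the file in a 3D viewer with a diverging colormap highlights the two sides
#' in different colors.
#'
#' @param group a `ContactGroup` with `interface_split` and an attached
#'   ensemble.
#' @param freqs a `ContactFrequencies` for the group.
#' @param path output PDB file.
#' @param frame optional list(traj, frame); default: the representative frame.
#' @return `path`, invisibly.
#' @export
bfactor_heatmap_pdb <- function(group, freqs, path, frame = NULL) {
  if (is.null(group$interface_split)) {
    stop("group has no interface split; bfactor heatmaps need an interface ContactGroup")
  }
  if (is.null(group$ensemble)) {
    stop("group carries no coordinate ensemble (was it deserialized?); re-attach one")
  }
  if (is.null(frame)) frame <- select_representative_frame(group)
  part <- per_residue_participation(freqs, group)
  sign_v <- numeric(length(part))
  sign_v[group$interface_split$A] <- -1
  sign_v[group$interface_split$B] <- 1
  res_b <- part * sign_v
  b_at <- res_b[group$topology$atoms$residue]
  xyz <- group$ensemble$xyz[[frame$traj]][frame$frame, , ]
  write_pdb(group$topology, xyz, path, bfactors = b_at,
            box = if (!is.null(group$ensemble$box))
              group$ensemble$box[[frame$traj]])
  invisible(path)
}

# ---- cross-system comparison ----------------------------------------------

#' Compare contact frequencies across systems
#'
#' Merges per-pair frequencies from several ContactGroups into one table keyed
#' by rendered pair labels. With `key_mode = "consensus_label"` the keys use
#' consensus tags, so homologous systems with different author numbering align
#' on the same rows; pairs absent from a system are explicit `NA` gaps, never
#' 0. Violin data pools the per-system distance samples per key and marks each
#' system's representative-frame distance.
#'
#' @param groups named list (>= 2) of `ContactGroup`s.
#' @param cutoff cutoff in Angstrom.
#' @param key_mode `"consensus_label"` or `"residue_name"`.
#' @return object of class `ContactComparison`: `table` (key + one frequency
#'   column per system), `violins` (list key -> system -> distances in
#'   Angstrom), `representatives` (key x system matrix of representative-frame
#'   distances, Angstrom).
#' @export
compare_groups <- function(groups, cutoff = 4.5,
                           key_mode = c("consensus_label", "residue_name")) {
  key_mode <- match.arg(key_mode)
  stopifnot(length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- sprintf("system_%d", seq_along(groups))
  }
  per_sys <- lapply(groups, function(g) {
    fr <- compute_frequencies(g, cutoff)
    labs <- pair_labels(g, key_mode)
    key <- paste(labs[, 1L], labs[, 2L], sep = "-")
    rep_fr <- select_representative_frame(g)
    rep_d <- vapply(seq_len(nrow(g$pairs)), function(p) {
      g$dist[[p]][[rep_fr$traj]][rep_fr$frame] * 10
    }, numeric(1))
    pooled <- lapply(seq_len(nrow(g$pairs)), function(p) {
      unlist(g$dist[[p]]) * 10
    })
    list(key = key, freq = fr$freq, rep_d = rep_d, pooled = pooled)
  })
  keys <- unique(unlist(lapply(per_sys, `[[`, "key")))
  shared <- Reduce(intersect, lapply(per_sys, `[[`, "key"))
  if (!length(shared)) {
    stop(sprintf(
      "no shared pair keys between systems under key_mode '%s'; try key_mode '%s'",
      key_mode,
      setdiff(c("consensus_label", "residue_name"), key_mode)))
  }
  tab <- data.frame(key = keys, stringsAsFactors = FALSE)
  for (nm in names(per_sys)) {
    s <- per_sys[[nm]]
    tab[[nm]] <- s$freq[match(keys, s$key)]
  }
  viol <- lapply(keys, function(k) {
    out <- lapply(per_sys, function(s) {
      hit <- match(k, s$key)
      if (is.na(hit)) NULL else s$pooled[[hit]]
    })
    out[!vapply(out, is.null, logical(1))]
  })
  names(viol) <- keys
  reps <- vapply(per_sys, function(s) {
    s$rep_d[match(keys, s$key)]
  }, numeric(length(keys)))
  reps <- matrix(reps, nrow = length(keys),
                 dimnames = list(keys, names(per_sys)))
  structure(list(table = tab, violins = viol, representatives = reps,
                 cutoff = cutoff, key_mode = key_mode),
            class = "ContactComparison")
}

#' @export
print.ContactComparison <- function(x, ...) {
  cat(sprintf("ContactComparison (%s, %.2f Ang): %d keys x %d systems\n",
              x$key_mode, x$cutoff, nrow(x$table), ncol(x$table) - 1L))
  print(utils::head(x$table, 10L))
  invisible(x)
}
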