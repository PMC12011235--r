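# Fragmentation heuristics: partition a topology into named fragments without
# trusting the PDB chain field (which may be wrong or absent, as in GRO).
# Criteria: sequence jumps in resSeq, presence/absence of bonds, and residue
# names (protein vs non-protein, ion, water).

.FRAG_METHODS <- c("default", "chains", "resSeq", "bonds", "resSeq_bonds",
                   "molecule_type")

.new_fragmentation <- function(method, residue_sets, names = NULL) {
  residue_sets <- lapply(residue_sets, function(x) sort(unique(as.integer(x))))
  keep <- lengths(residue_sets) > 0L
  residue_sets <- residue_sets[keep]
  ord <- order(vapply(residue_sets, min, integer(1)))
  residue_sets <- residue_sets[ord]
  if (is.null(names)) {
    names <- sprintf("frag %d", seq_along(residue_sets) - 1L)
  } else {
    names <- names[keep][ord]
  }
  structure(list(method = method,
                 fragments = setNames(residue_sets, names)),
            class = "Fragmentation")
}

#' @export
print.Fragmentation <- function(x, ...) {
  cat(sprintf("Fragmentation (%s): %d fragments\n", x$method,
              length(x$fragments)))
  for (nm in names(x$fragments)) {
    f <- x$fragments[[nm]]
    cat(sprintf("  %-12s %4d residues [%d..%d]\n", nm, length(f),
                min(f), max(f)))
  }
  invisible(x)
}

# break vector: TRUE at position k means a break between residues k and k+1
.breaks_resseq <- function(topology) {
  rs <- topology$residues$resSeq
  n <- length(rs)
  if (n < 2L) return(logical(0))
  rs[-1L] != rs[-n] + 1L
}

.breaks_bonds <- function(topology) {
  n <- n_residues(topology)
  if (n < 2L) return(logical(0))
  direct <- matrix(FALSE, 1L, n - 1L)
  if (nrow(topology$bonds)) {
    ra <- topology$atoms$residue[topology$bonds[, 1L]]
    rb <- topology$atoms$residue[topology$bonds[, 2L]]
    adj <- abs(ra - rb) == 1L
    direct[pmin(ra, rb)[adj]] <- TRUE
  }
  !as.vector(direct)
}

.runs_to_sets <- function(breaks, n) {
  grp <- cumsum(c(TRUE, breaks))
  split(seq_len(n), grp)
}

#' Partition a topology into fragments
#'
#' Methods:
#' * `chains` — group by the file's chain identifier (errors when absent).
#' * `resSeq` — break wherever the author numbering is not consecutive
#'   (a gap, a restart or a duplicate all count as breaks).
#' * `bonds` — connected components of the residue-level bond graph, ordered
#'   by smallest member.
#' * `resSeq_bonds` — break where either criterion breaks between consecutive
#'   residues; a refinement of both parents.
#' * `molecule_type` — contiguous runs of equal molecule class.
#' * `default` — `resSeq_bonds`, then every non-protein residue that forms its
#'   own bond component (free ligands, ions, waters) is detached into a
#'   per-molecule fragment appended at the end. With `merge_solvent = TRUE`
#'   waters and ions are merged into a single "solvent" fragment instead.
#'
#' Every method yields a partition: fragments are pairwise disjoint and their
#' union is all residues. Fragmentation depends only on the topology, never on
#' coordinates.
#'
#' @param topology a [Topology].
#' @param method one of `r paste0('"', .FRAG_METHODS, '"', collapse = ", ")`.
#' @param merge_solvent merge detached waters/ions into one fragment
#'   (`default` method only).
#' @return object of class `Fragmentation`.
#' @export
fragment_topology <- function(topology, method = "default",
                              merge_solvent = FALSE) {
  method <- match.arg(method, .FRAG_METHODS)
  n <- n_residues(topology)
  res <- topology$residues
  if (method == "chains") {
    if (anyNA(res$chain)) {
      stop(paste("topology has no chain identifiers; try methods 'bonds',",
                 "'resSeq_bonds' or 'default' instead"))
    }
    sets <- split(seq_len(n), res$chain)
    return(.new_fragmentation("chains", sets))
  }
  if (method == "resSeq") {
    return(.new_fragmentation("resSeq", .runs_to_sets(.breaks_resseq(topology), n)))
  }
  if (method == "bonds") {
    comp <- residue_bond_components(topology)
    return(.new_fragmentation("bonds", split(seq_len(n), comp)))
  }
  if (method == "resSeq_bonds") {
    br <- .breaks_resseq(topology) | .breaks_bonds(topology)
    return(.new_fragmentation("resSeq_bonds", .runs_to_sets(br, n)))
  }
  if (method == "molecule_type") {
    cls <- res$molecule_class
    br <- cls[-1L] != cls[-n]
    if (n == 1L) br <- logical(0)
    return(.new_fragmentation("molecule_type", .runs_to_sets(br, n)))
  }
  # default: resSeq_bonds, then detach free non-protein molecules
  br <- .breaks_resseq(topology) | .breaks_bonds(topology)
  base <- .runs_to_sets(br, n)
  comp <- residue_bond_components(topology)
  comp_size <- table(comp)
  free <- which(res$molecule_class != "protein" &
                  comp_size[as.character(comp)] == 1L)
  kept <- lapply(base, function(s) setdiff(s, free))
  kept <- kept[lengths(kept) > 0L]
  kept <- kept[order(vapply(kept, min, integer(1)))]
  names_kept <- sprintf("frag %d", seq_along(kept) - 1L)
  if (merge_solvent) {
    solv <- free[res$molecule_class[free] %in% c("water", "ion")]
    other <- setdiff(free, solv)
    extra <- lapply(other, identity)
    extra_names <- residue_display(topology, unlist(other), short = FALSE)
    if (length(solv)) {
      extra <- c(extra, list(sort(solv)))
      extra_names <- c(extra_names, "solvent")
    }
  } else {
    extra <- lapply(free, identity)
    extra_names <- if (length(free)) {
      residue_display(topology, free, short = FALSE)
    } else character(0)
  }
  frags <- c(kept, extra)
  nms <- c(names_kept, extra_names)
  structure(list(method = "default",
                 fragments = setNames(lapply(frags, as.integer), nms)),
            class = "Fragmentation")
}

#' Rename fragments
#'
#' Default names are `"frag 0"`, `"frag 1"`, ...; user names override
#' positionally and must match the fragment count.
#'
#' @param fragmentation a `Fragmentation`.
#' @param user_names character vector, one name per fragment, or `NULL` to
#'   reset to defaults.
#' @return the renamed `Fragmentation`.
#' @export
name_fragments <- function(fragmentation, user_names = NULL) {
  nf <- length(fragmentation$fragments)
  if (is.null(user_names)) {
    names(fragmentation$fragments) <- sprintf("frag %d", seq_len(nf) - 1L)
    return(fragmentation)
  }
  if (length(user_names) != nf) {
    stop(sprintf("%d fragment names supplied for %d fragments",
                 length(user_names), nf))
  }
  names(fragmentation$fragments) <- user_names
  fragmentation
}

#' Fragment containing each residue
#' @param fragmentation a `Fragmentation`.
#' @param res_index residue indices (vectorized).
#' @return character vector of fragment names (`NA` if unassigned).
#' @export
fragment_of <- function(fragmentation, res_index) {
  map <- rep(NA_character_, max(unlist(fragmentation$fragments), 0L))
  for (nm in names(fragmentation$fragments)) {
    map[fragmentation$fragments[[nm]]] <- nm
  }
  map[res_index]
}

#' Text overview of all fragmentation heuristics
#'
#' One section per method, listing for each fragment the residue count and its
#' first/last residue as `name@resSeq`. Methods that do not apply (e.g.
#' `chains` on a chain-less GRO topology) report so instead of erroring, so
#' the overview is total.
#'
#' @param topology a [Topology].
#' @return character vector of report lines, invisibly printed by default.
#' @export
fragment_overview <- function(topology) {
  out <- character(0)
  for (m in .FRAG_METHODS) {
    out <- c(out, sprintf("method '%s':", m))
    fr <- tryCatch(fragment_topology(topology, m), error = function(e) e)
    if (inherits(fr, "error")) {
      out <- c(out, sprintf("  not applicable: %s", conditionMessage(fr)))
      next
    }
    for (nm in names(fr$fragments)) {
      f <- fr$fragments[[nm]]
      first <- residue_display(topology, min(f), short = FALSE)
      last <- residue_display(topology, max(f), short = FALSE)
      out <- c(out, sprintf("  %-14s %5d residues  %s-%s",
                            nm, length(f), first, last))
    }
  }
  class(out) <- "fragment_overview"
  out
}

#' @export
print.fragment_overview <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
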