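# User-facing residue selection grammar: comma-separated terms mixing residue
# name+number ("L394"), name wildcards ("GLU*"), resSeq ranges ("380-394"),
# consensus labels ("3.50") and wildcards ("3.5*", "TM*", "ICL*", "G.H*"),
# ligand codes ("P0G", "GDP") and fragment names ("frag 0"). Parsing is total:
# a term that resolves to nothing raises, never silently drops.

.as_assignment_list <- function(assignments) {
  if (is.null(assignments)) return(list())
  if (inherits(assignments, "LabelAssignment")) return(list(assignments))
  assignments
}

.near_misses <- function(term, topology) {
  cand <- unique(c(topology$residues$name,
                   residue_display(topology, seq_len(n_residues(topology)))))
  hits <- unique(c(
    cand[startsWith(tolower(cand), tolower(substr(term, 1, 2)))],
    utils::head(agrep(term, cand, value = TRUE, max.distance = 0.3), 5L)))
  utils::head(hits, 6L)
}

# resolve one term to residue indices; returns integer vector (may need
# disambiguation downstream). `via` is filled with a short description.
.resolve_term <- function(term, topology, fragmentation, assignments,
                          env) {
  res <- topology$residues
  alist <- .as_assignment_list(assignments)

  # 1. exact consensus label
  for (a in alist) {
    hit <- a$table$res_index[a$table$label == term]
    if (length(hit)) {
      env$via <- sprintf("consensus label %s", term)
      return(hit)
    }
  }
  # 2. wildcards: consensus labels / consensus fragments first, then names
  if (grepl("\\*", term, fixed = FALSE)) {
    rx <- utils::glob2rx(term)
    for (a in alist) {
      hit <- a$table$res_index[grepl(rx, a$table$label)]
      if (length(hit)) {
        env$via <- sprintf("consensus label glob %s", term)
        return(sort(unique(hit)))
      }
      cf <- consensus_fragments(a)
      fr_hit <- grep(rx, names(cf))
      if (length(fr_hit)) {
        env$via <- sprintf("consensus fragment(s) %s",
                           paste(names(cf)[fr_hit], collapse = ","))
        return(sort(unique(unlist(cf[fr_hit]))))
      }
    }
    hit <- which(grepl(rx, toupper(res$name)))
    if (length(hit)) {
      env$via <- sprintf("residue name glob %s", term)
      return(hit)
    }
    return(integer(0))
  }
  # 3. fragment name
  if (!is.null(fragmentation) && term %in% names(fragmentation$fragments)) {
    env$via <- sprintf("fragment %s", term)
    return(fragmentation$fragments[[term]])
  }
  # 4. resSeq range (fragment-scoped; a residue matches inside whichever
  # fragment it sits in, so ranges never bleed across resSeq restarts)
  if (grepl("^[0-9]+-[0-9]+$", term)) {
    lim <- as.integer(strsplit(term, "-")[[1L]])
    lo <- min(lim); hi <- max(lim)
    sets <- if (!is.null(fragmentation)) fragmentation$fragments else
      list(seq_len(nrow(res)))
    hit <- integer(0)
    for (s in sets) {
      hit <- c(hit, s[res$resSeq[s] >= lo & res$resSeq[s] <= hi])
    }
    env$via <- sprintf("resSeq range %d-%d", lo, hi)
    return(sort(unique(hit)))
  }
  # 5. one-letter code + resSeq ("L394", "R131")
  m <- regmatches(term, regexec("^([A-Za-z])([0-9]+)$", term))[[1L]]
  if (length(m) == 3L) {
    hit <- which(aa_one(res$name) == toupper(m[2L]) &
                   res$resSeq == as.integer(m[3L]))
    if (length(hit)) {
      env$via <- sprintf("residue %s", term)
      return(hit)
    }
  }
  # 6. residue name + resSeq ("GLU394", "GDP395")
  m <- regmatches(term,
                  regexec("^([A-Za-z][A-Za-z0-9]{1,3}?)([0-9]+)$",
                          term))[[1L]]
  if (length(m) == 3L) {
    hit <- which(toupper(res$name) == toupper(m[2L]) &
                   res$resSeq == as.integer(m[3L]))
    if (length(hit)) {
      env$via <- sprintf("residue %s", term)
      return(hit)
    }
  }
  # 7. bare residue / ligand code ("P0G", "GDP"): all copies
  hit <- which(toupper(res$name) == toupper(term))
  if (length(hit)) {
    env$via <- sprintf("residue name %s", term)
    return(hit)
  }
  integer(0)
}

#' Expand a selection expression to residue indices
#'
#' @param expr selection string, comma-separated terms (see the package
#'   vignette for the grammar), or a character vector of terms.
#' @param topology a [Topology].
#' @param fragmentation optional `Fragmentation` (enables fragment-name terms
#'   and fragment-scoped ranges).
#' @param assignments optional `LabelAssignment`(s) (enables consensus terms;
#'   a consensus match takes precedence over a residue-name match, with a
#'   notice).
#' @return list with `indices` (ordered, deduplicated union over terms) and
#'   `report` (data.frame: term, how it resolved, match count).
#' @export
expand_selection <- function(expr, topology, fragmentation = NULL,
                             assignments = NULL) {
  terms <- if (length(expr) > 1L) expr else
    trimws(strsplit(expr, ",", fixed = TRUE)[[1L]])
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("empty selection expression")
  idx <- integer(0)
  report <- data.frame(term = character(0), via = character(0),
                       n = integer(0), stringsAsFactors = FALSE)
  for (tm in terms) {
    env <- new.env()
    env$via <- "unresolved"
    hit <- .resolve_term(tm, topology, fragmentation, assignments, env)
    if (!length(hit)) {
      near <- .near_misses(tm, topology)
      stop(sprintf("selection term '%s' matches no residue%s", tm,
                   if (length(near)) paste0("; near misses: ",
                                            paste(near, collapse = ", "))
                   else ""))
    }
    report <- rbind(report,
                    data.frame(term = tm, via = env$via, n = length(hit),
                               stringsAsFactors = FALSE))
    idx <- c(idx, hit)
  }
  list(indices = unique(idx), report = report)
}

#' Resolve equally-named residue candidates to a single residue
#'
#' Interactive mode prompts with the fragment and serial index of each
#' candidate (re-prompting on out-of-range input); non-interactive mode (and
#' interactive mode without a TTY, with a warning) deterministically picks the
#' candidate in the lowest-indexed fragment and logs a notice.
#'
#' @param candidates integer vector of residue indices sharing a display name.
#' @param topology a [Topology].
#' @param fragmentation a `Fragmentation`.
#' @param mode `"auto"` (non-interactive) or `"interactive"`.
#' @return a single residue index.
#' @export
disambiguate <- function(candidates, topology, fragmentation,
                         mode = c("auto", "interactive")) {
  mode <- match.arg(mode)
  if (length(candidates) == 1L) return(candidates)
  fr <- fragment_of(fragmentation, candidates)
  fr_pos <- match(fr, names(fragmentation$fragments))
  if (mode == "interactive") {
    if (!interactive()) {
      warning("no interactive session; falling back to the non-interactive default")
      mode <- "auto"
    }
  }
  if (mode == "interactive") {
    repeat {
      for (k in seq_along(candidates)) {
        cat(sprintf("  [%d] %s (residue %d, fragment %s)\n", k,
                    residue_display(topology, candidates[k]),
                    candidates[k], fr[k]))
      }
      ans <- suppressWarnings(as.integer(readline("pick a residue: ")))
      if (!is.na(ans) && ans >= 1L && ans <= length(candidates)) {
        return(candidates[ans])
      }
      cat("out of range, try again\n")
    }
  }
  pick <- candidates[order(fr_pos, candidates)][1L]
  message(sprintf(
    "note: '%s' is ambiguous (%d candidates); using the copy in fragment '%s' (residue %d)",
    residue_display(topology, pick), length(candidates),
    fragment_of(fragmentation, pick), pick))
  pick
}

# resolve a selection term to exactly one residue (for site pairs/anchors)
.resolve_single <- function(term, topology, fragmentation, assignments,
                            mode = "auto") {
  hit <- expand_selection(term, topology, fragmentation, assignments)$indices
  if (length(hit) > 1L) {
    hit <- disambiguate(hit, topology, fragmentation, mode)
  }
  hit
}

#' Read site definitions from a JSON file
#'
#' A site file holds one object or a list of objects with fields `name` and
#' `pairs` (strings `"termA-termB"`, each term any selection term without an
#' internal dash — consensus labels like `"G.H5.23"` are fine). Self-pairs are
#' rejected. Pairs are resolved lazily, against the actual topology, by
#' [sites_contacts()].
#'
#' @param path JSON file.
#' @return list of objects of class `Site`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$name)) raw <- list(raw)
  out <- lapply(seq_along(raw), function(k) {
    s <- raw[[k]]
    if (is.null(s$name) || is.null(s$pairs) || !length(s$pairs)) {
      stop(sprintf("site %d in '%s' lacks a name or pairs", k, path))
    }
    pairs <- vapply(s$pairs, as.character, character(1))
    parsed <- lapply(seq_along(pairs), function(i) {
      p <- pairs[i]
      terms <- .split_pair_terms(p)
      if (is.null(terms)) {
        stop(sprintf("malformed pair '%s' in site '%s' (%s)",
                     p, s$name, path))
      }
      if (identical(terms[1L], terms[2L])) {
        stop(sprintf("self-pair '%s' in site '%s' (%s)", p, s$name, path))
      }
      terms
    })
    structure(list(name = as.character(s$name), pairs = parsed),
              class = "Site")
  })
  out
}

# split "termA-termB" on the dash that separates two valid terms; terms
# themselves never contain a dash (ranges are not allowed inside site pairs)
.split_pair_terms <- function(p) {
  parts <- strsplit(p, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !all(nzchar(trimws(parts)))) return(NULL)
  trimws(parts)
}

#' Resolve a Site to residue-index pairs
#'
#' @param site a `Site`.
#' @param topology a [Topology].
#' @param fragmentation optional `Fragmentation`.
#' @param assignments optional `LabelAssignment`(s).
#' @return two-column integer matrix, one row per pair.
#' @export
resolve_site <- function(site, topology, fragmentation = NULL,
                         assignments = NULL) {
  stopifnot(inherits(site, "Site"))
  rows <- lapply(site$pairs, function(terms) {
    a <- .resolve_single(terms[1L], topology, fragmentation, assignments)
    b <- .resolve_single(terms[2L], topology, fragmentation, assignments)
    if (a == b) {
      stop(sprintf("pair %s-%s resolves to a single residue in site '%s'",
                   terms[1L], terms[2L], site$name))
    }
    c(a, b)
  })
  do.call(rbind, rows)
}
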