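# Offline consensus-label machinery. Reference tables (CSV or Excel) carry a
# reference sequence with per-position consensus labels (GPCRdb "x.y", CGN
# dotted labels, KLIFS short codes) and fragment names (TM3, ICL2, G.H5, ...).
# Labels are transferred onto arbitrary topologies by global pairwise sequence
# alignment with free end gaps; labels are stored verbatim and never parsed
# for meaning beyond the fragment column.

.CONSENSUS_SCHEMES <- c("GPCR", "CGN", "KLIFS")

#' Construct a ConsensusMap
#'
#' @param table data.frame with columns `residue` (one-letter code),
#'   `position` (1-based reference position), `label` (consensus label) and
#'   `fragment` (consensus fragment name).
#' @param scheme one of `"GPCR"`, `"CGN"`, `"KLIFS"`.
#' @param source free-text source identifier (metadata only, e.g. a
#'   UniProt-style name).
#' @return object of class `ConsensusMap`.
#' @export
consensus_map <- function(table, scheme = "GPCR", source = "local") {
  scheme <- match.arg(scheme, .CONSENSUS_SCHEMES)
  need <- c("residue", "position", "label", "fragment")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop(sprintf("consensus table lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  table <- table[order(table$position), need]
  table$position <- as.integer(table$position)
  table$residue <- toupper(as.character(table$residue))
  table$label <- as.character(table$label)
  table$fragment <- as.character(table$fragment)
  bad <- which(is.na(table$position) | !nzchar(table$label) |
                 nchar(table$residue) != 1L)
  if (length(bad)) {
    stop(sprintf("malformed consensus table row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  dup <- table$label[duplicated(table$label)]
  if (length(dup)) {
    stop(sprintf("duplicate consensus label(s): %s",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(duplicated(table$position))) {
    stop("duplicate reference positions in consensus table")
  }
  # labeled positions need not be contiguous; the reference sequence spans
  # min..max position with X at unlabeled positions
  span <- seq(min(table$position), max(table$position))
  seq1 <- rep("X", length(span))
  seq1[match(table$position, span)] <- table$residue
  structure(list(scheme = scheme, source = source, table = table,
                 offset = min(table$position) - 1L,
                 reference_sequence = paste(seq1, collapse = "")),
            class = "ConsensusMap")
}

#' @export
print.ConsensusMap <- function(x, ...) {
  cat(sprintf("ConsensusMap (%s, source %s): %d labels, fragments: %s\n",
              x$scheme, x$source, nrow(x$table),
              paste(unique(x$table$fragment), collapse = ", ")))
  invisible(x)
}

#' Read a consensus nomenclature table from CSV or Excel
#'
#' Expected columns (case-insensitive): `residue`, `position`, `label`,
#' `fragment`. CSV and Excel encodings of the same table yield identical maps.
#'
#' @param path `.csv`, `.xlsx` or `.xls` file.
#' @param scheme consensus scheme; guessed from the label grammar when `NULL`
#'   (dotted `G.` labels are CGN, labels with a lowercase letter or `xDFG`
#'   style are KLIFS, plain `x.y` numerics are GPCR).
#' @param source source identifier; defaults to the file name.
#' @return a `ConsensusMap`.
#' @export
read_consensus_table <- function(path, scheme = NULL, source = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  # labels like "5.50" must never be parsed as numbers ("5.5"): read all
  # columns as text and convert explicitly
  df <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character")
  } else if (ext %in% c("xlsx", "xls")) {
    as.data.frame(readxl::read_excel(path, col_types = "text"),
                  stringsAsFactors = FALSE)
  } else {
    stop(sprintf("unsupported consensus table format '.%s'", ext))
  }
  names(df) <- tolower(names(df))
  if (is.null(scheme)) {
    labs <- as.character(df$label)
    scheme <- if (any(startsWith(labs, "G."))) "CGN"
      else if (any(grepl("[a-z]", labs))) "KLIFS"
      else "GPCR"
  }
  if (is.null(source)) source <- basename(path)
  consensus_map(df, scheme = scheme, source = source)
}

#' Placeholder for online nomenclature retrieval
#'
#' Live lookups of GPCRdb / CGN / KLIFS entries are intentionally not
#' performed. The offline path is [read_consensus_table()] on a locally
#' stored table file.
#'
#' @param name database entry name (e.g. a UniProt-style identifier).
#' @param scheme consensus scheme.
#' @export
fetch_consensus_table <- function(name, scheme = "GPCR") {
  stop(sprintf(
    paste("online nomenclature lookup ('%s', scheme %s) is not available;",
          "store the table locally and use read_consensus_table()"),
    name, scheme))
}

# alignment scoring: match +1, mismatch -1, gap open 3, gap extend 0.5,
# global with free end gaps ("overlap"). X marks unlabeled reference spacer
# positions and aligns neutrally (0): it neither matches nor penalizes.
.align_sub_matrix <- function() {
  m <- matrix(-1L, 26L, 26L, dimnames = list(LETTERS, LETTERS))
  diag(m) <- 1L
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
}

#' Transfer consensus labels onto a topology fragment by pairwise alignment
#'
#' The fragment's one-letter sequence is aligned globally (free end gaps)
#' against the map's reference sequence; labels transfer across aligned
#' columns (identical or substituted residues), while residues aligned to gaps
#' stay unlabeled. Alignments below the identity floor over aligned columns
#' yield a warning and an empty assignment rather than silent mislabeling.
#'
#' @param cmap a `ConsensusMap`.
#' @param topology a [Topology].
#' @param fragment integer vector of residue indices (a protein fragment), or
#'   a single fragment name resolved against `fragmentation`.
#' @param fragmentation optional `Fragmentation` (needed when `fragment` is a
#'   name).
#' @param min_identity identity floor over aligned columns (default 0.3).
#' @return object of class `LabelAssignment` with `table` (res_index, label,
#'   fragment, ref_pos), `unmapped`, `alignment` (the two gapped strings) and
#'   `identity`.
#' @export
assign_labels <- function(cmap, topology, fragment,
                          fragmentation = NULL, min_identity = 0.3) {
  stopifnot(inherits(cmap, "ConsensusMap"))
  if (is.character(fragment) && length(fragment) == 1L) {
    if (is.null(fragmentation)) {
      stop("a Fragmentation is required to resolve a fragment by name")
    }
    if (!fragment %in% names(fragmentation$fragments)) {
      stop(sprintf("unknown fragment '%s'", fragment))
    }
    fragment <- fragmentation$fragments[[fragment]]
  }
  fragment <- sort(unique(as.integer(fragment)))
  empty <- structure(list(scheme = cmap$scheme,
                          table = data.frame(res_index = integer(0),
                                             label = character(0),
                                             fragment = character(0),
                                             ref_pos = integer(0),
                                             stringsAsFactors = FALSE),
                          unmapped = fragment, alignment = NULL,
                          identity = 0),
                     class = "LabelAssignment")
  prot <- fragment[topology$residues$molecule_class[fragment] == "protein"]
  if (!length(prot)) {
    warning("fragment contains no protein residues; empty assignment")
    return(empty)
  }
  qseq <- paste(aa_one(topology$residues$name[prot]), collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    qseq, cmap$reference_sequence, type = "overlap",
    substitutionMatrix = .align_sub_matrix(),
    gapOpening = 3, gapExtension = 0.5)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  if (!length(ap)) {
    warning(sprintf(
      "alignment against %s reference '%s' is degenerate; empty assignment",
      cmap$scheme, cmap$source))
    return(empty)
  }
  qi <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  si <- Biostrings::start(Biostrings::subject(pa)) - 1L
  q_pos <- integer(0)
  s_pos <- integer(0)
  n_match <- 0L
  n_alncol <- 0L
  for (k in seq_along(ap)) {
    if (ap[k] != "-") qi <- qi + 1L
    if (as_[k] != "-") si <- si + 1L
    if (ap[k] != "-" && as_[k] != "-") {
      # X marks unlabeled reference spacer positions: aligned for transfer,
      # but excluded from the identity computation
      if (as_[k] != "X") {
        n_alncol <- n_alncol + 1L
        if (ap[k] == as_[k]) n_match <- n_match + 1L
      }
      q_pos <- c(q_pos, qi)
      s_pos <- c(s_pos, si)
    }
  }
  identity <- if (n_alncol) n_match / n_alncol else 0
  if (identity < min_identity) {
    warning(sprintf(
      "alignment identity %.0f%% below the %.0f%% floor for %s '%s'; empty assignment",
      100 * identity, 100 * min_identity, cmap$scheme, cmap$source))
    empty$identity <- identity
    return(empty)
  }
  ref_pos <- s_pos + cmap$offset
  hit <- match(ref_pos, cmap$table$position)
  keep <- !is.na(hit)
  tab <- data.frame(res_index = prot[q_pos[keep]],
                    label = cmap$table$label[hit[keep]],
                    fragment = cmap$table$fragment[hit[keep]],
                    ref_pos = ref_pos[keep],
                    stringsAsFactors = FALSE)
  structure(list(scheme = cmap$scheme, table = tab,
                 unmapped = setdiff(fragment, tab$res_index),
                 alignment = c(pattern = paste(ap, collapse = ""),
                               subject = paste(as_, collapse = "")),
                 identity = identity),
            class = "LabelAssignment")
}

#' @export
print.LabelAssignment <- function(x, ...) {
  cat(sprintf(
    "LabelAssignment (%s): %d residues labeled, %d unmapped, identity %.0f%%\n",
    x$scheme, nrow(x$table), length(x$unmapped), 100 * x$identity))
  invisible(x)
}

#' Consensus fragments present in an assignment
#'
#' @param assignment a `LabelAssignment`.
#' @param pattern optional glob over fragment names (`"TM*"`, `"ICL*"`,
#'   `"G.H*"`); `NULL` returns all.
#' @return named list of integer residue-index vectors, in reference order.
#'   Unknown names/globs yield an empty list with a warning.
#' @export
consensus_fragments <- function(assignment, pattern = NULL) {
  tab <- assignment$table
  frags <- split(tab$res_index[order(tab$ref_pos)],
                 tab$fragment[order(tab$ref_pos)])
  # preserve reference order of fragments
  first <- vapply(frags, function(x) min(match(x, tab$res_index)), numeric(1))
  frags <- frags[order(first)]
  if (is.null(pattern)) return(frags)
  hits <- unlist(lapply(pattern, function(p) {
    grep(utils::glob2rx(p), names(frags), value = TRUE)
  }))
  if (!length(hits)) {
    warning(sprintf("no consensus fragment matches '%s'",
                    paste(pattern, collapse = ",")))
    return(list())
  }
  frags[unique(hits)]
}

#' Render a residue display label, consensus-tagged when available
#'
#' Labeled residues render as `"R131@3.50"`; unlabeled ones fall back to
#' `"NAME+resSeq@fragment"` when `fragmentation` is given, else bare
#' `"NAME+resSeq"`.
#'
#' @param topology a [Topology].
#' @param res_index residue indices (vectorized).
#' @param assignments a `LabelAssignment`, or a (named) list of them, or
#'   `NULL`.
#' @param fragmentation optional `Fragmentation` for the fallback tag.
#' @param tag_fragment append the plain fragment name for unlabeled residues.
#' @return character vector of labels.
#' @export
render_residue_label <- function(topology, res_index, assignments = NULL,
                                 fragmentation = NULL, tag_fragment = FALSE) {
  base <- residue_display(topology, res_index)
  out <- base
  if (!is.null(assignments)) {
    if (inherits(assignments, "LabelAssignment")) {
      assignments <- list(assignments)
    }
    for (a in assignments) {
      hit <- match(res_index, a$table$res_index)
      lab <- !is.na(hit)
      out[lab] <- paste0(base[lab], "@", a$table$label[hit[lab]])
    }
  }
  if (tag_fragment && !is.null(fragmentation)) {
    plain <- out == base
    fr <- fragment_of(fragmentation, res_index)
    use <- plain & !is.na(fr)
    out[use] <- paste0(base[use], "@", fr[use])
  }
  out
}

#' Consensus labels as a de-facto multiple sequence alignment
#'
#' One column per consensus label present in any assignment (in reference
#' order), one row per system; cells hold residue display names, `NA` marks a
#' gap. Columns are keyed purely by label, never by author residue numbers,
#' so systems with clashing or shifted numbering align correctly.
#'
#' @param assignments named list of `LabelAssignment`s (same scheme).
#' @param topologies list of the matching [Topology] objects.
#' @return data.frame: rows = systems, columns = labels.
#' @export
labels_as_msa <- function(assignments, topologies) {
  stopifnot(length(assignments) == length(topologies),
            length(assignments) >= 1L)
  schemes <- unique(vapply(assignments, function(a) a$scheme, character(1)))
  if (length(schemes) > 1L) {
    stop(sprintf("assignments mix consensus schemes: %s",
                 paste(schemes, collapse = ", ")))
  }
  all_tabs <- lapply(assignments, function(a) a$table)
  labs <- unique(do.call(rbind, all_tabs)[, c("label", "ref_pos")])
  labs <- labs[order(labs$ref_pos), ]
  out <- matrix(NA_character_, nrow = length(assignments),
                ncol = nrow(labs),
                dimnames = list(names(assignments), labs$label))
  for (k in seq_along(assignments)) {
    tab <- all_tabs[[k]]
    hit <- match(labs$label, tab$label)
    ok <- !is.na(hit)
    out[k, ok] <- residue_display(topologies[[k]], tab$res_index[hit[ok]])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Text overview of a consensus map against a topology
#'
#' Mirrors the offline mode of the nomenclature-overview tools: prints the
#' map's fragments and, when a topology is given, the label transfer obtained
#' on its protein fragments.
#'
#' @param cmap a `ConsensusMap`.
#' @param topology optional [Topology].
#' @param fragmentation optional `Fragmentation` (defaults to the `default`
#'   heuristic).
#' @return character vector of report lines.
#' @export
nomenclature_overview <- function(cmap, topology = NULL,
                                  fragmentation = NULL) {
  out <- sprintf("%s nomenclature, source %s: %d labels",
                 cmap$scheme, cmap$source, nrow(cmap$table))
  for (fr in unique(cmap$table$fragment)) {
    sub <- cmap$table[cmap$table$fragment == fr, ]
    out <- c(out, sprintf("  %-10s %3d labels  %s..%s", fr, nrow(sub),
                          sub$label[1L], sub$label[nrow(sub)]))
  }
  if (!is.null(topology)) {
    if (is.null(fragmentation)) fragmentation <- fragment_topology(topology)
    for (nm in names(fragmentation$fragments)) {
      fres <- fragmentation$fragments[[nm]]
      if (!any(topology$residues$molecule_class[fres] == "protein")) next
      a <- suppressWarnings(assign_labels(cmap, topology, fres))
      if (nrow(a$table)) {
        out <- c(out, sprintf(
          "  fragment %-12s %3d/%3d residues labeled (identity %.0f%%), %s..%s",
          nm, nrow(a$table), length(fres), 100 * a$identity,
          a$table$label[1L], a$table$label[nrow(a$table)]))
      } else {
        out <- c(out, sprintf("  fragment %-12s no labels transferred", nm))
      }
    }
  }
  out
}
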