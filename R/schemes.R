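# Distance schemes: which atoms of each residue enter the residue-residue
# minimum-distance computation. The default ("closest_heavy") takes the
# minimum over all heavy-atom cross pairs, matching the 4.5 Angstrom default
# cutoff at the user surface.

.SCHEMES <- c("closest_heavy", "closest", "ca", "sidechain",
              "sidechain_heavy", "com")

#' Atoms of a residue selected by a distance scheme
#'
#' * `closest` — all atoms.
#' * `closest_heavy` (default) — heavy atoms only.
#' * `ca` — the single CA atom of a protein residue; non-protein residues
#'   fall back to their heavy atoms with a warning.
#' * `sidechain`, `sidechain_heavy` — sidechain atoms (all / heavy); residues
#'   with an empty sidechain selection (glycine, and any non-protein residue
#'   whose atoms are all classified backbone) fall back to the full heavy-atom
#'   set with a warning, so the scheme is total. Set
#'   `options(contactlens.strict_schemes = TRUE)` to turn the fallback into an
#'   error.
#' * `com` — heavy atoms; the distance uses their mass-weighted centroid.
#'
#' @param topology a [Topology].
#' @param res_index residue index.
#' @param scheme scheme name.
#' @param classes optional precomputed [atom_classes()] vector.
#' @return integer vector of atom indices (ordered).
#' @export
scheme_atoms <- function(topology, res_index, scheme = "closest_heavy",
                         classes = NULL) {
  scheme <- match.arg(scheme, .SCHEMES)
  idx <- which(topology$atoms$residue == res_index)
  heavy <- idx[topology$atoms$is_heavy[idx]]
  if (scheme %in% c("closest_heavy", "com")) return(heavy)
  if (scheme == "closest") return(idx)
  fallback <- function(what) {
    if (isTRUE(getOption("contactlens.strict_schemes"))) {
      stop(sprintf("scheme '%s' selects no atoms for residue %s",
                   scheme, residue_display(topology, res_index)))
    }
    warning(sprintf(
      "scheme '%s' selects no %s for residue %s; falling back to its heavy atoms",
      scheme, what, residue_display(topology, res_index)), call. = FALSE)
    heavy
  }
  if (scheme == "ca") {
    ca <- idx[toupper(topology$atoms$name[idx]) == "CA" &
                topology$atoms$is_heavy[idx]]
    if (topology$residues$molecule_class[res_index] == "protein" &&
        length(ca) >= 1L) {
      return(ca[1L])
    }
    return(fallback("CA atom"))
  }
  # sidechain schemes
  if (is.null(classes)) classes <- atom_classes(topology)
  sc <- idx[classes[idx] == "SC"]
  if (scheme == "sidechain_heavy") sc <- sc[topology$atoms$is_heavy[sc]]
  if (!length(sc)) return(fallback("sidechain atoms"))
  sc
}

# atomic mass lookup for the com scheme
.atom_masses <- function(topology, idx) {
  m <- .ELEMENT_MASSES[topology$atoms$element[idx]]
  m[is.na(m)] <- 12.011  # unknown elements weigh like carbon
  unname(m)
}
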