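---
title: "Hard-cutoff contact frequencies over MD ensembles: methods and design"
author: "contactlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hard-cutoff contact frequencies over MD ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactlens)
```

## The model

`contactlens` reduces an ensemble of trajectories sharing one molecular
topology to binary residue–residue contacts. A *distance scheme* maps each
frame and residue pair (A, B) to a single scalar d_AB; a *hard cutoff* δ
converts it into a contact indicator C_δ(d_AB) = 1 iff d_AB ≤ δ (the boundary
is deliberately inclusive). Per-trajectory frequencies are per-frame averages
of C_δ within each trajectory; the global frequency F is the total number of
formed frames divided by the total number of frames, i.e. the frame-count
weighted mean of the per-trajectory values. Both are always reported: a
two-trajectory ensemble with frequencies 1.0 and 0.0 has a global F equal to
the frame-share of the first trajectory, and showing only one of the two
numbers would hide either the disagreement or the weighting.

The assumptions are minimal but worth stating. Contacts are aggregated at
residue level; no distinction is made between salt bridges, hydrogen bonds or
π-stacking, which occur at different distances and geometries — the single
cutoff is a trade-off that buys transparency and transferability at the cost
of typing interactions. Frames are treated as exchangeable samples: no
autocorrelation correction, no reweighting. Coordinates are used as given; no
imaging or unwrapping is performed beyond the orthorhombic minimum-image
convention when a periodic box is present (triclinic cells are out of scope).

## Parameters that matter

* **cutoff δ** (Å, default 4.5). All user surfaces take Å; internally
  everything is nanometres. 4.5 Å with the closest-heavy scheme captures the
  short-range interaction distances of polar, charged, aromatic and non-polar
  pairs with a single parameter; results drift smoothly and monotonically with
  δ (frequencies can only grow as δ grows — a property the test suite checks
  over a 3.0–5.5 Å scan).
* **scheme** (default `closest_heavy`). The minimum over heavy-atom cross
  pairs. `closest` adds hydrogens (distances can only shrink, frequencies can
  only grow — also a tested invariant); `ca` uses the single Cα; `sidechain` /
  `sidechain_heavy` restrict to non-backbone atoms; `com` uses the
  mass-weighted heavy-atom centroid and therefore carries no per-frame atom
  pair. "Closest heavy" is taken literally: hydrogens are retained in the
  model but never enter the default scheme's atom set.
* **n_nearest** (default 4). Neighborhood analyses exclude partners within
  this many positions along the same bonded chain, suppressing the covalent
  neighbors that are trivially always in contact. It is restated in every
  report header.
* **ctc_control** (default 5 per anchor for neighborhoods, 0.9 for
  interfaces). Truncation of the reported pair list: an integer keeps the
  top-n pairs by F; a fraction in (0, 1] keeps the smallest pair set capturing
  that share of ΣF. An integer `1L` means top-1 while the double `1.0` means
  the full set. These defaults are declared, not derived: compact top-contact
  reports need a rule, and this one is explicit and configurable.
* **smoothing window** (time-trace display, default ≈1% of the trajectory
  length rounded to odd). A centered moving average with edges contracted;
  window 1 is the identity. Smoothing is display-only: every statistic is
  computed from raw distances.

## Residue identity and fragmentation

The only residue key is the serial index in the topology. Author-assigned
numbers (resSeq) repeat and jump in real files, so they are used exclusively
for display and user-facing selection; two residues numbered 45 in one chain
stay distinct. Fragmentation never trusts the PDB chain field: heuristics use
resSeq discontinuities (any non-`+1` step is a break, covering gaps, restarts
and duplicates), bond connectivity (connected components of the residue-level
bond graph), residue classes, and their combinations. The `default` heuristic
is `resSeq_bonds` plus detaching every non-protein residue that forms its own
bond component — free ligands, ions, waters — into per-molecule fragments
appended at the end (optionally merged into one solvent fragment). GRO files
carry no connectivity, so bonds are inferred geometrically: covalent-range
atom pairs within a residue (1.9 Å heavy–heavy, 1.25 Å with hydrogen) plus
the peptide C–N link below 2.0 Å between consecutive protein residues.

## Consensus labels

Reference tables (CSV or Excel; columns `residue`, `position`, `label`,
`fragment`) assign scheme labels — GPCRdb `x.y` positions, CGN dotted labels,
KLIFS codes — to positions of a reference sequence. Labels are stored
verbatim and never parsed for meaning beyond the fragment column. Transfer
onto a topology fragment is by pairwise global alignment with free end gaps,
match +1, mismatch −1, gap open 3, gap extension 0.5; unlabeled reference
positions are encoded as `X` and align neutrally (score 0), and are excluded
from the identity computation. Labels transfer across aligned columns
(identical or substituted residues); query residues aligned to gaps stay
unlabeled. An alignment below 30% identity over aligned non-`X` columns
produces a warning and an *empty* assignment — silent mislabeling across
distant homologs is worse than no labels, and cross-system work at low
identity is precisely what the labels themselves (not fresh alignments) are
for. Online retrieval of tables is intentionally unimplemented; the offline
table files are the reproducible path.

A known limitation of the transfer: when labeled positions are sparse and
isolated (single labeled columns separated by long neutral spacers), gap
placement next to an indel can be score-degenerate and a label adjacent to
the indel may land one position off. Real consensus tables label contiguous
stretches (helices, loops), where flanking matches anchor the gaps; the
recovery tests use that shape and demand ≥95% recovery under ≤10%
substitutions and ≤3 indels.

## Numerical and degenerate-input choices

* Minimum-distance ties between atom pairs break towards the lowest
  (atom_A, atom_B) index pair, making the per-frame argmin deterministic.
* The representative frame minimizes the Euclidean norm to the ensemble-mean
  pair-distance vector; ties break towards the earlier (trajectory, frame).
* Schemes are total functions: `sidechain`/`sidechain_heavy` on glycine (or
  any residue with an empty selection) fall back to the full heavy-atom set
  with a logged warning; `options(contactlens.strict_schemes = TRUE)` turns
  the fallback into an error. Non-protein residues classify entirely as
  sidechain, so ligand contacts report as sidechain interactions.
* Interaction-type fractions are computed over formed frames only, from each
  frame's argmin atom pair; pairs that never form report all-zero fractions,
  and centroid/Cα schemes report none.
* An anchor with no partner inside the cutoff yields an empty, valid
  ContactGroup ("no contacts" is a result, not an error). Interfaces require
  disjoint, non-empty sides and fail otherwise, naming the overlap.
* Serialized archives (`.clgrp`) are a versioned JSON header plus raw
  little-endian numeric blocks; distances round-trip bit-exactly, truncation
  and version mismatches are detected, and no absolute paths are relied on.
  Coordinates are not archived — everything frequency-related reproduces from
  the stored distances; frame-dependent exports need the ensemble re-attached.
* Secondary-structure letters on flareplots come from a deliberately simple,
  pluggable Cα-geometry classifier (H/B/C): canonical i→i+3 / i→i+4 Cα
  distances mark helices, an extended local span marks strands. It is an
  annotation aid, not a DSSP replacement, and any function with the same
  signature can be substituted.

## The synthetic-data generator

Every stage is tested against fixtures with planted ground truth, generated
offline. Residue templates carry conventional atom names (so classification,
element inference and bond inference behave as on real files) but synthetic
geometry; residues sit isolated on a sparse lattice (4 nm spacing) or, in
chain layout, as contiguous peptides with inferable C–N links. A scripted
contact moves one residue along a dedicated axis towards its anchor so that
the *true* minimum heavy-atom cross distance matches a per-frame target
profile; the displacement is solved by root-finding on the actual
minimum-distance function and validated to 1e-4 nm. The generator also
verifies isolation: unscripted pairs stay beyond 0.5 nm (two simultaneously
scripted movers of one anchor are the exception; such pairs are recorded as
uncontrolled in the ground truth and never asserted on). The bundled demo
mimics a receptor–G-protein system — four peptide fragments, a receptor
ligand, GDP, ions, waters, two trajectories of 100 and 50 frames — with
scripted frequencies chosen once to exercise the weighted-mean case
(100/100 and 0/50 formed → F = 2/3) and a spread of partner frequencies.

What the fixtures do not emulate: physical dynamics, solvation shells,
correlated motions, realistic distance *distributions* (profiles are step
functions, not fluctuating wells), periodic-image artifacts beyond simple
straddling, and file-format pathology beyond what the writers produce.
Passing tests therefore demonstrate that the bookkeeping, statistics and
transforms are exact on controlled geometry — not that any biological
conclusion follows from a particular trajectory.

Problem sizes are kept small by choice — fixtures under 200 atoms and 500
frames, twenty scripted systems for the oracle-equivalence property, demo
runs of 150 frames — because every tested property is scale-free: exact
integer counts, algebraic identities and round trips do not become more true
with more atoms.

## Design choices where the design was open

* One CLI entry point with subcommands instead of per-tool executables; the
  `cmd_*` functions are the same surface programmatically.
* Interface participation is exported as a *signed* bfactor (negative side A,
  positive side B) so any molecular viewer with a diverging colormap shows
  the two sides at a glance; only the signed values are specified, colormaps
  are viewer-side.
* Spreadsheet output is written by a minimal built-in OOXML writer (inline
  strings + numbers, zipped); ASCII, CSV and xlsx writers emit cell-identical
  numbers at 4 decimals, a tested equivalence.
* Comparison across systems keys rows by rendered pair labels,
  consensus-first, so homologs with shifted numbering align; a pair absent
  from a system is an explicit gap, never an implicit zero.
* Violin densities use a gaussian KDE with Scott-style bandwidth
  (`stats::bw.nrd`); representative-frame markers come from the same
  representative-frame rule as the structural exports.

## Limitations

Beyond the single-cutoff aggregation already discussed: XTC/TRR trajectories
have no reader in this toolchain (multi-model PDB, GRO and DCD are
supported); triclinic minimum-image is not implemented; the secondary
structure classifier is heuristic; and consensus-label transfer degrades on
references with sparse isolated labels or internal repeats, where alignment
placement is inherently ambiguous.
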