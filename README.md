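# contactlens

Residue–residue contact frequencies for molecular-dynamics ensembles, in R.

`contactlens` is for structural biologists and simulators who have one
molecular topology (PDB or GRO) and one or more trajectories of it, and want a
one-shot, production-ready answer to "who touches whom, how often?": annotated
frequency tables and spreadsheets, per-pair time-traces and distance
distributions, protein–protein interface summaries, flareplot geometry, and
signed-bfactor PDB heatmaps — all driven by a single transparent metric.

## The metric

For a residue pair (A, B), a distance scheme reduces each frame to one scalar
d_AB — by default the minimum over all heavy-atom cross pairs ("closest
heavy") — and a hard cutoff δ (default 4.5 Å) turns it into a binary contact:

    C_δ(d_AB) = 1 if d_AB ≤ δ, else 0

The per-trajectory frequency of the pair in trajectory i with N_i frames is

    f_i = (1 / N_i) · Σ_t C_δ(d_AB(t))

and the global frequency over T trajectories is the frame-count-weighted mean

    F = Σ_i Σ_t C_δ(d_AB(t)) / Σ_i N_i

Both are always reported, because the global average can mask per-trajectory
outliers. The atom pair achieving each frame's minimum is kept, so every
contact also carries its sidechain/backbone interaction-type breakdown.

All distance data of a run live in a `ContactGroup` — a serializable container
bundling the pairs, their per-frame distances and atom pairs, the topology,
its fragmentation, trajectory metadata and any consensus labels — from which
every table, matrix and plot layout is derived as a pure data transform.

Around the engine:

* **Fragmentation heuristics** split a topology into chains/molecules using
  resSeq jumps, bond connectivity and residue classes — never trusting the PDB
  chain field (GRO files have none).
* **Consensus nomenclature** (GPCRdb positions, CGN for G-proteins, KLIFS for
  kinases) is read from local tables and transferred onto arbitrary topologies
  by pairwise sequence alignment, enabling selections like `TM3`, `ICL*`,
  `G.H5.26` or `3.50` and cross-system comparisons keyed by label rather than
  by residue number.
* **A selection grammar**: `"P0G,GLU*,380-394,3.5*"` mixes ligand codes, name
  wildcards, author-numbering ranges and consensus labels.
* **A synthetic-fixture generator** plants time-scripted residue-pair
  distances with exact ground truth, so the entire stack is testable offline.

## Worked example

The bundled demo is a receptor–G-protein-shaped synthetic system: four
peptide fragments (Gα, Gβ, Gγ, a receptor), the receptor ligand P0G, GDP,
ions and waters, simulated as two trajectories of 100 and 50 frames with
scripted contacts between the Gα C-terminal helix-5 leucines and receptor
residues.

```r
library(contactlens)

fx   <- demo_fixture(seed = 1)
frag <- fragment_topology(fx$topology)     # 10 fragments, ligands last
grp  <- residue_neighborhood(fx$ensemble, c(29L, 30L))  # L393, L394
fr   <- compute_frequencies(grp, cutoff = 4.5)
print(fr)
```

```
ContactFrequencies at 4.50 Ang: 4 pairs, sum F = 2.10
  L394               Y132               F = 0.8667 [0.80 1.00]
  L394               E131               F = 0.6667 [1.00 0.00]
  L393               F133               F = 0.3667 [0.55 0.00]
  L394               A124               F = 0.2000 [0.30 0.00]
```

The second row is the instructive one: the pair is formed in every frame of
trajectory 1 and never in trajectory 2, so the global frequency is the
weighted 100/150 = 0.6667 — not the naive per-trajectory mean of 0.5 — and
the bracketed per-trajectory values expose the disagreement. The mean of the
per-frame formed-contacts trace (`formed_contacts_timetrace(grp, 4.5)`)
equals the frequency sum, 2.10, exactly.

With the demo's consensus tables the same pairs come out tagged
(`L394@G.H5.26 – E131@3.50`), and the whole run is available from the shell:

```sh
contact-lens examples --output-dir demo -x
contact-lens neighborhoods demo/topology.pdb demo/traj_1.pdb demo/traj_2.pdb \
    -r L393,L394 --CGN-table demo/cgn_table.csv --GPCR-table demo/gpcr_table.csv
```

which writes the ASCII report, CSV/xlsx frequency tables and time-trace data,
with the cutoff restated in every file name
(`neighborhood.L394@G.H5.26@4.5_Ang.xlsx`). Other subcommands: `interface`,
`sites`, `compare`, `residues`, `fragments`, `nomenclature-overview`.

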