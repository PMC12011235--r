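# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles recompute distances atom by atom, frame by frame, with
# plain double loops / outer products, independently of the engine's
# vectorized path.

# exhaustive minimum cross distance between two atom sets in one frame
oracle_min_dist <- function(frame_xyz, idxA, idxB, box = NULL) {
  best <- Inf
  for (a in idxA) {
    for (b in idxB) {
      d <- frame_xyz[a, ] - frame_xyz[b, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      best <- min(best, sqrt(sum(d * d)))
    }
  }
  best
}

# frame-by-frame formed-contact counts of one residue pair (heavy atoms)
oracle_counts <- function(ensemble, a, b, cutoff_nm, scheme = "closest_heavy") {
  top <- ensemble$topology
  idxA <- scheme_atoms(top, a, scheme)
  idxB <- scheme_atoms(top, b, scheme)
  vapply(seq_along(ensemble$xyz), function(tr) {
    xyz <- ensemble$xyz[[tr]]
    box <- if (is.null(ensemble$box)) NULL else ensemble$box[[tr]]
    formed <- 0L
    for (f in seq_len(dim(xyz)[1L])) {
      if (oracle_min_dist(xyz[f, , ], idxA, idxB, box) <= cutoff_nm) {
        formed <- formed + 1L
      }
    }
    formed
  }, integer(1))
}

# a small two-chain system with optional scripted contacts
small_fixture <- function(contacts = list(), n_frames = 50L, seed = 7L,
                          layout = "lattice",
                          seq1 = c("ALA", "SER", "LEU", "GLY"),
                          seq2 = c("VAL", "THR", "GLU", "ALA"),
                          ligands = "P0G", ...) {
  build_fixture(fixture_spec(
    chains = list(list(seq = seq1, resseq_start = 10L, name = "chainA"),
                  list(seq = seq2, resseq_start = 200L, name = "chainB")),
    ligands = ligands, contacts = contacts, n_frames = n_frames,
    layout = layout, seed = seed, ...))
}

# step profile helper: formed distance for the first n_on frames
step_profile <- function(d_on, d_off, n_on, n) {
  c(rep(d_on, n_on), rep(d_off, n - n_on))
}

# a batch of randomized scripted fixtures with known per-frame targets
random_scripted_fixture <- function(seed) {
  set.seed(seed)
  n1 <- sample(30:60, 1L)
  n2 <- sample(20:40, 1L)
  lv <- c(0.30, 0.38, 0.44, 0.46, 0.55, 0.70)
  prof <- function(n) sample(lv, n, replace = TRUE)
  small_fixture(
    contacts = list(
      list(pair = c(3L, 6L), profile = list(prof(n1), prof(n2))),
      list(pair = c(1L, 9L), profile = list(prof(n1), prof(n2)))),
    n_frames = c(n1, n2), seed = seed)
}

# raw topology builder for analytic scheme tests (no templates involved)
raw_topology <- function(atom_names, elements, residue_of, res_names,
                         res_seqs, bonds = NULL) {
  new_topology(
    data.frame(name = atom_names, element = elements, residue = residue_of,
               stringsAsFactors = FALSE),
    data.frame(name = res_names, resSeq = res_seqs, chain = NA_character_,
               stringsAsFactors = FALSE),
    bonds)
}

expect_partition <- function(fragmentation, n) {
  all_res <- sort(unname(unlist(fragmentation$fragments)))
  expect_identical(all_res, seq_len(n))  # exhaustive and no duplicates
}

demo_assignments <- function(fx) {
  frag <- fragment_topology(fx$topology)
  list(CGN = assign_labels(consensus_map(fx$tables$cgn, "CGN", "demo"),
                           fx$topology, frag$fragments[["frag 0"]]),
       GPCR = assign_labels(consensus_map(fx$tables$gpcr, "GPCR", "demo"),
                            fx$topology, frag$fragments[["frag 3"]]))
}
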