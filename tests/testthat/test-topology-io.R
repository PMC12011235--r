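# Topology model and PDB/GRO readers

test_that("PDB write/read round trip preserves the modeled fields", {
  fx <- demo_fixture(seed = 3, full = FALSE)
  path <- tempfile(fileext = ".pdb")
  write_pdb(fx$topology, fx$ensemble$xyz[[1]][1, , ], path)
  back <- read_pdb(path)
  expect_identical(back$topology$residues$name, fx$topology$residues$name)
  expect_identical(back$topology$residues$resSeq, fx$topology$residues$resSeq)
  expect_identical(back$topology$residues$chain, fx$topology$residues$chain)
  expect_identical(back$topology$atoms$name, fx$topology$atoms$name)
  expect_identical(back$topology$atoms$element, fx$topology$atoms$element)
  expect_identical(back$topology$atoms$residue, fx$topology$atoms$residue)
  # coordinates at PDB precision (1e-3 Angstrom = 1e-4 nm)
  expect_lt(max(abs(back$xyz[1, , ] - fx$ensemble$xyz[[1]][1, , ])), 1e-4)
})

test_that("two residues sharing resSeq are kept distinct serial residues", {
  fx <- build_fixture(fixture_spec(
    chains = list(list(seq = c("ALA", "ALA", "GLY"), resseq_start = 45L,
                       jumps = c("2" = 0L))),  # second ALA repeats resSeq 45
    n_frames = 1L, seed = 1))
  expect_identical(fx$topology$residues$resSeq[1:2], c(45L, 45L))
  path <- tempfile(fileext = ".pdb")
  write_pdb(fx$topology, fx$ensemble$xyz[[1]][1, , ], path)
  back <- read_pdb(path)$topology
  expect_identical(n_residues(back), 3L)
  expect_identical(back$residues$resSeq, c(45L, 45L, 46L))
})

test_that("GRO read infers template and peptide bonds", {
  fx <- build_fixture(fixture_spec(
    chains = list(list(seq = c("ALA", "SER", "GLY"), resseq_start = 1L)),
    n_frames = 1L, layout = "chain", seed = 2))
  path <- tempfile(fileext = ".gro")
  write_gro(fx$topology, fx$ensemble$xyz[[1]][1, , ], path)
  back <- read_gro(path)
  top <- back$topology
  expect_identical(n_residues(top), 3L)
  expect_true(all(is.na(top$residues$chain)))
  bonded <- function(t, r1, n1, r2, n2) {
    a <- which(t$atoms$residue == r1 & t$atoms$name == n1)
    b <- which(t$atoms$residue == r2 & t$atoms$name == n2)
    any((t$bonds[, 1] == a & t$bonds[, 2] == b) |
          (t$bonds[, 1] == b & t$bonds[, 2] == a))
  }
  # template bonds inside residues (oracle: the template bond list)
  tmpl <- residue_template("ALA")
  for (k in seq_len(nrow(tmpl$bonds))) {
    expect_true(bonded(top, 1, tmpl$bonds[k, 1], 1, tmpl$bonds[k, 2]),
                label = paste("ALA bond", paste(tmpl$bonds[k, ],
                                                collapse = "-")))
  }
  # peptide C-N links between consecutive residues
  expect_true(bonded(top, 1, "C", 2, "N"))
  expect_true(bonded(top, 2, "C", 3, "N"))
  # and the inferred graph matches the generator's bond set exactly
  canon <- function(b) unique(b[order(b[, 1], b[, 2]), , drop = FALSE])
  expect_identical(canon(top$bonds), canon(fx$topology$bonds))
})

test_that("atom classification is a total two-class partition", {
  fx <- demo_fixture(seed = 1)
  cls <- atom_classes(fx$topology)
  expect_true(all(cls %in% c("BB", "SC")))
  expect_identical(length(cls), n_atoms(fx$topology))
  at <- fx$topology$atoms
  res <- fx$topology$residues
  leu <- which(res$name == "LEU")[1]
  expect_identical(classify_atom(fx$topology,
                                 which(at$residue == leu & at$name == "CA")),
                   "backbone")
  cd1 <- which(at$residue == leu & at$name == "CD1")
  if (length(cd1)) {
    expect_identical(classify_atom(fx$topology, cd1[1]), "sidechain")
  }
  # every atom of a non-protein residue is sidechain (ligand contacts report
  # as sidechain)
  p0g <- which(res$name == "P0G")
  expect_true(all(cls[at$residue == p0g] == "SC"))
  # hydrogens follow the heavy atom they are bonded to
  h_on_n <- which(at$name == "H" & at$residue == 1L)
  expect_identical(cls[h_on_n], "BB")
})

test_that("trajectory loading preserves order, frames, and atom counts", {
  fx <- demo_fixture(seed = 2, full = FALSE)
  dir <- tempfile()
  paths <- write_fixture(fx, dir)
  ens <- load_trajectories(paths$trajectories, fx$topology)
  expect_identical(n_frames(ens), c(100L, 50L))
  expect_identical(sum(n_frames(ens)), 150L)
  # multi-model PDB -> one block with that many frames
  one <- load_trajectories(paths$trajectories[2], fx$topology)
  expect_identical(length(one$xyz), 1L)
  expect_identical(dim(one$xyz[[1]])[1], 50L)
  # wrong atom count is a clean topology mismatch error naming the file
  small <- build_fixture(fixture_spec(
    chains = list(list(seq = "AG", resseq_start = 1L)), n_frames = 2L,
    seed = 1))
  bad <- tempfile(fileext = ".pdb")
  write_pdb(small$topology, small$ensemble$xyz[[1]], bad)
  expect_error(load_trajectories(bad, fx$topology), "topology mismatch")
  expect_error(load_trajectories(paths$trajectories, small$topology),
               basename(paths$trajectories[1]), fixed = TRUE)
})

test_that("coordinate parsing agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  fx <- demo_fixture(seed = 4, full = FALSE)
  path <- tempfile(fileext = ".pdb")
  write_pdb(fx$topology, fx$ensemble$xyz[[1]][1, , ], path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  ref_xyz <- matrix(ref$xyz, ncol = 3, byrow = TRUE) / 10
  expect_lt(max(abs(ours$xyz[1, , ] - ref_xyz)), 1e-9)
  expect_identical(ours$topology$atoms$name, ref$atom$elety)
})

test_that("degenerate inputs raise informative errors", {
  empty <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_pdb(empty), "no ATOM records")
  bad <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.0xx   0.000  1.00  0.00           C"
  ), bad)
  expect_error(read_pdb(bad), "line 2")
  expect_error(load_topology(tempfile(fileext = ".xyz")), "unsupported")
})
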