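# Consensus nomenclature: tables, alignment transfer, rendering, MSA

ref_labels <- function() {
  data.frame(position = c(3:8, 12:16),
             label = c(sprintf("3.%d", 47:52), sprintf("G.H5.%d", 1:5)),
             fragment = c(rep("TM3", 6), rep("G.H5", 5)),
             stringsAsFactors = FALSE)
}

test_that("CSV and Excel encodings of a table give identical maps", {
  fx <- build_consensus_fixture("MKTAYIAKQRQISFVKSHFSRQ", ref_labels(),
                                seed = 41)
  m_csv <- read_consensus_table(fx$csv)
  m_xlsx <- read_consensus_table(fx$xlsx)
  expect_identical(m_csv$table, m_xlsx$table)
  expect_identical(m_csv$reference_sequence, m_xlsx$reference_sequence)
  expect_identical(m_csv$scheme, "CGN")  # guessed from the G. labels
})

test_that("malformed tables are rejected with specific messages", {
  tab <- data.frame(residue = c("A", "C"), position = 1:2,
                    label = c("3.50", "3.50"), fragment = "TM3")
  expect_error(consensus_map(tab), "duplicate consensus label.*3.50")
  expect_error(consensus_map(tab[, -4]), "fragment")
  tab2 <- data.frame(residue = c("ALA", "C"), position = 1:2,
                     label = c("3.50", "3.51"), fragment = "TM3")
  expect_error(consensus_map(tab2), "malformed")
})

test_that("identity alignment transfers every label", {
  seq <- "MKTAYIAKQRQISFVKSHFSRQ"
  fx <- build_consensus_fixture(seq, ref_labels(), seed = 42)
  cmap <- read_consensus_table(fx$csv)
  a <- assign_labels(cmap, fx$topology, seq_len(n_residues(fx$topology)))
  expect_identical(nrow(a$table), nrow(ref_labels()))
  expect_identical(a$table$res_index, ref_labels()$position)
  expect_identical(a$table$label, ref_labels()$label)
  expect_identical(a$identity, 1)
})

test_that("internal deletions shift surviving labels correctly", {
  seq <- "MKTAYIAKQRQISFVKSHFSRQ"
  # delete 2 residues upstream of the labeled stretch at 12..16
  fx <- build_consensus_fixture(seq, ref_labels(),
                                indels = list(list(9L, -2L)), seed = 43)
  cmap <- read_consensus_table(fx$csv)
  a <- assign_labels(cmap, fx$topology, seq_len(n_residues(fx$topology)))
  hit <- a$table[a$table$label == "G.H5.1", ]
  expect_identical(hit$res_index, 10L)  # 12 shifted by -2
  merged <- merge(a$table, fx$expected, by = "label")
  expect_true(all(merged$res_index.x == merged$res_index.y))
})

test_that("label transfer recovers >= 95% under mild mutation plans", {
  seq <- "MKTAYIAKQRQISFVKSHFSRQDELPWNGDTCVHEMLRYFAWIPKNSTQGVRLD"  # 54 aa
  labels <- data.frame(
    position = c(4:15, 31:42),
    label = c(sprintf("5.%d", 40 + 1:12), sprintf("6.%d", 30 + 1:12)),
    fragment = rep(c("TM5", "TM6"), each = 12), stringsAsFactors = FALSE)
  for (seed in 44:48) {
    fx <- build_consensus_fixture(seq, labels, n_sub = 5L,
                                  indels = list(list(11L, -1L),
                                                list(25L, 2L)),
                                  seed = seed)
    cmap <- read_consensus_table(fx$csv)
    a <- assign_labels(cmap, fx$topology,
                       seq_len(n_residues(fx$topology)))
    merged <- merge(a$table, fx$expected, by = "label")
    recovered <- sum(merged$res_index.x == merged$res_index.y)
    expect_gte(recovered / nrow(fx$expected), 0.95)
    # colinearity: transferred labels increase in both coordinates
    ord <- order(a$table$ref_pos)
    expect_false(is.unsorted(a$table$res_index[ord], strictly = TRUE))
    # determinism
    b <- assign_labels(cmap, fx$topology,
                       seq_len(n_residues(fx$topology)))
    expect_identical(a$table, b$table)
  }
})

test_that("alignments below the identity floor yield empty assignments", {
  labels <- data.frame(position = 2:6, label = sprintf("1.%d", 50:54),
                       fragment = "TM1", stringsAsFactors = FALSE)
  fx <- build_consensus_fixture("MKTAYIAKQRMKTAYIAKQR", labels, seed = 49)
  cmap <- read_consensus_table(fx$csv)
  # an unrelated planted sequence
  other <- build_fixture(fixture_spec(
    chains = list(list(seq = "GGSGGSGGSGGSGGSGGSGG", resseq_start = 1L)),
    n_frames = 1L, seed = 50))
  expect_warning(
    a <- assign_labels(cmap, other$topology,
                       seq_len(n_residues(other$topology))),
    "empty assignment")
  expect_identical(nrow(a$table), 0L)
})

test_that("consensus fragments support wildcard retrieval", {
  fx <- demo_fixture(seed = 1)
  asg <- demo_assignments(fx)
  icl <- consensus_fragments(asg$GPCR, "ICL*")
  expect_identical(names(icl), c("ICL1", "ICL2", "ICL3"))
  gh <- consensus_fragments(asg$CGN, "G.H*")
  expect_identical(names(gh), "G.H5")
  expect_length(gh$G.H5, 26L)
  expect_warning(none <- consensus_fragments(asg$GPCR, "ECL*"),
                 "no consensus fragment")
  expect_length(none, 0L)
})

test_that("labels render in the name@label grammar", {
  fx <- demo_fixture(seed = 1)
  asg <- demo_assignments(fx)
  expect_identical(render_residue_label(fx$topology, 27L, asg),
                   "Y391@G.H5.23")
  expect_identical(render_residue_label(fx$topology, 30L, asg),
                   "L394@G.H5.26")
  # unlabeled residue: bare name, or fragment-tagged on request
  expect_identical(render_residue_label(fx$topology, 1L, asg), "M365")
  frag <- fragment_topology(fx$topology)
  expect_identical(
    render_residue_label(fx$topology, 1L, asg, frag, tag_fragment = TRUE),
    "M365@frag 0")
  # an ARG at author position 131 labeled 3.50 renders as R131@3.50
  labels <- data.frame(position = 3L, label = "3.50", fragment = "TM3",
                       stringsAsFactors = FALSE)
  gp <- build_fixture(fixture_spec(
    chains = list(list(seq = c("LYS", "THR", "ARG", "TYR", "PHE"),
                       resseq_start = 129L)),
    n_frames = 1L, seed = 51))
  tab <- data.frame(residue = "R", position = 3L, label = "3.50",
                    fragment = "TM3")
  cmap <- consensus_map(tab, "GPCR", "toy")
  a <- assign_labels(cmap, gp$topology, 1:5)
  expect_identical(render_residue_label(gp$topology, 3L, a), "R131@3.50")
})

test_that("the label MSA is keyed purely by labels, never by resSeq", {
  labels <- data.frame(position = c(3L, 4L, 5L),
                       label = c("3.49", "3.50", "3.51"),
                       fragment = "TM3", stringsAsFactors = FALSE)
  seqs <- c("MKRAYIAKQR", "MKRAYAKQRW", "AKRAYIAKQ", "MKRAYIWKQR")
  starts <- c(100L, 300L, 100L, 55L)  # deliberately clashing numbering
  tops <- list(); asgs <- list()
  for (k in seq_along(seqs)) {
    fx <- build_consensus_fixture(seqs[1], labels, seed = 60L + k)
    cmap <- read_consensus_table(fx$csv, scheme = "GPCR")
    sys <- build_fixture(fixture_spec(
      chains = list(list(seq = seqs[k], resseq_start = starts[k])),
      n_frames = 1L, seed = 70L + k))
    tops[[k]] <- sys$topology
    asgs[[k]] <- assign_labels(cmap, sys$topology,
                               seq_len(n_residues(sys$topology)))
  }
  names(asgs) <- sprintf("sys%d", 1:4)
  msa <- labels_as_msa(asgs, tops)
  expect_identical(colnames(msa), c("3.49", "3.50", "3.51"))
  expect_identical(nrow(msa), 4L)
  expect_identical(msa["sys1", "3.50"], "A103")
  expect_identical(msa["sys2", "3.50"], "A303")
  expect_identical(msa["sys4", "3.50"], "A58")
  # a label absent in one system leaves a gap, not a zero
  asgs$sys3$table <- asgs$sys3$table[asgs$sys3$table$label != "3.50", ]
  msa2 <- labels_as_msa(asgs, tops)
  expect_true(is.na(msa2["sys3", "3.50"]))
  # mixed schemes refuse to align
  asgs$sys2$scheme <- "KLIFS"
  expect_error(labels_as_msa(asgs, tops), "mix consensus schemes")
})

test_that("online lookups are declared unavailable offline", {
  expect_error(fetch_consensus_table("adrb2_human"), "not available")
})
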