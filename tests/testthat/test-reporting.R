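# Reporting: tables and writers, traces, distributions, matrices, flare
# geometry, heatmap PDB, comparisons

demo_group <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- demo_fixture(seed = 1)
      frag <- fragment_topology(fx$topology)
      asg <- demo_assignments(fx)
      grp <- residue_neighborhood(fx$ensemble, c(29L, 30L),
                                  fragmentation = frag, assignments = asg)
      cache <<- list(fx = fx, grp = grp,
                     fr = compute_frequencies(grp, 4.5))
    }
    cache
  }
})

test_that("frequency tables rank by F and accumulate correctly", {
  d <- demo_group()
  tab <- frequency_table(d$fr, d$grp)
  expect_false(is.unsorted(rev(tab$freq)))
  expect_equal(tab$cum_freq, cumsum(tab$freq), tolerance = 1e-15)
  expect_identical(tab$rank, seq_len(nrow(tab)))
  # type fractions of formed pairs sum to 1
  ty <- as.matrix(tab[, c("sc_sc", "sc_bb", "bb_sc", "bb_bb")])
  expect_equal(unname(rowSums(ty)), rep(1, nrow(tab)), tolerance = 1e-12)
  # sum of table F equals the mean of the formed-contacts trace
  trace <- formed_contacts_timetrace(d$grp, 4.5)
  expect_equal(sum(tab$freq), mean(unlist(trace)), tolerance = 1e-12)
})

test_that("ASCII, CSV and xlsx writers are cell-identical at 4 decimals", {
  d <- demo_group()
  tab <- frequency_table(d$fr, d$grp)
  fa <- tempfile(fileext = ".dat")
  fc <- tempfile(fileext = ".csv")
  fx_ <- tempfile(fileext = ".xlsx")
  write_table_ascii(tab, fa, d$grp, 4.5)
  write_table_csv(tab, fc, d$grp, 4.5)
  write_table_xlsx(tab, fx_, d$grp, 4.5)
  ascii <- readLines(fa)
  expect_true(any(grepl("cutoff: 4.50 Ang", ascii)))  # provenance header
  csv <- utils::read.csv(fc, comment.char = "#")
  xlsx <- as.data.frame(readxl::read_xlsx(fx_))
  expect_equal(csv$freq, round(tab$freq, 4), tolerance = 1e-12)
  expect_equal(xlsx$freq, round(tab$freq, 4), tolerance = 1e-12)
  expect_identical(csv$label_a, xlsx$label_a)
  # the ASCII body carries the same numbers
  body <- ascii[!startsWith(ascii, "#")][-1]
  first_f <- as.numeric(regmatches(body[1],
                                   regexpr("[0-9]+\\.[0-9]{4}", body[1])))
  expect_equal(first_f, round(tab$freq[1], 4), tolerance = 1e-12)
})

test_that("smoothing is a centered moving average with contracted edges", {
  x <- c(1, 5, 1, 5, 1, 5, 1)
  expect_identical(smooth_series(x, 1L), x)
  expect_identical(smooth_series(rep(3, 10), 5L), rep(3, 10))
  got <- smooth_series(x, 3L)
  want <- c(1, (1 + 5 + 1) / 3, (5 + 1 + 5) / 3, (1 + 5 + 1) / 3,
            (5 + 1 + 5) / 3, (1 + 5 + 1) / 3, 1)
  expect_equal(got, want, tolerance = 1e-15)
  expect_error(smooth_series(x, 4L), "odd")
  d <- demo_group()
  tt <- timetrace_data(d$grp, 1L, window = 1L)
  expect_identical(tt[[1]]$raw, tt[[1]]$smooth)
  expect_identical(tt[[1]]$raw, d$grp$dist[[1]][[1]])
})

test_that("distance distributions pool trajectories additively", {
  d <- demo_group()
  h <- distance_distribution(d$grp, 1L, bin_width = 0.5)
  expect_identical(sum(h$counts), sum(d$grp$n_frames))
  expect_identical(as.integer(rowSums(h$per_traj)), h$counts)
  # all distances equal -> a single occupied bin containing that value
  top <- raw_topology(c("NA", "CL"), c("Na", "Cl"), c(1L, 2L),
                      c("NA", "CL"), c(1L, 2L))
  xyz <- array(0, c(5, 2, 3)); xyz[, 2, 1] <- 0.4
  ens <- trajectory_ensemble(top, list(xyz))
  g <- contact_group(ens, rbind(c(1L, 2L)))
  h1 <- distance_distribution(g, 1L, bin_width = 0.25)
  expect_identical(sum(h1$counts > 0), 1L)
  occupied <- which(h1$counts > 0)
  expect_true(h1$breaks[occupied] <= 4 && 4 <= h1$breaks[occupied + 1])
  # bimodal planted distances show two modes at the planted centers
  fxb <- small_fixture(contacts = list(list(
    pair = c(2L, 6L), profile = rep(c(0.32, 0.70), each = 30))),
    n_frames = 60L, seed = 91)
  gb <- contact_group(fxb$ensemble, rbind(c(2L, 6L)))
  hb <- distance_distribution(gb, 1L, bin_width = 0.5)
  expect_identical(sum(hb$counts > 0), 2L)
  modes <- hb$mids[hb$counts > 0]
  expect_true(all(abs(modes - c(3.2, 7.0)) <= 0.5))
})

test_that("contact matrix is symmetric with participation row sums", {
  d <- demo_group()
  M <- contact_matrix(d$fr, d$grp)
  expect_identical(M, t(M))
  expect_true(all(diag(M) == 0))
  part <- per_residue_participation(d$fr, d$grp)
  expect_equal(unname(rowSums(M)), unname(part), tolerance = 1e-15)
  # single computed pair populates exactly two symmetric cells
  p <- d$grp$pairs[1, ]
  expect_identical(M[p$a, p$b], d$fr$freq[1])
  # interface groups only populate the A x B block
  fx <- d$fx
  frag <- fragment_topology(fx$topology)
  intf <- contact_interface(fx$ensemble, "frag 0", "frag 3",
                            fragmentation = frag, ctc_control = 1.0)
  fri <- compute_frequencies(intf, 4.5)
  Mi <- contact_matrix(fri, intf)
  A <- intf$interface_split$A
  expect_true(all(Mi[A, A] == 0))
  B <- intf$interface_split$B
  expect_true(all(Mi[B, B] == 0))
})

test_that("fragment matrix aggregates and conserves total frequency", {
  d <- demo_group()
  fm <- fragment_matrix(d$fr, d$grp)
  tot <- sum(fm[upper.tri(fm, diag = TRUE)])
  expect_equal(tot, sum(d$fr$freq), tolerance = 1e-15)
  # all demo neighborhood contacts join the G-alpha and receptor fragments
  expect_equal(fm["frag 0", "frag 3"], sum(d$fr$freq), tolerance = 1e-15)
  # consensus partition: TM3-by-G.H5 block
  asg <- demo_assignments(d$fx)
  parts <- c(consensus_fragments(asg$CGN), consensus_fragments(asg$GPCR))
  # cover remaining residues in a catch-all so the partition is complete
  rest <- setdiff(seq_len(n_residues(d$fx$topology)), unlist(parts))
  parts$other <- rest
  fmc <- fragment_matrix(d$fr, d$grp, parts)
  expect_gt(fmc["G.H5", "TM3"], 0)
  # incomplete partitions are refused
  expect_error(fragment_matrix(d$fr, d$grp, parts["G.H5"]),
               "does not cover")
})

test_that("flare layout places fragments on disjoint arcs with F chords", {
  d <- demo_group()
  fl <- flare_layout(d$grp, d$fr)
  expect_false(is.unsorted(fl$angles, strictly = TRUE))
  expect_true(all(fl$angles > 0 & fl$angles < 2 * pi))
  # fragments occupy disjoint arcs
  fr_tab <- fl$fragments
  expect_true(all(fr_tab$start[-1] >= fr_tab$end[-nrow(fr_tab)]))
  # chord opacity equals F; no chord for F = 0
  expect_identical(sort(fl$chords$opacity),
                   sort(d$fr$freq[d$fr$freq > 0]))
  # aura defaults to participation
  part <- per_residue_participation(d$fr, d$grp)
  expect_equal(unname(fl$aura), unname(part[fl$residues]),
               tolerance = 1e-15)
  # 4 residues, 1 fragment, no gap -> equidistant points
  fx4 <- build_fixture(fixture_spec(
    chains = list(list(seq = "AGST", resseq_start = 1L)), n_frames = 2L,
    seed = 92))
  g4 <- contact_group(fx4$ensemble, rbind(c(1L, 3L)))
  f4 <- compute_frequencies(g4, 4.5)
  fl4 <- flare_layout(g4, f4, residues = 1:4, gap = 0)
  expect_equal(diff(fl4$angles), rep(pi / 2, 3), tolerance = 1e-12)
  # aura length mismatch is an error
  expect_error(flare_layout(d$grp, d$fr, aura = c(1, 2)), "aura")
  # secondary-structure letters come from the representative frame
  expect_true(all(fl$ss %in% c("H", "B", "C", "")))
})

test_that("signed-bfactor PDB round-trips participation at 2 decimals", {
  fx <- demo_fixture(seed = 1)
  frag <- fragment_topology(fx$topology)
  intf <- contact_interface(fx$ensemble, "frag 0", "frag 3",
                            fragmentation = frag, ctc_control = 1.0)
  fr <- compute_frequencies(intf, 4.5)
  path <- tempfile(fileext = ".pdb")
  bfactor_heatmap_pdb(intf, fr, path)
  back <- read_pdb(path)
  part <- per_residue_participation(fr, intf)
  res_of <- fx$topology$atoms$residue
  for (r in intf$interface_split$A) {
    expect_equal(unique(back$bfactors[res_of == r]),
                 round(-part[[r]], 2), tolerance = 5e-3)
  }
  for (r in intf$interface_split$B) {
    expect_equal(unique(back$bfactors[res_of == r]),
                 round(part[[r]], 2), tolerance = 5e-3)
  }
  outside <- setdiff(seq_len(n_residues(fx$topology)),
                     c(intf$interface_split$A, intf$interface_split$B))
  expect_true(all(back$bfactors[res_of %in% outside] == 0))
  # groups without an interface split refuse
  nb <- residue_neighborhood(fx$ensemble, 30L)
  frn <- compute_frequencies(nb, 4.5)
  expect_error(bfactor_heatmap_pdb(nb, frn, tempfile()), "interface")
})

test_that("cross-system comparison aligns keys and reports explicit gaps", {
  fx <- demo_fixture(seed = 1)
  frag <- fragment_topology(fx$topology)
  asg <- demo_assignments(fx)
  nb1 <- residue_neighborhood(fx$ensemble, 30L, fragmentation = frag,
                              assignments = asg)
  nb2 <- residue_neighborhood(fx$ensemble, c(29L, 30L),
                              fragmentation = frag, assignments = asg)
  cmp <- compare_groups(list(small = nb1, large = nb2), 4.5)
  # a group compared with itself shows zero differences
  self <- compare_groups(list(a = nb1, b = nb1), 4.5)
  expect_identical(self$table$a, self$table$b)
  # keys are consensus-rendered, so rows carry the tagged pair names
  expect_true(any(grepl("G.H5.26", cmp$table$key, fixed = TRUE)))
  # the pair present in nb2 only leaves a gap in nb1's column
  only2 <- setdiff(cmp$table$key[!is.na(cmp$table$large)],
                   cmp$table$key[!is.na(cmp$table$small)])
  expect_gte(length(only2), 1L)
  expect_true(all(is.na(cmp$table$small[cmp$table$key %in% only2])))
  # violin data pools all frames of each system
  k <- cmp$table$key[1]
  expect_identical(length(cmp$violins[[k]]$small), 150L)
  # representative markers exist for shared keys
  expect_true(all(!is.na(cmp$representatives[cmp$table$key[
    !is.na(cmp$table$small)], "small"])))
  # disjoint keys raise with a hint
  g1 <- contact_group(fx$ensemble, rbind(c(1L, 5L)))
  g2 <- contact_group(fx$ensemble, rbind(c(2L, 6L)))
  expect_error(compare_groups(list(x = g1, y = g2), 4.5), "key_mode")
})
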