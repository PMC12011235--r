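# Core engine: distances, frequencies, neighborhoods, interfaces,
# serialization

test_that("contact indicator is inclusive at the boundary", {
  expect_identical(contact_indicator(4.5, 4.5), 1L)       # d == cutoff
  expect_identical(contact_indicator(0, 4.5), 1L)
  expect_identical(contact_indicator(4.5 + 1e-12, 4.5), 0L)
  expect_identical(contact_indicator(c(1, 5), 4.5), c(1L, 0L))
  expect_error(contact_indicator(1, 0), "positive")
  expect_error(contact_indicator(-1, 4.5), "non-negative")
})

test_that("per-frame distances match the exhaustive double-loop oracle", {
  fx <- random_scripted_fixture(11)
  ens <- fx$ensemble
  pairs <- t(utils::combn(c(1L, 3L, 5L, 6L, 9L), 2L))
  grp <- contact_group(ens, pairs)
  top <- ens$topology
  for (p in seq_len(n_pairs(grp))) {
    idxA <- scheme_atoms(top, grp$pairs$a[p])
    idxB <- scheme_atoms(top, grp$pairs$b[p])
    for (tr in seq_along(ens$xyz)) {
      want <- vapply(seq_len(dim(ens$xyz[[tr]])[1]), function(f) {
        oracle_min_dist(ens$xyz[[tr]][f, , ], idxA, idxB)
      }, numeric(1))
      expect_lt(max(abs(grp$dist[[p]][[tr]] - want)), 1e-6)
    }
  }
})

test_that("scripted fixtures reproduce their planted frequencies", {
  # formed in exactly 30 of 100 frames -> F = 0.30
  fx <- small_fixture(
    contacts = list(list(pair = c(2L, 6L),
                         profile = step_profile(0.40, 0.80, 30L, 100L))),
    n_frames = 100L, seed = 12)
  grp <- contact_group(fx$ensemble, rbind(c(2L, 6L)))
  fr <- compute_frequencies(grp, 4.5)
  expect_identical(fr$freq, 0.30)
  expect_identical(fr$counts[1, 1], 30L)
})

test_that("global frequency is the frame-count-weighted mean", {
  # T = 2, N = [100, 50], formed 100/100 and 0/50 -> F = 2/3, not 1/2
  fx <- demo_fixture(seed = 1)
  grp <- contact_group(fx$ensemble, rbind(c(30L, 60L)))
  fr <- compute_frequencies(grp, 4.5)
  expect_identical(unname(fr$per_traj[1, ]), c(1, 0))
  expect_identical(fr$freq, 100 / 150)
  expect_false(isTRUE(all.equal(fr$freq, mean(fr$per_traj[1, ]))))
  # the identity F = sum(N_i f_i) / sum(N_i) holds exactly everywhere
  nb <- residue_neighborhood(fx$ensemble, c(29L, 30L))
  fr <- compute_frequencies(nb, 4.5)
  recon <- as.vector(fr$per_traj %*% fr$n_frames) / sum(fr$n_frames)
  expect_equal(fr$freq, recon, tolerance = 1e-15)
})

test_that("formed-contacts trace mean equals the frequency sum exactly", {
  fx <- demo_fixture(seed = 1)
  nb <- residue_neighborhood(fx$ensemble, c(29L, 30L))
  fr <- compute_frequencies(nb, 4.5)
  trace <- formed_contacts_timetrace(nb, 4.5)
  expect_identical(mean(unlist(trace)), sum(fr$freq) * 150 / 150)
  expect_equal(mean(unlist(trace)), sum(fr$freq), tolerance = 1e-15)
  # one pair always formed -> constant series of 1
  always <- contact_group(fx$ensemble, rbind(c(54L, 89L)))
  tr <- formed_contacts_timetrace(always, 4.5)
  expect_true(all(unlist(tr) == 1L))
})

test_that("frequencies are monotone in the cutoff", {
  fx <- random_scripted_fixture(21)
  grp <- contact_group(fx$ensemble,
                       t(utils::combn(c(1L, 3L, 6L, 9L), 2L)))
  cuts <- seq(3.0, 5.5, by = 0.25)
  fmat <- vapply(cuts, function(cc) compute_frequencies(grp, cc)$freq,
                 numeric(n_pairs(grp)))
  for (p in seq_len(nrow(fmat))) {
    expect_false(is.unsorted(fmat[p, ]))
  }
})

test_that("pair order does not matter and duplicates collapse", {
  fx <- small_fixture(n_frames = 5L, seed = 13)
  g1 <- contact_group(fx$ensemble, rbind(c(2L, 7L)))
  g2 <- contact_group(fx$ensemble, rbind(c(7L, 2L), c(2L, 7L)))
  expect_identical(n_pairs(g2), 1L)
  expect_identical(g1$dist, g2$dist)
  expect_error(contact_group(fx$ensemble, rbind(c(3L, 3L))), "itself")
})

test_that("minimum-image distances apply when a box is present", {
  # two ions straddling the boundary of a 4 nm box: direct 3.6, image 0.4
  top <- raw_topology(c("NA", "CL"), c("Na", "Cl"), c(1L, 2L),
                      c("NA", "CL"), c(1L, 2L))
  xyz <- rbind(c(0.2, 1, 1), c(3.8, 1, 1))
  ens_box <- trajectory_ensemble(top, list(array(xyz, c(1, 2, 3))),
                                 box = c(4, 4, 4))
  ens_free <- trajectory_ensemble(top, list(array(xyz, c(1, 2, 3))))
  g_box <- contact_group(ens_box, rbind(c(1L, 2L)))
  g_free <- contact_group(ens_free, rbind(c(1L, 2L)))
  expect_equal(g_box$dist[[1]][[1]], 0.4, tolerance = 1e-12)
  expect_equal(g_free$dist[[1]][[1]], 3.6, tolerance = 1e-12)
})

test_that("neighborhoods exclude bonded sequence neighbors via n_nearest", {
  fx <- build_fixture(fixture_spec(
    chains = list(list(seq = "AGSTVLAGSTVL", resseq_start = 1L)),
    n_frames = 3L, layout = "chain", seed = 14))
  nb0 <- residue_neighborhood(fx$ensemble, 6L, n_nearest = 0L,
                              ctc_control = 20L)
  partners0 <- setdiff(unique(c(nb0$pairs$a, nb0$pairs$b)), 6L)
  expect_true(all(c(5L, 7L) %in% partners0))
  nb4 <- residue_neighborhood(fx$ensemble, 6L, n_nearest = 4L,
                              ctc_control = 20L)
  partners4 <- setdiff(unique(c(nb4$pairs$a, nb4$pairs$b)), 6L)
  expect_true(all(abs(partners4 - 6L) > 4L))
  # an anchor with no partner within the cutoff is a valid empty report
  iso <- small_fixture(n_frames = 3L, seed = 15)
  nb <- residue_neighborhood(iso$ensemble, 1L)
  expect_identical(n_pairs(nb), 0L)
})

test_that("ctc_control truncates neighborhoods per anchor", {
  fx <- demo_fixture(seed = 1)
  all_nb <- residue_neighborhood(fx$ensemble, 30L, ctc_control = 10L)
  expect_identical(n_pairs(all_nb), 3L)  # three scripted partners
  top2 <- residue_neighborhood(fx$ensemble, 30L, ctc_control = 2L)
  fr <- compute_frequencies(top2, 4.5)
  expect_identical(n_pairs(top2), 2L)
  expect_identical(sort(fr$freq, decreasing = TRUE),
                   c(130 / 150, 100 / 150))
  frac <- residue_neighborhood(fx$ensemble, 30L, ctc_control = 0.5)
  expect_identical(n_pairs(frac), 1L)  # top pair already covers 50%
})

test_that("interfaces keep only cross pairs and validate their sides", {
  fx <- demo_fixture(seed = 1)
  frag <- fragment_topology(fx$topology)
  intf <- contact_interface(fx$ensemble, "frag 0", "frag 3",
                            fragmentation = frag, ctc_control = 1.0)
  A <- frag$fragments[["frag 0"]]
  B <- frag$fragments[["frag 3"]]
  expect_true(all(intf$pairs$a %in% A))
  expect_true(all(intf$pairs$b %in% B))
  fr <- compute_frequencies(intf, 4.5)
  expect_true(all(fr$freq > 0))
  expect_identical(n_pairs(intf), 4L)  # the four scripted cross contacts
  expect_identical(intf$interface_split, list(A = A, B = B))
  expect_error(contact_interface(fx$ensemble, "frag 0", "frag 0",
                                 fragmentation = frag), "overlap")
  expect_error(contact_interface(fx$ensemble, 1:5, 3:8,
                                 fragmentation = frag), "overlap")
})

test_that("consensus-expression sides equal explicit index lists", {
  fx <- demo_fixture(seed = 1)
  frag <- fragment_topology(fx$topology)
  asg <- demo_assignments(fx)
  by_expr <- contact_interface(fx$ensemble, "G.H*", "TM*",
                               fragmentation = frag, assignments = asg,
                               ctc_control = 1.0)
  gh <- sort(unlist(consensus_fragments(asg$CGN, "G.H*")))
  tm <- sort(unlist(consensus_fragments(asg$GPCR, "TM*")))
  by_idx <- contact_interface(fx$ensemble, gh, tm, fragmentation = frag,
                              assignments = asg, ctc_control = 1.0)
  expect_identical(by_expr$pairs, by_idx$pairs)
  expect_identical(compute_frequencies(by_expr, 4.5)$freq,
                   compute_frequencies(by_idx, 4.5)$freq)
})

test_that("participation sums to twice the total frequency", {
  fx <- demo_fixture(seed = 1)
  nb <- residue_neighborhood(fx$ensemble, c(29L, 30L))
  fr <- compute_frequencies(nb, 4.5)
  part <- per_residue_participation(fr, nb)
  expect_equal(sum(part), 2 * sum(fr$freq), tolerance = 1e-15)
  expect_identical(unname(part[10]), 0)  # residue in no pair
  # residue in two pairs with F = .5 and .25 participates with .75
  top <- raw_topology(c("NA", "NA", "NA"), rep("Na", 3), 1:3,
                      rep("NA", 3), 1:3)
  xyz <- array(0, c(4, 3, 3))
  xyz[, 2, 1] <- 1; xyz[, 3, 1] <- 2
  xyz[, 1, 1] <- c(0.6, 0.6, 2, 2)        # pair (1,2): formed 2/4
  xyz[3:4, 3, 1] <- c(1.3, 5)             # pair (2,3): formed 1/4 at 4.5 A
  ens <- trajectory_ensemble(top, list(xyz))
  g <- contact_group(ens, rbind(c(1L, 2L), c(2L, 3L)))
  fr2 <- compute_frequencies(g, 4.5)
  part2 <- per_residue_participation(fr2, g)
  expect_identical(unname(part2[2]), fr2$freq[1] + fr2$freq[2])
})

test_that("representative frame minimizes distance to the mean vector", {
  # single pair scanning 0.40..0.60: the middle frame is the mean
  prof <- seq(0.40, 0.60, length.out = 11)
  fx <- small_fixture(contacts = list(list(pair = c(2L, 6L), profile = prof)),
                      n_frames = 11L, seed = 16)
  grp <- contact_group(fx$ensemble, rbind(c(2L, 6L)))
  rep_fr <- select_representative_frame(grp)
  expect_identical(rep_fr$frame, 6L)
  expect_identical(rep_fr$traj, 1L)
  # two equidistant frames -> the earlier one wins
  fx2 <- small_fixture(contacts = list(list(pair = c(2L, 6L),
                                            profile = c(0.40, 0.60))),
                       n_frames = 2L, seed = 17)
  g2 <- contact_group(fx2$ensemble, rbind(c(2L, 6L)))
  expect_identical(select_representative_frame(g2)$frame, 1L)
  # single frame -> that frame
  fx3 <- small_fixture(n_frames = 1L, seed = 18)
  g3 <- contact_group(fx3$ensemble, rbind(c(1L, 5L)))
  expect_identical(select_representative_frame(g3)$frame, 1L)
})

test_that("serialization round-trips distances, labels and frequencies", {
  fx <- demo_fixture(seed = 1)
  frag <- fragment_topology(fx$topology)
  asg <- demo_assignments(fx)
  nb <- residue_neighborhood(fx$ensemble, c(29L, 30L),
                             fragmentation = frag, assignments = asg)
  path <- tempfile(fileext = ".clgrp")
  serialize_group(nb, path)
  back <- deserialize_group(path)
  expect_identical(back$dist, nb$dist)
  expect_identical(back$atoms, nb$atoms)
  expect_identical(back$pairs, nb$pairs)
  expect_identical(back$n_frames, nb$n_frames)
  for (cc in c(3.5, 4.5, 5.5)) {
    a <- compute_frequencies(nb, cc)
    b <- compute_frequencies(back, cc)
    expect_identical(a$freq, b$freq)
    expect_identical(a$per_traj, b$per_traj)
    expect_identical(a$type_fractions, b$type_fractions)
    expect_identical(a$pairs$label_a, b$pairs$label_a)
  }
  # truncated archive -> integrity error
  raw <- readBin(path, "raw", file.size(path))
  short <- tempfile(fileext = ".clgrp")
  writeBin(raw[1:(length(raw) - 2000L)], short)
  expect_error(deserialize_group(short), "truncated")
  # wrong magic -> incompatibility error
  junk <- tempfile(fileext = ".clgrp")
  writeBin(charToRaw("NOTAGROUPFILE"), junk)
  expect_error(deserialize_group(junk), "not a contactlens group archive")
})
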