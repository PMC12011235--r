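# Synthetic-data generator: topologies (multi-chain peptides + ligands + ions
# + waters) and trajectories with planted, time-scripted residue-pair
# distances, so that every analysis stage is testable without external data.
# Coordinates are synthetic (residues on a sparse lattice, scripted rigid
# displacements), not physical dynamics: only distance geometry matters to the
# engine under test. The generator validates its own ground truth: scripted
# pair distances are solved to 1e-4 nm on the true minimum-distance function,
# and unscripted pairs are kept isolated beyond the analysis cutoffs.

.one2three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# sidechain layouts: chain atoms run along -y from CB; branches stick out in z
.SIDECHAINS <- list(
  GLY = list(chain = character(0), branches = list()),
  ALA = list(chain = "CB", branches = list()),
  SER = list(chain = c("CB", "OG"), branches = list()),
  CYS = list(chain = c("CB", "SG"), branches = list()),
  THR = list(chain = c("CB", "OG1"),
             branches = list(list("CG2", 1L, 1))),
  VAL = list(chain = "CB",
             branches = list(list("CG1", 1L, 1), list("CG2", 1L, -1))),
  LEU = list(chain = c("CB", "CG"),
             branches = list(list("CD1", 2L, 1), list("CD2", 2L, -1))),
  ILE = list(chain = c("CB", "CG1", "CD1"),
             branches = list(list("CG2", 1L, 1))),
  MET = list(chain = c("CB", "CG", "SD", "CE"), branches = list()),
  PRO = list(chain = c("CB", "CG", "CD"), branches = list()),
  PHE = list(chain = c("CB", "CG", "CD1", "CE1", "CZ"),
             branches = list(list("CD2", 2L, 1), list("CE2", 3L, 1))),
  TYR = list(chain = c("CB", "CG", "CD1", "CE1", "CZ", "OH"),
             branches = list(list("CD2", 2L, 1), list("CE2", 3L, 1))),
  TRP = list(chain = c("CB", "CG", "CD1", "NE1", "CE2", "CZ2"),
             branches = list(list("CD2", 2L, -1), list("CE3", 3L, -1))),
  ASP = list(chain = c("CB", "CG"),
             branches = list(list("OD1", 2L, 1), list("OD2", 2L, -1))),
  GLU = list(chain = c("CB", "CG", "CD"),
             branches = list(list("OE1", 3L, 1), list("OE2", 3L, -1))),
  ASN = list(chain = c("CB", "CG"),
             branches = list(list("OD1", 2L, 1), list("ND2", 2L, -1))),
  GLN = list(chain = c("CB", "CG", "CD"),
             branches = list(list("OE1", 3L, 1), list("NE2", 3L, -1))),
  HIS = list(chain = c("CB", "CG", "ND1", "CE1", "NE2"),
             branches = list(list("CD2", 2L, 1))),
  LYS = list(chain = c("CB", "CG", "CD", "CE", "NZ"), branches = list()),
  ARG = list(chain = c("CB", "CG", "CD", "NE", "CZ"),
             branches = list(list("NH1", 5L, 1), list("NH2", 5L, -1))))

.LIGAND_TEMPLATES <- list(
  P0G = list(names = c("C1", "C2", "C3", "N1", "O1", "H1"),
             elements = c("C", "C", "C", "N", "O", "H"),
             xyz = rbind(c(0, 0, 0), c(0.01, -0.14, 0), c(0.02, -0.28, 0),
                         c(0.03, -0.42, 0), c(0.02, -0.30, 0.17),
                         c(0.08, 0.06, 0))),
  GDP = list(names = c("PB", "O1B", "O2B", "PA", "O3A", "C5A", "C4A",
                       "C1A", "N9", "C8"),
             elements = c("P", "O", "O", "P", "O", "C", "C", "C", "N", "C"),
             xyz = rbind(c(0, 0, 0), c(0.01, -0.02, 0.17),
                         c(0.01, -0.02, -0.17), c(0.01, -0.14, 0),
                         c(0.02, -0.28, 0), c(0.03, -0.42, 0),
                         c(0.04, -0.56, 0), c(0.05, -0.70, 0),
                         c(0.06, -0.84, 0), c(0.07, -0.98, 0))),
  HOH = list(names = c("O", "H1", "H2"), elements = c("O", "H", "H"),
             xyz = rbind(c(0, 0, 0), c(0.08, 0.06, 0), c(-0.08, 0.06, 0))),
  "NA" = list(names = "NA", elements = "Na", xyz = rbind(c(0, 0, 0))),
  CL = list(names = "CL", elements = "Cl", xyz = rbind(c(0, 0, 0))))

#' Local-coordinate template of a residue
#'
#' Amino acids get a standard backbone (N, H, CA, HA, C, O) with the sidechain
#' running towards -y and branch atoms offset in z; atom names are the
#' conventional ones so that classification and bond inference behave like on
#' real files. A small set of ligand/solvent templates (P0G, GDP, HOH, NA, CL)
#' covers the non-protein cases.
#'
#' @param name residue name (3-letter amino acid or template code).
#' @return list with `names`, `elements`, `xyz` (local nm coordinates) and
#'   `bonds` (intra-residue bonded name pairs).
#' @export
residue_template <- function(name) {
  nm <- toupper(name)
  if (nm %in% names(.LIGAND_TEMPLATES)) {
    t <- .LIGAND_TEMPLATES[[nm]]
    nb <- length(t$names)
    bonds <- if (nb > 1L) {
      heavy <- which(t$elements != "H")
      cbind(head(heavy, -1L), tail(heavy, -1L))
    } else matrix(integer(0), ncol = 2)
    return(list(names = t$names, elements = t$elements, xyz = t$xyz,
                bonds = matrix(t$names[bonds], ncol = 2)))
  }
  if (!nm %in% names(.SIDECHAINS)) {
    stop(sprintf("no residue template for '%s'", name))
  }
  names_v <- c("N", "H", "CA", "HA", "C", "O")
  elements <- c("N", "H", "C", "H", "C", "O")
  xyz <- rbind(c(0, 0, 0), c(-0.08, 0.06, 0), c(0.15, 0, 0),
               c(0.15, 0.10, 0.05), c(0.29, 0.05, 0), c(0.33, 0.16, 0))
  bonds <- rbind(c("N", "H"), c("N", "CA"), c("CA", "HA"), c("CA", "C"),
                 c("C", "O"))
  sc <- .SIDECHAINS[[nm]]
  chain_pos <- function(k) c(0.15 + 0.01 * k, -0.14 * k, 0)
  prev <- "CA"
  for (k in seq_along(sc$chain)) {
    names_v <- c(names_v, sc$chain[k])
    elements <- c(elements, guess_element(sc$chain[k], nm))
    xyz <- rbind(xyz, chain_pos(k))
    bonds <- rbind(bonds, c(prev, sc$chain[k]))
    prev <- sc$chain[k]
  }
  for (br in sc$branches) {
    parent_k <- br[[2L]]
    names_v <- c(names_v, br[[1L]])
    elements <- c(elements, guess_element(br[[1L]], nm))
    xyz <- rbind(xyz, chain_pos(parent_k) + c(0, -0.02, 0.17 * br[[3L]]))
    bonds <- rbind(bonds, c(sc$chain[parent_k], br[[1L]]))
  }
  if (length(sc$chain)) {  # one sidechain hydrogen on CB
    names_v <- c(names_v, "HB")
    elements <- c(elements, "H")
    xyz <- rbind(xyz, chain_pos(1L) + c(0.08, 0, 0.08))
    bonds <- rbind(bonds, c("CB", "HB"))
  }
  rownames(xyz) <- NULL
  list(names = names_v, elements = elements, xyz = xyz, bonds = bonds)
}

#' Specify a synthetic fixture
#'
#' @param chains list of chain specs: `list(seq = <3-letter vector or
#'   one-letter string>, resseq_start = <int>, jumps = <named vector:
#'   within-chain position -> resSeq increment instead of 1>, chain_id =
#'   <letter>)`.
#' @param ligands character vector of ligand template codes (`"P0G"`,
#'   `"GDP"`).
#' @param ions character vector of ion codes (`"NA"`, `"CL"`).
#' @param waters number of water molecules.
#' @param contacts list of scripted contacts: `list(pair = c(i, j), profile =
#'   <numeric target min heavy-atom distance per frame, nm; or list with one
#'   vector per trajectory>)`. Residue `j` moves along a dedicated axis
#'   towards `i`; one residue may move in at most one script.
#' @param n_frames integer vector: frames per trajectory.
#' @param layout `"lattice"` (every residue isolated on a sparse grid,
#'   default) or `"chain"` (peptide chains laid out contiguously, so that
#'   consecutive residues are bonded-range and GRO bond inference applies).
#' @param box optional length-3 periodic box (nm).
#' @param positions optional named list: residue index -> length-3 position
#'   overriding the layout (e.g. to straddle a periodic boundary).
#' @param seed integer seed (fully determines the output).
#' @return object of class `FixtureSpec`.
#' @export
fixture_spec <- function(chains = list(), ligands = character(0),
                         ions = character(0), waters = 0L,
                         contacts = list(), n_frames = 100L,
                         layout = c("lattice", "chain"), box = NULL,
                         positions = NULL, seed = 1L) {
  layout <- match.arg(layout)
  chains <- lapply(chains, function(ch) {
    if (is.character(ch$seq) && length(ch$seq) == 1L &&
        !ch$seq[1L] %in% names(.SIDECHAINS)) {
      letters1 <- strsplit(toupper(ch$seq), "")[[1L]]
      ch$seq <- unname(.one2three[letters1])
      if (anyNA(ch$seq)) stop("unknown one-letter code in chain seq")
    }
    if (is.null(ch$resseq_start)) ch$resseq_start <- 1L
    ch
  })
  structure(list(chains = chains, ligands = ligands, ions = ions,
                 waters = as.integer(waters), contacts = contacts,
                 n_frames = as.integer(n_frames), layout = layout,
                 box = box, positions = positions, seed = as.integer(seed)),
            class = "FixtureSpec")
}

# grid of sparse lattice sites (4 nm spacing)
.lattice_sites <- function(n, spacing = 4) {
  m <- ceiling(n^(1 / 3))
  k <- seq_len(n) - 1L
  cbind((k %% m), ((k %/% m) %% m), (k %/% (m * m))) * spacing + 1
}

# solve the translation s so that the minimum heavy-atom cross distance
# between static atoms A and the mover template placed at base + s*u equals d
.solve_script_s <- function(A_heavy, B_local_heavy, base, u, d) {
  nA <- nrow(A_heavy); nB <- nrow(B_local_heavy)
  C <- A_heavy[rep(seq_len(nA), each = nB), , drop = FALSE] -
    B_local_heavy[rep(seq_len(nB), nA), , drop = FALSE] -
    matrix(base, nA * nB, 3L, byrow = TRUE)
  g <- function(s) {
    D <- C - matrix(u * s, nrow(C), 3L, byrow = TRUE)
    sqrt(min(rowSums(D * D)))
  }
  grid <- seq(0, 6, by = 0.02)
  gv <- vapply(grid, g, numeric(1))
  imin <- which.min(gv)
  if (d < gv[imin] - 1e-9) {
    stop(sprintf(
      "infeasible script: target distance %.3f nm below closest approach %.3f nm",
      d, gv[imin]))
  }
  k <- imin + which(gv[(imin + 1L):length(gv)] >= d)[1L]
  if (is.na(k)) stop("infeasible script: target distance too large")
  stats::uniroot(function(s) g(s) - d, c(grid[k - 1L], grid[k]),
                 tol = 1e-12)$root
}

#' Build a synthetic fixture
#'
#' Places every residue from its template, solves the scripted per-frame
#' displacements exactly, validates the planted ground truth (scripted
#' distances to 1e-4 nm; unscripted pairs isolated), and returns topology,
#' trajectory ensemble and the ground-truth record.
#'
#' @param spec a `FixtureSpec`.
#' @return list with `topology`, `ensemble`, and `truth`: `contacts` (pair,
#'   per-trajectory target distance profiles), `fragments` (planted residue
#'   sets with names), `n_frames`, `uncontrolled_pairs` (mover-mover pairs
#'   whose mutual distance is not scripted), `seed`.
#' @export
build_fixture <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)

  # ---- roster -------------------------------------------------------------
  res_names <- character(0)
  res_seq <- integer(0)
  res_chain <- character(0)
  unit_of <- integer(0)    # planted fragment id per residue
  unit_names <- character(0)
  chain_members <- list()
  uid <- 0L
  for (ci in seq_along(spec$chains)) {
    ch <- spec$chains[[ci]]
    uid <- uid + 1L
    unit_names <- c(unit_names, if (!is.null(ch$name)) ch$name
                    else sprintf("chain %d", ci))
    rs <- ch$resseq_start
    seqs <- integer(length(ch$seq))
    for (k in seq_along(ch$seq)) {
      if (k > 1L) {
        step <- 1L
        if (!is.null(ch$jumps) && as.character(k) %in% names(ch$jumps)) {
          step <- as.integer(ch$jumps[[as.character(k)]])
        }
        rs <- rs + step
      }
      seqs[k] <- rs
    }
    first <- length(res_names) + 1L
    res_names <- c(res_names, ch$seq)
    res_seq <- c(res_seq, seqs)
    res_chain <- c(res_chain,
                   rep(if (is.null(ch$chain_id)) LETTERS[ci] else ch$chain_id,
                       length(ch$seq)))
    unit_of <- c(unit_of, rep(uid, length(ch$seq)))
    chain_members[[ci]] <- first:length(res_names)
  }
  singles <- c(spec$ligands, spec$ions, rep("HOH", spec$waters))
  for (nm in singles) {
    uid <- uid + 1L
    unit_names <- c(unit_names, nm)
    res_names <- c(res_names, nm)
    res_seq <- c(res_seq, max(c(res_seq, 0L)) + 1L)
    res_chain <- c(res_chain, NA_character_)
    unit_of <- c(unit_of, uid)
  }
  n_res <- length(res_names)
  if (!n_res) stop("fixture spec defines no residues")

  # ---- base placement -----------------------------------------------------
  base <- matrix(NA_real_, n_res, 3L)
  if (spec$layout == "lattice") {
    base <- .lattice_sites(n_res)
  } else {
    row <- 0L
    for (ci in seq_along(chain_members)) {
      mem <- chain_members[[ci]]
      base[mem, ] <- cbind(1 + (seq_along(mem) - 1L) * 0.42,
                           1 + row * 4, 1)
      row <- row + 1L
    }
    extra <- which(is.na(base[, 1L]))
    if (length(extra)) {
      base[extra, ] <- cbind(1 + (seq_along(extra) - 1L) * 4,
                             1 + row * 4, 1)
    }
  }
  if (!is.null(spec$positions)) {
    for (nm in names(spec$positions)) {
      base[as.integer(nm), ] <- spec$positions[[nm]]
    }
  }

  # ---- atoms --------------------------------------------------------------
  templates <- lapply(res_names, residue_template)
  atom_res <- rep(seq_len(n_res), vapply(templates, function(t)
    length(t$names), integer(1)))
  atom_name <- unlist(lapply(templates, `[[`, "names"))
  atom_el <- unlist(lapply(templates, `[[`, "elements"))
  first_atom <- match(seq_len(n_res), atom_res)
  xyz0 <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    templates[[r]]$xyz + matrix(base[r, ], nrow(templates[[r]]$xyz), 3L,
                                byrow = TRUE)
  }))

  # bonds: template intra-residue + peptide links inside declared chains
  bond_rows <- list()
  for (r in seq_len(n_res)) {
    tb <- templates[[r]]$bonds
    if (nrow(tb)) {
      off <- first_atom[r] - 1L
      ai <- off + match(tb[, 1L], templates[[r]]$names)
      bi <- off + match(tb[, 2L], templates[[r]]$names)
      bond_rows[[length(bond_rows) + 1L]] <- cbind(ai, bi)
    }
  }
  for (mem in chain_members) {
    for (k in seq_len(length(mem) - 1L)) {
      ci <- first_atom[mem[k]] - 1L +
        match("C", templates[[mem[k]]]$names)
      ni <- first_atom[mem[k + 1L]]  # N is the first template atom
      bond_rows[[length(bond_rows) + 1L]] <- cbind(ci, ni)
    }
  }
  topology <- new_topology(
    data.frame(name = atom_name, element = atom_el, residue = atom_res,
               stringsAsFactors = FALSE),
    data.frame(name = res_names, resSeq = res_seq, chain = res_chain,
               stringsAsFactors = FALSE),
    do.call(rbind, bond_rows))

  # ---- scripted motion ----------------------------------------------------
  nT <- length(spec$n_frames)
  xyz_list <- lapply(spec$n_frames, function(nf) {
    a <- array(NA_real_, c(nf, nrow(xyz0), 3L))
    for (f in seq_len(nf)) a[f, , ] <- xyz0
    a
  })
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  movers <- integer(0)
  anchors <- integer(0)
  axis_used <- list()
  truth_contacts <- list()
  for (sc in spec$contacts) {
    i <- sc$pair[1L]; j <- sc$pair[2L]
    if (i == j) stop("infeasible script: a residue cannot contact itself")
    if (j %in% movers) {
      stop(sprintf(
        "infeasible script: residue %d moves in more than one script", j))
    }
    if (j %in% anchors || i %in% movers) {
      stop(sprintf(
        "infeasible script: residue %d is both anchor and mover",
        if (j %in% anchors) j else i))
    }
    movers <- c(movers, j)
    anchors <- c(anchors, i)
    used <- axis_used[[as.character(i)]]
    ax <- setdiff(seq_len(6L), used)
    if (!length(ax)) {
      stop(sprintf("infeasible script: more than 6 movers on anchor %d", i))
    }
    axis_used[[as.character(i)]] <- c(used, ax[1L])
    u <- axes[ax[1L], ]

    profiles <- sc$profile
    if (!is.list(profiles)) {
      if (nT > 1L) stop("profile must be a list with one vector per trajectory")
      profiles <- list(profiles)
    }
    if (length(profiles) != nT) {
      stop("profile list length must equal the number of trajectories")
    }
    A_heavy <- xyz0[residue_atoms(topology, i, heavy_only = TRUE), ,
                    drop = FALSE]
    tj <- templates[[j]]
    B_local <- tj$xyz[tj$elements != "H", , drop = FALSE]
    mover_atoms <- which(atom_res == j)
    cache <- new.env(parent = emptyenv())
    for (tr in seq_len(nT)) {
      prof <- profiles[[tr]]
      if (length(prof) != spec$n_frames[tr]) {
        stop(sprintf(
          "profile for trajectory %d has %d values, expected %d frames",
          tr, length(prof), spec$n_frames[tr]))
      }
      if (any(prof > 1.6)) stop("profile distances must stay below 1.6 nm")
      for (f in seq_len(spec$n_frames[tr])) {
        key <- sprintf("%.6f", prof[f])
        if (is.null(cache[[key]])) {
          cache[[key]] <- .solve_script_s(A_heavy, B_local, base[i, ], u,
                                          prof[f])
        }
        s <- cache[[key]]
        pos <- base[i, ] + s * u
        xyz_list[[tr]][f, mover_atoms, ] <-
          tj$xyz + matrix(pos, nrow(tj$xyz), 3L, byrow = TRUE)
      }
    }
    truth_contacts[[length(truth_contacts) + 1L]] <-
      list(pair = c(i, j), profiles = profiles)
  }

  ensemble <- trajectory_ensemble(topology, xyz_list, box = spec$box,
                                  files = sprintf("fixture_traj_%d",
                                                  seq_len(nT)))

  # ---- validation ---------------------------------------------------------
  scripted_keys <- vapply(truth_contacts, function(tc) {
    paste(sort(tc$pair), collapse = "-")
  }, character(1))
  # scripted exactness on the true minimum heavy-atom distance
  for (tc in truth_contacts) {
    ia <- residue_atoms(topology, tc$pair[1L], heavy_only = TRUE)
    ib <- residue_atoms(topology, tc$pair[2L], heavy_only = TRUE)
    for (tr in seq_len(nT)) {
      blk <- .pair_block(xyz_list[[tr]], ia, ib)
      err <- max(abs(blk$d - tc$profiles[[tr]]))
      if (err > 1e-4) {
        stop(sprintf(
          "fixture validation failed: scripted pair %d-%d off by %.2g nm",
          tc$pair[1L], tc$pair[2L], err))
      }
    }
  }
  # isolation of unscripted pairs (centroid bound, exact check when flagged);
  # mover-mover pairs are not controlled and only checked against overlap
  radius <- vapply(seq_len(n_res), function(r) {
    tx <- templates[[r]]$xyz
    ctr <- colMeans(tx)
    max(sqrt(rowSums(sweep(tx, 2L, ctr)^2)))
  }, numeric(1))
  uncontrolled <- list()
  margin <- 0.50
  bonded_ok <- function(a, b) {
    spec$layout == "chain" && abs(a - b) <= 1L &&
      unit_of[a] == unit_of[b] && unit_of[a] <= length(spec$chains)
  }
  check_pair <- function(a, b, tr, frames) {
    ia <- residue_atoms(topology, a, heavy_only = TRUE)
    ib <- residue_atoms(topology, b, heavy_only = TRUE)
    blk <- .pair_block(xyz_list[[tr]][frames, , , drop = FALSE], ia, ib)
    min(blk$d)
  }
  centroid_tr <- function(tr) {
    # residue centroids per frame: frames x residues x 3
    nf <- spec$n_frames[tr]
    ctr <- array(0, c(nf, n_res, 3L))
    for (r in seq_len(n_res)) {
      idx <- which(atom_res == r)
      for (k in 1:3) {
        ctr[, r, k] <- rowMeans(matrix(xyz_list[[tr]][, idx, k],
                                       nrow = nf))
      }
    }
    ctr
  }
  for (tr in seq_len(nT)) {
    ctr <- centroid_tr(tr)
    # coarse per-frame screen on centroid distances, exact check when flagged
    for (f in seq_len(spec$n_frames[tr])) {
      cf <- ctr[f, , ]
      D <- as.matrix(stats::dist(cf))
      flag <- which(D - outer(radius, radius, "+") < margin &
                      upper.tri(D), arr.ind = TRUE)
      for (rw in seq_len(nrow(flag))) {
        a <- flag[rw, 1L]; b <- flag[rw, 2L]
        key <- paste(sort(c(a, b)), collapse = "-")
        if (key %in% scripted_keys || bonded_ok(a, b)) next
        if (a %in% movers && b %in% movers) {
          dmin <- check_pair(a, b, tr, f)
          if (dmin < 0.25) {
            stop(sprintf(
              "fixture validation failed: movers %d and %d overlap (%.2f nm)",
              a, b, dmin))
          }
          uncontrolled[[key]] <- sort(c(a, b))
          next
        }
        dmin <- check_pair(a, b, tr, f)
        if (dmin < margin) {
          stop(sprintf(
            "fixture validation failed: unscripted pair %d-%d at %.2f nm (frame %d)",
            a, b, dmin, f))
        }
      }
    }
  }

  fragments <- split(seq_len(n_res), unit_of)
  names(fragments) <- unit_names
  list(topology = topology, ensemble = ensemble,
       truth = list(contacts = truth_contacts, fragments = fragments,
                    n_frames = spec$n_frames,
                    uncontrolled_pairs = unname(uncontrolled),
                    seed = spec$seed))
}

#' Write a fixture to standard files
#'
#' @param fixture result of [build_fixture()].
#' @param dir output directory (created).
#' @param format `"pdb"` (topology PDB + one multi-model PDB per trajectory)
#'   or `"gro"` (topology GRO + concatenated-frame GRO per trajectory).
#' @return list with `topology` path and `trajectories` paths.
#' @export
write_fixture <- function(fixture, dir, format = c("pdb", "gro")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ens <- fixture$ensemble
  box <- if (!is.null(ens$box)) ens$box[[1L]]
  top_path <- file.path(dir, paste0("topology.", format))
  if (format == "pdb") {
    write_pdb(fixture$topology, ens$xyz[[1L]][1L, , ], top_path, box = box)
  } else {
    write_gro(fixture$topology, ens$xyz[[1L]][1L, , ], top_path, box = box)
  }
  traj_paths <- character(length(ens$xyz))
  for (tr in seq_along(ens$xyz)) {
    traj_paths[tr] <- file.path(dir, sprintf("traj_%d.%s", tr, format))
    if (format == "pdb") {
      write_pdb(fixture$topology, ens$xyz[[tr]], traj_paths[tr], box = box)
    } else {
      write_gro(fixture$topology, ens$xyz[[tr]], traj_paths[tr], box = box)
    }
  }
  list(topology = top_path, trajectories = traj_paths)
}

#' Consensus-labeling fixture: reference table + mutated topology
#'
#' Builds a reference consensus table from a sequence and labeled positions,
#' applies a mutation/indel plan to derive a homolog, and returns the expected
#' label assignment (labels follow their residues through the indels;
#' substituted positions still transfer, deleted ones vanish).
#'
#' @param ref_seq one-letter reference sequence.
#' @param labels data.frame with `position`, `label`, `fragment`.
#' @param n_sub number of random substitutions (seeded).
#' @param indels list of `list(pos, len)`: `len > 0` inserts that many
#'   residues after `pos`, `len < 0` deletes `-len` residues starting at
#'   `pos`.
#' @param scheme consensus scheme of the table.
#' @param dir directory for the table files.
#' @param seed integer seed.
#' @return list with `csv`, `xlsx` (table files), `topology`, `ensemble`
#'   (single frame), `expected` (data.frame res_index, label), `mutated_seq`.
#' @export
build_consensus_fixture <- function(ref_seq, labels, n_sub = 0L,
                                    indels = list(), scheme = "GPCR",
                                    dir = tempdir(), seed = 1L) {
  set.seed(seed)
  ref <- strsplit(ref_seq, "")[[1L]]
  n <- length(ref)
  stopifnot(all(labels$position >= 1L), all(labels$position <= n))
  tab <- data.frame(residue = ref[labels$position],
                    position = labels$position,
                    label = labels$label, fragment = labels$fragment,
                    stringsAsFactors = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, sprintf("consensus_%s_%d.csv", scheme, seed))
  utils::write.csv(tab, csv, row.names = FALSE)
  xlsx <- file.path(dir, sprintf("consensus_%s_%d.xlsx", scheme, seed))
  write_xlsx_sheet(tab, xlsx, sheet = "nomenclature")

  # mutate: substitutions first (on reference coordinates), then indels
  mut <- ref
  if (n_sub > 0L) {
    sub_pos <- sample(n, n_sub)
    for (p in sub_pos) {
      mut[p] <- sample(setdiff(names(.one2three), mut[p]), 1L)
    }
  }
  map <- seq_len(n)  # reference position -> mutated position (NA = deleted)
  for (ind in indels) {
    pos <- ind[[1L]]; len <- ind[[2L]]
    if (len < 0L) {
      del <- pos:(pos - len - 1L)
      mpos <- map[del]
      mpos <- mpos[!is.na(mpos)]
      mut <- mut[-mpos]
      map[del] <- NA_integer_
      shift <- !is.na(map) & map > max(mpos)
      map[shift] <- map[shift] - length(mpos)
    } else {
      at <- map[pos]
      if (is.na(at)) next
      ins <- sample(names(.one2three), len, replace = TRUE)
      mut <- append(mut, ins, after = at)
      shift <- !is.na(map) & map > at
      map[shift] <- map[shift] + len
    }
  }
  surviving <- labels[!is.na(map[labels$position]), , drop = FALSE]
  if (nrow(surviving) < 0.5 * nrow(labels)) {
    stop("mutation plan removes more than half of the labels; refusing")
  }
  fx <- build_fixture(fixture_spec(
    chains = list(list(seq = paste(mut, collapse = ""), resseq_start = 1L,
                       name = "query")),
    n_frames = 1L, seed = seed))
  expected <- data.frame(res_index = map[surviving$position],
                         label = surviving$label,
                         stringsAsFactors = FALSE)
  list(csv = csv, xlsx = xlsx, topology = fx$topology,
       ensemble = fx$ensemble, expected = expected,
       mutated_seq = paste(mut, collapse = ""))
}
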