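# Bundled demo system: a receptor--G-protein-shaped synthetic fixture (four
# peptide fragments: G-alpha, G-beta, G-gamma and a receptor, plus the
# receptor ligand P0G and, optionally, GDP, ions and waters), with scripted
# contacts between the two C-terminal residues of the G-alpha helix 5 and
# receptor residues. Consensus tables (CGN for G-alpha helix 5, GPCRdb-style
# for the receptor) are generated alongside, so CLI walkthroughs and tests
# run fully offline.

.DEMO_GALPHA <- "MTEYKLVVVGAGGVGKSALTIQLIQNYFLL"  # resSeq 365..394
.DEMO_GBETA <- "WDVREGMCRQ"                       # resSeq 30..39
.DEMO_GGAMMA <- "ASNNTASI"                        # resSeq 50..57
.DEMO_RECEPTOR <- "KTSLAVITDYEEYFARVEPLSQNKALEGTMVFWESNLIHQ"  # 120..159

#' CGN and GPCR consensus tables of the demo system
#'
#' The CGN table labels the last 26 G-alpha positions as helix 5
#' (`G.H5.1`..`G.H5.26`, so the C-terminal LEU394 is `G.H5.26` and TYR391 is
#' `G.H5.23`); the GPCR table labels receptor stretches as ICL1, TM3 (with
#' position 3.50 at resSeq 131), ICL2, ICL3, TM5 and TM6.
#'
#' @return list of two data.frames (`cgn`, `gpcr`) in the
#'   [read_consensus_table()] column layout.
#' @export
demo_consensus_tables <- function() {
  ga <- strsplit(.DEMO_GALPHA, "")[[1L]]
  cgn <- data.frame(residue = ga[5:30], position = 5:30,
                    label = sprintf("G.H5.%d", 1:26),
                    fragment = "G.H5", stringsAsFactors = FALSE)
  rc <- strsplit(.DEMO_RECEPTOR, "")[[1L]]
  blocks <- list(
    list(pos = 2:4, label = sprintf("12.%d", 48:50), fragment = "ICL1"),
    list(pos = 8:16, label = sprintf("3.%d", 46:54), fragment = "TM3"),
    list(pos = 18:21, label = sprintf("34.%d", 50:53), fragment = "ICL2"),
    list(pos = 25:27, label = sprintf("35.%d", 50:52), fragment = "ICL3"),
    list(pos = 29:32, label = sprintf("5.%d", 62:65), fragment = "TM5"),
    list(pos = 34:38, label = sprintf("6.%d", 30:34), fragment = "TM6"))
  gpcr <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(residue = rc[b$pos], position = b$pos, label = b$label,
               fragment = b$fragment, stringsAsFactors = FALSE)
  }))
  list(cgn = cgn, gpcr = gpcr)
}

#' Build the bundled demo fixture
#'
#' Two trajectories (100 and 50 frames) with scripted contacts: the G-alpha
#' C-terminal LEU394 against receptor E131 (formed throughout trajectory 1,
#' never in trajectory 2, so its global frequency is 100/150 = 2/3 while the
#' naive mean of the per-trajectory frequencies would be 1/2), Y132 and A124
#' at intermediate frequencies, LEU393 against F133, the ligand P0G against
#' V125, and (in the full variant) GDP against the G-alpha K380.
#'
#' @param seed integer seed.
#' @param full include GDP, two ions and two waters (10 fragments under the
#'   `default` heuristic); `FALSE` gives the minimal four-peptide-chains +
#'   P0G system (5 fragments, ligand last).
#' @return as [build_fixture()], plus `tables` (the consensus data.frames) and
#'   `anchors` (the display names of the scripted anchor residues).
#' @export
demo_fixture <- function(seed = 1L, full = TRUE) {
  n1 <- 100L; n2 <- 50L
  prof <- function(v1, v2) list(v1, v2)
  const <- function(x, n) rep(x, n)
  step <- function(x_on, x_off, n_on, n) c(rep(x_on, n_on),
                                           rep(x_off, n - n_on))
  contacts <- list(
    # L394 (res 30) -- E131 (res 60): the unequal-trajectory worked case
    list(pair = c(30L, 60L),
         profile = prof(const(0.32, n1), const(0.90, n2))),
    # L394 -- Y132 (res 61): formed 80/100 and 50/50
    list(pair = c(30L, 61L),
         profile = prof(step(0.35, 0.80, 80L, n1), const(0.35, n2))),
    # L394 -- A124 (res 53): formed 30/100 and 0/50
    list(pair = c(30L, 53L),
         profile = prof(step(0.40, 0.90, 30L, n1), const(0.90, n2))),
    # L393 (res 29) -- F133 (res 62): formed 55/100 and 0/50
    list(pair = c(29L, 62L),
         profile = prof(step(0.38, 0.85, 55L, n1), const(0.85, n2))),
    # P0G (res 89) -- V125 (res 54): always formed
    list(pair = c(54L, 89L),
         profile = prof(const(0.33, n1), const(0.33, n2))))
  if (full) {
    contacts <- c(contacts, list(
      # GDP (res 90) -- K380 (res 16): always formed
      list(pair = c(16L, 90L),
           profile = prof(const(0.36, n1), const(0.36, n2)))))
  }
  spec <- fixture_spec(
    chains = list(
      list(seq = .DEMO_GALPHA, resseq_start = 365L, name = "Galpha",
           chain_id = "A"),
      list(seq = .DEMO_GBETA, resseq_start = 30L, name = "Gbeta",
           chain_id = "B"),
      list(seq = .DEMO_GGAMMA, resseq_start = 50L, name = "Ggamma",
           chain_id = "G"),
      list(seq = .DEMO_RECEPTOR, resseq_start = 120L, name = "receptor",
           chain_id = "R")),
    ligands = if (full) c("P0G", "GDP") else "P0G",
    ions = if (full) c("NA", "CL") else character(0),
    waters = if (full) 2L else 0L,
    contacts = contacts, n_frames = c(n1, n2), seed = seed)
  fx <- build_fixture(spec)
  fx$tables <- demo_consensus_tables()
  fx$anchors <- residue_display(fx$topology, c(29L, 30L))
  fx
}

#' Write the demo fixture and its side files to a directory
#'
#' Produces topology + trajectory files, the two consensus tables (CSV) and a
#' JSON site file, i.e. everything a command-line walkthrough needs, offline.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param format `"pdb"` or `"gro"`.
#' @param full see [demo_fixture()].
#' @return named list of file paths (plus the fixture under `$fixture`).
#' @export
demo_files <- function(dir, seed = 1L, format = "pdb", full = TRUE) {
  fx <- demo_fixture(seed = seed, full = full)
  paths <- write_fixture(fx, dir, format = format)
  tabs <- fx$tables
  cgn <- file.path(dir, "cgn_table.csv")
  gpcr <- file.path(dir, "gpcr_table.csv")
  utils::write.csv(tabs$cgn, cgn, row.names = FALSE)
  utils::write.csv(tabs$gpcr, gpcr, row.names = FALSE)
  sites <- file.path(dir, "sites.json")
  jsonlite::write_json(
    list(list(name = "receptor core",
              pairs = list("R135-E131", "L394-E131"))),
    sites, auto_unbox = TRUE)
  list(topology = paths$topology, trajectories = paths$trajectories,
       cgn_table = cgn, gpcr_table = gpcr, sites = sites, fixture = fx)
}
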