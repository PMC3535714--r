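# Shared configuration for the synthetic comparative-promoter study.
#
# A panel of synthetic "species" genomes, each carrying the
# TBC1D9-UCP1-ELMOD2 triplet, with promoter features planted at known
# anchor-relative positions so every downstream call can be scored against
# truth.  Island composition targets and element divergences are chosen to
# span the regimes of interest: dense islands the seeded scan finds (high
# stringency), marginal islands only exhaustive enumeration finds (low
# stringency), absent islands, and enhancer/PRR homologs from near-identity
# down to sub-threshold divergence.

suppressPackageStartupMessages(library(prometh))

RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "synthetic")
BASE_SEED <- 20120304L

# ~500 bp query elements ("enhancer" at human anchor position -3488, "prr"
# at -2095), fixed across the panel
element_queries <- function(seed = BASE_SEED) {
  list(
    enhancer = element_query(
      "enhancer",
      prometh:::with_seed(seed + 1L, prometh:::sample_chain(500L, 0.45, 0.10)),
      human_anchor_position = -3488L
    ),
    prr = element_query(
      "prr",
      prometh:::with_seed(seed + 2L, prometh:::sample_chain(500L, 0.45, 0.10)),
      human_anchor_position = -2095L
    )
  )
}

# per-species plan: island (NULL = none), element divergences (NA = absent),
# focal strand, and whether the triplet is deliberately scrambled
species_panel <- list(
  Human = list(
    island = c(len = 420, gc = 0.63, oe = 0.90), island_pos = -350L,
    enhancer_div = 0.05, prr_div = 0.10, strand = "+", scrambled = FALSE
  ),
  Cow = list(
    island = c(len = 380, gc = 0.61, oe = 0.85), island_pos = -420L,
    enhancer_div = 0.215, prr_div = 0.20, strand = "+", scrambled = FALSE
  ),
  Pig = list(
    island = c(len = 400, gc = 0.62, oe = 0.88), island_pos = -300L,
    enhancer_div = 0.24, prr_div = NA, strand = "+", scrambled = FALSE
  ),
  Rat = list(
    island = c(len = 300, gc = 0.55, oe = 0.68), island_pos = -500L,
    enhancer_div = 0.15, prr_div = NA, strand = "-", scrambled = FALSE
  ),
  Mouse = list(
    island = NULL, island_pos = NA,
    enhancer_div = 0.10, prr_div = NA, strand = "-", scrambled = FALSE
  ),
  Marmoset = list(
    island = c(len = 450, gc = 0.64, oe = 0.95), island_pos = -250L,
    enhancer_div = NA, prr_div = NA, strand = "+", scrambled = FALSE
  ),
  Xenopus = list(
    island = NULL, island_pos = NA,
    enhancer_div = NA, prr_div = NA, strand = "+", scrambled = FALSE
  ),
  Hedgehog = list(
    # island downstream of the anchor: the reason the CGI screen keeps a
    # downstream margin
    island = c(len = 350, gc = 0.62, oe = 0.90), island_pos = 150L,
    enhancer_div = NA, prr_div = NA, strand = "+", scrambled = FALSE
  ),
  Decoy = list(
    island = c(len = 400, gc = 0.62, oe = 0.88), island_pos = -300L,
    enhancer_div = 0.05, prr_div = 0.05, strand = "+", scrambled = TRUE
  )
)

species_seed <- function(i) BASE_SEED + 100L * i
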