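#!/usr/bin/env Rscript
# Builds the synthetic species panel: one contig per species carrying the
# TBC1D9-UCP1-ELMOD2 triplet, with a CpG island and diverged copies of the
# enhancer / putative regulatory region spliced into the UCP1 upstream
# region at known anchor-relative positions.  Writes per-species FASTA +
# BED and a machine-readable truth table.

source("analysis/00_config.R")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

# Splice `feature` into `sequence` so that it occupies anchor-relative
# coordinates [position, position + len) of the focal gene (anchor `a`,
# 0-based) on `strand`; for a minus-strand gene the feature is stored
# reverse-complemented at the mirrored location.
plant_in_genome <- function(sequence, a, strand, position, feature) {
  len <- nchar(feature)
  if (strand == "+") {
    i0 <- a + position
    stopifnot(i0 >= 0L, i0 + len <= nchar(sequence))
    substr(sequence, i0 + 1L, i0 + len) <- feature
  } else {
    i0 <- a - position - len
    stopifnot(i0 >= 0L, i0 + len <= nchar(sequence))
    substr(sequence, i0 + 1L, i0 + len) <- revcomp(feature)
  }
  sequence
}

queries <- element_queries()
truth <- list()

for (i in seq_along(species_panel)) {
  sp <- names(species_panel)[[i]]
  plan <- species_panel[[sp]]
  seed <- species_seed(i)

  ord <- if (plan$scrambled) c("TBC1D9", "ELMOD2", "UCP1") else c("TBC1D9", "UCP1", "ELMOD2")
  tg <- make_triplet_genome(
    focal_strand = plan$strand, order = ord,
    gene_length = c(2500L, 1200L, 1800L), intergenic = c(11500L, 3000L),
    flank = 1500L, species_label = sp, contig_id = paste0("contig_", sp),
    seed = seed
  )
  focal <- tg$annotations[tg$annotations$gene_symbol == "UCP1", ]
  a <- if (plan$strand == "+") focal$start else focal$end
  seqn <- tg$genome$sequence

  feats <- list()
  if (!is.null(plan$island)) {
    isl <- make_island_sequence(
      plan$island[["len"]], plan$island[["gc"]], plan$island[["oe"]],
      seed = seed + 1L
    )
    seqn <- plant_in_genome(seqn, a, plan$strand, plan$island_pos, isl$sequence)
    feats[[length(feats) + 1L]] <- data.frame(
      species = sp, feature = "cgi", start = plan$island_pos,
      end = plan$island_pos + nchar(isl$sequence),
      divergence = NA_real_, truth_identity = NA_real_
    )
  }
  for (el in c("enhancer", "prr")) {
    d <- plan[[paste0(el, "_div")]]
    if (is.na(d)) next
    mut <- mutate_element(queries[[el]]$sequence, d, 0, seed = seed + 2L + match(el, c("enhancer", "prr")))
    pos <- queries[[el]]$human_anchor_position
    seqn <- plant_in_genome(seqn, a, plan$strand, pos, mut$sequence)
    feats[[length(feats) + 1L]] <- data.frame(
      species = sp, feature = el, start = pos, end = pos + nchar(mut$sequence),
      divergence = d, truth_identity = mut$truth_identity
    )
  }
  truth[[sp]] <- if (length(feats)) do.call(rbind, feats) else NULL

  genome <- genome_sequence(sp, tg$genome$contig_id, seqn)
  fa <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$contig_id))
  Biostrings::writeXStringSet(fa, file.path(DATA_DIR, paste0(sp, ".fa")))
  bed <- tg$annotations
  writeLines(
    sprintf("%s\t%d\t%d\t%s\t0\t%s", bed$contig_id, bed$start, bed$end, bed$gene_symbol, bed$strand),
    file.path(DATA_DIR, paste0(sp, ".bed"))
  )
}

truth_df <- do.call(rbind, truth)
rownames(truth_df) <- NULL
write.table(truth_df, file.path(DATA_DIR, "truth_features.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)
for (el in c("enhancer", "prr")) {
  fa <- Biostrings::DNAStringSet(setNames(queries[[el]]$sequence, el))
  Biostrings::writeXStringSet(fa, file.path(DATA_DIR, paste0("query_", el, ".fa")))
}

cat(sprintf(
  "wrote %d species genomes (+BED), 2 query elements and %d truth records under %s\n",
  length(species_panel), nrow(truth_df), DATA_DIR
))
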