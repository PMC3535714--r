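#!/usr/bin/env Rscript
# Assembles the per-species presence/absence matrix and the anchor-relative
# feature map from the scan outputs of steps 02 and 03.

source("analysis/00_config.R")

queries <- element_queries()
records <- list()
for (sp in names(species_panel)) {
  genome <- read_fasta(file.path(DATA_DIR, paste0(sp, ".fa")), species_label = sp)[[1L]]
  ann <- read_annotations(file.path(DATA_DIR, paste0(sp, ".bed")))
  verdict <- check_synteny_triplet(ann)
  if (verdict$pass) {
    focal <- ann[ann$gene_symbol == "UCP1", ]
    cgi_region <- extract_upstream(genome, focal, region_spec(5000L, 1000L))
    islands <- classify_islands(scan_exhaustive(cgi_region), scan_seeded(cgi_region))
    el_region <- extract_upstream(genome, focal, region_spec(10000L, 0L))
    enh <- find_element(el_region, queries$enhancer)
    prr <- find_element(el_region, queries$prr)
    records[[sp]] <- assemble_record(sp, verdict, islands, enh, prr)
  } else {
    records[[sp]] <- assemble_record(sp, verdict, NULL)
  }
}

matrix_txt <- render_matrix(unname(records))
writeLines(matrix_txt, file.path(RESULTS_DIR, "presence_matrix.tsv"), sep = "")
map_json <- render_map(unname(records))
writeLines(map_json, file.path(RESULTS_DIR, "feature_map.json"))

cat("presence/absence matrix:\n\n")
cat(matrix_txt)
cat(sprintf(
  "\nmatrix -> %s ; feature map -> %s\n",
  file.path(RESULTS_DIR, "presence_matrix.tsv"),
  file.path(RESULTS_DIR, "feature_map.json")
))
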