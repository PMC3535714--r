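test_that("island sequences realize their target composition and are deterministic", {
  for (cfg in list(c(300, 0.60, 0.9), c(250, 0.55, 0.7), c(800, 0.70, 1.2))) {
    isl <- make_island_sequence(cfg[1L], cfg[2L], cfg[3L], seed = 17)
    expect_identical(nchar(isl$sequence), as.integer(cfg[1L]))
    st <- cpg_stats(isl$sequence)
    expect_lte(abs(st$gc_fraction - cfg[2L]), 0.03)
    expect_lte(abs(st$oe_ratio - cfg[3L]), 0.1)
  }
  expect_identical(
    make_island_sequence(300, 0.6, 0.9, seed = 4)$sequence,
    make_island_sequence(300, 0.6, 0.9, seed = 4)$sequence
  )
  expect_false(identical(
    make_island_sequence(300, 0.6, 0.9, seed = 4)$sequence,
    make_island_sequence(300, 0.6, 0.9, seed = 5)$sequence
  ))
})

test_that("infeasible island targets are rejected with the violated bound named", {
  expect_error(make_island_sequence(300, 0, 0.9, seed = 1), "no C or G")
  expect_error(make_island_sequence(300, 0.6, 5, seed = 1), "attainable maximum")
  expect_error(make_island_sequence(150, 0.6, 0.9, seed = 1), "at least 200")
})

test_that("promoters plant features where stated and emit matching truth", {
  isl <- make_island_sequence(400, 0.62, 0.85, seed = 23)
  pr <- make_promoter(
    6000, 500,
    planted = list(list(kind = "cgi", sequence = isl$sequence, position = -1200L)),
    seed = 29
  )
  expect_identical(nchar(pr$region$sequence), 6500L)
  expect_identical(pr$region$anchor_offset, 6000L)
  expect_identical(pr$truth$start, -1200L)
  expect_identical(pr$truth$end, -800L)
  planted_back <- substr(pr$region$sequence, 6000L - 1200L + 1L, 6000L - 800L)
  expect_identical(planted_back, isl$sequence)

  expect_error(
    make_promoter(1000, 0, planted = list(
      list(kind = "cgi", sequence = isl$sequence, position = -300L)
    )),
    "outside"
  )
  expect_error(
    make_promoter(6000, 0, planted = list(
      list(kind = "cgi", sequence = isl$sequence, position = -1200L),
      list(kind = "cgi", sequence = isl$sequence, position = -1000L)
    )),
    "overlap"
  )
})

test_that("planted islands and elements are found by the scans end to end", {
  isl <- make_island_sequence(400, 0.62, 0.85, seed = 31)
  pr <- make_promoter(
    5000, 1000,
    planted = list(list(kind = "cgi", sequence = isl$sequence, position = -700L)),
    seed = 37
  )
  islands <- classify_islands(scan_exhaustive(pr$region), scan_seeded(pr$region))
  expect_false(species_cgi_call(islands) == "absent")
  best <- islands[which.max(pmin(islands$end, -300L) - pmax(islands$start, -700L)), ]
  expect_lte(best$start, -700L + 40L)
  expect_gte(best$end, -300L - 40L)
})

test_that("feature-free backgrounds stay below every detection threshold", {
  set.seed(131)
  probe <- element_query("probe", random_dna(400, gc = 0.45))
  for (k in 1:5) {
    pr <- make_promoter(4000, 0, seed = 1000 + k)
    expect_identical(nrow(scan_exhaustive(pr$region)), 0L)
    expect_false(find_element(pr$region, probe)$present)
  }
})

test_that("triplet genomes support both strands and scrambled negative controls", {
  tg <- make_triplet_genome(seed = 41)
  expect_true(check_synteny_triplet(tg$annotations)$pass)
  expect_identical(nchar(tg$genome$sequence), max(tg$annotations$end) + 1000L)

  tgm <- make_triplet_genome(focal_strand = "-", seed = 43)
  expect_true(check_synteny_triplet(tgm$annotations)$pass)
  expect_identical(
    tgm$annotations$gene_symbol[order(tgm$annotations$start)],
    c("ELMOD2", "UCP1", "TBC1D9")
  )

  tgs <- make_triplet_genome(order = c("UCP1", "TBC1D9", "ELMOD2"), seed = 47)
  expect_false(check_synteny_triplet(tgs$annotations)$pass)

  # a triplet genome feeds extraction directly
  focal <- tg$annotations[tg$annotations$gene_symbol == "UCP1", ]
  r <- extract_upstream(tg$genome, focal, region_spec(2000, 0))
  expect_identical(nchar(r$sequence), 2000L)
})

test_that("mutated homologs carry an exact edit record", {
  set.seed(139)
  el <- random_dna(500, gc = 0.5)
  same <- mutate_element(el, 0, 0, seed = 1)
  expect_identical(same$sequence, el)
  expect_identical(nrow(same$edits), 0L)
  expect_equal(same$truth_identity, 100)

  mut <- mutate_element(el, 0.215, 0, seed = 2)
  expect_identical(nchar(mut$sequence), 500L)
  expect_identical(mut$n_substitutions, sum(mut$edits$op == "sub"))
  expect_equal(mut$truth_identity, 100 * (1 - mut$n_substitutions / 500))
  # every recorded substitution changed the base it named
  v0 <- strsplit(el, "")[[1L]]
  v1 <- strsplit(mut$sequence, "")[[1L]]
  subs <- mut$edits[mut$edits$op == "sub", ]
  expect_identical(v0[subs$position], subs$from)
  expect_identical(v1[subs$position], subs$to)
  expect_true(all(subs$from != subs$to))

  indel <- mutate_element(el, 0.1, 0.05, seed = 3)
  ind <- indel$edits[indel$edits$op %in% c("ins", "del"), ]
  expect_gt(nrow(ind), 0L)
  expect_true(all(ind$position > 10L & ind$position <= 490L))
  expect_true(is.na(indel$truth_identity))

  # heavy divergence is no longer called present at default thresholds
  far <- mutate_element(el, 0.9, 0, seed = 5)
  pr <- make_promoter(3000, 0,
    planted = list(list(kind = "element", sequence = far$sequence, position = -2000L)),
    seed = 7
  )
  expect_false(find_element(pr$region, element_query("probe", el))$present)
})

test_that("simulated Ct tables encode survival exactly and flag dead reactions", {
  ct <- simulate_ct(0.25, 0.8, 0, replicates = 2L, seed = 53)
  expect_identical(ct, simulate_ct(0.25, 0.8, 0, replicates = 2L, seed = 53))
  mock <- ct[ct$target == "amplicon" & ct$treatment == "mock", ]
  expect_true(all(mock$ct == 24))
  dig <- ct[ct$target == "amplicon" & ct$treatment == "methyl_sensitive_digest", ]
  expect_equal(unique(dig$ct), 24 - log2(0.25 + 0.75 * 0.2), tolerance = 1e-12)
  ctrl <- ct[ct$target == "amplicon" & ct$treatment == "control_digest", ]
  expect_equal(unique(ctrl$ct), 24 - log2(0.2), tolerance = 1e-12)
  expect_true(all(ct$ct[ct$target == "18S"] == 12))

  dead <- simulate_ct(0, 1, 0, replicates = 1L, seed = 59)
  dd <- dead[dead$target == "amplicon" & dead$treatment == "methyl_sensitive_digest", ]
  expect_true(dd$no_amplification)
  expect_equal(dd$ct, 45)
  expect_equal(msrd_percent_methylation(dead, "amplicon")$percent, 0)
})

test_that("simulated bisulfite counts follow the conversion-aware binomial", {
  zero <- simulate_bisulfite(c(0, 0), depth = 100L, seed = 61)
  expect_identical(zero$count_c, c(0L, 0L))
  full <- simulate_bisulfite(c(1, 1), depth = 100L, conversion_efficiency = 0.9, seed = 67)
  expect_identical(full$count_c, c(100L, 100L))
  expect_identical(
    simulate_bisulfite(0.3, 500L, 0.98, seed = 71),
    simulate_bisulfite(0.3, 500L, 0.98, seed = 71)
  )
  set.seed(73)
  x <- simulate_bisulfite(0.4, 2000L, 0.95)
  expect_gt(x$count_c, 0.4 * 2000 * 0.8)
})
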