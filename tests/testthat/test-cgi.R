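test_that("cpg_stats counts composition, CpG starts and the O/E ratio", {
  s <- cpg_stats("CGCGCGCG")
  expect_equal(s$gc_fraction, 1)
  expect_identical(s$obs_cpg, 4L)
  expect_equal(s$exp_cpg, 2)
  expect_equal(s$oe_ratio, 2)
  expect_true(s$oe_defined)

  s2 <- cpg_stats("ACGT")
  expect_equal(s2$gc_fraction, 0.5)
  expect_identical(s2$obs_cpg, 1L)
  expect_equal(s2$exp_cpg, 0.25)
  expect_equal(s2$oe_ratio, 4)

  s3 <- cpg_stats("ATATATAT")
  expect_false(s3$oe_defined)
  expect_equal(s3$oe_ratio, 0)

  expect_equal(cpg_stats("ANGN")$n_fraction, 0.5)
  expect_error(cpg_stats(""), "empty")
})

at_background <- function(n) paste(rep("AT", ceiling(n / 2)), collapse = "")

planted_cg_sequence <- function(total = 2000L, island = 300L, at = 850L) {
  paste0(
    substr(at_background(total), 1L, at),
    paste(rep("CG", island / 2L), collapse = ""),
    substr(at_background(total), at + island + 1L, total)
  )
}

test_that("the seeded scan recovers a planted CpG run tightly and rejects noise", {
  seq <- planted_cg_sequence()
  seg <- scan_seeded(seq)
  expect_identical(nrow(seg), 1L)
  expect_lte(abs(seg$start - 850L), 2L)
  expect_lte(abs(seg$end - 1150L), 2L)
  expect_true(all(seg$criteria_pass))

  expect_identical(nrow(scan_seeded(at_background(2000L))), 0L)

  short <- planted_cg_sequence(island = 150L, at = 900L)
  expect_identical(nrow(scan_seeded(short)), 0L) # below min_length

  expect_error(scan_seeded(substr(seq, 1, 100)), "below min_length")
})

test_that("bridged maximal segments failing the criteria fall through to the exhaustive scan", {
  # two dense islands 1 kb apart: the +17/-1 maximal segment spans both
  # (2 x 2401 beats the -1001 bridge), its merged statistics fail the GC
  # criterion and the seeded pass filters it out; the exhaustive scan still
  # reports both islands, which therefore carry the low-stringency tier
  seq <- paste0(
    substr(at_background(3000L), 1L, 500L),
    paste(rep("CG", 150L), collapse = ""),
    substr(at_background(3000L), 801L, 1800L),
    paste(rep("CG", 150L), collapse = ""),
    substr(at_background(3000L), 2101L, 3000L)
  )
  seg <- scan_seeded(seq)
  expect_identical(nrow(seg), 0L)
  ex <- scan_exhaustive(seq)
  expect_identical(nrow(ex), 2L)
  cl <- classify_islands(ex, seg)
  expect_identical(cl$tier, c("low", "low"))
})

test_that("the exhaustive scan reproduces the brute-force window union", {
  seq <- planted_cg_sequence()
  ex <- scan_exhaustive(seq)
  expect_identical(nrow(ex), 1L)
  expect_identical(
    coverage_of_islands(ex, nchar(seq)),
    coverage_of_ranges(oracle_cgi_coverage(seq), nchar(seq))
  )

  two <- paste0(
    substr(at_background(3000L), 1L, 500L),
    paste(rep("CG", 150L), collapse = ""),
    substr(at_background(3000L), 801L, 1800L),
    paste(rep("CG", 150L), collapse = ""),
    substr(at_background(3000L), 2101L, 3000L)
  )
  ex2 <- scan_exhaustive(two)
  expect_identical(nrow(ex2), 2L)
  expect_true(all(diff(ex2$start) > 0))
  expect_identical(
    coverage_of_islands(ex2, nchar(two)),
    coverage_of_ranges(oracle_cgi_coverage(two), nchar(two))
  )

  expect_error(scan_exhaustive(random_dna(199L)), "below min_length")
})

test_that("windows touching an N are ineligible by default", {
  with_n <- planted_cg_sequence(island = 600L, at = 700L)
  substr(with_n, 1000L, 1000L) <- "N"
  ex <- scan_exhaustive(with_n)
  # the island is split around the gap; no reported interval contains the N
  expect_identical(nrow(ex), 2L)
  expect_true(all(ex$start >= 1000L | ex$end <= 999L))
  expect_identical(
    coverage_of_islands(ex, nchar(with_n)),
    coverage_of_ranges(oracle_cgi_coverage(with_n), nchar(with_n))
  )
})

test_that("island classification and the per-species call follow the tier rules", {
  seq <- planted_cg_sequence()
  ex <- scan_exhaustive(seq)
  seg <- scan_seeded(seq)
  cl <- classify_islands(ex, seg)
  expect_identical(cl$tier, "high")
  expect_identical(species_cgi_call(cl), "high stringency")

  # no seeded support -> low tier
  cl_low <- classify_islands(ex, seg[0L, ])
  expect_identical(cl_low$tier, "low")
  expect_identical(species_cgi_call(cl_low), "low stringency")

  empty <- classify_islands(ex[0L, ], seg)
  expect_identical(nrow(empty), 0L)
  expect_identical(species_cgi_call(empty), "absent")

  mixed <- rbind(cl, transform(cl_low, start = start + 5000L, end = end + 5000L))
  expect_identical(species_cgi_call(mixed), "high stringency")
})

test_that("anchor-relative island coordinates follow the region anchor", {
  seq <- planted_cg_sequence()
  region <- upstream_region(seq, anchor_offset = 2000L, species_label = "sp")
  ex <- scan_exhaustive(region)
  expect_lt(ex$end[1L], 0L) # island lies upstream of the anchor
  ex0 <- scan_exhaustive(seq)
  expect_identical(ex$start + 2000L, ex0$start)
})

test_that("reported statistics are faithful and passing islands meet the criteria", {
  set.seed(31)
  params <- scan_params()
  for (k in 1:8) {
    seq <- random_dna(sample(400:1500, 1L), gc = runif(1, 0.4, 0.7))
    ex <- scan_exhaustive(seq, params)
    seg <- scan_seeded(seq, params)
    for (df in list(ex, seg)) {
      if (!nrow(df)) next
      for (r in seq_len(nrow(df))) {
        st <- cpg_stats(substr(seq, df$start[r] + 1L, df$end[r]))
        expect_equal(st$gc_fraction, df$gc_fraction[r])
        expect_identical(st$obs_cpg, df$obs_cpg[r])
        expect_equal(st$oe_ratio, df$oe_ratio[r])
        passes <- st$length >= params$min_length &&
          st$gc_fraction >= params$min_gc &&
          st$oe_defined && st$oe_ratio > params$min_oe
        expect_identical(df$criteria_pass[r], passes)
      }
      # seeded output only ever contains passing segments
    }
    if (nrow(seg)) expect_true(all(seg$criteria_pass))
  }
})

test_that("seeded segments are covered by exhaustive islands", {
  set.seed(41)
  for (k in 1:6) {
    seq <- random_dna(sample(500:1500, 1L), gc = runif(1, 0.45, 0.65))
    seg <- scan_seeded(seq)
    if (!nrow(seg)) next
    cov <- coverage_of_islands(scan_exhaustive(seq), nchar(seq))
    segcov <- coverage_of_islands(seg[, c("start", "end")], nchar(seq))
    expect_true(all(cov[segcov]))
  }
})

test_that("island coverage is mirrored on the reverse complement", {
  set.seed(51)
  for (k in 1:6) {
    seq <- random_dna(sample(400:1200, 1L), gc = runif(1, 0.45, 0.65))
    n <- nchar(seq)
    cov <- coverage_of_islands(scan_exhaustive(seq), n)
    cov_rc <- coverage_of_islands(scan_exhaustive(revcomp(seq)), n)
    expect_identical(cov, rev(cov_rc))
  }
})

test_that("raising the GC or O/E threshold never increases island coverage", {
  set.seed(61)
  for (k in 1:4) {
    seq <- random_dna(sample(600:1500, 1L), gc = runif(1, 0.45, 0.65))
    n <- nchar(seq)
    prev <- Inf
    for (gc in c(0.45, 0.5, 0.55, 0.6, 0.65)) {
      cov <- sum(coverage_of_islands(scan_exhaustive(seq, scan_params(min_gc = gc)), n))
      expect_lte(cov, prev)
      prev <- cov
    }
    prev <- Inf
    for (oe in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
      cov <- sum(coverage_of_islands(scan_exhaustive(seq, scan_params(min_oe = oe)), n))
      expect_lte(cov, prev)
      prev <- cov
    }
  }
})
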