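test_that("read_fasta normalizes case, maps U to T and preserves record order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s", "acgtn", ">t desc", "uuac"), f)
  recs <- read_fasta(f, species_label = "sp")
  expect_length(recs, 2L)
  expect_identical(names(recs), c("s", "t"))
  expect_identical(recs$s$sequence, "ACGTN")
  expect_identical(recs$t$sequence, "TTAC")
  expect_identical(recs$s$species_label, "sp")
})

test_that("read_fasta enforces its parse-error contracts", {
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0L), empty)
  expect_error(read_fasta(empty), "no FASTA records")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(read_fasta(dup), "duplicate record id 'a'")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">weird", "ACXGT"), bad)
  expect_error(read_fasta(bad), "illegal character 'X' at position 3.*'weird'")
})

test_that("annotations round-trip through BED and GFF3 with 0-based coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t200\tTBC1D9\t0\t+",
    "chr1\t300\t450\tUCP1\t0\t+"
  ), bed)
  ann <- read_annotations(bed)
  expect_identical(ann$gene_symbol, c("TBC1D9", "UCP1"))
  expect_identical(ann$start, c(100L, 300L))
  expect_identical(ann$end, c(200L, 450L))
  expect_identical(ann$strand, c("+", "+"))

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t-\t.\tID=g1;gene=UCP1"
  ), gff)
  ann2 <- read_annotations(gff)
  expect_identical(ann2$gene_symbol, "UCP1")
  expect_identical(ann2$start, 100L)
  expect_identical(ann2$end, 200L)
  expect_identical(ann2$strand, "-")
})

test_that("extract_upstream anchors plus- and minus-strand genes as specified", {
  g <- genome_sequence("sp", "c1", "AAAAACGTGG")
  plus <- extract_upstream(
    g, data.frame(gene_symbol = "x", contig_id = "c1", start = 5L, end = 9L, strand = "+"),
    region_spec(5, 0)
  )
  expect_identical(plus$sequence, "AAAAA")
  expect_identical(plus$anchor_offset, 5L)
  expect_false(plus$truncated_upstream)

  minus <- extract_upstream(
    g, data.frame(gene_symbol = "x", contig_id = "c1", start = 1L, end = 5L, strand = "-"),
    region_spec(5, 0)
  )
  expect_identical(minus$sequence, "CCACG") # revcomp of CGTGG
  expect_identical(minus$anchor_offset, 5L)

  clipped <- extract_upstream(
    g, data.frame(gene_symbol = "x", contig_id = "c1", start = 2L, end = 9L, strand = "+"),
    region_spec(5, 0)
  )
  expect_identical(clipped$sequence, "AA")
  expect_true(clipped$truncated_upstream)

  expect_error(
    extract_upstream(
      g, data.frame(gene_symbol = "x", contig_id = "c1", start = 5L, end = 9L, strand = "+"),
      region_spec(0, 0)
    ),
    "positive"
  )
  expect_error(
    extract_upstream(
      genome_sequence("sp", "c2", "ACGT"),
      data.frame(gene_symbol = "x", contig_id = "c1", start = 1L, end = 2L, strand = "+")
    ),
    "contig"
  )
})

test_that("extraction is consistent under recoding a locus on the opposite strand", {
  set.seed(11)
  for (k in 1:12) {
    L <- sample(200:400, 1L)
    seq <- random_dna(L, gc = runif(1, 0.3, 0.6))
    a <- sample(60:(L - 60), 1L)
    g <- genome_sequence("sp", "c", seq)
    spec <- region_spec(sample(20:50, 1L), sample(0:30, 1L))
    plus <- extract_upstream(
      g, data.frame(gene_symbol = "x", contig_id = "c", start = a, end = a + 10L, strand = "+"),
      spec
    )
    # same locus on the minus strand of the reverse-complemented contig
    g2 <- genome_sequence("sp", "c", revcomp(seq))
    minus <- extract_upstream(
      g2, data.frame(
        gene_symbol = "x", contig_id = "c",
        start = L - (a + 10L), end = L - a, strand = "-"
      ),
      spec
    )
    expect_identical(minus$sequence, plus$sequence)
    expect_identical(minus$anchor_offset, plus$anchor_offset)
  }
})

test_that("double reverse complement is the identity on extracted regions", {
  set.seed(5)
  seq <- random_dna(300)
  g <- genome_sequence("sp", "c", seq)
  r <- extract_upstream(
    g, data.frame(gene_symbol = "x", contig_id = "c", start = 250L, end = 280L, strand = "+"),
    region_spec(200, 0)
  )
  expect_identical(revcomp(revcomp(r$sequence)), r$sequence)
  expect_identical(r$sequence, substr(seq, 51L, 250L))
})

test_that("synteny gate passes conserved triplets on either strand and fails scrambles", {
  plus <- data.frame(
    gene_symbol = c("TBC1D9", "UCP1", "ELMOD2"),
    contig_id = "c", start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
    strand = "+", stringsAsFactors = FALSE
  )
  expect_true(check_synteny_triplet(plus)$pass)

  # minus-strand focal gene: coordinate order ELMOD2 < UCP1 < TBC1D9
  minus <- data.frame(
    gene_symbol = c("ELMOD2", "UCP1", "TBC1D9"),
    contig_id = "c", start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
    strand = "-", stringsAsFactors = FALSE
  )
  expect_true(check_synteny_triplet(minus)$pass)

  scrambled <- plus
  scrambled$gene_symbol <- c("TBC1D9", "ELMOD2", "UCP1")
  v <- check_synteny_triplet(scrambled)
  expect_false(v$pass)
  expect_match(v$reason, "wrong 5' neighbor")

  other_contig <- plus
  other_contig$contig_id <- c("c", "c", "c2")
  v2 <- check_synteny_triplet(other_contig)
  expect_false(v2$pass)
  expect_match(v2$reason, "different contig")

  intruder <- rbind(plus, data.frame(
    gene_symbol = "OTHER", contig_id = "c", start = 60L, end = 90L,
    strand = "+", stringsAsFactors = FALSE
  ))
  expect_false(check_synteny_triplet(intruder)$pass)

  expect_error(check_synteny_triplet(plus[-2L, ]), "absent")
  expect_error(check_synteny_triplet(rbind(plus, plus[2L, ])), "more than once")
})

test_that("synteny verdict is invariant under reverse-complementing the contig", {
  set.seed(21)
  for (k in 1:10) {
    order <- if (k %% 3 == 0) c("TBC1D9", "ELMOD2", "UCP1") else c("TBC1D9", "UCP1", "ELMOD2")
    tg <- make_triplet_genome(
      focal_strand = sample(c("+", "-"), 1L), order = order,
      gene_length = sample(500:1500, 3L), intergenic = sample(500:2000, 2L),
      seed = 400 + k
    )
    v1 <- check_synteny_triplet(tg$annotations)
    L <- nchar(tg$genome$sequence)
    v2 <- check_synteny_triplet(flip_annotations(tg$annotations, L))
    expect_identical(v1$pass, v2$pass)
    expect_identical(v1$pass, identical(order, c("TBC1D9", "UCP1", "ELMOD2")))
  }
})

test_that("upstream regions survive a FASTA round trip with their anchor", {
  r <- upstream_region("ACGTACGTAC", 7L,
    species_label = "Cow", strand_of_source = "-"
  )
  f <- withr::local_tempfile(fileext = ".fa")
  write_region_fasta(r, f)
  r2 <- read_region_fasta(f)
  expect_identical(r2$sequence, r$sequence)
  expect_identical(r2$anchor_offset, r$anchor_offset)
  expect_identical(r2$species_label, "Cow")
  expect_identical(r2$strand_of_source, "-")
})
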