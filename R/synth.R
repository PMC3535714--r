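# Synthetic-data generators.  Every generator is a pure function of its
# arguments including `seed`, and ships a machine-readable truth record for
# every planted feature, so downstream scans can be scored against known
# truth without any external data.

BASES <- c("A", "C", "G", "T")

# First-order chain sampler: stationary-ish base composition `gc`, with the
# C->G transition probability forced to `q`.  From any state except C the
# next base is drawn from the base distribution; from C, G has probability q
# and the remainder is spread over A/C/T proportionally to the base
# distribution.
sample_chain <- function(n, gc, q) {
  stopifnot(n >= 1L, gc > 0, gc < 1, q >= 0, q <= 1)
  pi0 <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  from_c <- pi0
  from_c[["G"]] <- 0
  from_c <- from_c / sum(from_c) * (1 - q)
  from_c[["G"]] <- q
  cum_pi <- cumsum(pi0)
  cum_c <- cumsum(from_c)
  u <- stats::runif(n)
  out <- integer(n)
  out[[1L]] <- findInterval(u[[1L]], cum_pi) + 1L
  for (i in seq_len(n)[-1L]) {
    p <- if (out[[i - 1L]] == 2L) cum_c else cum_pi
    out[[i]] <- (u[[i]] > p[[1L]]) + (u[[i]] > p[[2L]]) + (u[[i]] > p[[3L]]) + 1L
  }
  paste(BASES[out], collapse = "")
}

# Transition matrix of the chain above and its stationary distribution.
chain_stationary <- function(gc, q) {
  pi0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  Tm <- matrix(pi0, nrow = 4L, ncol = 4L, byrow = TRUE)
  from_c <- pi0
  from_c[[3L]] <- 0
  from_c <- from_c / sum(from_c) * (1 - q)
  from_c[[3L]] <- q
  Tm[2L, ] <- from_c
  # stationary distribution: left eigenvector; solve (T' - I) v = 0, sum v = 1
  A <- rbind(t(Tm) - diag(4L), rep(1, 4L))
  b <- c(rep(0, 4L), 1)
  v <- qr.solve(A, b)
  list(transition = Tm, stationary = v)
}

# Expected observed/expected CpG ratio of the chain, from its stationary
# distribution: E[obs]/L = pi_C * q, E[exp]/L ~ pi_C * pi_G.
chain_expected_oe <- function(gc, q) {
  st <- chain_stationary(gc, q)$stationary
  if (st[[3L]] <= 0) {
    return(0)
  }
  q / st[[3L]]
}

#' Generate a CpG-island-like sequence with target composition
#'
#' Samples a first-order chain whose C->G transition probability is tuned by
#' bisection so the expected observed/expected CpG ratio matches
#' `target_oe`, with the base distribution iteratively adjusted so the
#' realized G+C fraction matches `target_gc`.  Sequences are resampled (up
#' to 100 attempts) until the realized statistics fall within +/- 0.03 of
#' the GC target and +/- 0.1 of the O/E target; persistent failure is an
#' error, as is an infeasible target combination.
#'
#' @param length Sequence length in bp (>= 200).
#' @param target_gc Target G+C fraction (0 < gc < 1).
#' @param target_oe Target observed/expected CpG ratio.
#' @param seed Integer seed; same arguments and seed give the same sequence.
#' @return List with `sequence`, realized `stats` ([cpg_stats()]), and the
#'   tuned transition probability `q`.
#' @export
make_island_sequence <- function(length, target_gc, target_oe, seed = NULL) {
  length <- as.integer(length)
  if (length < 200L) stop("island length must be at least 200 bp", call. = FALSE)
  if (target_gc <= 0 || target_gc >= 1) {
    stop("infeasible target_gc: need 0 < gc < 1 (no C or G means the O/E ratio is undefined)",
      call. = FALSE
    )
  }
  if (target_oe < 0) stop("infeasible target_oe: must be >= 0", call. = FALSE)
  oe_max <- chain_expected_oe(target_gc, 1)
  if (target_oe > oe_max) {
    stop(sprintf(
      "infeasible target combination: O/E %.2f exceeds the attainable maximum %.2f at GC %.2f",
      target_oe, oe_max, target_gc
    ), call. = FALSE)
  }

  tune <- function(gc0) {
    lo <- 0
    hi <- 1
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (chain_expected_oe(gc0, mid) < target_oe) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  # fixed point on the base composition so the stationary GC hits the target
  gc0 <- target_gc
  q <- tune(gc0)
  for (k in 1:25) {
    st <- chain_stationary(gc0, q)$stationary
    gc_stat <- st[[2L]] + st[[3L]]
    gc0 <- min(0.999, max(0.001, gc0 + (target_gc - gc_stat)))
    q <- tune(gc0)
  }

  with_seed(seed, {
    for (attempt in 1:100) {
      s <- sample_chain(length, gc0, q)
      st <- cpg_stats(s)
      if (abs(st$gc_fraction - target_gc) <= 0.03 &&
        st$oe_defined && abs(st$oe_ratio - target_oe) <= 0.1) {
        return(list(sequence = s, stats = st, q = q))
      }
    }
    stop(sprintf(
      "could not realize GC %.2f / O-E %.2f within tolerance in 100 attempts",
      target_gc, target_oe
    ), call. = FALSE)
  })
}

# Background composition approximating vertebrate bulk DNA: GC 0.35 with the
# CpG transition suppressed to 0.2 of its independence expectation.
BACKGROUND_GC <- 0.35
BACKGROUND_CPG_SUPPRESSION <- 0.2

sample_background <- function(n, gc = BACKGROUND_GC,
                              suppression = BACKGROUND_CPG_SUPPRESSION) {
  sample_chain(n, gc, q = suppression * gc / 2)
}

#' Build a synthetic promoter region with planted features
#'
#' An AT-rich, CpG-depleted background with islands and/or element copies
#' spliced in at stated anchor-relative positions, plus a truth table
#' recording every planted interval.
#'
#' @param span_upstream,span_downstream Extent of the region around the
#'   anchor, in bp.
#' @param planted List of features, each a list with `kind` (`"cgi"`,
#'   `"element"`, ...), `sequence`, and anchor-relative `position` of its
#'   first base; optionally a `name`.  Intervals must be disjoint and inside
#'   the region.
#' @param species_label Label attached to the region.
#' @param seed Integer seed.
#' @return List with `region` (an `upstream_region`) and `truth` (data frame
#'   with `kind`, `name`, anchor-relative `start`/`end`, `length`).
#' @export
make_promoter <- function(span_upstream = 10000L, span_downstream = 0L,
                          planted = list(), species_label = "synthetic",
                          seed = NULL) {
  span_upstream <- as.integer(span_upstream)
  span_downstream <- as.integer(span_downstream)
  n <- span_upstream + span_downstream
  stopifnot(n > 0L)
  anchor <- span_upstream

  truth <- data.frame(
    kind = character(0L), name = character(0L),
    start = integer(0L), end = integer(0L), length = integer(0L),
    stringsAsFactors = FALSE
  )
  iv <- list()
  for (f in planted) {
    stopifnot(!is.null(f$kind), !is.null(f$sequence), !is.null(f$position))
    len <- nchar(f$sequence)
    i0 <- anchor + as.integer(f$position)
    if (i0 < 0L || i0 + len > n) {
      stop("planted feature falls outside the region", call. = FALSE)
    }
    for (other in iv) {
      if (i0 < other[[2L]] && other[[1L]] < i0 + len) {
        stop("planted features overlap", call. = FALSE)
      }
    }
    iv[[length(iv) + 1L]] <- c(i0, i0 + len)
    truth <- rbind(truth, data.frame(
      kind = f$kind, name = f$name %||% f$kind,
      start = as.integer(f$position), end = as.integer(f$position) + len,
      length = len, stringsAsFactors = FALSE
    ))
  }

  seq <- with_seed(seed, sample_background(n))
  for (k in seq_along(planted)) {
    f <- planted[[k]]
    i0 <- iv[[k]][[1L]]
    substr(seq, i0 + 1L, i0 + nchar(f$sequence)) <- f$sequence
  }
  list(
    region = upstream_region(
      sequence = seq, anchor_offset = anchor,
      species_label = species_label, strand_of_source = "+"
    ),
    truth = truth
  )
}

#' Build a synthetic contig carrying the TBC1D9-UCP1-ELMOD2 triplet
#'
#' Lays out three annotated genes (in the requested 5'-to-3' order along the
#' focal gene's strand) on a background contig, supporting a minus-strand
#' focal gene and deliberately scrambled orders for negative controls.
#'
#' @param focal_strand Strand of every gene, `"+"` or `"-"`.
#' @param order Gene symbols in 5'-to-3' order along `focal_strand`.
#' @param gene_length Length of each gene (recycled to 3).
#' @param intergenic The two intergenic gap sizes in bp.
#' @param flank Flanking sequence on each side.
#' @param species_label,contig_id Labels for the contig.
#' @param seed Integer seed.
#' @return List with `genome` (a `genome_sequence`), `annotations` (data
#'   frame), and `truth`.
#' @export
make_triplet_genome <- function(focal_strand = "+",
                                order = c("TBC1D9", "UCP1", "ELMOD2"),
                                gene_length = 2000L, intergenic = c(3000L, 3000L),
                                flank = 1000L, species_label = "synthetic",
                                contig_id = "contig_1", seed = NULL) {
  stopifnot(focal_strand %in% c("+", "-"), length(order) == 3L)
  gene_length <- rep_len(as.integer(gene_length), 3L)
  intergenic <- rep_len(as.integer(intergenic), 2L)
  stopifnot(all(gene_length > 0L), all(intergenic > 0L), flank >= 0L)

  # left-to-right gene order in contig coordinates
  coord_order <- if (focal_strand == "+") order else rev(order)
  coord_len <- if (focal_strand == "+") gene_length else rev(gene_length)
  coord_gap <- if (focal_strand == "+") intergenic else rev(intergenic)

  starts <- integer(3L)
  pos <- as.integer(flank)
  for (k in 1:3) {
    starts[[k]] <- pos
    pos <- pos + coord_len[[k]] + if (k < 3L) coord_gap[[k]] else 0L
  }
  total <- pos + as.integer(flank)

  ann <- data.frame(
    gene_symbol = coord_order,
    contig_id = contig_id,
    start = starts,
    end = starts + coord_len,
    strand = focal_strand,
    stringsAsFactors = FALSE
  )
  seq <- with_seed(seed, sample_background(total))
  list(
    genome = genome_sequence(species_label, contig_id, seq),
    annotations = ann,
    truth = list(order = order, focal_strand = focal_strand)
  )
}

#' Mutate an element into a diverged homolog with an exact edit record
#'
#' Substitutions occur independently at each position with probability
#' `divergence_fraction` (never to the same base); single-base insertions
#' and deletions occur with probability `indel_fraction`, but never within
#' the first or last 10 bp so position-fidelity checks on the element
#' boundaries stay well defined.  The per-column edit record makes the true
#' identity of the homolog computable exactly.
#'
#' @param sequence Element sequence over `{A,C,G,T}`.
#' @param divergence_fraction Per-position substitution probability (<= 0.9).
#' @param indel_fraction Per-position single-base indel probability.
#' @param seed Integer seed.
#' @return List with `sequence` (the homolog), `edits` (data frame with
#'   `position` in original coordinates, `op`, `from`, `to`),
#'   `n_substitutions`, and `truth_identity` (percent; `NA` when indels were
#'   introduced).
#' @export
mutate_element <- function(sequence, divergence_fraction, indel_fraction = 0,
                           seed = NULL) {
  sequence <- normalize_sequence(sequence, "element")
  stopifnot(
    divergence_fraction >= 0, divergence_fraction <= 0.9,
    indel_fraction >= 0, indel_fraction <= 0.5
  )
  v <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(v)
  with_seed(seed, {
    sub_at <- which(stats::runif(n) < divergence_fraction)
    edits <- list()
    for (i in sub_at) {
      to <- sample(setdiff(BASES, v[[i]]), 1L)
      edits[[length(edits) + 1L]] <- data.frame(
        position = i, op = "sub", from = v[[i]], to = to,
        stringsAsFactors = FALSE
      )
      v[[i]] <- to
    }
    out <- as.list(v)
    if (indel_fraction > 0 && n > 20L) {
      eligible <- 11:(n - 10L)
      ind_at <- eligible[stats::runif(length(eligible)) < indel_fraction]
      for (i in ind_at) {
        if (stats::runif(1L) < 0.5) {
          ins <- sample(BASES, 1L)
          out[[i]] <- c(out[[i]], ins)
          edits[[length(edits) + 1L]] <- data.frame(
            position = i, op = "ins", from = "", to = ins,
            stringsAsFactors = FALSE
          )
        } else {
          edits[[length(edits) + 1L]] <- data.frame(
            position = i, op = "del", from = v[[i]], to = "",
            stringsAsFactors = FALSE
          )
          out[[i]] <- character(0L)
        }
      }
    }
    edits <- if (length(edits)) do.call(rbind, edits) else data.frame(
      position = integer(0L), op = character(0L),
      from = character(0L), to = character(0L), stringsAsFactors = FALSE
    )
    n_sub <- sum(edits$op == "sub")
    has_indel <- any(edits$op %in% c("ins", "del"))
    list(
      sequence = paste(unlist(out), collapse = ""),
      edits = edits,
      n_substitutions = n_sub,
      truth_identity = if (has_indel) NA_real_ else 100 * (1 - n_sub / n)
    )
  })
}

#' Simulate a methylation-sensitive restriction-digest qPCR experiment
#'
#' Generates a Ct table from known template fractions.  Template surviving a
#' methylation-blocked digest is `m + (1 - m) * (1 - d)` for methylated
#' fraction `m` and digestion completeness `d`; mock arms survive fully and
#' control-digest arms (insensitive isoschizomer) survive `1 - d`.  The
#' reference amplicon carries no restriction site and survives every arm.
#' Each Ct is `baseline - log2(survival)` plus Gaussian noise; zero survival
#' yields a non-amplifying sentinel at `max_cycle`, flagged in the
#' `no_amplification` column.
#'
#' @param methylated_fraction True methylated template fraction in `[0, 1]`.
#' @param digestion_completeness Fraction of unprotected template actually
#'   cut.
#' @param noise_sd Gaussian Ct noise, in cycles.
#' @param replicates Number of replicates per arm.
#' @param baseline_ct,reference_baseline_ct Ct of undigested target and
#'   reference template.
#' @param target,reference_target Amplicon names.
#' @param include_control Also emit control-digest arms?
#' @param tissue,sample_id Labels copied into the records.
#' @param max_cycle Sentinel cycle for non-amplifying reactions.
#' @param seed Integer seed.
#' @return A Ct table data frame (see [msrd_percent_methylation()]).
#' @export
simulate_ct <- function(methylated_fraction, digestion_completeness = 1,
                        noise_sd = 0, replicates = 3L, baseline_ct = 24,
                        reference_baseline_ct = 12, target = "amplicon",
                        reference_target = "18S", include_control = TRUE,
                        tissue = "tissue", sample_id = "s1", max_cycle = 45,
                        seed = NULL) {
  m <- methylated_fraction
  d <- digestion_completeness
  stopifnot(m >= 0, m <= 1, d >= 0, d <= 1, noise_sd >= 0, replicates >= 1L)
  survival <- list(
    mock = 1,
    methyl_sensitive_digest = m + (1 - m) * (1 - d),
    control_digest = 1 - d
  )
  treatments <- c("mock", "methyl_sensitive_digest", if (include_control) "control_digest")
  with_seed(seed, {
    rows <- list()
    for (tr in treatments) {
      for (rep_i in seq_len(replicates)) {
        for (tg in c(target, reference_target)) {
          S <- if (tg == reference_target) 1 else survival[[tr]]
          base <- if (tg == reference_target) reference_baseline_ct else baseline_ct
          if (S <= 0) {
            ct <- max_cycle
            no_amp <- TRUE
          } else {
            ct <- base - log2(S) + stats::rnorm(1L, 0, noise_sd)
            ct <- min(max(ct, 0.01), max_cycle)
            no_amp <- FALSE
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, tissue = tissue, target = tg,
            treatment = tr, replicate = rep_i, ct = ct,
            no_amplification = no_amp, stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate bisulfite base counts at a panel of CpGs
#'
#' At each CpG with true methylation `m` and conversion efficiency `e`, the
#' read-level C count is `Binomial(depth, m + (1 - m) * (1 - e))`: residual
#' unconverted unmethylated cytosines inflate the C signal, which
#' [bisulfite_percent()] corrects for.
#'
#' @param methylation Vector of true per-CpG methylation fractions.
#' @param depth Read depth per position.
#' @param conversion_efficiency Conversion efficiency `e` in `(0, 1]`.
#' @param seed Integer seed.
#' @return Data frame with `cpg_index`, `count_c`, `count_t`.
#' @export
simulate_bisulfite <- function(methylation, depth = 1000L,
                               conversion_efficiency = 1, seed = NULL) {
  e <- conversion_efficiency
  stopifnot(
    all(methylation >= 0), all(methylation <= 1), depth >= 1L,
    e > 0, e <= 1
  )
  p <- methylation + (1 - methylation) * (1 - e)
  with_seed(seed, {
    cc <- stats::rbinom(length(methylation), depth, p)
    data.frame(
      cpg_index = seq_along(methylation),
      count_c = cc, count_t = depth - cc
    )
  })
}
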