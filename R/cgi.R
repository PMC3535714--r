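#' CpG-island scan parameters
#'
#' The three Gardiner-Garden-Frommer thresholds (length >= 200 bp, G+C
#' fraction >= 0.5, observed/expected CpG > 0.6) plus the scoring constants
#' of the seeded maximal-segment pass: +17 at every CG dinucleotide start and
#' -1 at every other position, the classic parameterization under which a
#' segment scores positively once its CpG start density exceeds 1/18.
#'
#' @param min_length Minimum island length in bp (>= 2).
#' @param min_gc Minimum G+C fraction.
#' @param min_oe Observed/expected CpG ratio that islands must exceed.
#' @param seed_bonus Score at each CG dinucleotide start (seeded pass).
#' @param seed_penalty Score at every other position (seeded pass; negative).
#' @param max_n_fraction Maximum tolerated fraction of `N` in a window;
#'   the default 0 makes any window touching an assembly gap ineligible.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(min_length = 200L, min_gc = 0.5, min_oe = 0.6,
                        seed_bonus = 17, seed_penalty = -1,
                        max_n_fraction = 0) {
  min_length <- as.integer(min_length)
  stopifnot(
    min_length >= 2L, min_gc >= 0, min_gc <= 1, min_oe >= 0,
    seed_bonus > 0, seed_penalty < 0,
    max_n_fraction >= 0, max_n_fraction <= 1
  )
  structure(
    list(
      min_length = min_length, min_gc = min_gc, min_oe = min_oe,
      seed_bonus = seed_bonus, seed_penalty = seed_penalty,
      max_n_fraction = max_n_fraction
    ),
    class = "scan_params"
  )
}

#' CpG statistics of a sequence
#'
#' G+C fraction, observed CpG dinucleotide count (overlap-free by
#' construction: each CG start is counted once), expected CpG count
#' `#C * #G / length`, and their ratio.  `N` bases count toward length only.
#' When the expected count is zero the ratio is undefined and reported as 0
#' with `oe_defined = FALSE`; such a sequence can never pass the island
#' criteria.
#'
#' @param sequence Sequence string over `{A,C,G,T,N}` (length >= 1).
#' @return An object of class `cpg_stats`: list with `length`,
#'   `gc_fraction`, `obs_cpg`, `exp_cpg`, `oe_ratio`, `oe_defined`,
#'   `n_fraction`.
#' @export
#' @examples
#' cpg_stats("CGCGCGCG") # gc 1, obs 4, exp 2, o/e 2
cpg_stats <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  v <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  len <- length(v)
  n_c <- sum(v == "C")
  n_g <- sum(v == "G")
  n_n <- sum(v == "N")
  obs <- if (len >= 2L) sum(v[-len] == "C" & v[-1L] == "G") else 0L
  exp_cpg <- n_c * n_g / len
  oe_defined <- exp_cpg > 0
  structure(
    list(
      length = len,
      gc_fraction = (n_c + n_g) / len,
      obs_cpg = as.integer(obs),
      exp_cpg = exp_cpg,
      oe_ratio = if (oe_defined) obs / exp_cpg else 0,
      oe_defined = oe_defined,
      n_fraction = n_n / len
    ),
    class = "cpg_stats"
  )
}

# Do stats satisfy the three island criteria (and the N budget)?
stats_pass <- function(stats, params) {
  stats$length >= params$min_length &&
    stats$gc_fraction >= params$min_gc &&
    stats$oe_defined && stats$oe_ratio > params$min_oe &&
    stats$n_fraction <= params$max_n_fraction
}

# All maximal positive-scoring segments of a score vector (Ruzzo & Tompa's
# linear-time algorithm).  Returns a data frame of 1-based inclusive [l, r]
# bounds over score positions.
maximal_scoring_segments <- function(score) {
  n <- length(score)
  cum <- c(0, cumsum(score))
  segs <- vector("list", 0L)
  k <- 0L
  for (i in seq_len(n)) {
    if (score[[i]] <= 0) next
    L <- i - 1L
    R <- i
    Ls <- cum[[L + 1L]]
    Rs <- cum[[R + 1L]]
    repeat {
      j <- k
      while (j >= 1L && segs[[j]]$Ls >= Ls) j <- j - 1L
      if (j == 0L || segs[[j]]$Rs >= Rs) {
        k <- k + 1L
        segs[[k]] <- list(L = L, R = R, Ls = Ls, Rs = Rs)
        break
      }
      L <- segs[[j]]$L
      Ls <- segs[[j]]$Ls
      k <- j - 1L
      segs <- segs[seq_len(k)]
    }
  }
  segs <- segs[seq_len(k)]
  data.frame(
    l = vapply(segs, function(s) s$L + 1L, integer(1L)),
    r = vapply(segs, function(s) s$R, integer(1L))
  )
}

island_frame <- function(starts, ends, seqs, params, anchor_offset, extra = NULL) {
  stats <- lapply(seqs, cpg_stats)
  out <- data.frame(
    start = starts - anchor_offset,
    end = ends - anchor_offset,
    length = ends - starts,
    gc_fraction = vapply(stats, `[[`, numeric(1L), "gc_fraction"),
    obs_cpg = vapply(stats, `[[`, integer(1L), "obs_cpg"),
    exp_cpg = vapply(stats, `[[`, numeric(1L), "exp_cpg"),
    oe_ratio = vapply(stats, `[[`, numeric(1L), "oe_ratio"),
    oe_defined = vapply(stats, `[[`, logical(1L), "oe_defined"),
    n_fraction = vapply(stats, `[[`, numeric(1L), "n_fraction"),
    stringsAsFactors = FALSE
  )
  out$criteria_pass <- vapply(stats, stats_pass, logical(1L), params = params)
  if (!is.null(extra)) out <- cbind(out, extra)
  out[order(out$start), , drop = FALSE]
}

#' Seeded maximal-segment CpG-island scan (high-stringency pass)
#'
#' Scores every position (+`seed_bonus` at a CG dinucleotide start,
#' `seed_penalty` elsewhere), extracts all maximal positive-scoring segments,
#' and keeps those whose [cpg_stats()] satisfy the three island criteria and
#' the `N` budget.  Segment ends are extended to include the trailing `G` of
#' a terminal CpG.
#'
#' @param region An `upstream_region` (or a bare sequence string, in which
#'   case coordinates are plain 0-based offsets).
#' @param params A [scan_params()].
#' @return Data frame of candidate segments with anchor-relative half-open
#'   `start`/`end`, the recomputed statistics, and `score`.
#' @export
scan_seeded <- function(region, params = scan_params()) {
  region <- as_upstream_region(region)
  seq <- region$sequence
  n <- nchar(seq)
  if (n < params$min_length) {
    stop(sprintf("sequence length %d below min_length %d", n, params$min_length),
      call. = FALSE
    )
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cg <- v[-n] == "C" & v[-1L] == "G" # cg[i]: CG starts at 1-based position i
  score <- rep(params$seed_penalty, n)
  score[which(cg)] <- params$seed_bonus
  segs <- maximal_scoring_segments(score)
  if (nrow(segs) == 0L) {
    return(empty_island_frame(score_col = TRUE))
  }
  start0 <- segs$l - 1L
  end0 <- ifelse(segs$r < n & cg[pmin(segs$r, n - 1L)], segs$r + 1L, segs$r)
  seg_score <- vapply(
    seq_len(nrow(segs)),
    function(i) sum(score[segs$l[i]:segs$r[i]]), numeric(1L)
  )
  out <- island_frame(
    start0, as.integer(end0),
    substring(seq, start0 + 1L, end0),
    params, region$anchor_offset,
    extra = data.frame(score = seg_score)
  )
  out <- out[out$criteria_pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "species_label") <- region$species_label
  out
}

empty_island_frame <- function(score_col = FALSE, tier_col = FALSE) {
  out <- data.frame(
    start = integer(0L), end = integer(0L), length = integer(0L),
    gc_fraction = numeric(0L), obs_cpg = integer(0L), exp_cpg = numeric(0L),
    oe_ratio = numeric(0L), oe_defined = logical(0L), n_fraction = numeric(0L),
    criteria_pass = logical(0L)
  )
  if (score_col) out$score <- numeric(0L)
  if (tier_col) out$tier <- character(0L)
  out
}

#' Exhaustive window CpG-island scan (low-stringency pass)
#'
#' Considers every window of length at least `min_length` whose statistics
#' satisfy the three island criteria and whose `N` content is within budget,
#' and reports the merged (overlapping-or-abutting) union of all qualifying
#' windows.  Each merged interval is re-checked against the criteria; because
#' a union of qualifying windows can dilute below a threshold, the re-check
#' result is kept as the `criteria_pass` flag rather than used to drop the
#' interval.  The reported base coverage is exactly the union of all
#' qualifying windows.
#'
#' @inheritParams scan_seeded
#' @return Data frame of merged islands with anchor-relative half-open
#'   `start`/`end`, merged-interval statistics, and `criteria_pass`.
#' @export
scan_exhaustive <- function(region, params = scan_params()) {
  region <- as_upstream_region(region)
  seq <- region$sequence
  n <- nchar(seq)
  if (n < params$min_length) {
    stop(sprintf("sequence length %d below min_length %d", n, params$min_length),
      call. = FALSE
    )
  }
  max_end <- cgi_max_end_cpp(
    seq, params$min_length, params$min_gc, params$min_oe, params$max_n_fraction
  )
  keep <- which(max_end > 0L)
  if (length(keep) == 0L) {
    out <- empty_island_frame()
    attr(out, "species_label") <- region$species_label
    return(out)
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = keep, end = max_end[keep]))
  start0 <- IRanges::start(ir) - 1L
  end0 <- IRanges::end(ir)
  out <- island_frame(
    start0, end0, substring(seq, start0 + 1L, end0),
    params, region$anchor_offset
  )
  rownames(out) <- NULL
  attr(out, "species_label") <- region$species_label
  out
}

#' Assign stringency tiers to exhaustive islands
#'
#' An island is tier `"high"` when it overlaps (by at least one base) a
#' criteria-passing segment from the seeded scan, i.e. it would also have
#' been found by the classic maximal-segment screen; islands found only by
#' exhaustive enumeration are tier `"low"`.  Both inputs must come from the
#' same region and parameters.
#'
#' @param exhaustive_islands Output of [scan_exhaustive()].
#' @param seeded_segments Output of [scan_seeded()].
#' @return The exhaustive island data frame with a `tier` column, sorted by
#'   start.
#' @export
classify_islands <- function(exhaustive_islands, seeded_segments) {
  sp_a <- attr(exhaustive_islands, "species_label")
  sp_b <- attr(seeded_segments, "species_label")
  if (!is.null(sp_a) && !is.null(sp_b) && !identical(sp_a, sp_b)) {
    stop("exhaustive and seeded results come from different regions", call. = FALSE)
  }
  out <- exhaustive_islands
  if (nrow(out) == 0L) {
    out$tier <- character(0L)
    return(out)
  }
  overlaps <- function(s, e) {
    nrow(seeded_segments) > 0L &&
      any(pmax(s, seeded_segments$start) < pmin(e, seeded_segments$end))
  }
  out$tier <- ifelse(
    mapply(overlaps, out$start, out$end),
    "high", "low"
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "species_label") <- sp_a
  out
}

#' Per-species CpG-island call
#'
#' Collapses a species' islands to the presence-matrix vocabulary:
#' `"high stringency"` when any island carries tier high, `"low stringency"`
#' when islands exist but none does, `"absent"` when none was found.
#'
#' @param islands Output of [classify_islands()] (may have zero rows).
#' @return One of `"high stringency"`, `"low stringency"`, `"absent"`.
#' @export
species_cgi_call <- function(islands) {
  if (is.null(islands) || nrow(islands) == 0L) {
    return("absent")
  }
  if (!"tier" %in% names(islands)) {
    stop("islands must carry a 'tier' column; run classify_islands() first",
      call. = FALSE
    )
  }
  if (any(islands$tier == "high")) "high stringency" else "low stringency"
}
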