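#' Construct a restriction enzyme description
#'
#' Only the recognition pattern and whether CpG methylation blocks cleavage
#' matter here.  The classic methylation assay pairs a blocked enzyme with a
#' methylation-insensitive isoschizomer cutting the same site to control for
#' incomplete digestion.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition string (>= 4 bases).
#' @param methylation_blocked Is cleavage prevented by CpG methylation?
#' @return An object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, methylation_blocked) {
  recognition <- toupper(recognition)
  stopifnot(
    is.character(name), nchar(recognition) >= 4L,
    is.logical(methylation_blocked)
  )
  if (grepl("[^ACGTRYSWKMBDHVN]", recognition)) {
    stop("recognition sequence must use the IUPAC alphabet", call. = FALSE)
  }
  structure(
    list(
      name = name, recognition = recognition,
      methylation_blocked = methylation_blocked
    ),
    class = "restriction_enzyme"
  )
}

#' The enzyme panel of the UCP1 promoter methylation assay
#'
#' HpaII (CCGG, blocked by methylation) with its insensitive isoschizomer
#' MspI; TaiI (ACGT, blocked) for amplicons lacking a CCGG site, with MnlI
#' (CCTC, insensitive) gauging digestion completeness.
#'
#' @return Named list of [restriction_enzyme()] objects.
#' @export
known_enzymes <- function() {
  list(
    HpaII = restriction_enzyme("HpaII", "CCGG", TRUE),
    MspI = restriction_enzyme("MspI", "CCGG", FALSE),
    TaiI = restriction_enzyme("TaiI", "ACGT", TRUE),
    MnlI = restriction_enzyme("MnlI", "CCTC", FALSE)
  )
}

#' Find restriction sites in a sequence
#'
#' Reports 0-based start positions of the recognition pattern.  `N` in the
#' sequence never matches.  With `search_both_strands`, non-palindromic
#' patterns (such as MnlI's CCTC) are additionally searched as their reverse
#' complement and tagged with strand `"-"`; palindromic patterns are searched
#' on one strand only.
#'
#' @param sequence Sequence string over `{A,C,G,T,N}`.
#' @param enzyme A [restriction_enzyme()].
#' @param search_both_strands Also search the reverse-complement pattern?
#' @return Data frame with columns `position` (0-based) and `strand`.
#' @export
#' @examples
#' find_sites("AACCGGTTACCGGA", known_enzymes()$HpaII) # positions 2 and 9
find_sites <- function(sequence, enzyme, search_both_strands = FALSE) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  sequence <- normalize_sequence(sequence)
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(enzyme$recognition)
  match_starts <- function(p) {
    hits <- Biostrings::matchPattern(
      p, subj,
      fixed = c(pattern = FALSE, subject = TRUE)
    )
    s <- Biostrings::start(hits)
    w <- Biostrings::width(hits)
    # windows touching an N never count as sites
    keep <- !vapply(
      seq_along(s),
      function(i) grepl("N", substr(sequence, s[i], s[i] + w[i] - 1L), fixed = TRUE),
      logical(1L)
    )
    s[keep] - 1L
  }
  fwd <- match_starts(pat)
  out <- data.frame(position = fwd, strand = rep("+", length(fwd)))
  rc <- Biostrings::reverseComplement(pat)
  palindromic <- as.character(rc) == as.character(pat)
  if (search_both_strands && !palindromic) {
    rev <- match_starts(rc)
    out <- rbind(out, data.frame(position = rev, strand = rep("-", length(rev))))
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mean Ct of the rows of a Ct table matching target/treatment/replicate;
# returns list(ct, no_amp).  `rep` = NULL averages over everything.
ct_lookup <- function(records, target, treatment, rep = NULL) {
  rows <- records[records$target == target & records$treatment == treatment, , drop = FALSE]
  if (!is.null(rep)) rows <- rows[rows$replicate == rep, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(NULL)
  }
  no_amp <- if ("no_amplification" %in% names(rows)) all(rows$no_amplification) else FALSE
  list(ct = mean(rows$ct), no_amp = no_amp)
}

#' Percent methylation from a methylation-sensitive restriction-digest qPCR
#'
#' Template surviving a methylation-blocked digest, relative to a mock
#' digest, measures the methylated fraction.  Per replicate,
#' `S = 2^-((Ct_target,digest - Ct_ref,digest) - (Ct_target,mock - Ct_ref,mock))`
#' and percent methylation is `100 * min(S, 1)`; survival above 1 arises from
#' noise and is clamped with a warning.  Digest-arm reactions flagged as
#' non-amplifying (complete digestion of an unmethylated template) count as
#' `S = 0`.  When control-digest records from a methylation-insensitive
#' isoschizomer are present, their survival `S_control` gauges digestion
#' completeness: `completeness_flag` is raised when it exceeds `tolerance`,
#' and a background-corrected percent
#' `100 * (S - S_control) / (1 - S_control)` (clamped to `[0, 100]`) is also
#' reported.  Replicates are paired by replicate index when the four arms
#' share indices, otherwise a single all-vs-mean estimate is formed.
#'
#' @param records Ct table: data frame with columns `sample_id`, `tissue`,
#'   `target`, `treatment` (`mock`, `methyl_sensitive_digest`,
#'   `control_digest`), `replicate`, `ct`, and optionally `no_amplification`.
#' @param target Amplicon / target name to quantify.
#' @param reference_target Reference amplicon without a restriction site
#'   (default `"18S"`).
#' @param tolerance Control-digest survival above which digestion is flagged
#'   incomplete.
#' @return An object of class `methylation_estimate`: list with `target`,
#'   `method = "msrd_qpcr"`, `percent` (mean over replicates), `sd`,
#'   `n_replicates`, per-replicate `survival`, `completeness_flag`,
#'   `control_survival`, `percent_corrected`.
#' @export
msrd_percent_methylation <- function(records, target, reference_target = "18S",
                                     tolerance = 0.05) {
  records <- as.data.frame(records)
  needed <- c("target", "treatment", "replicate", "ct")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop(sprintf("Ct table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
      call. = FALSE
    )
  }
  if (!any(records$target == reference_target)) {
    stop(sprintf("reference records absent for '%s'", reference_target), call. = FALSE)
  }
  arms <- list(
    c(target, "methyl_sensitive_digest"),
    c(target, "mock"),
    c(reference_target, "methyl_sensitive_digest"),
    c(reference_target, "mock")
  )
  for (arm in arms) {
    if (is.null(ct_lookup(records, arm[[1L]], arm[[2L]]))) {
      stop(sprintf("missing treatment arm: %s / %s", arm[[1L]], arm[[2L]]), call. = FALSE)
    }
  }
  reps_of <- function(tg, tr) {
    unique(records$replicate[records$target == tg & records$treatment == tr])
  }
  common <- Reduce(intersect, lapply(arms, function(a) reps_of(a[[1L]], a[[2L]])))
  reps <- if (length(common) >= 1L) sort(common) else list(NULL)

  survival_one <- function(rep, treatment) {
    td <- ct_lookup(records, target, treatment, rep)
    tm <- ct_lookup(records, target, "mock", rep)
    rd <- ct_lookup(records, reference_target, treatment, rep)
    rm_ <- ct_lookup(records, reference_target, "mock", rep)
    if (is.null(rd)) rd <- ct_lookup(records, reference_target, "mock", rep)
    if (any(vapply(list(td, tm, rd, rm_), is.null, logical(1L)))) {
      return(NA_real_)
    }
    if (td$no_amp) {
      return(0)
    }
    ddct <- (td$ct - rd$ct) - (tm$ct - rm_$ct)
    2^(-ddct)
  }

  S <- vapply(reps, survival_one, numeric(1L), treatment = "methyl_sensitive_digest")
  S <- S[!is.na(S)]
  if (any(S > 1)) {
    warning("survival above 1 in some replicate(s); clamping to 100%", call. = FALSE)
  }
  percent_rep <- 100 * pmin(S, 1)
  percent <- mean(percent_rep)
  disp <- if (length(percent_rep) > 1L) stats::sd(percent_rep) else NA_real_

  has_control <- any(records$target == target & records$treatment == "control_digest")
  completeness_flag <- NA
  control_survival <- NA_real_
  percent_corrected <- NA_real_
  if (has_control) {
    Sc <- vapply(reps, survival_one, numeric(1L), treatment = "control_digest")
    Sc <- Sc[!is.na(Sc)]
    control_survival <- mean(pmin(Sc, 1))
    completeness_flag <- control_survival > tolerance
    s_bar <- mean(pmin(S, 1))
    if (control_survival < 1) {
      percent_corrected <- 100 * min(1, max(0, (s_bar - control_survival) / (1 - control_survival)))
    }
  }

  structure(
    list(
      target = target, method = "msrd_qpcr",
      percent = percent, sd = disp, n_replicates = length(percent_rep),
      survival = S, completeness_flag = completeness_flag,
      control_survival = control_survival,
      percent_corrected = percent_corrected
    ),
    class = "methylation_estimate"
  )
}

#' @export
print.methylation_estimate <- function(x, ...) {
  cat(sprintf(
    "<methylation_estimate> %s [%s]: %.2f%%%s (n = %d)%s\n",
    x$target, x$method, x$percent,
    if (!is.na(x$sd)) sprintf(" +/- %.2f", x$sd) else "",
    x$n_replicates,
    if (isTRUE(x$completeness_flag)) " [incomplete digestion]" else ""
  ))
  invisible(x)
}

#' Per-CpG percent methylation from bisulfite base counts
#'
#' Unmethylated cytosines read as T after conversion, so the residual C
#' fraction estimates methylation.  With conversion efficiency `e < 1` the
#' raw fraction is inflated by `(1 - e)`; the corrected estimate is
#' `100 * max(0, c/(c + t) - (1 - e)) / e`, clamped to `[0, 100]`.  Positions
#' with zero coverage are reported as missing rather than dropped, mirroring
#' failed pyrosequencing assays.
#'
#' @param counts Data frame with columns `cpg_index`, `count_c`, `count_t`.
#' @param conversion_efficiency Fraction of unmethylated C actually
#'   converted (default 1).
#' @return Data frame with one row per CpG: `cpg_index`, counts, `depth`,
#'   `percent_raw`, `percent` (conversion-corrected), `missing`, `method`.
#' @export
#' @examples
#' bisulfite_percent(
#'   data.frame(cpg_index = 1, count_c = 32, count_t = 68),
#'   conversion_efficiency = 0.98
#' )
bisulfite_percent <- function(counts, conversion_efficiency = 1) {
  counts <- as.data.frame(counts)
  stopifnot(
    all(c("cpg_index", "count_c", "count_t") %in% names(counts)),
    conversion_efficiency > 0, conversion_efficiency <= 1,
    all(counts$count_c >= 0), all(counts$count_t >= 0)
  )
  depth <- counts$count_c + counts$count_t
  missing <- depth == 0L
  p <- ifelse(missing, NA_real_, counts$count_c / depth)
  e <- conversion_efficiency
  corrected <- 100 * pmin(1, pmax(0, (p - (1 - e)) / e))
  data.frame(
    cpg_index = counts$cpg_index,
    count_c = counts$count_c, count_t = counts$count_t, depth = depth,
    percent_raw = 100 * p,
    percent = corrected,
    missing = missing,
    method = "bisulfite",
    stringsAsFactors = FALSE
  )
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per tissue, `dCt = Ct(target) - Ct(reference)` (averaged over
#' replicates); the fold change against the calibrator tissue is
#' `2^-(dCt - dCt_calibrator)`, assuming perfect doubling per cycle.  The
#' calibrator's fold change is 1 by construction.
#'
#' @param records Ct table with columns `tissue`, `target`, `ct` (any
#'   `treatment` column is ignored here).
#' @param target Gene of interest.
#' @param reference_target Internal-control gene (default `"18S"`).
#' @param calibrator_tissue Tissue defining fold change 1.
#' @return Data frame with columns `tissue`, `delta_ct`, `fold`.
#' @export
relative_expression <- function(records, target, reference_target = "18S",
                                calibrator_tissue) {
  records <- as.data.frame(records)
  stopifnot(all(c("tissue", "target", "ct") %in% names(records)))
  tissues <- unique(records$tissue)
  if (!calibrator_tissue %in% tissues) {
    stop(sprintf("calibrator tissue '%s' absent from records", calibrator_tissue),
      call. = FALSE
    )
  }
  dct <- vapply(tissues, function(ti) {
    tt <- records$ct[records$tissue == ti & records$target == target]
    rr <- records$ct[records$tissue == ti & records$target == reference_target]
    if (!length(tt) || !length(rr)) {
      stop(sprintf("missing target or reference Ct for tissue '%s'", ti), call. = FALSE)
    }
    mean(tt) - mean(rr)
  }, numeric(1L))
  fold <- 2^(-(dct - dct[[calibrator_tissue]]))
  data.frame(
    tissue = tissues, delta_ct = unname(dct), fold = unname(fold),
    stringsAsFactors = FALSE
  )
}
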