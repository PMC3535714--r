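#' Alignment scoring scheme
#'
#' Defaults (+2 match, -3 mismatch, -5 gap open, -2 gap extend) favour
#' compact, high-identity local hits; a gap of length `L` costs
#' `gap_open + (L - 1) * gap_extend`.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0); also the score of any column
#'   involving `N`.
#' @param gap_open Cost of the first gapped column (<= `gap_extend` < 0).
#' @param gap_extend Cost of each further gapped column.
#' @return An object of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -2) {
  stopifnot(
    match > 0, mismatch < 0,
    gap_open <= gap_extend, gap_extend < 0
  )
  structure(
    list(
      match = match, mismatch = mismatch,
      gap_open = gap_open, gap_extend = gap_extend
    ),
    class = "align_scoring"
  )
}

#' Optimal affine-gap local alignment
#'
#' Smith-Waterman with affine gaps.  `N` in either sequence scores as a
#' universal mismatch, so runs of assembly gaps cannot anchor an alignment;
#' against an all-`N` target the best alignment is empty with score 0.
#' Among equal-scoring optima the alignment with the smallest target start,
#' then the smallest target end, is returned.
#'
#' @param query,target Sequence strings over `{A,C,G,T,N}`.
#' @param scoring An [align_scoring()].
#' @return An object of class `local_alignment`: list with `score`,
#'   0-based half-open `q_start`/`q_end`/`t_start`/`t_end`, `n_columns`,
#'   `n_identical`, and the gapped `aligned_query`/`aligned_target` strings.
#' @export
local_align <- function(query, target, scoring = align_scoring()) {
  query <- normalize_sequence(query, "query")
  target <- normalize_sequence(target, "target")
  res <- sw_align_cpp(
    query, target,
    scoring$match, scoring$mismatch, scoring$gap_open, scoring$gap_extend
  )
  structure(res, class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "<local_alignment> score %g, target [%d, %d), %d columns (%d identical)\n",
    x$score, x$t_start, x$t_end, x$n_columns, x$n_identical
  ))
  invisible(x)
}

#' Percent identity of a local alignment
#'
#' 100 x identical columns over total aligned columns, gap columns counted
#' in the denominator.  The column convention matters when comparing to
#' published pairwise identities, so it is fixed here and recorded in
#' element-hit output.
#'
#' @param alignment A `local_alignment` with at least one column.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "local_alignment"))
  if (alignment$n_columns == 0L) {
    stop("alignment has zero columns", call. = FALSE)
  }
  100 * alignment$n_identical / alignment$n_columns
}

#' Construct a regulatory-element query
#'
#' A query element to be located in upstream regions: typically the ~500 bp
#' distal UCP1 enhancer (human anchor-relative position -3488) or the
#' putative regulatory region (human position -2095).
#'
#' @param name `"enhancer"`, `"prr"`, or a custom label.
#' @param sequence Element sequence over `{A,C,G,T}` (>= 50 bp).
#' @param human_anchor_position Anchor-relative position of the element in
#'   the human reference, if known (negative = upstream).
#' @return An object of class `element_query`.
#' @export
element_query <- function(name, sequence, human_anchor_position = NA_integer_) {
  sequence <- normalize_sequence(sequence, sprintf("query '%s'", name))
  if (nchar(sequence) < 50L) {
    stop("element query must be at least 50 bp", call. = FALSE)
  }
  structure(
    list(
      name = name, sequence = sequence,
      human_anchor_position = as.integer(human_anchor_position),
      nominal_length = nchar(sequence)
    ),
    class = "element_query"
  )
}

#' Search an upstream region for a homolog of a query element
#'
#' Two alignments against the (already strand-normalized) region are
#' combined.  A Smith-Waterman [local_align()] finds the best-conserved core
#' and supplies the raw score and the query-coverage statistic.  A
#' semi-global alignment (query end to end, target ends free) then places
#' the whole element: its target span is the reported hit interval and its
#' identity — computed over every column of the full element, internal gaps
#' included — estimates element-level divergence the way a global pairwise
#' comparison would, rather than the inflated identity of a trimmed
#' high-scoring core.  For a substitution-only homolog the semi-global
#' optimum is the ungapped diagonal through the homolog, so the reported
#' start and identity match the underlying divergence exactly.  Presence
#' requires identity and coverage to reach their thresholds; sub-threshold
#' hits are returned with `present = FALSE` but keep the best score,
#' interval and identity for auditability.
#'
#' @param region An `upstream_region` (the enhancer screen conventionally
#'   uses 10 kb of upstream sequence).
#' @param query An [element_query()] (or a bare sequence string).
#' @param scoring An [align_scoring()].
#' @param identity_threshold Minimum percent identity for presence.
#' @param coverage_threshold Minimum fraction of the query inside the
#'   alignment for presence.
#' @return An object of class `element_hit`: list with `query_name`,
#'   `present`, the anchor-relative element placement `start`/`end`, the
#'   aligned core `core_start`/`core_end`, element-level `percent_identity`,
#'   core `query_coverage`, `raw_score`, thresholds used, `species_label`.
#' @export
find_element <- function(region, query, scoring = align_scoring(),
                         identity_threshold = 60, coverage_threshold = 0.6) {
  region <- as_upstream_region(region)
  if (is.character(query)) query <- element_query("custom", query)
  stopifnot(inherits(query, "element_query"))
  qlen <- nchar(query$sequence)
  if (qlen > nchar(region$sequence)) {
    stop("query is longer than the region", call. = FALSE)
  }
  aln <- local_align(query$sequence, region$sequence, scoring)
  if (aln$n_columns == 0L) {
    hit <- list(
      query_name = query$name, present = FALSE,
      start = NA_integer_, end = NA_integer_,
      core_start = NA_integer_, core_end = NA_integer_,
      percent_identity = 0, query_coverage = 0, raw_score = 0,
      identity_threshold = identity_threshold,
      coverage_threshold = coverage_threshold,
      species_label = region$species_label,
      alignment = aln
    )
    return(structure(hit, class = "element_hit"))
  }
  # element-level placement: semi-global alignment (query end to end, free
  # target ends), whose identity reflects the whole element rather than a
  # trimmed high-scoring core
  glo <- glocal_align_cpp(
    query$sequence, region$sequence,
    scoring$match, scoring$mismatch, scoring$gap_open, scoring$gap_extend
  )
  pid <- 100 * glo$n_identical / glo$n_columns
  cov <- (aln$q_end - aln$q_start) / qlen
  present <- pid >= identity_threshold && cov >= coverage_threshold
  structure(
    list(
      query_name = query$name, present = present,
      start = glo$t_start - region$anchor_offset,
      end = glo$t_end - region$anchor_offset,
      core_start = aln$t_start - region$anchor_offset,
      core_end = aln$t_end - region$anchor_offset,
      percent_identity = pid, query_coverage = cov, raw_score = aln$score,
      identity_threshold = identity_threshold,
      coverage_threshold = coverage_threshold,
      species_label = region$species_label,
      alignment = aln
    ),
    class = "element_hit"
  )
}

#' @export
print.element_hit <- function(x, ...) {
  cat(sprintf(
    "<element_hit> %s in %s: %s (identity %.1f%%, coverage %.2f, score %g)\n",
    x$query_name, x$species_label,
    if (x$present) sprintf("present at [%d, %d)", x$start, x$end) else "absent",
    x$percent_identity, x$query_coverage, x$raw_score
  ))
  invisible(x)
}
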