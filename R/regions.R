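#' Construct a genome sequence record
#'
#' Holds one contig of one species.  Sequences are normalized to uppercase
#' `{A,C,G,T,N}`; `U` is mapped to `T`; anything else is an error naming the
#' offending position.
#'
#' @param species_label Free-text species label.
#' @param contig_id Contig/chromosome identifier.
#' @param sequence DNA sequence string.
#' @return An object of class `genome_sequence` (a list with fields
#'   `species_label`, `contig_id`, `sequence`).
#' @export
genome_sequence <- function(species_label, contig_id, sequence) {
  stopifnot(is.character(species_label), is.character(contig_id))
  seq <- normalize_sequence(sequence, label = sprintf("record '%s'", contig_id))
  structure(
    list(species_label = species_label, contig_id = contig_id, sequence = seq),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf(
    "<genome_sequence> %s / %s (%d bp)\n",
    x$species_label, x$contig_id, nchar(x$sequence)
  ))
  invisible(x)
}

#' Read genome or promoter sequences from a FASTA file
#'
#' One `genome_sequence` per FASTA record; the record id (first word of the
#' header) becomes the contig id.  Record order is preserved.  Duplicate ids,
#' an empty file, and characters outside `{A,C,G,T,N}` (after uppercasing and
#' U->T mapping) are errors.
#'
#' @param path Path to a FASTA file.
#' @param species_label Species label attached to every record; defaults to
#'   the file name without extension.
#' @return A named list of `genome_sequence` objects.
#' @export
read_fasta <- function(path, species_label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  species_label <- species_label %||% sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) {
    stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf(
      "duplicate record id '%s' in %s", ids[duplicated(ids)][1L], path
    ), call. = FALSE)
  }
  recs <- lapply(seq_along(set), function(i) {
    genome_sequence(species_label, ids[[i]], as.character(set[[i]]))
  })
  names(recs) <- ids
  recs
}

#' Read gene annotations from BED or GFF3
#'
#' Returns annotations as a data frame with 0-based half-open coordinates.
#' Gene symbols come from the BED `name` field or from a GFF3 attribute
#' (default `gene`).
#'
#' @param path Path to a 6-column BED or a GFF3 file.
#' @param format `"auto"` (by extension), `"bed"`, or `"gff3"`.
#' @param gene_key GFF3 attribute holding the gene symbol.
#' @return A data frame with columns `gene_symbol`, `contig_id`, `start`
#'   (0-based), `end` (exclusive), `strand`.
#' @export
read_annotations <- function(path, format = c("auto", "bed", "gff3"),
                             gene_key = "gene") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
      bed = "bed",
      gff = "gff3", gff3 = "gff3",
      stop(sprintf("cannot guess annotation format from '%s'", path), call. = FALSE)
    )
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  sym <- if (format == "bed") meta$name else meta[[gene_key]]
  if (is.null(sym)) {
    stop(sprintf("no '%s' field found in %s", if (format == "bed") "name" else gene_key, path),
      call. = FALSE
    )
  }
  ann <- data.frame(
    gene_symbol = as.character(sym),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  required <- c("gene_symbol", "contig_id", "start", "end", "strand")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    stop(sprintf("annotation table lacks column(s): %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  if (any(!ann$strand %in% c("+", "-"))) {
    stop("annotation strand must be '+' or '-'", call. = FALSE)
  }
  if (any(ann$start < 0L) || any(ann$end <= ann$start)) {
    stop("annotations must satisfy 0 <= start < end", call. = FALSE)
  }
  ann
}

#' Check the conserved-synteny gate for a focal gene
#'
#' A focal gene passes when, on its own contig and in its own transcriptional
#' orientation, the nearest annotated neighbour on the 5' side is
#' `upstream_neighbor` and the nearest on the 3' side is `downstream_neighbor`.
#' For a minus-strand focal gene "upstream" and "downstream" are evaluated
#' after flipping, so the verdict is invariant under reverse-complementing the
#' contig and flipping all strands.  The canonical use is requiring UCP1 to
#' sit inside the conserved TBC1D9-UCP1-ELMOD2 triplet before its upstream
#' region is accepted as orthologous.
#'
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param focal Focal gene symbol (must occur exactly once).
#' @param upstream_neighbor Required nearest 5' neighbour symbol.
#' @param downstream_neighbor Required nearest 3' neighbour symbol.
#' @return An object of class `synteny_verdict`: list with `pass` (logical)
#'   and `reason` (character).
#' @export
check_synteny_triplet <- function(annotations, focal = "UCP1",
                                  upstream_neighbor = "TBC1D9",
                                  downstream_neighbor = "ELMOD2") {
  ann <- validate_annotations(as.data.frame(annotations))
  frows <- ann[ann$gene_symbol == focal, , drop = FALSE]
  if (nrow(frows) == 0L) {
    stop(sprintf("focal gene '%s' absent from annotations", focal), call. = FALSE)
  }
  if (nrow(frows) > 1L) {
    stop(sprintf("focal gene '%s' annotated more than once", focal), call. = FALSE)
  }
  for (sym in c(upstream_neighbor, downstream_neighbor)) {
    per_contig <- table(ann$contig_id[ann$gene_symbol == sym])
    if (any(per_contig > 1L)) {
      stop(sprintf("gene '%s' annotated more than once on a contig", sym), call. = FALSE)
    }
  }
  verdict <- function(pass, reason) {
    structure(list(pass = pass, reason = reason), class = "synteny_verdict")
  }
  contig <- frows$contig_id
  for (sym in c(upstream_neighbor, downstream_neighbor)) {
    hit <- ann[ann$gene_symbol == sym, , drop = FALSE]
    if (nrow(hit) == 0L) {
      return(verdict(FALSE, sprintf("neighbor '%s' not annotated", sym)))
    }
    if (!any(hit$contig_id == contig)) {
      return(verdict(FALSE, sprintf("neighbor '%s' on a different contig", sym)))
    }
  }
  here <- ann[ann$contig_id == contig & ann$gene_symbol != focal, , drop = FALSE]
  left <- here[here$end <= frows$start, , drop = FALSE]
  right <- here[here$start >= frows$end, , drop = FALSE]
  nearest_left <- if (nrow(left)) left$gene_symbol[which.max(left$end)] else NA_character_
  nearest_right <- if (nrow(right)) right$gene_symbol[which.min(right$start)] else NA_character_
  if (frows$strand == "+") {
    five <- nearest_left
    three <- nearest_right
  } else {
    five <- nearest_right
    three <- nearest_left
  }
  if (is.na(five)) {
    return(verdict(FALSE, "no annotated 5' neighbor"))
  }
  if (five != upstream_neighbor) {
    return(verdict(FALSE, sprintf("wrong 5' neighbor (found '%s')", five)))
  }
  if (is.na(three)) {
    return(verdict(FALSE, "no annotated 3' neighbor"))
  }
  if (three != downstream_neighbor) {
    return(verdict(FALSE, sprintf("wrong 3' neighbor (found '%s')", three)))
  }
  verdict(TRUE, "triplet order confirmed")
}

#' @export
print.synteny_verdict <- function(x, ...) {
  cat(sprintf("<synteny_verdict> %s (%s)\n", if (x$pass) "PASS" else "FAIL", x$reason))
  invisible(x)
}

#' Region extraction specification
#'
#' How much sequence to take around the anchor.  The CpG-island screen uses
#' 5 kb upstream plus a 1 kb downstream margin (islands can sit just
#' downstream of the start, as in the hedgehog promoter); element searches
#' use 10 kb upstream only.  The anchor is either the ORF start or an
#' annotated transcription start; when only gene bounds are known the two
#' coincide with the gene boundary, and the choice is recorded so downstream
#' coordinates are interpretable.
#'
#' @param span_upstream Bases upstream of the anchor (>= 0).
#' @param span_downstream Bases downstream of the anchor (>= 0).
#' @param anchor_kind `"orf_start"` or `"annotated_tss"`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(span_upstream = 5000L, span_downstream = 1000L,
                        anchor_kind = c("orf_start", "annotated_tss")) {
  anchor_kind <- match.arg(anchor_kind)
  span_upstream <- as.integer(span_upstream)
  span_downstream <- as.integer(span_downstream)
  stopifnot(span_upstream >= 0L, span_downstream >= 0L)
  if (span_upstream + span_downstream <= 0L) {
    stop("span_upstream + span_downstream must be positive", call. = FALSE)
  }
  structure(
    list(
      span_upstream = span_upstream, span_downstream = span_downstream,
      anchor_kind = anchor_kind
    ),
    class = "region_spec"
  )
}

#' Construct an upstream region
#'
#' A strand-normalized promoter sequence with an explicit anchor: the
#' anchor-relative coordinate of sequence index `i` (0-based) is
#' `i - anchor_offset`, negative values lying upstream of the gene.
#'
#' @param sequence Sequence string over `{A,C,G,T,N}` (5' to 3' of the gene).
#' @param anchor_offset 0-based index mapping to anchor coordinate 0; may
#'   equal the sequence length when the region is entirely upstream.
#' @param species_label Species label.
#' @param strand_of_source Strand of the source gene, `"+"` or `"-"`.
#' @param truncated_upstream,truncated_downstream Whether the requested span
#'   was clamped at a contig edge.
#' @return An object of class `upstream_region`.
#' @export
upstream_region <- function(sequence, anchor_offset,
                            species_label = "unspecified",
                            strand_of_source = "+",
                            truncated_upstream = FALSE,
                            truncated_downstream = FALSE) {
  seq <- normalize_sequence(sequence, label = sprintf("region '%s'", species_label))
  anchor_offset <- as.integer(anchor_offset)
  stopifnot(
    anchor_offset >= 0L, anchor_offset <= nchar(seq),
    strand_of_source %in% c("+", "-")
  )
  structure(
    list(
      species_label = species_label, sequence = seq,
      anchor_offset = anchor_offset, strand_of_source = strand_of_source,
      truncated_upstream = truncated_upstream,
      truncated_downstream = truncated_downstream
    ),
    class = "upstream_region"
  )
}

#' @export
print.upstream_region <- function(x, ...) {
  cat(sprintf(
    "<upstream_region> %s: %d bp, anchor offset %d, source strand %s%s\n",
    x$species_label, nchar(x$sequence), x$anchor_offset, x$strand_of_source,
    if (x$truncated_upstream || x$truncated_downstream) " (truncated)" else ""
  ))
  invisible(x)
}

# Accept either an upstream_region or a bare sequence string (anchor at 0).
as_upstream_region <- function(x, ...) {
  if (inherits(x, "upstream_region")) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    return(upstream_region(x, anchor_offset = 0L, ...))
  }
  stop("expected an upstream_region or a single sequence string", call. = FALSE)
}

#' Extract a strand-normalized upstream region around a gene anchor
#'
#' For a plus-strand gene the anchor `a` is the annotation start and the
#' returned bases are `[max(0, a - span_upstream), min(L, a + span_downstream))`
#' as-is; for a minus-strand gene the anchor is the annotation end and the
#' window `[max(0, a - span_downstream), min(L, a + span_upstream))` is
#' reverse-complemented, so the result always reads 5' to 3' of the gene with
#' negative anchor-relative coordinates upstream.  Clamping at contig edges is
#' recorded in the truncation flags.
#'
#' @param genome A `genome_sequence`.
#' @param focal One-row annotation data frame (or list) with `contig_id`,
#'   `start`, `end`, `strand`.
#' @param spec A [region_spec()].
#' @return An `upstream_region`.
#' @export
extract_upstream <- function(genome, focal, spec = region_spec()) {
  stopifnot(inherits(genome, "genome_sequence"), inherits(spec, "region_spec"))
  focal <- as.list(as.data.frame(focal, stringsAsFactors = FALSE))
  if (!identical(as.character(focal$contig_id), genome$contig_id)) {
    stop(sprintf(
      "focal gene lies on contig '%s', not on genome contig '%s'",
      focal$contig_id, genome$contig_id
    ), call. = FALSE)
  }
  L <- nchar(genome$sequence)
  up <- spec$span_upstream
  down <- spec$span_downstream
  if (focal$strand == "+") {
    a <- as.integer(focal$start)
    if (a < 0L || a > L) stop("anchor outside contig", call. = FALSE)
    w1 <- max(0L, a - up)
    w2 <- min(L, a + down)
    seq <- substr(genome$sequence, w1 + 1L, w2)
    anchor_offset <- a - w1
    trunc_up <- (a - up) < 0L
    trunc_down <- (a + down) > L
  } else {
    a <- as.integer(focal$end)
    if (a < 0L || a > L) stop("anchor outside contig", call. = FALSE)
    w1 <- max(0L, a - down)
    w2 <- min(L, a + up)
    seq <- revcomp(substr(genome$sequence, w1 + 1L, w2))
    anchor_offset <- w2 - a
    trunc_up <- (a + up) > L
    trunc_down <- (a - down) < 0L
  }
  if (!nzchar(seq)) stop("requested region is empty", call. = FALSE)
  upstream_region(
    sequence = seq, anchor_offset = anchor_offset,
    species_label = genome$species_label, strand_of_source = focal$strand,
    truncated_upstream = trunc_up, truncated_downstream = trunc_down
  )
}

#' Write an upstream region as FASTA
#'
#' The header encodes `species|anchor_offset|strand` so the anchor survives a
#' round trip through the file.
#'
#' @param region An `upstream_region`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(region, path) {
  stopifnot(inherits(region, "upstream_region"))
  header <- sprintf(
    "%s|%d|%s", region$species_label, region$anchor_offset,
    region$strand_of_source
  )
  set <- Biostrings::DNAStringSet(setNames(region$sequence, header))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read an upstream region written by [write_region_fasta()]
#'
#' @param path FASTA file with a single `species|anchor_offset|strand` record.
#' @return An `upstream_region`.
#' @export
read_region_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) != 1L) stop("expected exactly one region record", call. = FALSE)
  parts <- strsplit(names(set)[[1L]], "|", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) {
    stop("region header must be 'species|anchor_offset|strand'", call. = FALSE)
  }
  upstream_region(
    sequence = as.character(set[[1L]]),
    anchor_offset = as.integer(parts[[2L]]),
    species_label = parts[[1L]], strand_of_source = parts[[3L]]
  )
}
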