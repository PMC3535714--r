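# Independent oracles and small construction helpers shared across tests.

# Union coverage of ALL qualifying windows by explicit O(L^2) enumeration:
# every window of length >= min_length is checked against the island
# criteria and the union is formed with IRanges::reduce.  This is the
# brute-force definition the exhaustive scanner must reproduce.
oracle_cgi_coverage <- function(seq, params = scan_params()) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(v)
  cC <- cumsum(v == "C")
  cG <- cumsum(v == "G")
  cN <- cumsum(v == "N")
  cg <- c(v[-n] == "C" & v[-1L] == "G", FALSE)
  cCG <- cumsum(cg)
  at0 <- function(x, i) if (i >= 1L) x[[i]] else 0L
  ss <- integer(0L)
  ee <- integer(0L)
  for (i in 0:(n - params$min_length)) {
    j <- (i + params$min_length):n
    len <- j - i
    c_ <- cC[j] - at0(cC, i)
    g_ <- cG[j] - at0(cG, i)
    nn <- cN[j] - at0(cN, i)
    obs <- cCG[j - 1L] - at0(cCG, i)
    gc <- (c_ + g_) / len
    expv <- c_ * g_ / len
    ok <- nn <= params$max_n_fraction * len &
      gc >= params$min_gc & expv > 0 & obs > params$min_oe * expv
    if (any(ok)) {
      ss <- c(ss, rep(i + 1L, sum(ok)))
      ee <- c(ee, j[ok])
    }
  }
  if (!length(ss)) {
    return(IRanges::IRanges())
  }
  IRanges::reduce(IRanges::IRanges(start = ss, end = ee))
}

coverage_of_islands <- function(islands, n, anchor_offset = 0L) {
  x <- logical(n)
  if (nrow(islands)) {
    for (k in seq_len(nrow(islands))) {
      x[(islands$start[k] + anchor_offset + 1L):(islands$end[k] + anchor_offset)] <- TRUE
    }
  }
  x
}

coverage_of_ranges <- function(ir, n) {
  x <- logical(n)
  if (length(ir)) {
    for (k in seq_along(ir)) {
      x[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- TRUE
    }
  }
  x
}

# Brute-force affine-gap local alignment score by memoized recursion over
# (i, j, state): best score of an alignment ending at query i / target j.
oracle_local_score <- function(q, t, sc = align_scoring()) {
  qv <- strsplit(q, "", fixed = TRUE)[[1L]]
  tv <- strsplit(t, "", fixed = TRUE)[[1L]]
  n <- length(qv)
  m <- length(tv)
  memo <- array(NA_real_, c(n + 1L, m + 1L, 3L))
  sub <- function(a, b) {
    if (a == "N" || b == "N") sc$mismatch else if (a == b) sc$match else sc$mismatch
  }
  f <- function(i, j, st) {
    if (i == 0L || j == 0L) {
      return(-Inf)
    }
    if (!is.na(memo[i + 1L, j + 1L, st])) {
      return(memo[i + 1L, j + 1L, st])
    }
    val <- if (st == 1L) {
      sub(qv[[i]], tv[[j]]) +
        max(0, f(i - 1L, j - 1L, 1L), f(i - 1L, j - 1L, 2L), f(i - 1L, j - 1L, 3L))
    } else if (st == 2L) {
      max(f(i - 1L, j, 1L) + sc$gap_open, f(i - 1L, j, 2L) + sc$gap_extend)
    } else {
      max(f(i, j - 1L, 1L) + sc$gap_open, f(i, j - 1L, 3L) + sc$gap_extend)
    }
    memo[i + 1L, j + 1L, st] <<- val
    val
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) best <- max(best, f(i, j, 1L))
  }
  best
}

random_dna <- function(n, gc = 0.5, with_n = 0) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (with_n > 0) {
    probs <- c(probs * (1 - with_n), with_n)
    paste(sample(c("A", "C", "G", "T", "N"), n, TRUE, probs), collapse = "")
  } else {
    paste(sample(c("A", "C", "G", "T"), n, TRUE, probs), collapse = "")
  }
}

# Mirror a gene annotation table onto the reverse complement of its contig.
flip_annotations <- function(ann, contig_length) {
  out <- ann
  out$start <- contig_length - ann$end
  out$end <- contig_length - ann$start
  out$strand <- ifelse(ann$strand == "+", "-", "+")
  out
}

# Build a species_promoter_record directly from presence flags (used for
# rendering fixtures where no sequences exist).
record_from_flags <- function(species, cgi_call, enhancer, prr,
                              synteny_pass = TRUE) {
  call <- switch(cgi_call,
    high = "high stringency", low = "low stringency", absent = "absent"
  )
  mk_hit <- function(present, start = -3000L, end = -2500L) {
    if (present) {
      list(present = TRUE, start = start, end = end)
    } else {
      list(present = FALSE, start = NA_integer_, end = NA_integer_)
    }
  }
  structure(
    list(
      species_label = species,
      cgi_call = call,
      cgi_interval = if (call == "absent") NULL else c(start = -400L, end = -150L),
      enhancer = mk_hit(enhancer),
      prr = mk_hit(prr, -2095L, -1595L),
      synteny_pass = synteny_pass,
      synteny_reason = if (synteny_pass) "triplet order confirmed" else "wrong 5' neighbor"
    ),
    class = "species_promoter_record"
  )
}

load_flag_fixture <- function() {
  path <- system.file("extdata", "ucp1_promoter_flags.tsv", package = "prometh")
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
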