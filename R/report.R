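#' Assemble one species' promoter record
#'
#' Combines the synteny verdict, classified islands and the two element hits
#' into one row of the presence/absence matrix.  Species labels carried by
#' the inputs must agree with `species_label`.  Records failing the synteny
#' gate are kept (for auditability of the ortholog filter) but marked, and
#' rendered in a separate excluded section by [render_matrix()].
#'
#' @param species_label Species label for the row.
#' @param synteny A `synteny_verdict` from [check_synteny_triplet()].
#' @param islands Classified islands from [classify_islands()].
#' @param enhancer_hit,prr_hit `element_hit` objects from [find_element()]
#'   (may be `NULL` when the search was not run).
#' @return An object of class `species_promoter_record`.
#' @export
assemble_record <- function(species_label, synteny, islands,
                            enhancer_hit = NULL, prr_hit = NULL) {
  stopifnot(inherits(synteny, "synteny_verdict"))
  check_species <- function(lbl, what) {
    if (!is.null(lbl) && !identical(lbl, "unspecified") &&
      !identical(lbl, species_label)) {
      stop(sprintf(
        "%s carries species '%s' but record is for '%s'",
        what, lbl, species_label
      ), call. = FALSE)
    }
  }
  check_species(attr(islands, "species_label"), "island table")
  if (!is.null(enhancer_hit)) check_species(enhancer_hit$species_label, "enhancer hit")
  if (!is.null(prr_hit)) check_species(prr_hit$species_label, "prr hit")

  call <- species_cgi_call(islands)
  cgi_interval <- NULL
  if (call != "absent") {
    tier_wanted <- if (call == "high stringency") "high" else "low"
    cand <- islands[islands$tier == tier_wanted, , drop = FALSE]
    cgi_interval <- c(start = cand$start[[1L]], end = cand$end[[1L]])
  }
  summarize_hit <- function(hit) {
    if (is.null(hit)) {
      return(list(present = FALSE, start = NA_integer_, end = NA_integer_))
    }
    stopifnot(inherits(hit, "element_hit"))
    if (!hit$present) {
      return(list(present = FALSE, start = NA_integer_, end = NA_integer_))
    }
    list(present = TRUE, start = hit$start, end = hit$end)
  }
  structure(
    list(
      species_label = species_label,
      cgi_call = call,
      cgi_interval = cgi_interval,
      enhancer = summarize_hit(enhancer_hit),
      prr = summarize_hit(prr_hit),
      synteny_pass = synteny$pass,
      synteny_reason = synteny$reason
    ),
    class = "species_promoter_record"
  )
}

default_matrix_legend <- function() {
  c(
    present = "Yes", absent = "X",
    high = "High stringency", low = "Low stringency"
  )
}

#' Render the presence/absence matrix as TSV text
#'
#' One row per species in input order, using the legend tokens (`"Yes"`,
#' `"X"`, `"High stringency"`, `"Low stringency"` by default, so a rendered
#' matrix diffs cleanly against a transcription of a published survey
#' table).  Species failing the synteny gate are rendered in a separate
#' excluded section rather than silently dropped.  Output is byte-identical
#' for identical input.
#'
#' @param records List of `species_promoter_record` objects.
#' @param legend Named character vector with entries `present`, `absent`,
#'   `high`, `low`.
#' @return A single TSV string.
#' @export
render_matrix <- function(records, legend = default_matrix_legend()) {
  if (length(records) == 0L) stop("no records to render", call. = FALSE)
  stopifnot(all(c("present", "absent", "high", "low") %in% names(legend)))
  row_of <- function(r) {
    cgi <- switch(r$cgi_call,
      "high stringency" = legend[["high"]],
      "low stringency" = legend[["low"]],
      "absent" = legend[["absent"]]
    )
    enh <- if (r$enhancer$present) legend[["present"]] else legend[["absent"]]
    prr <- if (r$prr$present) legend[["present"]] else legend[["absent"]]
    paste(r$species_label, cgi, enh, prr, sep = "\t")
  }
  pass <- vapply(records, function(r) isTRUE(r$synteny_pass), logical(1L))
  lines <- c(
    paste("species", "cgi", "enhancer", "prr", sep = "\t"),
    vapply(records[pass], row_of, character(1L))
  )
  if (any(!pass)) {
    lines <- c(
      lines, "# excluded (synteny gate)",
      vapply(records[!pass], row_of, character(1L))
    )
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a matrix rendered by [render_matrix()]
#'
#' @param text TSV string produced by [render_matrix()].
#' @param legend The legend used at render time.
#' @return Data frame with columns `species`, `cgi_call`,
#'   `enhancer_present`, `prr_present`, `excluded`.
#' @export
parse_matrix <- function(text, legend = default_matrix_legend()) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 2L) stop("matrix text has no data rows", call. = FALSE)
  excluded_at <- which(lines == "# excluded (synteny gate)")
  body <- setdiff(seq_along(lines), c(1L, excluded_at))
  inv_cgi <- c("high stringency", "low stringency", "absent")
  names(inv_cgi) <- legend[c("high", "low", "absent")]
  rows <- lapply(body, function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L) stop("malformed matrix row", call. = FALSE)
    data.frame(
      species = f[[1L]],
      cgi_call = unname(inv_cgi[[f[[2L]]]]),
      enhancer_present = f[[3L]] == legend[["present"]],
      prr_present = f[[4L]] == legend[["present"]],
      excluded = length(excluded_at) > 0L && i > excluded_at,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a feature map as JSON
#'
#' Per species, the anchor-relative intervals of the CpG island and any
#' present elements, sorted by start: the machine-readable form of a
#' promoter feature map suitable for downstream plotting.
#'
#' @param records List of `species_promoter_record` objects.
#' @return A JSON string.
#' @export
render_map <- function(records) {
  entries <- lapply(records, function(r) {
    feats <- list()
    if (!is.null(r$cgi_interval)) {
      feats[[length(feats) + 1L]] <- list(
        feature = "cgi",
        start = unname(r$cgi_interval[["start"]]),
        end = unname(r$cgi_interval[["end"]])
      )
    }
    for (nm in c("enhancer", "prr")) {
      h <- r[[nm]]
      if (isTRUE(h$present)) {
        feats[[length(feats) + 1L]] <- list(
          feature = nm, start = h$start, end = h$end
        )
      }
    }
    if (length(feats) > 1L) {
      feats <- feats[order(vapply(feats, `[[`, numeric(1L), "start"))]
    }
    list(
      species = r$species_label,
      synteny_pass = isTRUE(r$synteny_pass),
      features = feats
    )
  })
  as.character(jsonlite::toJSON(entries, auto_unbox = TRUE, digits = NA))
}
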