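# Evidence filtering, publication-primacy resolution, the five-way
# binding-sequence classifier, and per-publication/per-protein statistics.
#
# The question answered here: when a protein's functions were first shown
# experimentally, did protein binding come before, after, or together with
# any other function? Only positive experimental evidence (direct assay,
# physical interaction) with a dated publication inside the analysis window
# participates.

#' Flatten a release into evidence records
#'
#' One row per (annotation, evidence) pair.
#'
#' @param rel An `ad_release`.
#' @return Tibble: `accession`, `category`, `term_id`, `term_label`,
#'   `evidence_kind`, `is_negative`, `pub_id`, `pub_date`,
#'   `date_granularity` (`"day"`, `"year"`, or `NA` when the evidence has
#'   no publication).
#' @export
evidence_records <- function(rel) {
  stopifnot(inherits(rel, "ad_release"))
  rows <- list()
  for (e in rel$entries) {
    for (a in e$annotations) {
      for (ev in a$evidences) {
        p <- ev$publication
        rows[[length(rows) + 1L]] <- tibble::tibble(
          accession = e$accession,
          category = a$category,
          term_id = a$term_id,
          term_label = a$term_label,
          evidence_kind = ev$evidence_kind,
          is_negative = ev$is_negative,
          pub_id = if (is.null(p)) NA_character_ else p$pub_id,
          pub_date = if (is.null(p)) as.Date(NA) else p$pub_date,
          date_granularity = if (is.null(p)) NA_character_ else {
            if (p$year_only) "year" else "day"
          }
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      accession = character(0), category = character(0),
      term_id = character(0), term_label = character(0),
      evidence_kind = character(0), is_negative = logical(0),
      pub_id = character(0), pub_date = as.Date(character(0)),
      date_granularity = character(0)
    ))
  }
  dplyr::bind_rows(rows)
}

#' Keep positive experimental evidence inside a publication window
#'
#' Retains records that (i) assert the presence of a function (negative
#' evidence is dropped), (ii) are experimental — direct assay or physical
#' interaction, and (iii) carry a publication dated inside
#' `[window_start, window_end]`. A year-only publication qualifies when its
#' year overlaps the window. Records without a publication are dropped.
#'
#' @param records An [evidence_records()] tibble.
#' @param window_start,window_end Window bounds (`Date` or parseable).
#' @return Filtered tibble, same columns.
#' @export
filter_positive_experimental <- function(records, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  stopifnot(window_start <= window_end)
  if (!nrow(records)) return(records)
  year <- as.integer(format(records$pub_date, "%Y"))
  year_start <- year_end <- rep(as.Date(NA), nrow(records))
  ok <- !is.na(year)
  year_start[ok] <- as.Date(sprintf("%04d-01-01", year[ok]))
  year_end[ok] <- as.Date(sprintf("%04d-12-31", year[ok]))
  in_window <- ifelse(
    is.na(records$pub_date), FALSE,
    ifelse(records$date_granularity == "year",
           year_end >= window_start & year_start <= window_end,
           records$pub_date >= window_start & records$pub_date <= window_end)
  )
  records[
    !records$is_negative &
      records$evidence_kind %in% experimental_kinds() &
      in_window, ,
    drop = FALSE
  ]
}

# granularity-aware date comparison: -1 / 0 / +1.
# A year-only date compares at year precision against any other date; equal
# years (or equal full dates) compare as simultaneous.
compare_pub_dates <- function(d1, g1, d2, g2) {
  if (identical(g1, "year") || identical(g2, "year")) {
    y1 <- as.integer(format(d1, "%Y"))
    y2 <- as.integer(format(d2, "%Y"))
    return(sign(y1 - y2))
  }
  sign(as.numeric(d1 - d2))
}

#' Resolve publication primacy per protein function
#'
#' For every (accession, function key) — the key being (category, term_id),
#' with term-less annotations keyed on their absent term — keeps the single
#' record citing the oldest publication; ties on date break on the smallest
#' publication id. Year-only dates sort at January 1st of their year. The
#' output ordering is a deterministic function of the record set, so any
#' permutation of the input yields the identical result; records lacking a
#' publication date are excluded with a warning.
#'
#' @param records A (typically [filter_positive_experimental()]-filtered)
#'   [evidence_records()] tibble.
#' @return Tibble of primacy records: `accession`, `category`, `term_id`,
#'   `term_label`, `first_pub_id`, `first_pub_date`, `date_granularity`.
#' @export
resolve_primacy <- function(records) {
  if (!nrow(records)) {
    return(tibble::tibble(
      accession = character(0), category = character(0),
      term_id = character(0), term_label = character(0),
      first_pub_id = character(0), first_pub_date = as.Date(character(0)),
      date_granularity = character(0)
    ))
  }
  n_missing <- sum(is.na(records$pub_date))
  if (n_missing > 0) {
    warning(sprintf("%d record(s) without publication date excluded from primacy resolution",
                    n_missing))
    records <- records[!is.na(records$pub_date), , drop = FALSE]
  }
  records |>
    dplyr::arrange(pub_date, accession, pub_id) |>
    dplyr::group_by(accession, category, term_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      accession, category, term_id, term_label,
      first_pub_id = pub_id,
      first_pub_date = pub_date,
      date_granularity
    ) |>
    dplyr::arrange(first_pub_date, accession, first_pub_id, category, term_id)
}

#' Convert primacy records back to evidence-record shape
#'
#' Useful for feeding resolved records through [resolve_primacy()] again
#' (idempotence) or into further filtering.
#'
#' @param primacy A [resolve_primacy()] tibble.
#' @return Tibble in [evidence_records()] column layout (experimental
#'   direct-assay kind, positive).
#' @export
primacy_as_records <- function(primacy) {
  tibble::tibble(
    accession = primacy$accession,
    category = primacy$category,
    term_id = primacy$term_id,
    term_label = primacy$term_label,
    evidence_kind = "direct-assay",
    is_negative = FALSE,
    pub_id = primacy$first_pub_id,
    pub_date = primacy$first_pub_date,
    date_granularity = primacy$date_granularity
  )
}

#' Classify the temporal order of binding vs. other functions
#'
#' Per protein, compares the earliest publication showing the designated
#' binding term with the earliest publication showing any other function:
#'
#' * `BINDING_ONLY` — only the binding function is on record;
#' * `OTHER_ONLY` — binding is absent;
#' * `SAME_PUBLICATION` — earliest binding and earliest other function
#'   share one publication;
#' * `BINDING_FIRST` — binding strictly precedes any other function, or the
#'   earliest dates are equal (at the available granularity) but the
#'   publications differ — an undecidable order resolved in favour of
#'   binding-first and logged;
#' * `BINDING_AFTER` — some other function strictly precedes binding.
#'
#' Year-only dates compare at year precision: a year-only date neither
#' strictly precedes nor follows a date in the same year.
#'
#' @param primacy A [resolve_primacy()] tibble.
#' @param binding_term Controlled term id designating protein binding.
#'   Term-less (free-text) annotations can never be the binding function.
#' @return Tibble `accession`, `class` (factor over
#'   [binding_sequence_classes()]); the accessions of date-tied proteins
#'   resolved to `BINDING_FIRST` are attached as attribute `date_ties`.
#' @export
classify_binding_sequence <- function(primacy, binding_term = BINDING_TERM_ID) {
  accs <- unique(primacy$accession)
  ties <- character(0)
  cls <- vapply(accs, function(acc) {
    rows <- primacy[primacy$accession == acc, , drop = FALSE]
    is_binding <- !is.na(rows$term_id) & rows$term_id == binding_term
    b <- rows[is_binding, , drop = FALSE]
    o <- rows[!is_binding, , drop = FALSE]
    if (!nrow(b)) return("OTHER_ONLY")
    if (!nrow(o)) return("BINDING_ONLY")
    b <- dplyr::arrange(b, first_pub_date, first_pub_id)[1, ]
    o_first <- dplyr::arrange(o, first_pub_date, first_pub_id)[1, ]
    cmps <- vapply(seq_len(nrow(o)), function(j) {
      compare_pub_dates(b$first_pub_date, b$date_granularity,
                        o$first_pub_date[j], o$date_granularity[j])
    }, numeric(1))
    if (any(cmps > 0)) return("BINDING_AFTER")
    earliest_equal <- o[cmps == 0, , drop = FALSE]
    if (nrow(earliest_equal) && b$first_pub_id %in% earliest_equal$first_pub_id) {
      return("SAME_PUBLICATION")
    }
    if (nrow(earliest_equal)) {
      ties <<- c(ties, acc)
    }
    "BINDING_FIRST"
  }, character(1))
  if (length(ties)) {
    message(sprintf(
      "%d protein(s) with equal earliest dates from different publications resolved as BINDING_FIRST",
      length(ties)
    ))
  }
  out <- tibble::tibble(
    accession = accs,
    class = factor(cls, levels = binding_sequence_classes())
  )
  attr(out, "date_ties") <- ties
  dplyr::arrange(out, accession)
}

#' Histogram of binding-sequence classes
#'
#' @param classes A [classify_binding_sequence()] tibble.
#' @return Tibble `class`, `n` with the five classes in canonical order.
#' @export
class_histogram <- function(classes) {
  counts <- table(classes$class)
  tibble::tibble(
    class = binding_sequence_classes(),
    n = as.integer(counts[binding_sequence_classes()])
  )
}

#' Per-publication and per-protein statistics
#'
#' Summarises the bipartite protein-publication graph induced by primacy
#' records: how many proteins a publication establishes functions for, how
#' many publications back one protein, and what fraction of proteins (and
#' of function records) involve the binding term.
#'
#' @param primacy A nonempty [resolve_primacy()] tibble.
#' @param binding_term Controlled term id designating protein binding.
#' @return List of class `ad_publication_stats`: `n_proteins`,
#'   `n_publications`, `mean_proteins_per_publication`,
#'   `n_single_protein_publications`, `mean_publications_per_protein`,
#'   `n_single_publication_proteins`, `binding_fraction_proteins`,
#'   `binding_fraction_records`.
#' @export
publication_stats <- function(primacy, binding_term = BINDING_TERM_ID) {
  if (!nrow(primacy)) stop("publication_stats: empty input")
  pairs <- unique(primacy[, c("accession", "first_pub_id")])
  per_pub <- table(pairs$first_pub_id)
  per_prot <- table(pairs$accession)
  has_binding <- !is.na(primacy$term_id) & primacy$term_id == binding_term
  structure(
    list(
      n_proteins = length(per_prot),
      n_publications = length(per_pub),
      mean_proteins_per_publication = nrow(pairs) / length(per_pub),
      n_single_protein_publications = sum(per_pub == 1),
      mean_publications_per_protein = nrow(pairs) / length(per_prot),
      n_single_publication_proteins = sum(per_prot == 1),
      binding_fraction_proteins =
        length(unique(primacy$accession[has_binding])) / length(per_prot),
      binding_fraction_records = sum(has_binding) / nrow(primacy)
    ),
    class = "ad_publication_stats"
  )
}

#' @export
print.ad_publication_stats <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<publication stats: %d proteins, %d publications>\n",
      "  proteins per publication (mean): %.2f (%d single-protein publications)\n",
      "  publications per protein (mean): %.2f (%d single-publication proteins)\n",
      "  binding fraction: %.1f%% of proteins, %.1f%% of function records\n"
    ),
    x$n_proteins, x$n_publications,
    x$mean_proteins_per_publication, x$n_single_protein_publications,
    x$mean_publications_per_protein, x$n_single_publication_proteins,
    100 * x$binding_fraction_proteins, 100 * x$binding_fraction_records
  ))
  invisible(x)
}
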