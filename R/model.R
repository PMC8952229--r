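# Domain model: releases, protein entries, function annotations, evidence.
#
# A release is one dated snapshot of the knowledgebase. Entries carry a
# protein-existence level (PE1 = existence shown at protein level, down to
# PE5 = dubious) and a list of function annotations; each annotation belongs
# to one of six curation categories, optionally carries a controlled
# vocabulary term, and is backed by evidence records pointing at dated
# publications.

#' Function-annotation categories
#'
#' The six curation categories a function annotation can belong to.
#'
#' @return Character vector of category names.
#' @export
annotation_categories <- function() {
  c(
    "catalytic-activity", "function-info", "go-biological-process",
    "go-molecular-function", "pathway", "transport-activity"
  )
}

#' Evidence kinds
#'
#' The recognised evidence kinds. Only `direct-assay` and
#' `physical-interaction` count as experimental; the remainder are
#' computational or curatorial.
#'
#' @return Character vector of evidence-kind names.
#' @export
evidence_kinds <- function() {
  c(
    "direct-assay", "physical-interaction", "sequence-similarity",
    "curator-inference", "author-statement"
  )
}

#' Experimental evidence kinds
#'
#' @return Character vector: the subset of [evidence_kinds()] that denote
#'   direct experimental support (direct assay, physical interaction).
#' @export
experimental_kinds <- function() {
  c("direct-assay", "physical-interaction")
}

#' Protein-existence levels
#'
#' @return Character vector `PE1`..`PE5`.
#' @export
existence_levels <- function() paste0("PE", 1:5)

#' Chromosome labels
#'
#' @return Character vector of valid chromosome labels: 1-22, X, Y, MT and
#'   `unknown`.
#' @export
chromosome_labels <- function() c(as.character(1:22), "X", "Y", "MT", "unknown")

#' Create a publication reference
#'
#' Publication dates come in two granularities: full calendar dates and
#' year-only dates (some source records state just the publication year,
#' which matters when resolving which publication came first).
#'
#' @param pub_id Nonempty publication identifier.
#' @param pub_date A `Date`. For year-only references, any date within the
#'   year; it is normalised to January 1st of that year.
#' @param year_only Logical; `TRUE` if only the publication year is known.
#' @return A list of class `ad_publication`.
#' @export
publication_ref <- function(pub_id, pub_date, year_only = FALSE) {
  stopifnot(is.character(pub_id), length(pub_id) == 1L, nzchar(pub_id))
  pub_date <- as.Date(pub_date)
  stopifnot(length(pub_date) == 1L, !is.na(pub_date))
  if (isTRUE(year_only)) {
    pub_date <- as.Date(sprintf("%04d-01-01", as.integer(format(pub_date, "%Y"))))
  }
  structure(
    list(pub_id = pub_id, pub_date = pub_date, year_only = isTRUE(year_only)),
    class = "ad_publication"
  )
}

#' Create an evidence record
#'
#' @param evidence_kind One of [evidence_kinds()].
#' @param is_negative Logical; `TRUE` when the evidence asserts the absence
#'   of the function rather than its presence. Negative evidence never
#'   counts toward "function present".
#' @param publication A [publication_ref()] or `NULL` when the evidence has
#'   no literature reference.
#' @return A list of class `ad_evidence`.
#' @export
evidence_record <- function(evidence_kind, is_negative = FALSE,
                            publication = NULL) {
  stopifnot(is.character(evidence_kind), length(evidence_kind) == 1L)
  stopifnot(is.null(publication) || inherits(publication, "ad_publication"))
  structure(
    list(
      evidence_kind = evidence_kind,
      is_negative = isTRUE(is_negative),
      publication = publication
    ),
    class = "ad_evidence"
  )
}

#' Create a function annotation
#'
#' @param category One of [annotation_categories()].
#' @param term_id Optional controlled-vocabulary identifier (`NA` for an
#'   uncontrolled annotation, e.g. free-text function descriptions).
#' @param term_label Optional human-readable label for the term.
#' @param evidences List of [evidence_record()]s.
#' @return A list of class `ad_annotation`.
#' @export
function_annotation <- function(category, term_id = NA_character_,
                                term_label = NA_character_,
                                evidences = list()) {
  structure(
    list(
      category = category,
      term_id = if (is.null(term_id)) NA_character_ else as.character(term_id),
      term_label = if (is.null(term_label)) NA_character_ else as.character(term_label),
      evidences = evidences
    ),
    class = "ad_annotation"
  )
}

#' Create a protein entry
#'
#' @param accession Stable protein identifier, unique within a release.
#' @param chromosome One of [chromosome_labels()].
#' @param existence_level One of [existence_levels()].
#' @param annotations List of [function_annotation()]s.
#' @return A list of class `ad_entry`.
#' @export
protein_entry <- function(accession, chromosome = "unknown",
                          existence_level = "PE1", annotations = list()) {
  structure(
    list(
      accession = accession,
      chromosome = chromosome,
      existence_level = existence_level,
      annotations = annotations
    ),
    class = "ad_entry"
  )
}

#' Create a release
#'
#' @param release_id Nonempty opaque release label.
#' @param release_date The release's calendar date (`Date` or parseable
#'   string).
#' @param entries List of [protein_entry()]s with unique accessions.
#' @return A list of class `ad_release` with elements `meta` (release_id,
#'   release_date) and `entries`.
#' @export
release <- function(release_id, release_date, entries = list()) {
  structure(
    list(
      meta = list(
        release_id = as.character(release_id),
        release_date = as.Date(release_date)
      ),
      entries = entries
    ),
    class = "ad_release"
  )
}

#' @export
print.ad_release <- function(x, ...) {
  n_ann <- sum(vapply(x$entries, function(e) length(e$annotations), integer(1)))
  cat(sprintf(
    "<release %s (%s): %d entries, %d function annotations>\n",
    x$meta$release_id, format(x$meta$release_date), length(x$entries), n_ann
  ))
  invisible(x)
}

#' Validate a release against the model invariants
#'
#' Checks every structural invariant of the domain model: nonempty release
#' id, valid release date, unique accessions, known chromosome labels,
#' valid existence levels, known annotation categories and evidence kinds,
#' well-formed publication references. Negative evidence is legal and
#' produces no violation.
#'
#' @param rel An `ad_release`.
#' @return Character vector of violation descriptions; empty when the
#'   release is valid. Each violation names the offending entry accession
#'   and the rule broken.
#' @export
validate_release <- function(rel) {
  stopifnot(inherits(rel, "ad_release"))
  bad <- character(0)
  if (!nzchar(rel$meta$release_id %||% "")) {
    bad <- c(bad, "release: release_id must be nonempty")
  }
  if (length(rel$meta$release_date) != 1L || is.na(rel$meta$release_date)) {
    bad <- c(bad, "release: release_date must be a valid date")
  }
  accs <- vapply(rel$entries, function(e) as.character(e$accession %||% ""), character(1))
  if (anyDuplicated(accs)) {
    dups <- unique(accs[duplicated(accs)])
    bad <- c(bad, sprintf("entry %s: duplicate accession", dups))
  }
  for (e in rel$entries) {
    acc <- as.character(e$accession %||% "")
    if (!nzchar(acc)) bad <- c(bad, "entry <missing>: accession must be nonempty")
    if (!e$chromosome %in% chromosome_labels()) {
      bad <- c(bad, sprintf("entry %s: invalid chromosome '%s'", acc, e$chromosome))
    }
    if (!e$existence_level %in% existence_levels()) {
      bad <- c(bad, sprintf("entry %s: invalid existence level '%s'", acc, e$existence_level))
    }
    for (a in e$annotations) {
      if (!a$category %in% annotation_categories()) {
        bad <- c(bad, sprintf(
          "entry %s: invalid annotation category '%s'", acc, a$category
        ))
      }
      for (ev in a$evidences) {
        if (!ev$evidence_kind %in% evidence_kinds()) {
          bad <- c(bad, sprintf(
            "entry %s: invalid evidence kind '%s'", acc, ev$evidence_kind
          ))
        }
        p <- ev$publication
        if (!is.null(p)) {
          if (!nzchar(p$pub_id %||% "")) {
            bad <- c(bad, sprintf("entry %s: publication id must be nonempty", acc))
          }
          if (length(p$pub_date) != 1L || is.na(p$pub_date)) {
            bad <- c(bad, sprintf("entry %s: publication date must be valid", acc))
          }
        }
      }
    }
  }
  bad
}

#' Validate a series of releases
#'
#' In addition to per-release validity, release dates must strictly
#' increase along the series.
#'
#' @param series List of `ad_release` objects, in chronological order.
#' @return Character vector of violations (empty when valid).
#' @export
validate_series <- function(series) {
  bad <- unlist(lapply(series, validate_release))
  dates <- as.Date(vapply(series, function(r) as.character(r$meta$release_date), character(1)))
  if (length(dates) > 1L && any(diff(dates) <= 0)) {
    bad <- c(bad, "series: release dates must strictly increase")
  }
  bad %||% character(0)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
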