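# Cross-release comparison: accession mapping to a reference release,
# PE1/function counts per release and chromosome, removed-function
# detection, and newly annotated proteins in a time window.
#
# "Annotated" throughout this module means >= 1 function annotation record
# of any category, irrespective of its evidence: release-level accounting
# deliberately precedes any evidence filtering, which belongs to the
# publication-primacy stage.

#' Flatten a release's entries to a table
#'
#' @param rel An `ad_release`.
#' @return Tibble with one row per entry: `accession`, `chromosome`,
#'   `existence_level`, `n_annotations`.
#' @export
entries_table <- function(rel) {
  stopifnot(inherits(rel, "ad_release"))
  tibble::tibble(
    accession = vapply(rel$entries, `[[`, character(1), "accession"),
    chromosome = vapply(rel$entries, `[[`, character(1), "chromosome"),
    existence_level = vapply(rel$entries, `[[`, character(1), "existence_level"),
    n_annotations = vapply(rel$entries, function(e) length(e$annotations), integer(1))
  )
}

#' Flatten a release's annotations to a table
#'
#' @param rel An `ad_release`.
#' @return Tibble with one row per annotation record: `accession`,
#'   `category`, `term_id`, `term_label`, `n_evidence`.
#' @export
annotations_table <- function(rel) {
  stopifnot(inherits(rel, "ad_release"))
  rows <- lapply(rel$entries, function(e) {
    if (!length(e$annotations)) return(NULL)
    tibble::tibble(
      accession = e$accession,
      category = vapply(e$annotations, `[[`, character(1), "category"),
      term_id = vapply(e$annotations, `[[`, character(1), "term_id"),
      term_label = vapply(e$annotations, `[[`, character(1), "term_label"),
      n_evidence = vapply(e$annotations, function(a) length(a$evidences), integer(1))
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble::tibble(
      accession = character(0), category = character(0),
      term_id = character(0), term_label = character(0),
      n_evidence = integer(0)
    ))
  }
  dplyr::bind_rows(rows)
}

# annotation identity used for presence/absence comparison across releases:
# (accession, category, term_id); an absent term_id is its own key
ann_keys <- function(rel) {
  tab <- annotations_table(rel)
  unique(paste(tab$accession, tab$category,
               ifelse(is.na(tab$term_id), "<none>", tab$term_id), sep = "\r"))
}

release_ids <- function(series) {
  vapply(series, function(r) r$meta$release_id, character(1))
}

release_dates <- function(series) {
  as.Date(vapply(series, function(r) as.character(r$meta$release_date), character(1)))
}

#' Map earlier releases onto a reference release
#'
#' Accession-identity mapping: shared accessions map to themselves;
#' accessions of earlier releases absent from the reference are reported
#' per release as unmapped, and conversely the reference accessions never
#' seen in earlier releases are reported as new. If an accession carries
#' conflicting chromosome labels across releases, the latest release wins
#' (logged via `message()`).
#'
#' @param series Date-sorted list of `ad_release`.
#' @param reference The reference release; defaults to the last (latest) of
#'   the series.
#' @return List with `mapping` (named character vector, identity on shared
#'   accessions), `unmapped` (named list: release_id -> accessions absent
#'   from the reference), and `new_in_reference` (reference accessions not
#'   present in any earlier release).
#' @export
map_to_reference <- function(series, reference = series[[length(series)]]) {
  stopifnot(length(series) >= 1)
  ref_accs <- entries_table(reference)$accession
  earlier <- Filter(function(r) !identical(r$meta$release_id, reference$meta$release_id), series)
  unmapped <- list()
  seen_earlier <- character(0)
  chrom_seen <- list()
  for (r in series) {
    tab <- entries_table(r)
    for (j in seq_len(nrow(tab))) {
      acc <- tab$accession[j]
      prev <- chrom_seen[[acc]]
      if (!is.null(prev) && !identical(prev, tab$chromosome[j])) {
        message(sprintf(
          "accession %s: chromosome label changed %s -> %s (latest release wins)",
          acc, prev, tab$chromosome[j]
        ))
      }
      chrom_seen[[acc]] <- tab$chromosome[j]
    }
  }
  for (r in earlier) {
    accs <- entries_table(r)$accession
    seen_earlier <- union(seen_earlier, accs)
    miss <- setdiff(accs, ref_accs)
    if (length(miss)) unmapped[[r$meta$release_id]] <- sort(miss)
  }
  shared <- intersect(union(seen_earlier, ref_accs), ref_accs)
  mapping <- stats::setNames(shared, shared)
  list(
    mapping = mapping,
    unmapped = unmapped,
    new_in_reference = sort(setdiff(ref_accs, seen_earlier))
  )
}

#' Count PE1 proteins and annotated PE1 proteins per release
#'
#' For each release: the number of PE1 entries (protein existence confirmed
#' at protein level) and the number of PE1 entries carrying at least one
#' function annotation of any category; plus the same counts broken down by
#' chromosome.
#'
#' @param series Nonempty date-sorted list of `ad_release`.
#' @return List with tibbles `per_release` (release_id, release_date,
#'   n_pe1, n_pe1_annotated) and `per_chromosome` (release_id, chromosome,
#'   n_pe1, n_pe1_annotated).
#' @export
count_functional_status <- function(series) {
  if (!length(series)) stop("empty release series")
  per_release <- dplyr::bind_rows(lapply(series, function(r) {
    tab <- entries_table(r)
    pe1 <- tab[tab$existence_level == "PE1", ]
    tibble::tibble(
      release_id = r$meta$release_id,
      release_date = r$meta$release_date,
      n_pe1 = nrow(pe1),
      n_pe1_annotated = sum(pe1$n_annotations > 0)
    )
  }))
  per_chromosome <- dplyr::bind_rows(lapply(series, function(r) {
    tab <- entries_table(r)
    pe1 <- tab[tab$existence_level == "PE1", , drop = FALSE]
    if (!nrow(pe1)) {
      return(tibble::tibble(
        release_id = character(0), chromosome = character(0),
        n_pe1 = integer(0), n_pe1_annotated = integer(0)
      ))
    }
    pe1 |>
      dplyr::group_by(chromosome) |>
      dplyr::summarise(
        n_pe1 = dplyr::n(),
        n_pe1_annotated = sum(n_annotations > 0),
        .groups = "drop"
      ) |>
      dplyr::mutate(release_id = r$meta$release_id, .before = 1)
  }))
  list(per_release = per_release, per_chromosome = per_chromosome)
}

#' Detect removed function annotations across a release series
#'
#' A removal case is an annotation key (accession, category, term_id;
#' term-less annotations keyed on their absent term) present in some
#' release and absent from a later one. Each key is reported once, at the
#' earliest release where it first goes absent after having been present;
#' re-addition after removal does not cancel the case.
#'
#' @param series Date-sorted list of at least 2 `ad_release`.
#' @return Tibble: `accession`, `category`, `term_id` (`NA` for term-less
#'   annotations), `release_present` (last release carrying the annotation
#'   before the removal), `release_absent` (first release missing it).
#' @export
detect_removed_functions <- function(series) {
  stopifnot(length(series) >= 2)
  ids <- release_ids(series)
  keysets <- lapply(series, ann_keys)
  all_keys <- unique(unlist(keysets))
  out <- list()
  for (key in all_keys) {
    present <- vapply(keysets, function(k) key %in% k, logical(1))
    f <- which(present)[1]
    absent_after <- which(!present & seq_along(present) > f)
    if (!length(absent_after)) next
    j <- absent_after[1]
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    out[[length(out) + 1L]] <- tibble::tibble(
      accession = parts[1],
      category = parts[2],
      term_id = if (parts[3] == "<none>") NA_character_ else parts[3],
      release_present = ids[j - 1L],
      release_absent = ids[j]
    )
  }
  if (!length(out)) {
    return(tibble::tibble(
      accession = character(0), category = character(0),
      term_id = character(0), release_present = character(0),
      release_absent = character(0)
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), accession, category, term_id)
}

#' Proteins newly annotated within a window
#'
#' An accession qualifies when a run of "has at least one function
#' annotation" starts at a release dated inside `[window_start,
#' window_end]` — either its very first annotation appears there, or all
#' its annotations had been removed and annotation reappears inside the
#' window.
#'
#' @param series Date-sorted list of `ad_release`.
#' @param window_start,window_end Window bounds (`Date` or parseable);
#'   must lie within the series' date span.
#' @return Sorted character vector of accessions.
#' @export
newly_annotated <- function(series, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  dates <- release_dates(series)
  if (window_end < window_start) stop("window_end precedes window_start")
  if (window_end < dates[1] || window_start > dates[length(dates)]) {
    stop(sprintf(
      "window [%s, %s] lies outside the series span [%s, %s]",
      window_start, window_end, dates[1], dates[length(dates)]
    ))
  }
  tabs <- lapply(series, entries_table)
  all_accs <- unique(unlist(lapply(tabs, `[[`, "accession")))
  hits <- character(0)
  for (acc in all_accs) {
    annotated <- vapply(seq_along(series), function(i) {
      tab <- tabs[[i]]
      any(tab$accession == acc & tab$n_annotations > 0)
    }, logical(1))
    if (!any(annotated)) next
    run_starts <- which(annotated & !c(FALSE, annotated[-length(annotated)]))
    if (any(dates[run_starts] >= window_start & dates[run_starts] <= window_end)) {
      hits <- c(hits, acc)
    }
  }
  sort(hits)
}

#' Accessions never carrying any function annotation
#'
#' @param series Date-sorted list of `ad_release`.
#' @return Sorted character vector of accessions that have zero function
#'   annotations in every release they appear in.
#' @export
never_annotated <- function(series) {
  tabs <- lapply(series, entries_table)
  all_tab <- dplyr::bind_rows(tabs)
  agg <- all_tab |>
    dplyr::group_by(accession) |>
    dplyr::summarise(total = sum(n_annotations), .groups = "drop")
  sort(agg$accession[agg$total == 0])
}

#' Full cross-release diff report
#'
#' Bundles per-release and per-chromosome PE1/annotated counts, removal
#' cases, never-annotated accessions and the reference mapping into one
#' report.
#'
#' @param series Date-sorted list of at least 2 `ad_release`.
#' @return List of class `ad_diff_report` with elements `per_release`,
#'   `per_chromosome`, `removed_function_cases`, `never_annotated`,
#'   `unmapped_accessions`, `new_in_reference`.
#' @export
diff_report <- function(series) {
  stopifnot(length(series) >= 2)
  counts <- count_functional_status(series)
  mapping <- map_to_reference(series)
  structure(
    list(
      per_release = counts$per_release,
      per_chromosome = counts$per_chromosome,
      removed_function_cases = detect_removed_functions(series),
      never_annotated = never_annotated(series),
      unmapped_accessions = mapping$unmapped,
      new_in_reference = mapping$new_in_reference
    ),
    class = "ad_diff_report"
  )
}
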