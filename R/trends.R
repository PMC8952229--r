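# Controlled-term frequency accounting across a release series, the
# recent-vs-lifetime trend partition, and min-max scaling of term
# frequencies for tag-cloud export.
#
# Frequencies count distinct proteins first annotated with a term (not raw
# annotation records): the object of interest is the per-protein function
# profile, and one protein re-annotated with the same term in several
# categories or releases is still one protein.

#' Term frequencies over a release series
#'
#' Only annotations bearing a controlled term are counted (term-less
#' records are skipped). A protein counts toward a term at its first
#' appearance: the earliest release in which the (accession, term) pair is
#' present. `lifetime_count` counts all first appearances; `window_count`
#' those whose first-appearance release date falls inside the window.
#' Rates are per year, over the series' date span and the window span
#' respectively (spans are floored at one day).
#'
#' @param series Date-sorted list of `ad_release`.
#' @param window_start,window_end Recent-window bounds (`Date` or parseable).
#' @return Tibble: `term_id`, `term_label`, `lifetime_count`,
#'   `window_count`, `lifetime_rate`, `window_rate`.
#' @export
term_frequencies <- function(series, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  stopifnot(length(series) >= 1, window_start <= window_end)
  dates <- release_dates(series)

  per_release <- lapply(seq_along(series), function(i) {
    tab <- annotations_table(series[[i]])
    tab <- tab[!is.na(tab$term_id), c("accession", "term_id", "term_label")]
    if (!nrow(tab)) return(NULL)
    tab$release_index <- i
    unique(tab)
  })
  per_release <- per_release[!vapply(per_release, is.null, logical(1))]
  if (!length(per_release)) {
    return(tibble::tibble(
      term_id = character(0), term_label = character(0),
      lifetime_count = integer(0), window_count = integer(0),
      lifetime_rate = numeric(0), window_rate = numeric(0)
    ))
  }
  flat <- dplyr::bind_rows(per_release)
  firsts <- flat |>
    dplyr::group_by(accession, term_id) |>
    dplyr::summarise(
      term_label = term_label[which.min(release_index)],
      first_index = min(release_index),
      .groups = "drop"
    ) |>
    dplyr::mutate(first_date = dates[first_index])

  span_years <- max(as.numeric(dates[length(dates)] - dates[1]), 1) / 365.25
  window_years <- max(as.numeric(window_end - window_start), 1) / 365.25

  firsts |>
    dplyr::group_by(term_id) |>
    dplyr::summarise(
      term_label = term_label[1],
      lifetime_count = dplyr::n(),
      window_count = sum(first_date >= window_start & first_date <= window_end),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lifetime_rate = lifetime_count / span_years,
      window_rate = window_count / window_years
    ) |>
    dplyr::arrange(dplyr::desc(lifetime_count), term_id)
}

#' Min-max scale term frequencies for a tag cloud
#'
#' Scales raw term frequencies x onto scores
#' x' = 1 + 19 (x - xmin) / (xmax - xmin), i.e. onto the interval 1-20,
#' after removing excluded labels (by default "protein binding", which in
#' curated corpora dwarfs every other term and carries little functional
#' information). xmin and xmax are computed after the exclusion. When all
#' remaining frequencies are equal the scaling is degenerate and every
#' score is 1, the bottom of the range.
#'
#' @param table A [term_frequencies()] tibble.
#' @param exclude_labels Character vector of term labels to drop before
#'   scaling.
#' @param freq Which frequency column to scale: `"window"` (default; the
#'   recent-cohort frequencies a tag cloud of newly annotated proteins
#'   shows) or `"lifetime"`.
#' @return Tibble (`term_id`, `term_label`, `frequency`, `scaled_score`),
#'   sorted by descending score; errors if no term survives the exclusion.
#' @export
scale_for_cloud <- function(table, exclude_labels = "protein binding",
                            freq = c("window", "lifetime")) {
  freq <- match.arg(freq)
  col <- if (freq == "window") "window_count" else "lifetime_count"
  keep <- table[!(table$term_label %in% exclude_labels), , drop = FALSE]
  if (!nrow(keep)) stop("no terms left after exclusion; cannot scale")
  x <- as.numeric(keep[[col]])
  xmin <- min(x)
  xmax <- max(x)
  score <- if (xmax > xmin) 1 + 19 * (x - xmin) / (xmax - xmin) else rep(1, length(x))
  tibble::tibble(
    term_id = keep$term_id,
    term_label = keep$term_label,
    frequency = x,
    scaled_score = score
  ) |>
    dplyr::arrange(dplyr::desc(scaled_score), term_label)
}

#' Partition terms into recently more/less frequently detected subsets
#'
#' Compares each term's detection rate inside the recent window with its
#' lifetime rate. Terms with `lifetime_count >= min_count` are eligible;
#' an eligible term is `more_frequent` when `window_rate / lifetime_rate >=
#' r_hi` (boundary inclusive), `less_frequent` when the ratio `<= r_lo`,
#' otherwise `stable`. A term with zero lifetime rate (no eligible span)
#' goes to `more_frequent` iff its `window_count >= min_count`.
#'
#' @param table A [term_frequencies()] tibble.
#' @param r_hi Ratio at or above which a term counts as more frequently
#'   detected (> 1).
#' @param r_lo Ratio at or below which a term counts as less frequently
#'   detected (in (0, 1)).
#' @param min_count Minimum lifetime count for a term to be classified.
#' @return List of class `ad_trend_partition`: `more_frequent`,
#'   `less_frequent`, `stable` (character vectors of term_ids, disjoint,
#'   covering all eligible terms), `table` (eligible rows with `ratio` and
#'   `trend`), and `thresholds`.
#' @export
trend_partition <- function(table, r_hi = 1.5, r_lo = 0.67, min_count = 5L) {
  stopifnot(r_hi > 1, r_lo > 0, r_lo < 1, min_count >= 1)
  eligible <- table[table$lifetime_count >= min_count, , drop = FALSE]
  ratio <- ifelse(eligible$lifetime_rate > 0,
                  eligible$window_rate / eligible$lifetime_rate, NA_real_)
  trend <- character(nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    if (is.na(ratio[i])) {
      trend[i] <- if (eligible$window_count[i] >= min_count) "more_frequent" else "stable"
    } else if (ratio[i] >= r_hi) {
      trend[i] <- "more_frequent"
    } else if (ratio[i] <= r_lo) {
      trend[i] <- "less_frequent"
    } else {
      trend[i] <- "stable"
    }
  }
  eligible$ratio <- ratio
  eligible$trend <- trend
  structure(
    list(
      more_frequent = eligible$term_id[trend == "more_frequent"],
      less_frequent = eligible$term_id[trend == "less_frequent"],
      stable = eligible$term_id[trend == "stable"],
      table = eligible,
      thresholds = list(r_hi = r_hi, r_lo = r_lo, min_count = min_count)
    ),
    class = "ad_trend_partition"
  )
}
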