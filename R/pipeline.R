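# End-to-end orchestration: (generate | read) -> diff -> trends -> primacy,
# with a declarative config and a reproducible report bundle on disk.
# Rerunning with the same config and seed reproduces the bundle
# byte-for-byte (the manifest records a config hash, not a timestamp).

#' Build a pipeline configuration
#'
#' Either `release_paths` (existing release XML files) or `generator`
#' (arguments for [series_config()]) must be given; with both, the files
#' win.
#'
#' @param release_paths Character vector of release XML files, or `NULL`.
#' @param generator Named list of [series_config()] arguments, or `NULL`.
#' @param window_start,window_end Analysis window (recent period) for
#'   trends and primacy.
#' @param r_hi,r_lo,min_count Trend-partition thresholds, see
#'   [trend_partition()].
#' @param exclude_labels Labels excluded from the tag cloud.
#' @param binding_term Controlled term id designating protein binding.
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed forwarded to the generator.
#' @return List of class `ad_pipeline_config`.
#' @export
pipeline_config <- function(release_paths = NULL,
                            generator = NULL,
                            window_start = "2016-01-01",
                            window_end = "2021-01-15",
                            r_hi = 1.5, r_lo = 0.67, min_count = 5L,
                            exclude_labels = "protein binding",
                            binding_term = "GO:0005515",
                            out_dir = "annodrift-report",
                            seed = 1L) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (!(window_start < window_end)) {
    stop("window_start must precede window_end")
  }
  if (is.null(release_paths) && is.null(generator)) {
    stop("either release_paths or generator must be configured")
  }
  structure(
    list(
      release_paths = release_paths,
      generator = generator,
      window_start = window_start,
      window_end = window_end,
      r_hi = r_hi, r_lo = r_lo, min_count = as.integer(min_count),
      exclude_labels = exclude_labels,
      binding_term = binding_term,
      out_dir = out_dir,
      seed = as.integer(seed)
    ),
    class = "ad_pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return An `ad_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: obtain the release series (from files or the seeded generator),
#' cross-release diff, term-frequency trends plus tag-cloud scaling, and
#' evidence filtering / primacy resolution / binding-sequence
#' classification on the latest release. Writes the report bundle under
#' `config$out_dir`:
#'
#' * `diff_report.json`, `per_release_counts.tsv`, `removal_cases.tsv`
#' * `trend_terms.tsv`, `cloud.tsv`
#' * `class_histogram.tsv`, `publication_stats.json`
#' * `manifest.json` (package version, seed, config hash, file list)
#'
#' @param config An `ad_pipeline_config` or the path to a YAML config file.
#' @return Invisibly, a list with the in-memory results (`series`, `diff`,
#'   `trends`, `cloud`, `partition`, `classes`, `stats`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "ad_pipeline_config"))

  if (!is.null(config$release_paths)) {
    series <- read_series(config$release_paths)
  } else {
    gen_args <- config$generator
    gen_args$seed <- config$seed
    series <- generate_series(do.call(series_config, gen_args))$releases
  }
  dates <- release_dates(series)
  if (config$window_end < dates[1] || config$window_start > dates[length(dates)]) {
    stop(sprintf(
      "analysis window [%s, %s] lies outside the release span [%s, %s]",
      config$window_start, config$window_end, dates[1], dates[length(dates)]
    ))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # --- diff ---------------------------------------------------------------
  diff <- diff_report(series)
  paths$diff_report <- file.path(config$out_dir, "diff_report.json")
  write_json_report(
    list(
      per_release = diff$per_release,
      per_chromosome = diff$per_chromosome,
      removed_function_cases = diff$removed_function_cases,
      n_removed_function_cases = nrow(diff$removed_function_cases),
      never_annotated = diff$never_annotated,
      unmapped_accessions = diff$unmapped_accessions,
      new_in_reference = diff$new_in_reference
    ),
    paths$diff_report
  )
  paths$per_release_counts <- file.path(config$out_dir, "per_release_counts.tsv")
  readr::write_tsv(diff$per_release, paths$per_release_counts, progress = FALSE)
  paths$removal_cases <- file.path(config$out_dir, "removal_cases.tsv")
  readr::write_tsv(diff$removed_function_cases, paths$removal_cases, progress = FALSE)

  # --- trends -------------------------------------------------------------
  freq <- term_frequencies(series, config$window_start, config$window_end)
  partition <- trend_partition(freq, config$r_hi, config$r_lo, config$min_count)
  paths$trend_terms <- file.path(config$out_dir, "trend_terms.tsv")
  readr::write_tsv(partition$table, paths$trend_terms, progress = FALSE)
  cloud <- scale_for_cloud(freq, exclude_labels = config$exclude_labels)
  paths$cloud <- file.path(config$out_dir, "cloud.tsv")
  readr::write_tsv(cloud, paths$cloud, progress = FALSE)

  # --- primacy ------------------------------------------------------------
  reference <- series[[length(series)]]
  records <- evidence_records(reference)
  kept <- filter_positive_experimental(records, config$window_start, config$window_end)
  primacy <- resolve_primacy(kept)
  classes <- classify_binding_sequence(primacy, config$binding_term)
  hist <- class_histogram(classes)
  paths$class_histogram <- file.path(config$out_dir, "class_histogram.tsv")
  readr::write_tsv(hist, paths$class_histogram, progress = FALSE)
  stats <- if (nrow(primacy)) publication_stats(primacy, config$binding_term) else NULL
  paths$publication_stats <- file.path(config$out_dir, "publication_stats.json")
  write_json_report(
    c(
      unclass(stats),
      list(n_classified = nrow(classes), n_eligible_records = nrow(kept))
    ),
    paths$publication_stats
  )

  # --- manifest -----------------------------------------------------------
  cfg_for_hash <- unclass(config)
  cfg_for_hash$window_start <- format(config$window_start)
  cfg_for_hash$window_end <- format(config$window_end)
  manifest <- list(
    package = "annodrift",
    version = as.character(utils::packageVersion("annodrift")),
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    files = sort(basename(unlist(paths)))
  )
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  write_json_report(manifest, paths$manifest)

  invisible(list(
    series = series, diff = diff, trends = freq, cloud = cloud,
    partition = partition, classes = classes, stats = stats, paths = paths
  ))
}
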