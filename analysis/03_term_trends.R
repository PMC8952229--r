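#!/usr/bin/env Rscript
# Stage 3: controlled-term frequencies, recent-vs-lifetime trend partition,
# and the tag-cloud export.
#
# Frequencies count distinct proteins first annotated with each controlled
# term; the dominant, uninformative "protein binding" label is excluded
# from the cloud before min-max scaling onto [1, 20].

suppressMessages(library(annodrift))

in_dir <- "results/releases"
out_dir <- "results/trends"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

series <- read_series(list.files(in_dir, pattern = "^r\\d{4}\\.xml$", full.names = TRUE))
window <- c("2016-01-01", "2021-01-15")

freq <- term_frequencies(series, window[1], window[2])
part <- trend_partition(freq, r_hi = 1.5, r_lo = 0.67, min_count = 5)
cloud <- scale_for_cloud(freq, exclude_labels = "protein binding")

readr::write_tsv(part$table, file.path(out_dir, "trend_terms.tsv"))
readr::write_tsv(cloud, file.path(out_dir, "cloud.tsv"))

cat(sprintf("%d controlled terms; %d eligible for trend classification (min lifetime count %d)\n",
            nrow(freq), nrow(part$table), part$thresholds$min_count))
cat(sprintf("more frequently detected recently: %d terms\n", length(part$more_frequent)))
for (t in part$more_frequent) {
  cat(sprintf("  + %s\n", freq$term_label[freq$term_id == t]))
}
cat(sprintf("less frequently detected recently: %d terms\n", length(part$less_frequent)))
for (t in part$less_frequent) {
  cat(sprintf("  - %s\n", freq$term_label[freq$term_id == t]))
}
cat(sprintf("cloud: %d terms scaled onto [%.1f, %.1f]\n",
            nrow(cloud), min(cloud$scaled_score), max(cloud$scaled_score)))
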