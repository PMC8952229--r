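#!/usr/bin/env Rscript
# Stage 2: cross-release comparison.
#
# How did the PE1 inventory and its functional coverage grow, which
# annotations were removed by curation, and which proteins were newly
# annotated during the recent window?

suppressMessages(library(annodrift))

in_dir <- "results/releases"
out_dir <- "results/diff"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

series <- read_series(list.files(in_dir, pattern = "^r\\d{4}\\.xml$", full.names = TRUE))
rep <- diff_report(series)

readr::write_tsv(rep$per_release, file.path(out_dir, "per_release_counts.tsv"))
readr::write_tsv(rep$per_chromosome, file.path(out_dir, "per_chromosome_counts.tsv"))
readr::write_tsv(rep$removed_function_cases, file.path(out_dir, "removal_cases.tsv"))

first <- rep$per_release[1, ]
last <- rep$per_release[nrow(rep$per_release), ]
cat(sprintf("PE1 proteins: %d (%s) -> %d (%s)\n",
            first$n_pe1, first$release_id, last$n_pe1, last$release_id))
cat(sprintf("PE1 proteins with a known function: %d -> %d (+%.0f%%)\n",
            first$n_pe1_annotated, last$n_pe1_annotated,
            100 * (last$n_pe1_annotated / first$n_pe1_annotated - 1)))
cat(sprintf("function-removal cases (presence-then-absence): %d\n",
            nrow(rep$removed_function_cases)))
cat(sprintf("PE1 proteins still without any function annotation: %d\n",
            length(intersect(rep$never_annotated,
                             entries_table(series[[length(series)]])$accession))))

window <- c("2016-01-01", "2021-01-15")
newly <- newly_annotated(series, window[1], window[2])
writeLines(newly, file.path(out_dir, "newly_annotated_accessions.txt"))
cat(sprintf("proteins newly annotated in [%s, %s]: %d\n",
            window[1], window[2], length(newly)))
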