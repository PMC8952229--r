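# Cross-release diffing: reference mapping, PE1/function counts,
# removed-function detection, newly annotated proteins.

test_that("map_to_reference is identity on persisting accessions", {
  series <- tiny_series()
  m <- map_to_reference(series)
  expect_identical(unname(m$mapping), names(m$mapping))
  expect_length(m$unmapped, 0)
  expect_equal(m$new_in_reference, character(0))
  # single-release series: identity, nothing unmapped
  m1 <- map_to_reference(series[3])
  expect_equal(sort(names(m1$mapping)), c("P1", "P2", "P3", "P4"))
  expect_length(m1$unmapped, 0)
})

test_that("accessions retired before the reference are reported as unmapped", {
  r1 <- release("r1", "2015-01-01", list(
    protein_entry("KEEP1", "1", "PE1"),
    protein_entry("GONE1", "2", "PE1"),
    protein_entry("GONE2", "3", "PE1"),
    protein_entry("GONE3", "4", "PE1")
  ))
  r2 <- release("r2", "2016-01-01", list(
    protein_entry("KEEP1", "1", "PE1"),
    protein_entry("NEW1", "5", "PE1")
  ))
  m <- map_to_reference(list(r1, r2))
  expect_equal(m$unmapped, list(r1 = c("GONE1", "GONE2", "GONE3")))
  expect_equal(m$new_in_reference, "NEW1")
})

test_that("PE1 and annotated-PE1 counts follow the construction", {
  entries <- c(
    lapply(1:5, function(i) {
      protein_entry(sprintf("A%02d", i), "1", "PE1", list(
        function_annotation("pathway", "GO:0016055", "Wnt signaling pathway")
      ))
    }),
    lapply(6:10, function(i) protein_entry(sprintf("A%02d", i), "2", "PE1")),
    # a PE2 entry with annotations is excluded from both counts
    list(protein_entry("B01", "3", "PE2", list(
      function_annotation("pathway", "GO:0000165", "MAPK cascade")
    )))
  )
  r <- release("r1", "2015-01-01", entries)
  counts <- count_functional_status(list(r))
  expect_equal(counts$per_release$n_pe1, 10)
  expect_equal(counts$per_release$n_pe1_annotated, 5)
  per_chr <- counts$per_chromosome
  expect_false("3" %in% per_chr$chromosome)
  expect_equal(per_chr$n_pe1[per_chr$chromosome == "1"], 5)
  expect_error(count_functional_status(list()), "empty")
})

test_that("per-release counts equal an independent replay of the emission log", {
  g <- generate_series(series_config(n_proteins = 40, n_releases = 5, seed = 17))
  counts <- count_functional_status(g$releases)$per_release
  prot <- g$log$proteins
  ann <- g$log$annotations
  for (i in seq_along(g$releases)) {
    pe1 <- prot[prot$existence_level == "PE1" & prot$intro_index <= i, ]
    expect_equal(counts$n_pe1[i], nrow(pe1))
    live <- ann[ann$created_index <= i &
                  (is.na(ann$removed_index) | ann$removed_index > i), ]
    expect_equal(counts$n_pe1_annotated[i],
                 sum(pe1$accession %in% live$accession))
  }
})

test_that("annotated counts are nondecreasing when nothing is removed", {
  g <- generate_series(series_config(n_proteins = 60, n_releases = 8,
                                     removal_count = 0, seed = 23))
  counts <- count_functional_status(g$releases)$per_release
  expect_true(all(diff(counts$n_pe1_annotated) >= 0))
})

test_that("removed-function detection matches the generator's ground truth", {
  g0 <- generate_series(series_config(n_proteins = 40, n_releases = 5,
                                      removal_count = 0, seed = 31))
  expect_equal(nrow(detect_removed_functions(g0$releases)), 0)

  g <- generate_series(series_config(n_proteins = 40, n_releases = 5,
                                     removal_count = 5, seed = 37))
  cases <- detect_removed_functions(g$releases)
  expect_equal(nrow(cases), 5)
  want <- g$log$removals
  ids <- vapply(g$releases, function(r) r$meta$release_id, character(1))
  key <- function(acc, cat, tid) paste(acc, cat, ifelse(is.na(tid), "-", tid))
  expect_setequal(
    key(cases$accession, cases$category, cases$term_id),
    key(want$accession, want$category, want$term_id)
  )
  # the first release missing the annotation is the logged removal release
  m <- merge(cases, want, by = c("accession", "category"))
  expect_true(all(m$release_absent == ids[m$removed_index]))
})

test_that("an annotation removed and re-added yields exactly one case", {
  ann <- function_annotation("pathway", "GO:0016055", "Wnt signaling pathway")
  mk <- function(id, date, with_ann) {
    release(id, date, list(
      protein_entry("P1", "1", "PE1", if (with_ann) list(ann) else list())
    ))
  }
  series <- list(
    mk("r1", "2014-01-01", TRUE), mk("r2", "2015-01-01", FALSE),
    mk("r3", "2016-01-01", TRUE), mk("r4", "2017-01-01", FALSE)
  )
  cases <- detect_removed_functions(series)
  expect_equal(nrow(cases), 1)
  expect_equal(cases$release_present, "r1")
  expect_equal(cases$release_absent, "r2")
})

test_that("removed-function detection agrees with the brute-force presence-matrix oracle", {
  for (seed in 1:8) {
    cfg <- series_config(
      n_proteins = 30, n_releases = 4,
      removal_count = seed %% 4, seed = 100 + seed
    )
    g <- generate_series(cfg)
    got <- as.data.frame(detect_removed_functions(g$releases))
    want <- oracle_removed_functions(g$releases)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("newly annotated proteins are those whose annotation runs start in the window", {
  series <- tiny_series()
  # P1 annotated since r1 (2015) -> outside a 2016+ window; P2's annotation
  # run starts at r2 (2016); P4's at r3 (2017)
  expect_equal(newly_annotated(series, "2015-06-01", "2017-06-01"), c("P2", "P4"))
  expect_equal(newly_annotated(series, "2016-06-01", "2017-06-01"), "P4")
  expect_error(newly_annotated(series, "2020-01-01", "2021-01-01"), "outside")

  # fully removed then re-annotated inside the window counts
  ann <- function_annotation("pathway", "GO:0016055", "Wnt signaling pathway")
  mk <- function(id, date, with_ann) {
    release(id, date, list(
      protein_entry("P1", "1", "PE1", if (with_ann) list(ann) else list())
    ))
  }
  reappear <- list(
    mk("r1", "2014-01-01", TRUE), mk("r2", "2015-01-01", FALSE),
    mk("r3", "2016-06-01", TRUE)
  )
  expect_equal(newly_annotated(reappear, "2016-01-01", "2017-01-01"), "P1")
})

test_that("never-annotated, first-release-annotated and newly annotated partition PE1 accessions", {
  g <- generate_series(series_config(n_proteins = 50, n_releases = 6,
                                     removal_count = 0, seed = 41))
  series <- g$releases
  dates <- vapply(series, function(r) as.character(r$meta$release_date), character(1))
  ref <- entries_table(series[[length(series)]])
  pe1 <- ref$accession[ref$existence_level == "PE1"]

  first_tab <- entries_table(series[[1]])
  at_first <- first_tab$accession[first_tab$n_annotations > 0]
  post_first <- newly_annotated(series, as.Date(dates[1]) + 1, dates[length(dates)])
  never <- never_annotated(series)

  expect_length(intersect(at_first, post_first), 0)
  expect_length(intersect(never, c(at_first, post_first)), 0)
  expect_setequal(pe1, intersect(union(union(at_first, post_first), never), pe1))
})

test_that("diff_report bundles all components coherently", {
  g <- generate_series(series_config(n_proteins = 30, n_releases = 4, seed = 43))
  rep <- diff_report(g$releases)
  expect_s3_class(rep, "ad_diff_report")
  expect_equal(nrow(rep$per_release), 4)
  expect_true(all(rep$per_release$n_pe1_annotated <= rep$per_release$n_pe1))
})
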