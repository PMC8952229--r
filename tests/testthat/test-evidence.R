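# Evidence filtering, primacy resolution, binding-sequence classification,
# publication statistics.

mk_record <- function(accession = "P1", category = "go-molecular-function",
                      term_id = "GO:0005515", term_label = "protein binding",
                      kind = "direct-assay", negative = FALSE,
                      pub_id = "PUB1", pub_date = "2017-05-01",
                      granularity = "day") {
  tibble::tibble(
    accession = accession, category = category,
    term_id = term_id, term_label = term_label,
    evidence_kind = kind, is_negative = negative,
    pub_id = pub_id,
    pub_date = as.Date(pub_date),
    date_granularity = granularity
  )
}

test_that("the positive-experimental filter keeps exactly the eligible records", {
  allneg <- dplyr::bind_rows(
    mk_record(negative = TRUE),
    mk_record(pub_id = "PUB2", negative = TRUE)
  )
  expect_equal(nrow(filter_positive_experimental(allneg, "2016-01-01", "2021-12-31")), 0)

  recs <- dplyr::bind_rows(
    mk_record(pub_id = "A"),                                    # kept
    mk_record(pub_id = "B", kind = "physical-interaction"),     # kept
    mk_record(pub_id = "C", negative = TRUE),                   # negative
    mk_record(pub_id = "D", kind = "sequence-similarity"),      # not experimental
    mk_record(pub_id = "E", kind = "author-statement"),         # not experimental
    mk_record(pub_id = "F", pub_date = "2013-01-01")            # outside window
  )
  kept <- filter_positive_experimental(recs, "2016-01-01", "2021-12-31")
  expect_equal(sort(kept$pub_id), c("A", "B"))
})

test_that("year-only dates pass the window filter when the year intersects it", {
  recs <- dplyr::bind_rows(
    mk_record(pub_id = "Y1", pub_date = "2016-01-01", granularity = "year"),
    mk_record(pub_id = "Y2", pub_date = "2015-01-01", granularity = "year")
  )
  # window starts mid-2016: the 2016 year-only publication still intersects
  kept <- filter_positive_experimental(recs, "2016-06-01", "2021-12-31")
  expect_equal(kept$pub_id, "Y1")
})

test_that("records without a publication are dropped by the filter", {
  rec <- mk_record()
  rec$pub_id <- NA_character_; rec$pub_date <- as.Date(NA); rec$date_granularity <- NA_character_
  expect_equal(nrow(filter_positive_experimental(rec, "2016-01-01", "2021-12-31")), 0)
})

test_that("primacy keeps the oldest publication per protein function", {
  one <- mk_record()
  pr <- resolve_primacy(one)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$first_pub_id, "PUB1")

  two <- dplyr::bind_rows(
    mk_record(pub_id = "NEW", pub_date = "2019-03-01"),
    mk_record(pub_id = "OLD", pub_date = "2017-03-01")
  )
  pr <- resolve_primacy(two)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$first_pub_id, "OLD")

  # date ties break on the smallest publication id
  tie <- dplyr::bind_rows(
    mk_record(pub_id = "PUBZ", pub_date = "2017-03-01"),
    mk_record(pub_id = "PUBA", pub_date = "2017-03-01")
  )
  expect_equal(resolve_primacy(tie)$first_pub_id, "PUBA")
})

test_that("primacy output is invariant under input permutation and idempotent", {
  fx <- generate_sequencing_fixture(
    sequencing_scenario_config(
      c(SAME_PUBLICATION = 10L, BINDING_FIRST = 10L, BINDING_AFTER = 10L,
        OTHER_ONLY = 10L, BINDING_ONLY = 10L),
      date_spacing = 7
    ),
    seed = 5
  )
  recs <- filter_positive_experimental(
    evidence_records(fx$release), "2016-01-01", "2021-12-31"
  )
  base <- resolve_primacy(recs)
  for (seed in 1:5) {
    shuffled <- withr::with_seed(seed, recs[sample.int(nrow(recs)), ])
    expect_identical(resolve_primacy(shuffled), base)
  }
  expect_identical(resolve_primacy(primacy_as_records(base)), base)
})

test_that("records lacking a publication date are excluded with a warning", {
  rec <- dplyr::bind_rows(mk_record(), mk_record(pub_id = "X"))
  rec$pub_date[2] <- NA
  expect_warning(pr <- resolve_primacy(rec), "without publication date")
  expect_equal(nrow(pr), 1)
})

test_that("the classifier applies the five temporal-order rules", {
  # binding 2017, kinase activity 2019 -> binding first
  pr <- resolve_primacy(dplyr::bind_rows(
    mk_record(pub_id = "P-B", pub_date = "2017-02-01"),
    mk_record(term_id = "GO:0004674", term_label = "kinase", pub_id = "P-K",
              pub_date = "2019-02-01")
  ))
  cl <- classify_binding_sequence(pr)
  expect_equal(as.character(cl$class), "BINDING_FIRST")

  # both functions citing one publication -> same publication
  pr <- resolve_primacy(dplyr::bind_rows(
    mk_record(pub_id = "SHARED"),
    mk_record(term_id = "GO:0004674", term_label = "kinase", pub_id = "SHARED")
  ))
  expect_equal(as.character(classify_binding_sequence(pr)$class), "SAME_PUBLICATION")

  # only binding / no binding
  expect_equal(
    as.character(classify_binding_sequence(resolve_primacy(mk_record()))$class),
    "BINDING_ONLY"
  )
  expect_equal(
    as.character(classify_binding_sequence(resolve_primacy(
      mk_record(term_id = "GO:0004674", term_label = "kinase")
    ))$class),
    "OTHER_ONLY"
  )

  # other function strictly first -> binding after
  pr <- resolve_primacy(dplyr::bind_rows(
    mk_record(pub_id = "P-B", pub_date = "2019-02-01"),
    mk_record(term_id = "GO:0004674", term_label = "kinase", pub_id = "P-K",
              pub_date = "2017-02-01")
  ))
  expect_equal(as.character(classify_binding_sequence(pr)$class), "BINDING_AFTER")
})

test_that("equal earliest dates from different publications resolve to binding-first", {
  pr <- resolve_primacy(dplyr::bind_rows(
    mk_record(pub_id = "P-B", pub_date = "2017-02-01"),
    mk_record(term_id = "GO:0004674", term_label = "kinase", pub_id = "P-K",
              pub_date = "2017-02-01")
  ))
  expect_message(cl <- classify_binding_sequence(pr), "equal earliest dates")
  expect_equal(as.character(cl$class), "BINDING_FIRST")
  expect_equal(attr(cl, "date_ties"), "P1")

  # a year-only date is "equal" to a full date in the same year
  pr <- resolve_primacy(dplyr::bind_rows(
    mk_record(pub_id = "P-B", pub_date = "2017-01-01", granularity = "year"),
    mk_record(term_id = "GO:0004674", term_label = "kinase", pub_id = "P-K",
              pub_date = "2017-09-01")
  ))
  expect_message(cl <- classify_binding_sequence(pr))
  expect_equal(as.character(cl$class), "BINDING_FIRST")
})

test_that("every classified accession gets exactly one class and the histogram sums", {
  fx <- generate_sequencing_fixture(
    sequencing_scenario_config(
      c(SAME_PUBLICATION = 5L, BINDING_FIRST = 3L, BINDING_AFTER = 4L,
        OTHER_ONLY = 2L, BINDING_ONLY = 6L),
      date_spacing = 3
    ),
    seed = 9
  )
  cl <- classify_fixture(fx)
  expect_equal(anyDuplicated(cl$accession), 0)
  expect_false(any(is.na(cl$class)))
  expect_equal(sum(class_histogram(cl)$n), nrow(cl))
})

test_that("publication statistics are exact bipartite-graph ratios", {
  # 2 proteins x 1 distinct publication each
  pr <- resolve_primacy(dplyr::bind_rows(
    mk_record(accession = "P1", pub_id = "A"),
    mk_record(accession = "P2", pub_id = "B")
  ))
  st <- publication_stats(pr)
  expect_equal(st$mean_publications_per_protein, 1.0)
  expect_equal(st$n_single_publication_proteins, 2)

  # 1 publication covering 4 proteins
  pr <- resolve_primacy(dplyr::bind_rows(lapply(1:4, function(i) {
    mk_record(accession = sprintf("P%d", i), pub_id = "BIG")
  })))
  st <- publication_stats(pr)
  expect_equal(st$mean_proteins_per_publication, 4.0)
  expect_equal(st$n_single_protein_publications, 0)
  expect_equal(st$binding_fraction_proteins, 1.0)

  expect_error(publication_stats(resolve_primacy(mk_record()[0, ])), "empty")
})

test_that("fixture statistics equal a brute-force recount from the ground truth", {
  fx <- generate_sequencing_fixture(
    sequencing_scenario_config(
      c(SAME_PUBLICATION = 6L, BINDING_FIRST = 4L, BINDING_AFTER = 3L,
        OTHER_ONLY = 5L, BINDING_ONLY = 7L),
      date_spacing = 11
    ),
    seed = 33
  )
  recs <- filter_positive_experimental(
    evidence_records(fx$release), "2016-01-01", "2021-12-31"
  )
  pr <- resolve_primacy(recs)
  st <- publication_stats(pr)

  # brute-force: enumerate (protein, publication) pairs straight from the
  # fixture's truth table
  tr <- fx$log$truth
  pairs <- unique(rbind(
    stats::na.omit(data.frame(acc = tr$accession, pub = tr$binding_pub_id)),
    stats::na.omit(data.frame(acc = tr$accession, pub = tr$other_pub_id))
  ))
  expect_equal(st$n_proteins, length(unique(pairs$acc)))
  expect_equal(st$n_publications, length(unique(pairs$pub)))
  expect_equal(st$mean_proteins_per_publication,
               nrow(pairs) / length(unique(pairs$pub)))
  expect_equal(st$mean_publications_per_protein,
               nrow(pairs) / length(unique(pairs$acc)))
  has_binding <- !is.na(tr$binding_pub_id)
  expect_equal(st$binding_fraction_proteins,
               sum(has_binding) / length(unique(pairs$acc)))
})
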