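# Shared fixture builders and independent oracles.

# convenience: an annotation with a single positive experimental evidence
ann_with_pub <- function(category, term_id, term_label, pub_id, pub_date,
                         kind = "direct-assay", negative = FALSE,
                         year_only = FALSE) {
  function_annotation(
    category, term_id, term_label,
    evidences = list(evidence_record(
      kind, is_negative = negative,
      publication = publication_ref(pub_id, as.Date(pub_date), year_only = year_only)
    ))
  )
}

# a small hand-built 3-release series:
#   P1: annotated from release 1 (kinase activity)
#   P2: annotated in release 2 (protein binding), annotation removed in r3
#   P3: never annotated, PE2
#   P4: appears only from release 2 (new entry), annotated in release 3
tiny_series <- function() {
  kin <- function_annotation("go-molecular-function", "GO:0004674",
                             "protein serine/threonine kinase activity")
  bind <- function_annotation("go-molecular-function", "GO:0005515",
                              "protein binding")
  path <- function_annotation("go-biological-process", "GO:0007165",
                              "signal transduction")
  r1 <- release("r1", "2015-01-01", list(
    protein_entry("P1", "1", "PE1", list(kin)),
    protein_entry("P2", "2", "PE1", list()),
    protein_entry("P3", "3", "PE2", list())
  ))
  r2 <- release("r2", "2016-01-01", list(
    protein_entry("P1", "1", "PE1", list(kin)),
    protein_entry("P2", "2", "PE1", list(bind)),
    protein_entry("P3", "3", "PE2", list()),
    protein_entry("P4", "4", "PE1", list())
  ))
  r3 <- release("r3", "2017-01-01", list(
    protein_entry("P1", "1", "PE1", list(kin)),
    protein_entry("P2", "2", "PE1", list()),
    protein_entry("P3", "3", "PE2", list()),
    protein_entry("P4", "4", "PE1", list(path))
  ))
  list(r1, r2, r3)
}

# Independent removal-detection oracle: exhaustively recompute the
# presence matrix of every (accession, category, term_id) triple by
# scanning entries with plain loops, then report, per triple present at
# some release and absent at a later one, the earliest such absence.
# Shares no code with detect_removed_functions().
oracle_removed_functions <- function(series) {
  triples <- list()
  for (i in seq_along(series)) {
    for (e in series[[i]]$entries) {
      for (a in e$annotations) {
        key <- paste(e$accession, a$category,
                     ifelse(is.na(a$term_id), "<NA>", a$term_id), sep = "|")
        if (is.null(triples[[key]])) triples[[key]] <- logical(length(series))
        triples[[key]][i] <- TRUE
      }
    }
  }
  out <- data.frame(
    accession = character(0), category = character(0), term_id = character(0),
    release_present = character(0), release_absent = character(0),
    stringsAsFactors = FALSE
  )
  ids <- vapply(series, function(r) r$meta$release_id, character(1))
  for (key in names(triples)) {
    pres <- triples[[key]]
    first <- match(TRUE, pres)
    j <- NA_integer_
    for (idx in seq_along(pres)) {
      if (idx > first && !pres[idx]) { j <- idx; break }
    }
    if (is.na(j)) next
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    out <- rbind(out, data.frame(
      accession = parts[1], category = parts[2],
      term_id = if (parts[3] == "<NA>") NA_character_ else parts[3],
      release_present = ids[j - 1], release_absent = ids[j],
      stringsAsFactors = FALSE
    ))
  }
  out[order(out$accession, out$category, out$term_id), , drop = FALSE]
}

# run the full classification pipeline on a sequencing fixture
classify_fixture <- function(fixture,
                             window_start = "2016-01-01",
                             window_end = "2021-12-31") {
  rec <- evidence_records(fixture$release)
  kept <- filter_positive_experimental(rec, window_start, window_end)
  classify_binding_sequence(resolve_primacy(kept))
}

random_scenario_multiplicities <- function(max_per_class = 50L) {
  m <- sample(0:max_per_class, 5L, replace = TRUE)
  names(m) <- binding_sequence_classes()
  m
}
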