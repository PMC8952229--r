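# Seeded synthetic release series.
#
# The generator emulates the structure of a curated protein knowledgebase
# followed over ~a decade of releases: a mostly stable protein inventory
# with occasional new entries, per-category accrual of function annotations,
# a small number of annotation removals (curation corrections), a mixture of
# experimental and computational evidence, occasional negative evidence, and
# publication dates that are sometimes known only to the year. Every record
# it emits is also written to an emission log, which downstream tests use as
# ground truth for parameter recovery.

#' Load the bundled controlled-term vocabulary
#'
#' A flat GO-like vocabulary (no DAG structure) used by the generator. It
#' always contains the label "protein binding", so trend analyses can
#' exercise their named exclusion rule.
#'
#' @return Tibble with columns `term_id`, `term_label`, `category_hint`.
#' @export
term_vocabulary <- function() {
  path <- system.file("extdata", "term_vocabulary.tsv", package = "annodrift")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Configure a synthetic release series
#'
#' @param n_proteins Number of protein entries in the inventory.
#' @param n_releases Number of releases.
#' @param release_dates Vector of `n_releases` strictly increasing dates.
#'   Default: first-of-year releases starting 2012.
#' @param pe1_fraction Fraction of proteins at existence level PE1
#'   (remainder spread over PE2-PE5).
#' @param per_category_rates Named numeric vector: expected number of new
#'   annotations per release for each annotation category. Defaults follow
#'   the relative category profile of a curated human-protein knowledgebase
#'   (biological-process records most common, catalytic-activity records
#'   rarest), scaled to desk size.
#' @param removal_count Exact number of annotation removals to inject
#'   (presence in an earlier release, absence from a later one).
#' @param negative_evidence_count Exact number of negative evidence records
#'   to inject.
#' @param experimental_fraction Fraction of evidence records that are
#'   experimental (direct assay / physical interaction).
#' @param term_vocabulary_size Number of distinct controlled terms to draw
#'   annotations from ("protein binding" is always among them).
#' @param seed Integer RNG seed; the whole series is a deterministic
#'   function of the config including this seed.
#' @return A list of class `ad_series_config`.
#' @export
series_config <- function(n_proteins = 100,
                          n_releases = 10,
                          release_dates = NULL,
                          pe1_fraction = 0.87,
                          per_category_rates = c(
                            "catalytic-activity" = 0.5,
                            "function-info" = 8,
                            "go-biological-process" = 27,
                            "go-molecular-function" = 16,
                            "pathway" = 13,
                            "transport-activity" = 1
                          ),
                          removal_count = 4,
                          negative_evidence_count = 3,
                          experimental_fraction = 0.4,
                          term_vocabulary_size = 30,
                          seed = 1L) {
  if (is.null(release_dates)) {
    release_dates <- as.Date(sprintf("%d-01-15", 2012 + seq_len(n_releases) - 1))
  }
  release_dates <- as.Date(release_dates)
  cfg <- structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_releases = as.integer(n_releases),
      release_dates = release_dates,
      pe1_fraction = pe1_fraction,
      per_category_rates = per_category_rates,
      removal_count = as.integer(removal_count),
      negative_evidence_count = as.integer(negative_evidence_count),
      experimental_fraction = experimental_fraction,
      term_vocabulary_size = as.integer(term_vocabulary_size),
      seed = as.integer(seed)
    ),
    class = "ad_series_config"
  )
  validate_series_config(cfg)
  cfg
}

validate_series_config <- function(cfg) {
  stopifnot(
    cfg$n_proteins >= 0, cfg$n_releases >= 1,
    length(cfg$release_dates) == cfg$n_releases,
    cfg$pe1_fraction >= 0, cfg$pe1_fraction <= 1,
    all(cfg$per_category_rates >= 0),
    all(names(cfg$per_category_rates) %in% annotation_categories()),
    cfg$removal_count >= 0,
    cfg$negative_evidence_count >= 0,
    cfg$experimental_fraction >= 0, cfg$experimental_fraction <= 1,
    cfg$term_vocabulary_size >= 1
  )
  if (cfg$n_releases > 1 && any(diff(cfg$release_dates) <= 0)) {
    stop("release_dates must strictly increase")
  }
  invisible(cfg)
}

# Probability that an annotation of a category carries a controlled term.
# Free-text function summaries ("function-info") never do.
controlled_term_prob <- function(category) {
  ifelse(category == "function-info", 0, 0.9)
}

YEAR_ONLY_PROB <- 0.15     # fraction of publication dates known only to the year
PUBLICATION_PROB <- 0.9    # evidence records carrying a literature reference
BINDING_WEIGHT <- 0.5      # share of molecular-function terms that are
                           # "protein binding": the term dominates curated
                           # corpora, where most first annotations are
                           # interaction evidence

build_vocab <- function(size) {
  vocab <- term_vocabulary()
  pb <- vocab[vocab$term_label == "protein binding", ]
  rest <- vocab[vocab$term_label != "protein binding", ]
  if (size - 1L <= nrow(rest)) {
    rest <- rest[sample.int(nrow(rest), size - 1L), ]
  } else {
    extra_n <- size - 1L - nrow(rest)
    extra <- tibble::tibble(
      term_id = sprintf("SYNT:%04d", seq_len(extra_n)),
      term_label = sprintf("synthetic function %d", seq_len(extra_n)),
      category_hint = "go-biological-process"
    )
    rest <- dplyr::bind_rows(rest, extra)
  }
  dplyr::bind_rows(pb, rest)
}

#' Generate a synthetic release series
#'
#' Deterministic given the config (including its seed). Besides the list of
#' releases, returns an emission log recording every annotation (with its
#' creation and removal release) and every evidence record — the ground
#' truth for parameter-recovery tests. Exactly `removal_count` annotations
#' present in some release are absent from a later one; removals never
#' target an annotation created in the final release, so every removal is
#' observable as presence-then-absence.
#'
#' @param config An [series_config()].
#' @return List with elements `releases` (list of `ad_release`) and `log`
#'   (list of tibbles `annotations`, `evidence`, `removals`, plus `proteins`
#'   and the echoed `config`).
#' @export
generate_series <- function(config) {
  validate_series_config(config)
  withr::with_seed(config$seed, generate_series_impl(config))
}

generate_series_impl <- function(cfg) {
  n <- cfg$n_proteins
  k <- cfg$n_releases
  accessions <- sprintf("SYN%05d", seq_len(n))
  vocab <- build_vocab(cfg$term_vocabulary_size)

  chrom_pool <- setdiff(chromosome_labels(), "unknown")
  proteins <- tibble::tibble(
    accession = accessions,
    chromosome = if (n) sample(chrom_pool, n, replace = TRUE) else character(0),
    existence_level = if (n) {
      ifelse(stats::runif(n) < cfg$pe1_fraction, "PE1",
             sample(paste0("PE", 2:5), n, replace = TRUE))
    } else character(0),
    # most proteins are in the inventory from the first release; a few are
    # added in later releases (new-entry events)
    intro_index = if (n) {
      ifelse(stats::runif(n) < 0.92, 1L, sample.int(k, n, replace = TRUE))
    } else integer(0)
  )

  # --- annotation accrual -------------------------------------------------
  ann_rows <- list()
  used_keys <- character(0)
  for (i in seq_len(k)) {
    eligible <- proteins$accession[proteins$intro_index <= i]
    if (!length(eligible)) next
    for (cat in names(cfg$per_category_rates)) {
      n_new <- stats::rpois(1L, cfg$per_category_rates[[cat]])
      if (n_new == 0) next
      accs <- sample(eligible, n_new, replace = TRUE)
      for (acc in accs) {
        controlled <- stats::runif(1) < controlled_term_prob(cat)
        if (controlled) {
          pool <- vocab[vocab$category_hint == cat, ]
          if (!nrow(pool)) pool <- vocab
          row <- if (cat == "go-molecular-function" &&
                     stats::runif(1) < BINDING_WEIGHT) {
            vocab[vocab$term_label == BINDING_TERM_LABEL, ]
          } else {
            pool[sample.int(nrow(pool), 1L), ]
          }
          tid <- row$term_id; tlab <- row$term_label
        } else {
          tid <- NA_character_; tlab <- NA_character_
        }
        key <- paste(acc, cat, tid, sep = "\r")
        if (key %in% used_keys) next  # keep (accession, category, term) unique
        used_keys <- c(used_keys, key)
        ann_rows[[length(ann_rows) + 1L]] <- tibble::tibble(
          accession = acc, category = cat,
          term_id = tid, term_label = tlab, created_index = i
        )
      }
    }
  }
  annotations <- if (length(ann_rows)) dplyr::bind_rows(ann_rows) else {
    tibble::tibble(
      accession = character(0), category = character(0),
      term_id = character(0), term_label = character(0),
      created_index = integer(0)
    )
  }
  annotations$ann_id <- seq_len(nrow(annotations))

  # --- removals -----------------------------------------------------------
  annotations$removed_index <- NA_integer_
  removable <- which(annotations$created_index < k)
  if (cfg$removal_count > length(removable)) {
    stop(sprintf(
      "removal_count (%d) exceeds annotations available for removal (%d)",
      cfg$removal_count, length(removable)
    ))
  }
  if (cfg$removal_count > 0) {
    victims <- sample(removable, cfg$removal_count)
    for (v in victims) {
      ci <- annotations$created_index[v]
      annotations$removed_index[v] <-
        if (ci + 1L == k) k else sample(seq(ci + 1L, k), 1L)
    }
  }

  # --- evidence -----------------------------------------------------------
  ev_rows <- list()
  pub_counter <- 0L
  make_pub <- function(release_date) {
    pub_counter <<- pub_counter + 1L
    offset <- sample.int(720L, 1L)
    date <- release_date - offset
    year_only <- stats::runif(1) < YEAR_ONLY_PROB
    publication_ref(sprintf("PUB%06d", pub_counter), date, year_only = year_only)
  }
  draw_kind <- function() {
    if (stats::runif(1) < cfg$experimental_fraction) {
      sample(experimental_kinds(), 1L)
    } else {
      sample(setdiff(evidence_kinds(), experimental_kinds()), 1L)
    }
  }
  for (j in seq_len(nrow(annotations))) {
    n_ev <- 1L + stats::rpois(1L, 0.6)
    created_date <- cfg$release_dates[annotations$created_index[j]]
    for (e in seq_len(n_ev)) {
      kind <- draw_kind()
      pub <- if (stats::runif(1) < PUBLICATION_PROB) make_pub(created_date) else NULL
      ev_rows[[length(ev_rows) + 1L]] <- tibble::tibble(
        ann_id = annotations$ann_id[j],
        evidence_kind = kind,
        is_negative = FALSE,
        pub_id = if (is.null(pub)) NA_character_ else pub$pub_id,
        pub_date = if (is.null(pub)) as.Date(NA) else pub$pub_date,
        year_only = if (is.null(pub)) NA else pub$year_only
      )
    }
  }
  # inject exactly the configured number of negative evidence records as
  # additional records on random annotations
  if (cfg$negative_evidence_count > 0) {
    if (!nrow(annotations)) stop("cannot inject negative evidence: no annotations")
    targets <- sample(annotations$ann_id, cfg$negative_evidence_count, replace = TRUE)
    for (t in targets) {
      created_date <- cfg$release_dates[annotations$created_index[annotations$ann_id == t]]
      pub <- make_pub(created_date)
      ev_rows[[length(ev_rows) + 1L]] <- tibble::tibble(
        ann_id = t, evidence_kind = draw_kind(), is_negative = TRUE,
        pub_id = pub$pub_id, pub_date = pub$pub_date, year_only = pub$year_only
      )
    }
  }
  evidence <- if (length(ev_rows)) dplyr::bind_rows(ev_rows) else {
    tibble::tibble(
      ann_id = integer(0), evidence_kind = character(0),
      is_negative = logical(0), pub_id = character(0),
      pub_date = as.Date(character(0)), year_only = logical(0)
    )
  }

  # --- materialise the releases ------------------------------------------
  releases <- lapply(seq_len(k), function(i) {
    materialise_release(
      release_id = sprintf("r%s", format(cfg$release_dates[i], "%Y")),
      release_date = cfg$release_dates[i],
      index = i, proteins = proteins,
      annotations = annotations, evidence = evidence
    )
  })

  removals <- annotations[!is.na(annotations$removed_index), ]
  log <- list(
    proteins = proteins,
    annotations = dplyr::left_join(
      annotations,
      tibble::tibble(
        created_index = seq_len(k),
        release_created = vapply(releases, function(r) r$meta$release_id, character(1))
      ),
      by = "created_index"
    ),
    evidence = dplyr::left_join(
      evidence,
      annotations[, c("ann_id", "accession", "category", "term_id")],
      by = "ann_id"
    ),
    removals = removals,
    config = cfg
  )
  list(releases = releases, log = log)
}

materialise_release <- function(release_id, release_date, index, proteins,
                                annotations, evidence) {
  present <- annotations[
    annotations$created_index <= index &
      (is.na(annotations$removed_index) | annotations$removed_index > index),
  ]
  entries <- lapply(seq_len(nrow(proteins)), function(p) {
    if (proteins$intro_index[p] > index) return(NULL)
    acc <- proteins$accession[p]
    anns_p <- present[present$accession == acc, ]
    anns <- lapply(seq_len(nrow(anns_p)), function(j) {
      evs_j <- evidence[evidence$ann_id == anns_p$ann_id[j], ]
      evs <- lapply(seq_len(nrow(evs_j)), function(m) {
        pub <- if (is.na(evs_j$pub_id[m])) NULL else {
          publication_ref(evs_j$pub_id[m], evs_j$pub_date[m],
                          year_only = evs_j$year_only[m])
        }
        evidence_record(evs_j$evidence_kind[m],
                        is_negative = evs_j$is_negative[m],
                        publication = pub)
      })
      function_annotation(anns_p$category[j], anns_p$term_id[j],
                          anns_p$term_label[j], evidences = evs)
    })
    protein_entry(acc, proteins$chromosome[p], proteins$existence_level[p], anns)
  })
  entries <- entries[!vapply(entries, is.null, logical(1))]
  release(release_id, release_date, entries)
}

#' The five binding-sequence classes
#'
#' Temporal-order categories for when protein binding was first shown
#' relative to any other function, in canonical order: same publication,
#' binding first, binding after, other function only, binding only.
#'
#' @return Character vector of the five class names.
#' @export
binding_sequence_classes <- function() {
  c("SAME_PUBLICATION", "BINDING_FIRST", "BINDING_AFTER",
    "OTHER_ONLY", "BINDING_ONLY")
}

#' Configure a binding-sequence scenario fixture
#'
#' @param multiplicities Named integer vector over exactly the five
#'   [binding_sequence_classes()]: how many proteins instantiate each
#'   temporal-order pattern.
#' @param date_spacing Days between successive publications of one protein
#'   (and between proteins' base dates).
#' @param year_only_fraction Fraction of publications carrying only a year.
#' @return A list of class `ad_scenario_config`.
#' @export
sequencing_scenario_config <- function(multiplicities = c(
                                         SAME_PUBLICATION = 3L,
                                         BINDING_FIRST = 3L,
                                         BINDING_AFTER = 3L,
                                         OTHER_ONLY = 3L,
                                         BINDING_ONLY = 3L
                                       ),
                                       date_spacing = 30L,
                                       year_only_fraction = 0) {
  if (!setequal(names(multiplicities), binding_sequence_classes())) {
    stop("multiplicities must be named by exactly the five binding-sequence classes")
  }
  stopifnot(all(multiplicities >= 0), date_spacing >= 0,
            year_only_fraction >= 0, year_only_fraction <= 1)
  structure(
    list(
      multiplicities = vapply(binding_sequence_classes(), function(cl) {
        as.integer(multiplicities[[cl]])
      }, integer(1)),
      date_spacing = as.integer(date_spacing),
      year_only_fraction = year_only_fraction
    ),
    class = "ad_scenario_config"
  )
}

BINDING_TERM_ID <- "GO:0005515"
BINDING_TERM_LABEL <- "protein binding"

#' Generate a binding-sequence classification fixture
#'
#' Builds one release in which every protein's evidence/publication pattern
#' instantiates exactly one of the five binding-sequence classes: a protein
#' binding annotation and/or one other function annotation, each backed by
#' positive experimental evidence with dated publications arranged to
#' realise the configured temporal order. Ground-truth class per protein is
#' recorded in the emission log. All publication dates fall in 2016-2020.
#'
#' When order matters and a publication is drawn year-only, the two
#' publications are placed in different years so the pattern still
#' instantiates its class at year granularity. `date_spacing = 0` combined
#' with year-only dates is an intentional-ambiguity fixture and produces a
#' warning.
#'
#' @param config An [sequencing_scenario_config()].
#' @param seed Integer RNG seed.
#' @return List with elements `release` (an `ad_release` dated 2021-01-15)
#'   and `log` (tibble `truth` with accession, class, and the publication
#'   ids/dates used).
#' @export
generate_sequencing_fixture <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ad_scenario_config"))
  if (config$date_spacing == 0 && config$year_only_fraction > 0) {
    warning("date_spacing = 0 with year-only dates: temporal order is intentionally ambiguous")
  }
  withr::with_seed(as.integer(seed), generate_sequencing_fixture_impl(config))
}

generate_sequencing_fixture_impl <- function(cfg) {
  other_terms <- term_vocabulary()
  other_terms <- other_terms[other_terms$term_label != BINDING_TERM_LABEL, ]
  classes <- rep(binding_sequence_classes(), times = cfg$multiplicities)
  n <- length(classes)
  base0 <- as.Date("2016-01-10")
  spacing <- max(cfg$date_spacing, 0L)
  pub_counter <- 0L
  next_pub_id <- function() {
    pub_counter <<- pub_counter + 1L
    sprintf("SPUB%05d", pub_counter)
  }
  truth_rows <- list()
  entries <- list()
  for (i in seq_len(n)) {
    cl <- classes[i]
    acc <- sprintf("SEQ%05d", i)
    base <- base0 + ((i - 1L) * max(spacing, 1L)) %% 1400L
    yo1 <- stats::runif(1) < cfg$year_only_fraction
    yo2 <- stats::runif(1) < cfg$year_only_fraction
    # when a year-only date is involved in an ordered pair, force the two
    # publications into different years so the order holds at year precision
    gap <- if ((yo1 || yo2) && cl %in% c("BINDING_FIRST", "BINDING_AFTER")) {
      max(spacing, 400L)
    } else {
      spacing
    }
    ot <- other_terms[sample.int(nrow(other_terms), 1L), ]
    kind1 <- sample(experimental_kinds(), 1L)
    kind2 <- sample(experimental_kinds(), 1L)

    binding_ann <- function(pub) {
      function_annotation(
        "go-molecular-function", BINDING_TERM_ID, BINDING_TERM_LABEL,
        evidences = list(evidence_record(kind1, FALSE, pub))
      )
    }
    other_ann <- function(pub) {
      function_annotation(
        ot$category_hint, ot$term_id, ot$term_label,
        evidences = list(evidence_record(kind2, FALSE, pub))
      )
    }

    anns <- switch(
      cl,
      SAME_PUBLICATION = {
        pub <- publication_ref(next_pub_id(), base, year_only = yo1)
        bd <- od <- pub$pub_date
        bp <- op <- pub$pub_id
        list(binding_ann(pub), other_ann(pub))
      },
      BINDING_FIRST = {
        p1 <- publication_ref(next_pub_id(), base, year_only = yo1)
        p2 <- publication_ref(next_pub_id(), base + gap, year_only = yo2)
        bd <- p1$pub_date; od <- p2$pub_date; bp <- p1$pub_id; op <- p2$pub_id
        list(binding_ann(p1), other_ann(p2))
      },
      BINDING_AFTER = {
        p1 <- publication_ref(next_pub_id(), base + gap, year_only = yo1)
        p2 <- publication_ref(next_pub_id(), base, year_only = yo2)
        bd <- p1$pub_date; od <- p2$pub_date; bp <- p1$pub_id; op <- p2$pub_id
        list(other_ann(p2), binding_ann(p1))
      },
      OTHER_ONLY = {
        p2 <- publication_ref(next_pub_id(), base, year_only = yo2)
        bd <- as.Date(NA); od <- p2$pub_date; bp <- NA_character_; op <- p2$pub_id
        list(other_ann(p2))
      },
      BINDING_ONLY = {
        p1 <- publication_ref(next_pub_id(), base, year_only = yo1)
        bd <- p1$pub_date; od <- as.Date(NA); bp <- p1$pub_id; op <- NA_character_
        list(binding_ann(p1))
      }
    )
    entries[[i]] <- protein_entry(acc, sample(as.character(1:22), 1L), "PE1", anns)
    truth_rows[[i]] <- tibble::tibble(
      accession = acc, class = cl,
      binding_pub_id = bp, binding_date = bd,
      other_pub_id = op, other_date = od
    )
  }
  rel <- release("rseq2021", as.Date("2021-01-15"), entries)
  truth <- if (length(truth_rows)) dplyr::bind_rows(truth_rows) else {
    tibble::tibble(
      accession = character(0), class = character(0),
      binding_pub_id = character(0), binding_date = as.Date(character(0)),
      other_pub_id = character(0), other_date = as.Date(character(0))
    )
  }
  list(release = rel, log = list(truth = truth, config = cfg))
}
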