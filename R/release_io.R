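# Reading and writing the versioned-release XML dialect.
#
# The dialect is this package's own (documented in inst/extdata/release.xsd):
# a compact document-oriented snapshot format, one file per release:
#
#   <release id="r2016" date="2016-01-15">
#     <entry accession="SYN00001" chromosome="7" existence="PE1">
#       <annotation category="go-molecular-function"
#                   term="GO:0005515" label="protein binding">
#         <evidence kind="direct-assay" negative="false">
#           <publication id="PUB000001" date="2016-03-01" granularity="day"/>
#         </evidence>
#       </annotation>
#     </entry>
#   </release>
#
# Year-only publication dates are written as date="2017" with
# granularity="year": downstream primacy resolution needs to know the
# precision, so the flag survives round-trips. Removal of an annotation
# between releases is encoded as plain absence in the later file (no
# tombstone element).

KNOWN_RELEASE_CHILDREN <- "entry"
KNOWN_ENTRY_CHILDREN <- "annotation"
KNOWN_ANNOTATION_CHILDREN <- "evidence"
KNOWN_EVIDENCE_CHILDREN <- "publication"

#' Read a release file
#'
#' Parses one XML release file into an [release()] object. Unknown elements
#' are ignored with a warning; unknown evidence kinds are mapped to
#' `curator-inference` with a warning (forward compatibility). Structural
#' violations (missing accession, invalid category, duplicate accessions)
#' abort with an error naming the offending entry.
#'
#' @param path Path to a release XML file.
#' @return An `ad_release`.
#' @export
read_release <- function(path) {
  stopifnot(file.exists(path))
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (root != "release") {
    stop(sprintf("expected <release> root element, found <%s>", root))
  }
  rel_id <- xml2::xml_attr(doc, "id")
  rel_date <- xml2::xml_attr(doc, "date")
  if (is.na(rel_id) || is.na(rel_date)) {
    stop("release element must carry 'id' and 'date' attributes")
  }

  children <- xml2::xml_children(doc)
  unknown <- setdiff(unique(xml2::xml_name(children)), KNOWN_RELEASE_CHILDREN)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown element(s) under <release>: %s",
                    paste(unknown, collapse = ", ")))
  }
  entry_nodes <- children[xml2::xml_name(children) == "entry"]
  entries <- lapply(seq_along(entry_nodes), function(i) {
    parse_entry(entry_nodes[[i]], i)
  })

  rel <- release(rel_id, as.Date(rel_date), entries)
  bad <- validate_release(rel)
  if (length(bad)) {
    stop(sprintf("invalid release file '%s':\n  %s",
                 path, paste(bad, collapse = "\n  ")))
  }
  rel
}

parse_entry <- function(node, idx) {
  acc <- xml2::xml_attr(node, "accession")
  if (is.na(acc) || !nzchar(acc)) {
    stop(sprintf("entry #%d: missing accession attribute", idx))
  }
  chromosome <- xml2::xml_attr(node, "chromosome")
  pe <- xml2::xml_attr(node, "existence")
  children <- xml2::xml_children(node)
  unknown <- setdiff(unique(xml2::xml_name(children)), KNOWN_ENTRY_CHILDREN)
  if (length(unknown)) {
    warning(sprintf("entry %s: ignoring unknown element(s): %s",
                    acc, paste(unknown, collapse = ", ")))
  }
  ann_nodes <- children[xml2::xml_name(children) == "annotation"]
  anns <- lapply(ann_nodes, parse_annotation, acc = acc)
  protein_entry(
    accession = acc,
    chromosome = if (is.na(chromosome)) "unknown" else chromosome,
    existence_level = if (is.na(pe)) "PE5" else pe,
    annotations = anns
  )
}

parse_annotation <- function(node, acc) {
  category <- xml2::xml_attr(node, "category")
  if (is.na(category)) {
    stop(sprintf("entry %s: annotation without category attribute", acc))
  }
  term <- xml2::xml_attr(node, "term")
  label <- xml2::xml_attr(node, "label")
  children <- xml2::xml_children(node)
  unknown <- setdiff(unique(xml2::xml_name(children)), KNOWN_ANNOTATION_CHILDREN)
  if (length(unknown)) {
    warning(sprintf("entry %s: ignoring unknown element(s) under <annotation>: %s",
                    acc, paste(unknown, collapse = ", ")))
  }
  ev_nodes <- children[xml2::xml_name(children) == "evidence"]
  evs <- lapply(ev_nodes, parse_evidence, acc = acc)
  function_annotation(
    category = category,
    term_id = if (is.na(term)) NA_character_ else term,
    term_label = if (is.na(label)) NA_character_ else label,
    evidences = evs
  )
}

parse_evidence <- function(node, acc) {
  kind <- xml2::xml_attr(node, "kind")
  if (is.na(kind)) kind <- "curator-inference"
  if (!kind %in% evidence_kinds()) {
    warning(sprintf(
      "entry %s: unknown evidence kind '%s' mapped to curator-inference",
      acc, kind
    ))
    kind <- "curator-inference"
  }
  negative <- identical(xml2::xml_attr(node, "negative"), "true")
  pub_nodes <- xml2::xml_find_all(node, "./publication")
  pub <- NULL
  if (length(pub_nodes)) {
    pn <- pub_nodes[[1]]
    pid <- xml2::xml_attr(pn, "id")
    pdate <- xml2::xml_attr(pn, "date")
    gran <- xml2::xml_attr(pn, "granularity")
    year_only <- identical(gran, "year")
    if (is.na(pid) || is.na(pdate)) {
      stop(sprintf("entry %s: publication must carry 'id' and 'date'", acc))
    }
    date <- if (year_only) as.Date(sprintf("%s-01-01", pdate)) else as.Date(pdate)
    pub <- publication_ref(pid, date, year_only = year_only)
  }
  evidence_record(kind, is_negative = negative, publication = pub)
}

#' Write a release file
#'
#' Serialises a release to the XML dialect. The release is validated first;
#' any invariant violation aborts the write. `read_release()` of the
#' resulting file reproduces the input field for field.
#'
#' @param rel An `ad_release`.
#' @param path Output file path (UTF-8 XML).
#' @return `path`, invisibly.
#' @export
write_release <- function(rel, path) {
  stopifnot(inherits(rel, "ad_release"))
  bad <- validate_release(rel)
  if (length(bad)) {
    stop(sprintf("refusing to write invalid release:\n  %s",
                 paste(bad, collapse = "\n  ")))
  }
  doc <- xml2::xml_new_root(
    "release",
    id = rel$meta$release_id,
    date = format(rel$meta$release_date, "%Y-%m-%d")
  )
  for (e in rel$entries) {
    en <- xml2::xml_add_child(
      doc, "entry",
      accession = e$accession,
      chromosome = e$chromosome,
      existence = e$existence_level
    )
    for (a in e$annotations) {
      attrs <- list(category = a$category)
      if (!is.na(a$term_id)) attrs$term <- a$term_id
      if (!is.na(a$term_label)) attrs$label <- a$term_label
      an <- do.call(xml2::xml_add_child, c(list(en, "annotation"), attrs))
      for (ev in a$evidences) {
        evn <- xml2::xml_add_child(
          an, "evidence",
          kind = ev$evidence_kind,
          negative = if (ev$is_negative) "true" else "false"
        )
        p <- ev$publication
        if (!is.null(p)) {
          xml2::xml_add_child(
            evn, "publication",
            id = p$pub_id,
            date = if (p$year_only) format(p$pub_date, "%Y")
                   else format(p$pub_date, "%Y-%m-%d"),
            granularity = if (p$year_only) "year" else "day"
          )
        }
      }
    }
  }
  xml2::write_xml(doc, path, options = "format")
  invisible(path)
}

#' Write a release series
#'
#' One XML file per release, named `<release_id>.xml`, under `dir`.
#'
#' @param series List of `ad_release` objects.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths written.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(series, function(r) {
    p <- file.path(dir, paste0(r$meta$release_id, ".xml"))
    write_release(r, p)
    p
  }, character(1))
}

#' Read a release series
#'
#' Reads several release files and sorts them by release date.
#'
#' @param paths Character vector of release XML files.
#' @return List of `ad_release`, date-sorted; errors if dates do not
#'   strictly increase.
#' @export
read_series <- function(paths) {
  series <- lapply(paths, read_release)
  dates <- as.Date(vapply(series, function(r) as.character(r$meta$release_date), character(1)))
  series <- series[order(dates)]
  bad <- validate_series(series)
  if (length(bad)) {
    stop(sprintf("invalid release series:\n  %s", paste(bad, collapse = "\n  ")))
  }
  series
}
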