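#' Read a Darwin Core Archive checklist
#'
#' Reads an unpacked archive directory or a `.zip` archive containing a
#' `meta.xml` descriptor, an optional `eml.xml` metadata document and a
#' tab-delimited taxon core file. Fields are mapped by the local name of the
#' Darwin Core term URI declared in `meta.xml` onto the 15-field layout of
#' [checklist_columns()]; unknown extra fields are retained as additional
#' columns.
#'
#' Duplicate `taxon_id` values and status tokens outside the nine-value
#' vocabulary are hard errors; dangling accepted/parent pointers are reported
#' by [validate_checklist()] but do not fail the read.
#'
#' @param path directory or zip file.
#' @return a `taxon_checklist` tibble with metadata from `eml.xml`.
#' @export
read_dwca <- function(path) {
  if (!file.exists(path)) {
    stop("no such file or directory: ", path, call. = FALSE)
  }
  dir <- path
  if (!dir.exists(path)) {
    if (!grepl("\\.zip$", path, ignore.case = TRUE)) {
      stop("path must be a directory or a .zip archive: ", path, call. = FALSE)
    }
    dir <- tempfile("dwca_")
    utils::unzip(path, exdir = dir)
    # tolerate a single top-level folder inside the zip
    if (!file.exists(file.path(dir, "meta.xml"))) {
      sub <- list.dirs(dir, recursive = FALSE)
      if (length(sub) == 1 && file.exists(file.path(sub, "meta.xml"))) {
        dir <- sub
      }
    }
  }
  meta_path <- file.path(dir, "meta.xml")
  if (!file.exists(meta_path)) {
    stop("not a Darwin Core Archive: missing meta.xml in ", dir,
         call. = FALSE)
  }
  meta <- xml2::read_xml(meta_path)
  xml2::xml_ns_strip(meta)
  core <- xml2::xml_find_first(meta, ".//core")
  if (is.na(xml2::xml_name(core))) {
    stop("meta.xml declares no <core> element", call. = FALSE)
  }
  loc <- xml2::xml_text(xml2::xml_find_first(core, ".//files/location"))
  core_path <- file.path(dir, loc)
  if (!file.exists(core_path)) {
    stop("core file declared in meta.xml not found: ", loc, call. = FALSE)
  }
  skip <- as.integer(xml2::xml_attr(core, "ignoreHeaderLines"))
  if (is.na(skip)) skip <- 0L

  fields <- xml2::xml_find_all(core, ".//field")
  f_idx <- as.integer(xml2::xml_attr(fields, "index"))
  f_term <- basename(xml2::xml_attr(fields, "term"))
  id_idx <- as.integer(xml2::xml_attr(xml2::xml_find_first(core, ".//id"),
                                      "index"))

  raw <- readr::read_delim(
    core_path, delim = "\t", quote = "", col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    skip = skip, na = character(), progress = FALSE,
    show_col_types = FALSE
  )
  # map declared indices onto our columns; term local names are matched
  # case-insensitively (infraspecificEpithet is also seen capitalized as
  # infraSpecificEpithet in the wild)
  term_to_col <- setNames(checklist_columns(), tolower(dwc_terms()))
  out <- tibble::tibble(.rows = nrow(raw))
  extras <- character()
  for (k in seq_along(f_idx)) {
    col_raw <- f_idx[k] + 1L
    if (col_raw > ncol(raw)) next
    term <- f_term[k]
    colname <- term_to_col[tolower(term)]
    if (is.na(colname)) {
      colname <- term
      extras <- c(extras, term)
    }
    out[[colname]] <- raw[[col_raw]]
  }
  if (!("taxon_id" %in% names(out)) && !is.na(id_idx) &&
      id_idx + 1L <= ncol(raw)) {
    out$taxon_id <- raw[[id_idx + 1L]]
  }
  for (col in setdiff(checklist_columns(), names(out))) out[[col]] <- ""
  out <- out[, c(checklist_columns(), extras)]

  # vocabulary: total or fails loudly
  status_norm <- normalize_status(out$taxonomic_status)
  bad <- which(is.na(status_norm))
  if (length(bad) > 0) {
    stop("unknown taxonomicStatus token(s): ",
         paste0("row ", utils::head(bad, 5), " '",
                out$taxonomic_status[utils::head(bad, 5)], "'",
                collapse = "; "), call. = FALSE)
  }
  out$taxonomic_status <- status_norm
  out$taxon_rank <- normalize_rank(out$taxon_rank)

  dup <- unique(out$taxon_id[duplicated(out$taxon_id)])
  if (length(dup) > 0) {
    stop("duplicate taxonID value(s): ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }

  md <- read_eml(file.path(dir, "eml.xml"))
  as_checklist(out, md)
}

read_eml <- function(path) {
  if (!file.exists(path)) return(list())
  eml <- xml2::read_xml(path)
  xml2::xml_ns_strip(eml)
  first_text <- function(xp) {
    node <- xml2::xml_find_first(eml, xp)
    if (is.na(xml2::xml_name(node))) NA_character_ else xml2::xml_text(node)
  }
  list(
    title = first_text(".//dataset/title"),
    version = first_text(".//dataset/pubDate"),
    citation = first_text(".//additionalMetadata//citation")
  )
}

#' Write a checklist as a Darwin Core Archive
#'
#' Emits an unpacked archive directory containing `meta.xml` (declaring
#' field indices 0-14 in the canonical order), `eml.xml` built from the
#' checklist metadata, and a tab-delimited `taxon.txt` core file (UTF-8, LF
#' line endings, no quoting). Output is deterministic for a fixed checklist.
#' Record-level invariant violations abort the write with a full report.
#'
#' @param checklist a checklist tibble.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dwca <- function(checklist, path) {
  assert_writable(checklist)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  cols <- c(checklist_columns(),
            setdiff(names(checklist), checklist_columns()))
  df <- as.data.frame(checklist)[, cols, drop = FALSE]
  for (j in seq_along(df)) df[[j]] <- blank_na(df[[j]])
  if (any(vapply(df, function(x) any(grepl("[\t\n\r]", x)), logical(1)))) {
    stop("field values contain tab or newline; cannot write unquoted core",
         call. = FALSE)
  }
  terms <- c(dwc_terms(), setdiff(names(checklist), checklist_columns()))

  # core file: header + rows, LF endings
  lines <- c(paste(terms, collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  if (nrow(df) == 0) lines <- lines[1]
  writeLines(lines, file.path(path, "taxon.txt"), sep = "\n", useBytes = TRUE)

  field_xml <- paste0(
    "    <field index=\"", seq_along(terms) - 1L, "\" term=\"",
    vapply(terms, dwc_term_uri, character(1)), "\"/>", collapse = "\n")
  meta <- paste0(
    "<archive xmlns=\"http://rs.tdwg.org/dwc/text/\">\n",
    "  <core encoding=\"UTF-8\" fieldsTerminatedBy=\"\\t\" ",
    "linesTerminatedBy=\"\\n\" fieldsEnclosedBy=\"\" ",
    "ignoreHeaderLines=\"1\" ",
    "rowType=\"http://rs.tdwg.org/dwc/terms/Taxon\">\n",
    "    <files>\n      <location>taxon.txt</location>\n    </files>\n",
    "    <id index=\"0\"/>\n",
    field_xml, "\n",
    "  </core>\n</archive>\n")
  writeLines(meta, file.path(path, "meta.xml"), sep = "", useBytes = TRUE)

  md <- checklist_metadata(checklist)
  esc <- function(x) {
    x <- blank_na(x %||% "")
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  eml <- paste0(
    "<eml:eml xmlns:eml=\"eml://ecoinformatics.org/eml-2.1.1\" ",
    "packageId=\"taxacade-checklist\" system=\"taxacade\">\n",
    "  <dataset>\n",
    "    <title>", esc(md$title), "</title>\n",
    "    <pubDate>", esc(md$version), "</pubDate>\n",
    "  </dataset>\n",
    "  <additionalMetadata>\n    <metadata>\n      <citation>",
    esc(md$citation), "</citation>\n    </metadata>\n",
    "  </additionalMetadata>\n</eml:eml>\n")
  writeLines(eml, file.path(path, "eml.xml"), sep = "", useBytes = TRUE)
  invisible(path)
}
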