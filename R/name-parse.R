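#' Parse verbatim scientific names
#'
#' Decomposes verbatim name strings into canonical components and authorship.
#' The grammar is deliberately simple, mirroring how occurrence aggregators
#' tokenize incoming names: the first alphabetic token is the genus; the
#' leading lower-case tokens that follow are epithets; the infraspecific rank
#' markers `subsp.`, `ssp.`, `var.` and `f.` are recognized (with or without
#' the trailing dot) and recorded separately; the hybrid sign (`×` or a
#' leading `x `) is stripped and flagged; everything from the first token
#' starting with an upper-case letter or `(` after the epithets is authorship.
#'
#' `f.` is treated as the forma marker only when it follows an epithet, so
#' authorship abbreviations such as `F. Muell.` (upper-case) or the filius
#' `f.` inside an authorship are not consumed as rank markers.
#'
#' @param x character vector of verbatim names.
#' @param quiet if `TRUE`, unparseable strings yield a row with
#'   `parse_ok = FALSE` instead of an error.
#' @return a tibble with one row per input: `verbatim`, `genus`,
#'   `specific_epithet`, `infraspecific_epithet`, `rank_marker`
#'   (`"subsp."`, `"var."`, `"f."` or `NA`), `authorship`, `is_hybrid`,
#'   `canonical` (genus capitalized, epithets lower-cased, marker included),
#'   `implied_rank` (`"genus"`, `"species"` or `"infraspecific"`) and
#'   `parse_ok`.
#' @examples
#' parse_name(c("Acacia xyz", "Vicia faba var. equina Pers."))
#' @export
parse_name <- function(x, quiet = FALSE) {
  x <- as.character(x)
  rows <- lapply(x, parse_name_one)
  out <- dplyr::bind_rows(rows)
  if (!quiet && any(!out$parse_ok)) {
    bad <- unique(out$verbatim[!out$parse_ok])
    stop("cannot parse scientific name(s): ",
         paste(utils::head(bad, 5), collapse = "; "), call. = FALSE)
  }
  out
}

parse_name_one <- function(s) {
  failed <- tibble::tibble(
    verbatim = ifelse(is.na(s), NA_character_, s),
    genus = NA_character_, specific_epithet = NA_character_,
    infraspecific_epithet = NA_character_, rank_marker = NA_character_,
    authorship = NA_character_, is_hybrid = FALSE, canonical = NA_character_,
    implied_rank = NA_character_, parse_ok = FALSE
  )
  if (is.na(s)) return(failed)
  raw <- gsub("\\s+", " ", trimws(s))
  if (!nzchar(raw)) return(failed)

  is_hybrid <- FALSE
  w <- raw
  # hybrid sign: multiplication sign anywhere, or a bare leading "x "/"X "
  if (grepl("×", w)) {
    is_hybrid <- TRUE
    w <- gsub("\\s+", " ", trimws(gsub("×", " ", w)))
  }
  if (grepl("^[xX] ", w)) {
    is_hybrid <- TRUE
    w <- sub("^[xX] ", "", w)
  }
  toks <- strsplit(w, " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return(failed)
  if (!grepl("^[A-Za-z]", toks[1])) return(failed)

  genus <- toks[1]
  substr(genus, 1, 1) <- toupper(substr(genus, 1, 1))
  i <- 2L
  markers <- c("subsp." = "subsp.", "subsp" = "subsp.", "ssp." = "subsp.",
               "ssp" = "subsp.", "var." = "var.", "var" = "var.",
               "f." = "f.", "f" = "f.")
  spec <- NA_character_
  infra <- NA_character_
  marker <- NA_character_
  pending_marker <- NA_character_
  while (i <= length(toks)) {
    tk <- toks[i]
    if (tk %in% names(markers) && !is.na(spec)) {
      # rank marker only meaningful after an epithet
      pending_marker <- markers[[tk]]
      i <- i + 1L
      next
    }
    if (grepl("^[a-z]", tk) && !grepl("\\.$", tk)) {
      ep <- tolower(tk)
      if (is.na(spec)) {
        spec <- ep
      } else if (is.na(infra)) {
        infra <- ep
        marker <- pending_marker
        pending_marker <- NA_character_
      } else {
        break # third epithet-like token: treat remainder as authorship
      }
      i <- i + 1L
      next
    }
    break
  }
  authorship <- if (i <= length(toks)) paste(toks[i:length(toks)], collapse = " ") else NA_character_
  if (!is.na(authorship)) authorship <- normalize_authorship(authorship)

  implied <- if (is.na(spec)) "genus" else if (is.na(infra)) "species" else "infraspecific"
  canonical <- make_canonical(genus, spec, marker, infra)
  tibble::tibble(
    verbatim = s, genus = genus, specific_epithet = spec,
    infraspecific_epithet = infra, rank_marker = marker,
    authorship = authorship, is_hybrid = is_hybrid, canonical = canonical,
    implied_rank = implied, parse_ok = TRUE
  )
}

make_canonical <- function(genus, spec = NA, marker = NA, infra = NA) {
  parts <- genus
  if (!is.na(spec) && nzchar(spec)) parts <- c(parts, spec)
  if (!is.na(infra) && nzchar(infra)) {
    if (!is.na(marker) && nzchar(marker)) parts <- c(parts, marker)
    parts <- c(parts, infra)
  }
  paste(parts, collapse = " ")
}

#' Normalize an authorship string
#'
#' Collapses internal whitespace, tightens spacing around parentheses and
#' normalizes spacing around `&` and the `ex` connective. Case is preserved.
#' Total function: `NA` and `""` pass through unchanged.
#'
#' @param x character vector of authorship strings.
#' @return character vector of the same length.
#' @examples
#' normalize_authorship("(L.)  DC.")   # "(L.) DC."
#' normalize_authorship("Benth. ex  Harv.")
#' @export
normalize_authorship <- function(x) {
  x <- as.character(x)
  out <- gsub("\\s+", " ", trimws(x))
  out <- gsub("\\( ", "(", out, fixed = FALSE)
  out <- gsub(" \\)", ")", out)
  out <- gsub("\\s*&\\s*", " & ", out)
  out <- gsub("\\s+ex\\s+", " ex ", out)
  out[is.na(x)] <- NA_character_
  out
}

# identity key used when comparing name strings across independently keyed
# systems: lower-cased canonical + normalized authorship
make_name_key <- function(canonical, authorship) {
  auth <- normalize_authorship(authorship)
  auth[is.na(auth)] <- ""
  paste0(tolower(canonical), "|", auth)
}
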