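# Lexicons standing in for EFO / ChEMBL / Ensembl exports, plus blacklists.
#
# A lexicon is an S3 object of class "litmine_lexicon":
#   ontology_name, entity_type, entries (data.frame: entry_id,
#   preferred_label, synonyms list-column), term_index (normalized term ->
#   character vector of entry_ids), cs_index (case-sensitive index of short
#   all-uppercase terms, which additionally live in term_index).

#' Normalize a term for indexing and matching
#'
#' Lowercases, collapses internal whitespace to single spaces, and strips
#' leading/trailing punctuation and whitespace. Short all-uppercase terms
#' (gene-symbol / abbreviation style, e.g. "WAS", "T2D") are *additionally*
#' indexed case-sensitively by [as_lexicon()]; see [compile_matcher()] for
#' how the tagger uses that index.
#'
#' @param x character vector of terms.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- stringi::stri_replace_all_regex(x, "^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "")
  x <- stringi::stri_replace_all_regex(x, "[[:space:]]+", " ")
  stringi::stri_trans_tolower(x)
}

# gene-symbol / abbreviation style: <=5 chars, at least one uppercase
# letter, no lowercase letters
is_short_allcaps <- function(x) {
  nchar(x) <= 5L & grepl("[A-Z]", x) & !grepl("[a-z]", x)
}

#' Construct a lexicon from an entries table
#'
#' @param entries data.frame with columns `entry_id`, `preferred_label` and
#'   either a `synonyms` list-column or a pipe-separated `synonyms` character
#'   column.
#' @param entity_type one of `"GP"`, `"DS"`, `"CD"`, `"OG"`.
#' @param ontology_name label for the source vocabulary.
#' @return object of class `litmine_lexicon`.
#' @export
as_lexicon <- function(entries, entity_type, ontology_name = "lexicon") {
  if (!entity_type %in% ENTITY_TYPES) validation_error("unknown entity type: ", entity_type)
  if (!nrow(entries)) validation_error("a lexicon must have at least one entry (", ontology_name, ")")
  if (anyDuplicated(entries$entry_id)) {
    validation_error("duplicate entry_id in lexicon ", ontology_name, ": ",
                     entries$entry_id[duplicated(entries$entry_id)][1])
  }
  if (any(!nzchar(trimws(entries$preferred_label)))) {
    validation_error("empty preferred_label in lexicon ", ontology_name)
  }
  if (is.null(entries$synonyms)) entries$synonyms <- replicate(nrow(entries), character(0), simplify = FALSE)
  if (is.character(entries$synonyms)) {
    entries$synonyms <- lapply(entries$synonyms, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else trimws(strsplit(s, "|", fixed = TRUE)[[1]])
    })
  }
  term_index <- new.env(parent = emptyenv())
  cs_index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(entries))) {
    id <- entries$entry_id[i]
    terms <- c(entries$preferred_label[i], entries$synonyms[[i]])
    terms <- terms[nzchar(terms)]
    for (t in terms) {
      key <- normalize_term(t)
      if (nzchar(key)) {
        term_index[[key]] <- sort(unique(c(term_index[[key]], id)))
      }
      if (is_short_allcaps(t)) {
        cs_index[[t]] <- sort(unique(c(cs_index[[t]], id)))
      }
    }
  }
  structure(list(
    ontology_name = ontology_name, entity_type = entity_type,
    entries = entries[, c("entry_id", "preferred_label", "synonyms")],
    term_index = term_index, cs_index = cs_index
  ), class = "litmine_lexicon")
}

#' Load a lexicon TSV
#'
#' Tab-separated columns `entry_id`, `preferred_label`, `synonyms`
#' (pipe-separated; may be empty). Duplicate identifiers and empty labels
#' are rejected.
#'
#' @param path lexicon TSV.
#' @param entity_type entity class of every entry (`"GP"`, `"DS"`, `"CD"`, `"OG"`).
#' @param ontology_name label for the source vocabulary (defaults to the
#'   file name).
#' @return a `litmine_lexicon`.
#' @export
load_lexicon <- function(path, entity_type, ontology_name = NULL) {
  if (!file.exists(path)) input_error("cannot read lexicon: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (!nrow(tab)) validation_error("a lexicon must have at least one entry: ", path)
  as_lexicon(tab, entity_type,
             ontology_name %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a lexicon TSV
#' @param lexicon a `litmine_lexicon`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  out <- data.frame(
    entry_id = lexicon$entries$entry_id,
    preferred_label = lexicon$entries$preferred_label,
    synonyms = vapply(lexicon$entries$synonyms, paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a term in a lexicon's indexes
#'
#' @param lexicon a `litmine_lexicon`.
#' @param term surface string (normalized internally; short all-uppercase
#'   forms also consult the case-sensitive index).
#' @return character vector of candidate entry_ids (possibly empty).
#' @export
lexicon_lookup <- function(lexicon, term) {
  ids <- lexicon$term_index[[normalize_term(term)]] %||% character(0)
  cs <- lexicon$cs_index[[term]] %||% character(0)
  sort(unique(c(ids, cs)))
}

#' All indexed (normalized) terms of a lexicon
#' @param lexicon a `litmine_lexicon`.
#' @return character vector of normalized index terms.
#' @export
lexicon_terms <- function(lexicon) sort(ls(lexicon$term_index))

#' @export
print.litmine_lexicon <- function(x, ...) {
  cat(sprintf("<litmine_lexicon '%s' type=%s entries=%d terms=%d>\n",
              x$ontology_name, x$entity_type, nrow(x$entries),
              length(ls(x$term_index))))
  invisible(x)
}

#' Load a term blacklist
#'
#' One term per line, `#` comments and blank lines ignored, duplicates
#' collapsed. Membership tests are case-insensitive.
#'
#' @param path blacklist file, or `NULL` for an empty blacklist.
#' @return object of class `litmine_blacklist`.
#' @export
load_blacklist <- function(path = NULL) {
  terms <- character(0)
  if (!is.null(path)) {
    if (!file.exists(path)) input_error("cannot read blacklist: ", path)
    lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
    terms <- lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  structure(list(terms = sort(unique(tolower(terms)))), class = "litmine_blacklist")
}

#' Case-insensitive blacklist membership
#' @param blacklist a `litmine_blacklist`.
#' @param term character vector.
#' @return logical vector.
#' @export
blacklist_contains <- function(blacklist, term) {
  tolower(term) %in% blacklist$terms
}

#' @export
print.litmine_blacklist <- function(x, ...) {
  cat(sprintf("<litmine_blacklist terms=%d>\n", length(x$terms)))
  invisible(x)
}
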