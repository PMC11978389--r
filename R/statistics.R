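# Corpus-level normalization statistics and benchmark match rates against a
# curated reference evidence set. All percentages are rounded half away from
# zero to 1 decimal.

#' Percentage of mapped entities
#'
#' `100 * mapped / total`, rounded half away from zero to 1 decimal — the
#' arithmetic behind every "count (xx.x%)" cell in the package's summary
#' tables.
#'
#' @param total positive count.
#' @param mapped count, `0 <= mapped <= total`.
#' @return percentage to 1 decimal.
#' @export
#' @examples
#' mapped_fraction(220392937, 168818017) # 76.6
mapped_fraction <- function(total, mapped) {
  if (length(total) != 1L || length(mapped) != 1L || is.na(total) || is.na(mapped)) {
    validation_error("mapped_fraction takes scalar counts")
  }
  if (total <= 0) validation_error("total must be positive")
  if (mapped < 0 || mapped > total) validation_error("mapped must lie in [0, total]")
  round_half_away(100 * mapped / total, 1)
}

#' Corpus-level normalization statistics
#'
#' Per groundable entity type: the number of mentions, how many of them were
#' mapped, the distinct normalized surface strings (unique entities), how
#' many of those distinct strings were mapped, and the distinct knowledge
#' base identifiers they map to. "Unique entity" means a distinct normalized
#' surface string (the package's term normalization), since mention counts
#' dwarf the distinct-label counts in any real corpus.
#'
#' @param groundings grounding data.frame (`$groundings` from
#'   [ground_corpus()]; UNMAPPED rows included).
#' @return data.frame with one row per entity type: `entity_type`,
#'   `entity_count`, `mapped_count`, `unique_count`, `mapped_unique_count`,
#'   `unique_ref_count`, `mapped_pct`, `mapped_unique_pct`.
#' @export
corpus_stats <- function(groundings) {
  types <- intersect(GROUNDABLE_TYPES, unique(groundings$entity_type))
  out <- lapply(types, function(tt) {
    g <- groundings[groundings$entity_type == tt, , drop = FALSE]
    mapped <- g$entry_id != "UNMAPPED"
    norm <- normalize_term(g$surface)
    uniq <- unique(norm)
    uniq_mapped <- unique(norm[mapped])
    data.frame(
      entity_type = tt,
      entity_count = nrow(g),
      mapped_count = sum(mapped),
      unique_count = length(uniq),
      mapped_unique_count = length(uniq_mapped),
      unique_ref_count = length(unique(g$entry_id[mapped])),
      mapped_pct = if (nrow(g)) mapped_fraction(nrow(g), sum(mapped)) else 0,
      mapped_unique_pct = if (length(uniq)) mapped_fraction(length(uniq), length(uniq_mapped)) else 0,
      stringsAsFactors = FALSE
    )
  })
  if (!length(out)) {
    return(data.frame(entity_type = character(), entity_count = integer(),
                      mapped_count = integer(), unique_count = integer(),
                      mapped_unique_count = integer(), unique_ref_count = integer(),
                      mapped_pct = numeric(), mapped_unique_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Benchmark match rates against a curated evidence set
#'
#' The reference is a table of curated rows `publication_id`, `target_id`,
#' `disease_id` (identifiers in the same vocabularies the pipeline grounds
#' to). Five granularities are scored; a reference item is matched iff the
#' pipeline produced the corresponding object, by exact identifier equality:
#'
#' * `publications` — the publication yielded at least one mapped mention;
#' * `publication_target_pairs` — a GP mention in that publication grounded
#'   to that target;
#' * `publication_disease_pairs` — likewise for DS mentions;
#' * `publication_disease_target_triplets` — a GP-DS co-occurrence in that
#'   publication linking the two identifiers;
#' * `disease_target_pairs` — such a co-occurrence anywhere in the corpus.
#'
#' @param reference data.frame with columns `publication_id`, `target_id`,
#'   `disease_id`.
#' @param groundings grounding data.frame (mapped rows are used).
#' @param cooccurrences output of [extract_cooccurrences()].
#' @return data.frame `granularity`, `reference_count`, `matched_count`,
#'   `match_rate` (percentage, 1 decimal).
#' @export
benchmark_match_rates <- function(reference, groundings, cooccurrences) {
  req <- c("publication_id", "target_id", "disease_id")
  miss <- setdiff(req, names(reference))
  if (length(miss)) {
    validation_error("reference table missing columns: ", paste(miss, collapse = ", "))
  }
  for (i in seq_len(nrow(reference))) {
    if (any(is.na(reference[i, req])) || any(!nzchar(trimws(unlist(reference[i, req]))))) {
      validation_error("malformed reference row ", i)
    }
  }
  mapped <- groundings[groundings$entry_id != "UNMAPPED", , drop = FALSE]
  pubs_seen <- unique(mapped$doc_id)
  gp_pairs <- unique(paste(mapped$doc_id[mapped$entity_type == "GP"],
                           mapped$entry_id[mapped$entity_type == "GP"], sep = "\r"))
  ds_pairs <- unique(paste(mapped$doc_id[mapped$entity_type == "DS"],
                           mapped$entry_id[mapped$entity_type == "DS"], sep = "\r"))
  gpds <- cooccurrences[cooccurrences$kind == "GP-DS", , drop = FALSE]
  trip_seen <- unique(paste(gpds$doc_id, gpds$entry_id_1, gpds$entry_id_2, sep = "\r"))
  dt_seen <- unique(paste(gpds$entry_id_1, gpds$entry_id_2, sep = "\r"))

  ref_pubs <- unique(reference$publication_id)
  ref_pt <- unique(paste(reference$publication_id, reference$target_id, sep = "\r"))
  ref_pd <- unique(paste(reference$publication_id, reference$disease_id, sep = "\r"))
  ref_trip <- unique(paste(reference$publication_id, reference$target_id,
                           reference$disease_id, sep = "\r"))
  ref_dt <- unique(paste(reference$target_id, reference$disease_id, sep = "\r"))

  rate_row <- function(granularity, ref_items, matched) {
    n_ref <- length(ref_items)
    n_hit <- sum(matched)
    data.frame(granularity = granularity, reference_count = n_ref,
               matched_count = n_hit,
               match_rate = if (n_ref) mapped_fraction(n_ref, n_hit) else 0,
               stringsAsFactors = FALSE)
  }
  rbind(
    rate_row("publications", ref_pubs, ref_pubs %in% pubs_seen),
    rate_row("publication_target_pairs", ref_pt, ref_pt %in% gp_pairs),
    rate_row("publication_disease_pairs", ref_pd, ref_pd %in% ds_pairs),
    rate_row("publication_disease_target_triplets", ref_trip, ref_trip %in% trip_seen),
    rate_row("disease_target_pairs", ref_dt, ref_dt %in% dt_seen)
  )
}

#' Write a stats or benchmark table as TSV
#' @param stats data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
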