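# Shared helpers. All character offsets in this package are 0-based,
# half-open [start, end), in units of characters (not bytes).

ENTITY_TYPES <- c("GP", "DS", "CD", "OG")
GROUNDABLE_TYPES <- c("GP", "DS", "CD")
# canonical type order for association pairs
TYPE_ORDER <- c(GP = 1L, DS = 2L, CD = 3L)

#' Round half away from zero
#'
#' Rounds to `digits` decimal places, breaking ties away from zero (so 0.415
#' rounds to 0.42, -0.415 to -0.42). This is the convention used for every
#' reported metric and percentage in the package; it differs from base
#' [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(0.415, 2) # 0.42
#' round_half_away(76.5985, 1) # 76.6
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a few ulp so values that are exactly representable halves
  # (and printed-table ratios landing epsilon below .5) round as intended
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' @noRd
lm_stop <- function(..., class = "litmine_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

validation_error <- function(...) lm_stop(..., class = "litmine_validation_error")
input_error <- function(...) lm_stop(..., class = "litmine_input_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# slice of `text` at 0-based half-open [start, end); vectorized over any arg
slice_chars <- function(text, start, end) {
  substring(text, start + 1L, end)
}

#' Cosine similarity between two numeric vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return cosine similarity in \[-1, 1\]; 0 when either vector has zero norm.
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x * x))
  ny <- sqrt(sum(y * y))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# empty mention table with canonical columns; char_start/char_end are
# sentence-relative, block_start/block_end block-relative (all 0-based)
empty_mentions <- function() {
  data.frame(
    doc_id = character(), block_index = integer(), sent_index = integer(),
    entity_type = character(), char_start = integer(), char_end = integer(),
    block_start = integer(), block_end = integer(), surface = character(),
    source = character(), score = numeric(), stringsAsFactors = FALSE
  )
}

check_mentions <- function(x, what = "mentions") {
  req <- c("doc_id", "block_index", "entity_type", "block_start", "block_end", "surface")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    validation_error(what, " is missing required columns: ", paste(miss, collapse = ", "))
  }
  bad <- !x$entity_type %in% ENTITY_TYPES
  if (any(bad)) {
    validation_error(what, " has unknown entity type(s): ",
                     paste(unique(x$entity_type[bad]), collapse = ", "))
  }
  invisible(x)
}

# run code under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
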