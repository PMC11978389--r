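# Pipeline driver: annotate -> (train embeddings) -> normalize ->
# associate -> stats, with a declarative config, stage toggles, and a JSON
# run manifest. All randomness is funneled through the single seed in the
# config, and every stage is single-threaded, so identical config + seed
# produce byte-identical outputs.

#' Pipeline configuration
#'
#' @param corpus_path corpus file (blocks NDJSON or plain text), or `NULL`
#'   to generate a synthetic corpus from `synth_config`.
#' @param corpus_format `"blocks"` or `"plain"`.
#' @param lexicon_dir directory of `lexicon_<TYPE>.tsv` files (types GP, DS,
#'   CD and optionally OG); `NULL` with a synthetic corpus uses the
#'   generated lexicons.
#' @param blacklist_path optional blacklist file.
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param seed integer seed driving the synthetic generator and embedding
#'   training.
#' @param embedding embedding parameter overrides (list or
#'   [embedding_params()]).
#' @param policy grounding policy overrides (list or [grounding_policy()]).
#' @param stages character vector of stages to run, a subset of
#'   `c("annotate", "embed", "normalize", "associate", "stats")`; a toggled
#'   -off stage leaves previously written outputs for downstream stages.
#' @param synth_config synthetic-corpus settings (list or
#'   [generator_config()]) used when `corpus_path` is `NULL`.
#' @return object of class `litmine_pipeline_config`.
#' @export
pipeline_config <- function(corpus_path = NULL, corpus_format = "blocks",
                            lexicon_dir = NULL, blacklist_path = NULL,
                            out_dir, seed = 42L, embedding = list(),
                            policy = list(),
                            stages = c("annotate", "embed", "normalize",
                                       "associate", "stats"),
                            synth_config = list()) {
  all_stages <- c("annotate", "embed", "normalize", "associate", "stats")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) validation_error("unknown stage(s): ", paste(bad, collapse = ", "))
  emb <- if (inherits(embedding, "litmine_embedding_params")) embedding else {
    do.call(embedding_params, utils::modifyList(list(seed = as.integer(seed)), embedding))
  }
  pol <- if (inherits(policy, "litmine_grounding_policy")) policy else {
    do.call(grounding_policy, policy)
  }
  syn <- if (inherits(synth_config, "litmine_generator_config")) synth_config else {
    do.call(generator_config, utils::modifyList(list(seed = as.integer(seed)), synth_config))
  }
  structure(list(
    corpus_path = corpus_path, corpus_format = corpus_format,
    lexicon_dir = lexicon_dir, blacklist_path = blacklist_path,
    out_dir = out_dir, seed = as.integer(seed), embedding = emb,
    policy = pol, stages = stages, synth_config = syn
  ), class = "litmine_pipeline_config")
}

#' Serialize / restore a pipeline config (lossless round-trip)
#' @param config a [pipeline_config()].
#' @param path JSON file.
#' @return `path` invisibly for write; the config for read.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$embedding <- unclass(x$embedding)
  x$policy <- unclass(x$policy)
  x$synth_config <- unclass(x$synth_config)
  x$synth_config$lexicon_sizes <- as.list(x$synth_config$lexicon_sizes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  sc <- x$synth_config
  sc$lexicon_sizes <- unlist(sc$lexicon_sizes)
  pipeline_config(
    corpus_path = x$corpus_path, corpus_format = x$corpus_format,
    lexicon_dir = x$lexicon_dir, blacklist_path = x$blacklist_path,
    out_dir = x$out_dir, seed = x$seed,
    embedding = x$embedding, policy = x$policy, stages = x$stages,
    synth_config = sc
  )
}

load_pipeline_lexicons <- function(config) {
  if (is.null(config$lexicon_dir)) {
    return(generate_lexicons(config$synth_config))
  }
  files <- list.files(config$lexicon_dir, pattern = "^lexicon_[A-Z]+\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) validation_error("no lexicon_<TYPE>.tsv files in ", config$lexicon_dir)
  lex <- lapply(files, function(f) {
    tt <- sub("^lexicon_([A-Z]+)\\.tsv$", "\\1", basename(f))
    load_lexicon(f, tt)
  })
  names(lex) <- vapply(lex, function(l) l$entity_type, "")
  lex
}

#' Run the full pipeline
#'
#' Executes the configured stages in order (annotate, embed, normalize,
#' associate, stats), writing each stage's artifact under
#' `config$out_dir` and a `manifest.json` recording per-stage record
#' counts, the config hash and the seed. A stage failure aborts the run
#' with the failing stage named; the manifest then flags the partial
#' outputs as stale.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- file.path(config$out_dir, "config.json")
  write_pipeline_config(config, cfg_json)
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_json)),
    stages = list(), complete = FALSE
  )
  path_of <- function(name) file.path(config$out_dir, name)
  write_manifest <- function() {
    jsonlite::write_json(manifest, path_of("manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      manifest$stale <<- TRUE
      write_manifest()
      lm_stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
              class = "litmine_stage_error")
    })
    manifest$stages[[name]] <<- res
    write_manifest()
    invisible(NULL)
  }

  # inputs
  if (!is.null(config$corpus_path)) {
    corpus <- load_documents(config$corpus_path, config$corpus_format)
  } else {
    gen <- generate_corpus(config$synth_config)
    corpus <- gen$corpus
    write_documents(corpus, path_of("corpus.ndjson"))
    write_gold(gen$truth$mentions, path_of("gold.tsv"))
  }
  validate_corpus(corpus)
  lexicons <- load_pipeline_lexicons(config)
  blacklist <- load_blacklist(config$blacklist_path)
  sentences <- split_sentences(corpus)

  mentions <- NULL; model <- NULL; grounded <- NULL; cooc <- NULL

  run_stage("annotate", function() {
    matcher <- compile_matcher(lexicons, blacklist)
    mentions <<- tag_corpus(matcher, sentences)
    counts <- table(mentions$entity_type)
    list(status = "ok", n_mentions = nrow(mentions),
         per_type = as.list(counts))
  })

  run_stage("embed", function() {
    model <<- train_embeddings(tokenize(sentences$text), config$embedding)
    write_embeddings(model, path_of("embeddings.txt"))
    list(status = "ok", vocab = nrow(model$vectors), dim = ncol(model$vectors))
  })

  run_stage("normalize", function() {
    if (is.null(mentions)) {
      ann <- path_of("annotations.ndjson")
      if (!file.exists(ann)) validation_error("annotate outputs missing")
      mentions <<- read_annotations(ann, sentences)
    }
    if (is.null(model) && file.exists(path_of("embeddings.txt"))) {
      model <<- read_embeddings(path_of("embeddings.txt"))
    }
    res <- ground_corpus(mentions, lexicons, model, config$policy, sentences)
    grounded <<- res$groundings
    write_annotations(grounded, sentences, path_of("annotations.ndjson"))
    write_failed(res$failed, path_of("failed.ndjson"))
    list(status = "ok", n_groundable = nrow(grounded),
         n_mapped = sum(grounded$entry_id != "UNMAPPED"),
         n_failed = nrow(res$failed))
  })

  run_stage("associate", function() {
    if (is.null(grounded)) {
      grounded <<- read_annotations(path_of("annotations.ndjson"), sentences)
    }
    cooc <<- extract_cooccurrences(grounded, sentences)
    records <- aggregate_associations(cooc)
    if (!is.null(model)) {
      records <- rank_associations(records, model, lexicons)
    }
    write_associations(records, path_of("associations.tsv"))
    utils::write.table(cooc, path_of("cooccurrences.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(status = "ok", n_cooccurrences = nrow(cooc),
         n_associations = nrow(records))
  })

  run_stage("stats", function() {
    if (is.null(grounded)) {
      grounded <<- read_annotations(path_of("annotations.ndjson"), sentences)
    }
    st <- corpus_stats(grounded)
    write_stats(st, path_of("stats.tsv"))
    list(status = "ok", rows = nrow(st))
  })

  # annotations are written by normalize; if only annotate ran, persist raw
  if ("annotate" %in% config$stages && !("normalize" %in% config$stages)) {
    write_annotations(mentions, sentences, path_of("annotations.ndjson"))
  }

  manifest$complete <- TRUE
  write_manifest()
  invisible(manifest)
}
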