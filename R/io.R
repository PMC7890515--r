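#' Canonical region labels and accepted aliases
#'
#' The challenge vocabulary has six global regions. Common variants
#' ("Oceania", "Australia/Oceania", "North America", ...) are normalized to
#' the canonical labels; anything else is an error, never a guess.
#'
#' @param x Character vector of region labels.
#' @return Character vector of canonical labels.
#' @export
normalize_region <- function(x) {
  key <- gsub("[^a-z]", "", tolower(as.character(x)))
  alias <- c(
    africa = "Africa", asia = "Asia",
    australasia = "Australasia", oceania = "Australasia",
    australia = "Australasia", australiaoceania = "Australasia",
    europe = "Europe",
    northamerica = "NorthAmerica", southamerica = "SouthAmerica"
  )
  out <- alias[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(snake_regions(), collapse = ", "), ")")
  }
  unname(out)
}

#' Read a taxonomy table
#'
#' Delimited text, one row per species; list-valued fields
#' (synonyms, common names, regions) are pipe-separated within a cell.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @return A validated [taxonomy()] object.
#' @export
read_taxonomy <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                         stringsAsFactors = FALSE, na.strings = NULL,
                         colClasses = "character")
  x$regions <- lapply(strsplit(x$regions, "|", fixed = TRUE),
                      function(v) normalize_region(trimws(v[nzchar(trimws(v))])))
  taxonomy(x)
}

#' Write a taxonomy table
#'
#' @param x A [taxonomy()] object.
#' @param path File path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "taxonomy"))
  out <- as.data.frame(x)
  for (col in c("synonyms", "common_names", "regions"))
    out[[col]] <- vapply(out[[col]], paste, "", collapse = "|")
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

response_columns <- function() {
  c("participant_id", "home_region", "photo_id", "true_species",
    "photo_region", "quality", "order_index", "answer_raw")
}

#' Read and validate a response table
#'
#' One row per (participant, photo) identification event. Region labels are
#' normalized to the six-region vocabulary; an empty or missing `answer_raw`
#' is a skip. Malformed rows (unknown region, non-numeric order, duplicate
#' participant-photo pairs) are reported with their line numbers.
#'
#' @param path File path to delimited text with a header.
#' @param sep Field delimiter (default comma).
#' @param col_map Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(participant_id = "user")`.
#' @return A data frame with the canonical columns; `quality` is a factor
#'   with levels `high`, `low`; `order_index` integer; `answer_raw` character
#'   with `""` for skips.
#' @export
read_responses <- function(path, sep = ",", col_map = NULL) {
  x <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                         stringsAsFactors = FALSE, na.strings = NULL,
                         colClasses = "character")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(x))
        stop("mapped column not in file: ", col_map[[canon]])
      names(x)[names(x) == col_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(response_columns(), names(x))
  if (length(missing))
    stop("response table is missing column(s): ", paste(missing, collapse = ", "))
  x <- x[response_columns()]
  line <- seq_len(nrow(x)) + 1L  # header is line 1
  x$home_region <- normalize_region(x$home_region)
  x$photo_region <- normalize_region(x$photo_region)
  qual <- tolower(trimws(x$quality))
  bad <- which(!qual %in% c("high", "low"))
  if (length(bad))
    stop("quality must be 'high' or 'low'; offending line(s): ",
         paste(line[bad], collapse = ", "))
  x$quality <- factor(qual, levels = c("high", "low"))
  ord <- suppressWarnings(as.integer(x$order_index))
  bad <- which(is.na(ord))
  if (length(bad))
    stop("non-integer order_index at line(s): ", paste(line[bad], collapse = ", "))
  x$order_index <- ord
  key <- paste(x$participant_id, x$photo_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (participant, photo) pair at lines ",
         paste(line[key == dup], collapse = " and "))
  }
  x$answer_raw <- trimws(x$answer_raw)
  x
}

#' Write a response table
#'
#' @param x Response data frame.
#' @param path File path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path, sep = ",") {
  out <- x[intersect(c(response_columns(),
                       setdiff(names(x), response_columns())), names(x))]
  out$quality <- as.character(out$quality)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML with blocks `paths` (responses, taxonomy, out_dir), `filter`
#' (min_photos), `split` (train_fraction), `models` (names from the
#' candidate grid), `mcmc` (chains, iter, warmup, seed) and `summaries`
#' (min_photos). A seed is mandatory: every stochastic stage of the pipeline
#' flows from it.
#'
#' @param path Path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$models)) cfg$models <- grm_model_names()
  cfg$models <- unlist(cfg$models)
  defaults <- list(
    filter = list(min_photos = 80),
    split = list(train_fraction = 0.8),
    mcmc = list(chains = 2, iter = 500, warmup = 500),
    summaries = list(min_photos = 80)
  )
  for (block in names(defaults)) {
    cfg[[block]] <- utils::modifyList(defaults[[block]],
                                      if (is.null(cfg[[block]])) list() else cfg[[block]])
  }
  if (is.null(cfg$paths$responses) || is.null(cfg$paths$taxonomy) ||
      is.null(cfg$paths$out_dir))
    stop("config must set paths: responses, taxonomy, out_dir")
  for (p in c(cfg$paths$responses, cfg$paths$taxonomy))
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  if (is.null(cfg$mcmc$seed)) stop("config must set mcmc: seed")
  bad <- setdiff(cfg$models, grm_model_names())
  if (length(bad))
    stop("unknown model name(s) in config: ", paste(bad, collapse = ", "),
         " (choose from ", paste(grm_model_names(), collapse = ", "), ")")
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(unclass(cfg), file = f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages: score the raw answers, filter participants below the response
#' threshold, split train/test stratified by participant, fit the selected
#' candidate models, compare them by PSIS-LOO, evaluate the best model on
#' the held-out set, and write the descriptive summary tables. Each stage
#' writes delimited-text artifacts into the output directory together with a
#' log carrying the seed, the config hash and record counts, so a rerun with
#' the same config and seed reproduces the same files.
#'
#' @param config A `run_config` from [read_run_config()], or a path to one.
#' @return The output directory, invisibly. Artifacts: `scored.csv`,
#'   `train.csv`, `test.csv`, `model_comparison.csv`, `fixed_effects_<best>.csv`,
#'   `evaluation.csv`, `quintile_table.csv`, `genus_confusion.csv`,
#'   `photo_consensus.csv`, `run_log.txt`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) cat(..., "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  log_line("seed: ", config$mcmc$seed)
  log_line("config_hash: ", config_hash(config))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  taxonomy <- stage("read", read_taxonomy(config$paths$taxonomy))
  responses <- stage("read", read_responses(config$paths$responses))
  log_line("read: ", nrow(responses), " responses, ", nrow(taxonomy), " species")

  scored <- stage("score", score_responses(responses, taxonomy))
  counts <- stage("filter", table(scored$participant_id))
  keep <- names(counts)[counts >= config$filter$min_photos]
  scored_kept <- scored[scored$participant_id %in% keep, ]
  log_line("filter: ", length(keep), " of ", length(counts),
           " participants with >= ", config$filter$min_photos, " responses (",
           nrow(scored_kept), " responses retained)")
  write_responses(scored_kept, file.path(out_dir, "scored.csv"))

  split <- stage("split", split_train_test(scored_kept,
                                           train_fraction = config$split$train_fraction,
                                           seed = config$mcmc$seed))
  log_line("split: ", nrow(split$train), " train / ", nrow(split$test), " test")
  write_responses(split$train, file.path(out_dir, "train.csv"))
  write_responses(split$test, file.path(out_dir, "test.csv"))

  fits <- stage("fit", lapply(config$models, function(m) {
    grm(split$train, taxonomy, model = m,
        chains = config$mcmc$chains, iter = config$mcmc$iter,
        warmup = config$mcmc$warmup, seed = config$mcmc$seed)
  }))
  names(fits) <- config$models
  cmp <- stage("compare", compare_models(fits))
  utils::write.table(cmp, file.path(out_dir, "model_comparison.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  best <- fits[[cmp$model[1]]]
  log_line("compare: best model ", cmp$model[1],
           " (looic ", round(cmp$looic[1], 1), ")")
  fe <- summary(best)$fixed
  utils::write.table(cbind(parameter = rownames(fe), fe),
                     file.path(out_dir, paste0("fixed_effects_", cmp$model[1], ".csv")),
                     sep = ",", row.names = FALSE, quote = FALSE)

  ev <- stage("evaluate", data.frame(
    metric = c("bayes_r2_group", "bayes_r2_population",
               "mae_group", "mae_population"),
    value = c(stats::median(bayes_r2(best, re = TRUE)),
              stats::median(bayes_r2(best, re = FALSE)),
              heldout_mae(best, split$test, taxonomy, re = TRUE),
              heldout_mae(best, split$test, taxonomy, re = FALSE))
  ))
  utils::write.table(ev, file.path(out_dir, "evaluation.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)

  stage("summarize", {
    qt <- quintile_table(scored, min_photos = config$summaries$min_photos)
    utils::write.table(qt, file.path(out_dir, "quintile_table.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    gc_tab <- genus_confusion(scored_kept, taxonomy)
    utils::write.table(gc_tab, file.path(out_dir, "genus_confusion.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    pc <- photo_consensus_stats(scored_kept)
    utils::write.table(pc$photos, file.path(out_dir, "photo_consensus.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    log_line("summarize: ", nrow(qt), " quintile rows, ",
             nrow(gc_tab), " MIVS genera, ", nrow(pc$photos), " photos")
  })
  invisible(out_dir)
}
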