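# Stage indices used to fan one global seed out into independent,
# individually reproducible stage seeds (seed + index).
STAGE_SEEDS <- c(simulate = 1L, split = 2L, balance = 3L, select = 4L,
                 train = 5L, evaluate = 6L)

#' Validate a pipeline run configuration
#'
#' Checks a configuration list (usually parsed from YAML) against the
#' pipeline schema and reports every violation at once. Required: integer
#' `seed`; exactly one of `simulate` (n_pos, n_neg, ...) or `input`
#' (fasta_pos, fasta_neg paths). Optional stage blocks: `split`
#' (n_test_pos, n_test_neg), `extract` (gap, features, ct_norm), `balance`
#' (method: smote / random_under / none, k_neighbors, target_ratio),
#' `select` (folds, step, trees), `train` (trees), `evaluate` (threshold).
#'
#' @param config Named list.
#' @return The config, with defaults filled in, invisibly; aborts with all
#'   accumulated messages otherwise.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  need <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  need(is.list(config), "config must be a named list")
  need(!is.null(config$seed) && is.numeric(config$seed),
       "missing or non-numeric field: seed")
  has_sim <- !is.null(config$simulate)
  has_in <- !is.null(config$input)
  need(has_sim || has_in, "one of 'simulate' or 'input' is required")
  need(!(has_sim && has_in), "'simulate' and 'input' are mutually exclusive")
  if (has_sim) {
    for (f in c("n_pos", "n_neg")) {
      need(!is.null(config$simulate[[f]]),
           paste0("missing field: simulate.", f))
    }
  }
  if (has_in) {
    for (f in c("fasta_pos", "fasta_neg")) {
      need(!is.null(config$input[[f]]),
           paste0("missing field: input.", f))
      if (!is.null(config$input[[f]])) {
        need(file.exists(config$input[[f]]),
             paste0("input file not found: ", config$input[[f]]))
      }
    }
  }
  bal <- config$balance$method %||% "smote"
  need(bal %in% c("smote", "random_under", "none"),
       paste0("unknown balance.method: ", bal))
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  defaults <- list(
    split = list(n_test_pos = 53L, n_test_neg = 52L),
    extract = list(gap = 3L, features = c("cksaap", "ct"), ct_norm = "max"),
    balance = list(method = "smote", k_neighbors = 5L, target_ratio = 1),
    select = list(folds = 3L, step = 1L, trees = 100L),
    train = list(trees = 100L),
    evaluate = list(threshold = 0.5))
  for (blk in names(defaults)) {
    config[[blk]] <- utils::modifyList(defaults[[blk]],
                                       config[[blk]] %||% list())
  }
  config$seed <- as.integer(config$seed)
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

#' Run the full classification pipeline
#'
#' Executes the four phases end to end — feature extraction (CKSAAP + CT),
#' class rebalancing of the training set only, MRMD ranking with
#' incremental subset selection, and final training plus independent
#' test-set evaluation — and writes all artifacts into a run directory:
#' `ranked.csv` (MRMD table), `subset.txt` (chosen features), `model.rds`,
#' `report.json` (confusion counts + all six metrics), `roc.csv` and
#' `run.log`. Every output carries the config hash and global seed for
#' provenance, and a fixed config yields identical reports across runs.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list (see [validate_config()]).
#' @param output_dir Run directory (created if needed); overrides
#'   `config$output_dir`.
#' @return List of class `pipeline_result`: `report` (the test-set
#'   `metrics_report`), `selection`, `ranked`, `model`, `paths`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_config(config)
  out <- output_dir %||% config$output_dir %||% tempfile("antioxrf_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  hash <- config_hash(config)
  stamp <- sprintf("# config_hash=%s seed=%d", hash, seed)
  logf <- file.path(out, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat(stamp, "\n", sep = "", file = logf)

  # Phase 0: obtain labeled train/test sequence sets
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    spec <- synthetic_spec(
      n_pos = sim$n_pos, n_neg = sim$n_neg,
      length_range = unlist(sim$length_range %||% c(50L, 300L)),
      enrichment = sim$enrichment %||% 3,
      seed = seed + STAGE_SEEDS[["simulate"]])
    ds <- generate_sequences(spec)
    log_line("simulated %d pos / %d neg sequences", sim$n_pos, sim$n_neg)
  } else {
    ds <- bind_datasets(read_fasta(config$input$fasta_pos, label = 1L),
                        read_fasta(config$input$fasta_neg, label = 0L))
    log_line("loaded %d sequences from FASTA", nrow(ds))
  }
  ds <- validate_sequences(ds, policy = "drop")
  parts <- stratified_split(ds, config$split$n_test_pos,
                            config$split$n_test_neg,
                            seed = seed + STAGE_SEEDS[["split"]])

  # Phase 1: feature extraction
  ex <- config$extract
  fm_train <- extract_features(parts$train, gap = ex$gap,
                               features = unlist(ex$features),
                               ct_norm = ex$ct_norm)
  fm_test <- extract_features(parts$test, gap = ex$gap,
                              features = unlist(ex$features),
                              ct_norm = ex$ct_norm)
  log_line("extracted %d features for %d train / %d test samples",
           ncol(fm_train$x), nrow(fm_train$x), nrow(fm_test$x))

  # Phase 2: rebalance the TRAINING set only; the test set never passes
  # through a resampler
  bal <- config$balance
  fm_bal <- switch(bal$method,
    smote = smote_oversample(fm_train, k_neighbors = bal$k_neighbors,
                             target_ratio = bal$target_ratio,
                             seed = seed + STAGE_SEEDS[["balance"]]),
    random_under = random_undersample(fm_train,
                                      target_ratio = bal$target_ratio,
                                      seed = seed + STAGE_SEEDS[["balance"]]),
    none = fm_train)
  log_line("rebalanced (%s): %d pos / %d neg", bal$method,
           sum(fm_bal$labels == 1L), sum(fm_bal$labels == 0L))

  # Phase 3: MRMD ranking + incremental subset selection
  ranked <- mrmd_rank(fm_bal)
  sel <- incremental_select(fm_bal, ranked, folds = config$select$folds,
                            step = config$select$step,
                            trees = config$select$trees,
                            seed = seed + STAGE_SEEDS[["select"]])
  log_line("selected %d features (CV accuracy %.3f)", sel$chosen_size,
           sel$chosen_accuracy)

  # Phase 4: final model + independent test evaluation
  model <- train_forest(fm_bal, subset = sel$chosen_features,
                        trees = config$train$trees,
                        seed = seed + STAGE_SEEDS[["train"]])
  report <- evaluate(model, fm_test, threshold = config$evaluate$threshold)
  log_line("test metrics: %s",
           paste(sprintf("%s=%.3f", names(report$metrics), report$metrics),
                 collapse = " "))

  # Artifacts
  paths <- list(ranked = file.path(out, "ranked.csv"),
                subset = file.path(out, "subset.txt"),
                model = file.path(out, "model.rds"),
                report = file.path(out, "report.json"),
                roc = file.path(out, "roc.csv"),
                log = logf)
  writeLines(c(stamp, "name,MR,MD,score,rank",
               sprintf("%s,%.10g,%.10g,%.10g,%d", ranked$name, ranked$MR,
                       ranked$MD, ranked$score, ranked$rank)),
             paths$ranked)
  writeLines(c(stamp, sel$chosen_features), paths$subset)
  saveRDS(model, paths$model)
  provenance <- list(config_hash = hash, seed = seed,
                     package_version = as.character(
                       utils::packageVersion("antioxrf")))
  jsonlite::write_json(
    list(provenance = provenance,
         confusion = as.list(unclass(report$confusion)),
         metrics = as.list(report$metrics),
         selection = list(chosen_size = sel$chosen_size,
                          chosen_accuracy = sel$chosen_accuracy)),
    paths$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(stamp, "fpr,tpr",
               sprintf("%.10g,%.10g", report$roc$fpr, report$roc$tpr)),
             paths$roc)

  structure(list(report = report, selection = sel, ranked = ranked,
                 model = model, paths = paths, provenance = provenance),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (config ", x$provenance$config_hash, ")\n", sep = "")
  print(x$report)
  invisible(x)
}
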