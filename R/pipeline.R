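#' Pipeline configuration
#'
#' One object that fully determines a run: cohort generation, preprocessing
#' parameters, the classifier list, the factor-analysis conditions, and a
#' single master seed that fans out deterministically to every stochastic
#' stage.
#'
#' @param cohort a [cohort_config()] (its seed is overridden by
#'   `master_seed`).
#' @param lambda,mad_k preprocessing parameters.
#' @param models character vector of feature-set names to train (empty to
#'   skip the classification stage).
#' @param epochs training epochs per model.
#' @param fa_conditions data.frame with `movement` and `speed` rows to run
#'   the factor analysis on; `NULL` for all generated conditions.
#' @param master_seed integer master seed.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(cohort, lambda = "auto", mad_k = 3,
                            models = character(0), epochs = 100L,
                            fa_conditions = NULL, master_seed = 1L) {
  cohort$seed <- as.integer(master_seed)
  structure(list(cohort = cohort, lambda = lambda, mad_k = mad_k,
                 models = models, epochs = as.integer(epochs),
                 fa_conditions = fa_conditions,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generate (streaming) -> preprocess -> extract features -> train the
#' requested classifiers with a subject-disjoint split -> per-movement
#' factor analysis. Stage failures propagate with the stage name attached.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return a `pipeline_run` with `feature_table`, `train_results`,
#'   `fa_results`, `split`, and the `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cohort <- stage("synth", generate_cohort(config$cohort, keep_trials = FALSE))
  tab <- stage("features",
               build_feature_table(cohort, lambda = config$lambda,
                                   mad_k = config$mad_k, verbose = verbose))
  split <- train_results <- NULL
  if (length(config$models)) {
    split <- split_subjects(cohort$subjects, seed = config$master_seed + 1L)
    train_results <- list()
    for (m in config$models) {
      if (verbose) message("training: ", m)
      fs <- stage("assemble", assemble_feature_set(tab, m))
      spec <- build_dnn(ncol(fs$x))
      train_results[[m]] <- stage("train",
        train_classifier(spec, fs$x, fs$y, fs$subject_id, split,
                         epochs = config$epochs,
                         seed = config$master_seed + 2L))
    }
  }
  fa_cond <- config$fa_conditions
  if (is.null(fa_cond))
    fa_cond <- expand.grid(movement = config$cohort$movements,
                           speed = config$cohort$speeds,
                           stringsAsFactors = FALSE)
  fa_results <- list()
  for (r in seq_len(nrow(fa_cond))) {
    mv <- fa_cond$movement[r]; sp <- fa_cond$speed[r]
    key <- paste(mv, sp, sep = ".")
    fa_results[[key]] <- stage("fa", {
      inp <- fa_input(tab, mv, sp)
      res <- run_factor_analysis(inp, seed = config$master_seed + 3L)
      res$group <- find_group_component(res)
      res$movement <- mv; res$speed <- sp
      res$axis <- attr(inp, "axis")
      res
    })
  }
  structure(list(feature_table = tab, train_results = train_results,
                 fa_results = fa_results, split = split, config = config),
            class = "pipeline_run")
}

#' Summarize a pipeline run
#'
#' Produces the two standard summary tables: model accuracies (one row
#' per trained feature set) and, per analysed condition, the starred
#' group-component loadings.
#'
#' @param run a `pipeline_run`.
#' @return list with `accuracy` (data.frame, possibly empty) and
#'   `loadings` (data.frame with stars), printed compactly by
#'   `print.pipeline_report`.
#' @export
pipeline_report <- function(run) {
  acc <- if (length(run$train_results)) {
    do.call(rbind, lapply(names(run$train_results), function(m) {
      tr <- run$train_results[[m]]
      h <- tr$history
      data.frame(model = m,
                 accuracy_test = 100 * max(h$acc_test, na.rm = TRUE),
                 accuracy_validation = 100 * tr$best_validation_accuracy,
                 best_epoch = tr$best_epoch)
    }))
  } else data.frame()
  loads <- do.call(rbind, lapply(run$fa_results, function(res) {
    g <- res$group
    co <- g$co_loadings
    data.frame(movement = res$movement, speed = res$speed, axis = res$axis,
               component = g$component,
               group_loading = g$group_loading,
               group_significant = g$significant,
               co_loadings = paste(sprintf("%s %.3f%s", co$variable,
                                           co$loading, co$stars),
                                   collapse = "; "))
  }))
  structure(list(accuracy = acc, loadings = loads),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  if (nrow(x$accuracy)) {
    cat("Model accuracies (%):\n")
    print(x$accuracy, row.names = FALSE, digits = 4)
    cat("\n")
  }
  cat("Group-component loadings (stars: * p<0.05, ** p<0.01, + p<0.005, ++ p<0.001):\n")
  print(x$loadings, row.names = FALSE, digits = 3)
  invisible(x)
}
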