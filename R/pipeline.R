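# Orchestration: descriptor computation -> optional interaction-field
# descriptor -> train/test split -> genetic-algorithm model selection ->
# validation and reporting. A run is a pure function of (inputs, config):
# every stage derives its seed deterministically from the one global seed,
# and all emitted artifacts except the log are timestamp-free.

# Deterministic 31-bit string hash (environment has no digest package);
# used to derive independent stage seeds from the global seed.
stage_seed <- function(global_seed, stage) {
  h <- as.numeric(global_seed) %% 2147483647
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Pipeline configuration
#'
#' @param smiles_file optional SMILES input (`SMILES id` per line); when
#'   NULL the synthetic planted-model generator supplies the table.
#' @param response_csv optional CSV with `compound_id` and the response
#'   column (required with `smiles_file`).
#' @param response_col response column name in `response_csv`.
#' @param n_synthetic compounds to generate in synthetic mode.
#' @param seed global seed; all stage seeds derive from it.
#' @param pool_width descriptor pool width.
#' @param train_fraction training-set proportion.
#' @param ga a [ga_config()]; its seed is overridden by the derived stage
#'   seed.
#' @param use_mif compute the interaction-field surface descriptor for
#'   SMILES input (slower; synthetic mode plants it instead).
#' @param mif_spacing,mif_iso interaction-field grid spacing and iso level.
#' @param thresholds interaction-typing thresholds (for pose profiling
#'   driven from the same config).
#' @param out_dir output directory or NULL for no files.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(smiles_file = NULL, response_csv = NULL,
                            response_col = "S", n_synthetic = 490L,
                            seed = 1L, pool_width = 336L,
                            train_fraction = 0.8, ga = ga_config(),
                            use_mif = FALSE, mif_spacing = 0.5,
                            mif_iso = 0.2,
                            thresholds = interaction_thresholds(),
                            out_dir = NULL) {
  structure(list(smiles_file = smiles_file, response_csv = response_csv,
                 response_col = response_col,
                 n_synthetic = as.integer(n_synthetic),
                 seed = as.integer(seed), pool_width = as.integer(pool_width),
                 train_fraction = train_fraction, ga = ga,
                 use_mif = use_mif, mif_spacing = mif_spacing,
                 mif_iso = mif_iso, thresholds = thresholds,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments
#'   (`ga:` sub-map passed to [ga_config()]).
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$ga)) y$ga <- do.call(ga_config, y$ga)
  do.call(pipeline_config, y)
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(paste0(format(Sys.time()), " ", msg), con)
}

#' Run the QSAR pipeline
#'
#' Stages: assemble the descriptor table (from SMILES + response files, or
#' from the synthetic planted-model generator), optionally add the
#' interaction-field surface descriptor, split train/test, evolve a
#' descriptor subset with the genetic algorithm, fit and validate. Emits
#' (under `out_dir`) `model.json`, `predictions.csv` with per-set labels
#' for scatter plotting, and `run.log`; the JSON and CSV are byte-stable
#' across reruns of one config.
#'
#' @param config a [pipeline_config()].
#' @return report list: the fitted `model`, `r2_all`, `r2_train`,
#'   `r2_test`, `q2`, split sizes, selected descriptors and file paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  logcon <- NULL
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)
    logcon <- file(file.path(config$out_dir, "run.log"), "w")
    on.exit(close(logcon))
  }
  .log_line(logcon, "pipeline start; global seed ", config$seed,
            "; R ", getRversion())
  stage <- "descriptors"
  table <- tryCatch({
    if (is.null(config$smiles_file)) {
      .log_line(logcon, "stage descriptors: synthetic planted table, n = ",
                config$n_synthetic, ", pool ", config$pool_width,
                ", seed ", stage_seed(config$seed, "table"))
      gen_descriptor_table(planted_model_spec(
        n = config$n_synthetic, pool_width = config$pool_width,
        seed = stage_seed(config$seed, "table")))
    } else {
      if (is.null(config$response_csv))
        stop("SMILES input needs a response CSV")
      mols <- read_smiles_file(config$smiles_file)
      if (length(mols) == 0) stop("no parsable SMILES records")
      resp_df <- utils::read.csv(config$response_csv, check.names = FALSE)
      if (!all(c("compound_id", config$response_col) %in% names(resp_df)))
        stop("response CSV needs columns compound_id and ",
             config$response_col)
      resp <- stats::setNames(as.numeric(resp_df[[config$response_col]]),
                              resp_df$compound_id)
      vecs <- lapply(mols, descriptor_pool, pool_width = config$pool_width)
      if (config$use_mif) {
        .log_line(logcon, "stage descriptors: interaction-field surface")
        for (id in names(vecs))
          vecs[[id]]["vsurf_S"] <- vsurf_s(
            mols[[id]], iso_level = config$mif_iso,
            spacing = config$mif_spacing,
            seed = stage_seed(config$seed, paste0("embed:", id)))
      }
      descriptor_table(vecs, resp)
    }
  }, error = function(e)
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  stage <- "split"
  split <- split_spec(stage_seed(config$seed, "split"),
                      config$train_fraction)
  stage <- "ga"
  ga <- config$ga
  ga$seed <- stage_seed(config$seed, "ga")
  .log_line(logcon, "stage ga: pop ", ga$pop_size, " x ", ga$generations,
            " generations, seed ", ga$seed)
  model <- tryCatch(ga_evolve(table, ga, split),
                    error = function(e)
                      stop("pipeline aborted at stage 'ga': ",
                           conditionMessage(e), call. = FALSE))
  parts <- attr(model, "split")
  preds <- predict_qsar(model, table)
  y <- response_of(table)[table$compound_id]
  set_label <- ifelse(table$compound_id %in% parts$train, "train", "test")
  pred_df <- data.frame(compound_id = table$compound_id,
                        S = as.numeric(y), predicted = as.numeric(preds),
                        set = set_label, stringsAsFactors = FALSE)
  files <- list()
  if (!is.null(config$out_dir)) {
    files$model <- file.path(config$out_dir, "model.json")
    write_qsar_model(model, files$model)
    files$predictions <- file.path(config$out_dir, "predictions.csv")
    num <- pred_df
    num$S <- sprintf("%.17g", num$S)
    num$predicted <- sprintf("%.17g", num$predicted)
    utils::write.csv(num, files$predictions, row.names = FALSE)
    .log_line(logcon, "artifacts written to ", config$out_dir)
  }
  .log_line(logcon, sprintf(
    "fit: r2_all %.4f, r2_train %.4f, r2_test %.4f, q2 %.4f (n %d/%d)",
    model$stats$r2, model$stats$train_r2, model$stats$test_r2,
    model$stats$q2, model$stats$n_train, model$stats$n_test))
  list(model = model,
       descriptors = names(model$coefficients),
       r2_all = model$stats$r2, r2_train = model$stats$train_r2,
       r2_test = model$stats$test_r2, q2 = model$stats$q2,
       n_train = model$stats$n_train, n_test = model$stats$n_test,
       predictions = pred_df, files = files)
}

#' Top-k / bottom-k binding-score ranking report
#'
#' Scores sort ascending (most negative = strongest predicted binder);
#' ties break lexicographically by compound id. `k` larger than the
#' compound count is clamped with a warning.
#'
#' @param scores named numeric vector of binding-energy scores, kcal/mol.
#' @param mw optional named numeric vector of molecular weights to include.
#' @param k rows in each of the top and bottom blocks.
#' @return list with data.frames `top` (strongest) and `bottom` (weakest).
#' @export
rank_report <- function(scores, mw = NULL, k = 10L) {
  n <- length(scores)
  if (k > n) {
    warning("k = ", k, " exceeds the ", n, " compounds; clamped")
    k <- n
  }
  ord <- order(scores, names(scores))
  df <- data.frame(compound_id = names(scores)[ord],
                   score = as.numeric(scores[ord]),
                   stringsAsFactors = FALSE)
  if (!is.null(mw)) df$MW <- as.numeric(mw[df$compound_id])
  top <- utils::head(df, k)
  bottom <- utils::tail(df, k)
  rownames(top) <- rownames(bottom) <- NULL
  list(top = top, bottom = bottom)
}
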