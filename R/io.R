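# On-disk formats: long-format CSV for cohorts (multichannel time series
# with per-round metadata), CSV for feature tables, YAML for configuration,
# JSON for summaries.  Every artifact carries the hash of the configuration
# that produced it.

#' Hash an R object (configuration fingerprint)
#'
#' MD5 of the object's canonical serialization; written into every artifact
#' so outputs can be traced to the configuration that produced them.
#'
#' @param x Any R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Write a cohort to long-format CSV
#'
#' One row per sample with `subject`, `round`, `state`, `updrs_total`,
#' `items` (semicolon-joined), `fs`, `t` and the six channel columns.  A
#' `# config_hash:` comment line precedes the header.
#'
#' @param cohort A cohort tibble from [synth_cohort()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  long <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    X <- cohort$X[[i]]
    dplyr::bind_cols(
      tibble::tibble(
        subject = cohort$subject[i], round = cohort$round[i],
        state = cohort$state[i], updrs_total = cohort$updrs_total[i],
        items = paste(cohort$label[[i]]$items, collapse = ";"),
        fs = cohort$fs[i], t = (seq_len(nrow(X)) - 1) / cohort$fs[i]),
      tibble::as_tibble(X))
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ",
                    config_hash(attr(cohort, "cohort_config"))), con)
  write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from long-format CSV
#'
#' Inverse of [write_cohort()]; validates the schema (six channel columns,
#' `fs` and `updrs_total` present) and reconstructs the per-round tibble
#' with item-level labels.
#'
#' @param path CSV file written by [write_cohort()].
#' @return A cohort tibble (`subject`, `round`, `state`, `updrs_total`,
#'   `label`, `fs`, `X`).
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  need <- c("subject", "round", "state", "updrs_total", "items", "fs", "t",
            .gyro_channels)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("cohort file schema error: missing field(s) ",
         paste(missing, collapse = ", "))
  }
  keys <- unique(df[, c("subject", "round")])
  purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    rows <- df$subject == keys$subject[i] & df$round == keys$round[i]
    sub <- df[rows, ]
    items <- as.integer(strsplit(sub$items[1], ";")[[1]])
    tibble::tibble(
      subject = keys$subject[i], round = keys$round[i],
      state = sub$state[1],
      updrs_total = sub$updrs_total[1],
      label = list(updrs_label(items)),
      fs = sub$fs[1],
      X = list(as.matrix(sub[, .gyro_channels])))
  })
}

#' Write feature tables to CSV
#'
#' @param cohort A cohort with feature columns ([cohort_features()]).
#' @param dir Output directory; writes `features_short.csv` and
#'   `features_long.csv`.
#' @return The directory, invisibly.
#' @export
write_features <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- paste0("# config_hash: ", config_hash(attr(cohort, "cohort_config")))
  for (which in c("short", "long")) {
    path <- file.path(dir, paste0("features_", which, ".csv"))
    con <- file(path, "w")
    writeLines(h, con)
    write.csv(features_to_tibble(cohort, which), con, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Pipeline configuration
#'
#' Reads (or builds) the pipeline configuration with the published training
#' defaults: 200 epochs, learning rate 1e-3, mini-batch 2, dropout 0.5.
#' Any override is reported via a message so deviations are visible in logs.
#'
#' @param path Optional YAML file with overrides.
#' @param ... Named overrides applied after the file.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    epochs = 200L, lr = 1e-3, batch = 2L, dropout = 0.5,
    n_h = 64L, lstm_layers = 2L, seed = 1L,
    cohort = "study", out_dir = "updrsens_out"
  )
  over <- c(if (!is.null(path)) yaml::read_yaml(path) else list(), list(...))
  for (nm in names(over)) {
    if (!is.null(cfg[[nm]]) && !identical(cfg[[nm]], over[[nm]])) {
      message("config override: ", nm, " = ", over[[nm]])
    }
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a CV report to disk
#'
#' Per-round predictions as CSV and the metric summary (plus medication
#' test and config hash) as JSON.
#'
#' @param report A `cv_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$predictions, file.path(dir, "cv_predictions.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(metrics = report$metrics, med_test = report$med_test,
         seed = report$seed, config_hash = config_hash(report$seed)),
    file.path(dir, "cv_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
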