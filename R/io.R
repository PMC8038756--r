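# Reproducible I/O: the standard CSV time-series dialect, canonical JSON
# fit results, and run manifests.

#' Read a release or kill time series from CSV
#'
#' Expects the dialect `time_h,value,sample_id` (UTF-8, dot decimal
#' separator).  Rows are validated (numeric cells, no duplicate times) and
#' returned sorted by time.
#'
#' @param path path to a CSV file.
#' @return data.frame with columns `time_h` (numeric), `value` (numeric),
#'   `sample_id` (character), sorted by `time_h`.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("time_h", "value", "sample_id")
  if (!identical(names(raw)[seq_along(need)], need))
    stop("format error (line 1): header must be 'time_h,value,sample_id', ",
         "got '", paste(names(raw), collapse = ","), "'", call. = FALSE)
  parse_num <- function(col, name) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("parse error (line %d): non-numeric %s cell '%s'",
                   bad[1] + 1L, name, raw[[col]][bad[1]]), call. = FALSE)
    v
  }
  t <- parse_num("time_h", "time_h")
  y <- parse_num("value", "value")
  if (anyDuplicated(t)) {
    dup <- t[duplicated(t)][1]
    stop("validation error: duplicate time value ", dup, call. = FALSE)
  }
  if (any(t < 0)) stop("validation error: negative time", call. = FALSE)
  ord <- order(t)
  data.frame(time_h = t[ord], value = y[ord],
             sample_id = raw$sample_id[ord])
}

#' Write a time series in the standard CSV dialect
#'
#' @param curve data.frame with `time_h`, `value`, `sample_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(curve, path) {
  stopifnot(all(c("time_h", "value", "sample_id") %in% names(curve)))
  df <- curve[c("time_h", "value", "sample_id")]
  # full double precision so read -> write roundtrips exactly
  df$time_h <- sprintf("%.17g", df$time_h)
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

fit_result_record <- function(fit) {
  stopifnot(inherits(fit, "release_fit"))
  list(model = fit$model,
       response = fit$response,
       coefficients = as.list(fit$coefficients),
       se = as.list(stats::setNames(fit$se, names(fit$coefficients))),
       r_squared = fit$r_squared,
       sigma = fit$sigma,
       aicc = fit$aicc,
       converged = fit$converged,
       n = nrow(fit$data),
       n_starts = fit$n_starts,
       seed = fit$seed,
       residuals = as.numeric(fit$residuals))
}

canonical_json <- function(x) {
  # stable key order (insertion order preserved by jsonlite), 17 sig digits
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null")
}

#' Write a fit result as canonical JSON
#'
#' Serialises a `"release_fit"` in a stable key order with 17 significant
#' digits (so write/read/write is byte-identical), including the seed and
#' a hash of the fit configuration, and appends a manifest entry next to
#' the output.
#'
#' @param fit a `"release_fit"` object.
#' @param path output `.json` path.
#' @param inputs optional character vector of input paths recorded in the
#'   manifest.
#' @return the manifest entry (list), invisibly.
#' @export
write_result_json <- function(fit, path, inputs = character()) {
  rec <- fit_result_record(fit)
  cfg <- list(model = fit$model, weights = fit$weights_mode,
              n_starts = fit$n_starts, seed = fit$seed)
  rec$config_hash <- config_hash(cfg)
  json <- canonical_json(rec)
  ok <- tryCatch({ writeLines(json, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write ", path, call. = FALSE)
  entry <- write_manifest(path, inputs = inputs, config = cfg,
                          seed = fit$seed)
  invisible(entry)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(canonical_json(cfg)), tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_path, inputs, config, seed) {
  entry <- list(output = basename(out_path),
                inputs = as.list(inputs),
                config = config,
                config_hash = config_hash(config),
                seed = seed,
                package_version = as.character(
                  utils::packageVersion("mfrelease")))
  mpath <- paste0(out_path, ".manifest.json")
  writeLines(as.character(canonical_json(entry)), mpath, useBytes = TRUE)
  entry
}

#' Read a flat key-value YAML config file
#'
#' @param path YAML file of flat keys mirroring the CLI flags.
#' @return named list (empty when `path` is `NULL`).
#' @export
read_run_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  cfg
}
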