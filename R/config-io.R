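#' Load a sweep configuration from YAML or JSON
#'
#' Reads a config file and returns a validated [sweep_config()]. Any field
#' omitted from the file takes its study-condition default (n = 1000, flow
#' mean 1, SD 0.18, alpha_true = 0.5, noise levels {0, 0.0125, 0.025,
#' 0.05}, 100 replicates, guard `"raw"`). Unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' Recognised keys: `alpha_grid`, `nl_list`, `replicates`, `n`,
#' `flow_mean`, `flow_sd`, `alpha_true`, `guard`, `seed`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file; an empty file (or
#'   empty mapping) yields the full default configuration.
#' @return A `"sweep_config"` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  # keep YAML-1.1 boolean-ish keys ("n", "y", ...) as literal strings, so
  # the field name `n` survives parsing; no schema field is a boolean
  keep <- list("bool#yes" = function(v) v, "bool#no" = function(v) v)
  raw <- switch(
    ext,
    "yaml" = , "yml" = yaml::yaml.load_file(path, handlers = keep),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "': use YAML or JSON.",
         call. = FALSE)
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    stop("config must be a mapping of field names to values.", call. = FALSE)
  }
  allowed <- names(formals(sweep_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sweep_config, raw)
}

# fixed 9-significant-digit rendering: reproducible diffs across runs
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", trimws(formatC(x, digits = 9, format = "g")))
}

write_fixed_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated dataset as CSV
#'
#' Columns `flow_ratio`, `expected_count_ratio`, `count_ratio`; doubles
#' rendered at fixed 9-significant-digit precision so repeated runs with
#' the same seed produce byte-identical files.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(is.data.frame(dataset))
  write_fixed_csv(as.data.frame(dataset), path)
}

#' Write per-condition sweep results as CSV
#'
#' One row per (replicate, nl, alpha); fixed-precision doubles.
#'
#' @param results a [run_sweep()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  write_fixed_csv(as.data.frame(results), path)
}

#' Write a sweep summary as CSV
#'
#' One row per (alpha, nl) cell; fixed-precision doubles.
#'
#' @param summary a [summarize_sweep()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(is.data.frame(summary))
  write_fixed_csv(summary, path)
}

#' Write a run manifest
#'
#' Records everything needed to replay a run byte-identically: the full
#' configuration, the package version, per-noise-level flag totals (so
#' singularity events are never invisible), and the output files written.
#'
#' @param config the [sweep_config()] used.
#' @param results the [run_sweep()] table (for flag totals); may be `NULL`.
#' @param files named character vector of output paths.
#' @param path manifest destination (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, results = NULL, files = character(),
                           path = "manifest.json") {
  stopifnot(inherits(config, "sweep_config"))
  flag_totals <- NULL
  if (!is.null(results)) {
    agg <- stats::aggregate(results$n_flagged,
                            by = list(nl = results$nl),
                            FUN = sum, na.rm = TRUE)
    flag_totals <- stats::setNames(as.list(agg$x), format(agg$nl))
  }
  manifest <- list(
    package = "lassensim",
    version = as.character(utils::packageVersion("lassensim")),
    config = unclass(config),
    flagged_points_by_nl = flag_totals,
    outputs = as.list(files)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
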