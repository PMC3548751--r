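# File interfaces: subject-level IPD CSVs, literature evidence CSVs in two
# dialects (2x2 counts or precomputed estimates), and result writing with
# embedded provenance.

#' Read individual participant data from CSV
#'
#' Expects a headered CSV with one row per subject and all-numeric values;
#' the outcome column (coded 0/1) is checked on read.
#'
#' @param path Path to the CSV file.
#' @param outcome Name of the outcome column. Default `"y"`.
#' @return A tibble of subjects.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' readr::write_csv(generate_ipd(scenario_config(n_ipd = 50, seed = 1)), f)
#' read_ipd_csv(f)
#' @export
read_ipd_csv <- function(path, outcome = "y") {
  if (!file.exists(path)) abort(sprintf("IPD file not found: %s", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!outcome %in% names(d)) {
    abort(sprintf("Outcome column `%s` not present in %s.", outcome, path))
  }
  if (!all(vapply(d, is.numeric, logical(1)))) {
    abort(sprintf("All columns of %s must be numeric.", path))
  }
  check_ipd(d, outcome, setdiff(names(d), outcome))
  d
}

#' Read literature evidence from CSV
#'
#' Two dialects are auto-detected from the header and must not be mixed in
#' one file:
#' * **2x2 counts**: columns `study_id, a, b, c, d` — events among exposed,
#'   non-events among exposed, events among unexposed, non-events among
#'   unexposed; routed through [estimate_from_2x2()].
#' * **estimates**: columns `study_id, beta, variance` — precomputed
#'   univariable log odds ratios, passed through.
#'
#' @param path Path to the CSV file.
#' @return A tibble of univariable estimates (see
#'   [univariable_estimates()]).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("study_id,a,b,c,d", "S1,10,90,5,195"), f)
#' read_literature_csv(f)
#' @export
read_literature_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Literature file not found: %s", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  counts <- all(c("a", "b", "c", "d") %in% names(d))
  ests <- all(c("beta", "variance") %in% names(d))
  if (counts && ests) {
    abort(sprintf("%s mixes the 2x2-count and estimate dialects; use one.", path))
  }
  if (counts) {
    tab <- tibble(
      study_id = if ("study_id" %in% names(d)) as.character(d$study_id) else
        paste0("study_", seq_len(nrow(d))),
      events_exposed = d$a, nonevents_exposed = d$b,
      events_unexposed = d$c, nonevents_unexposed = d$d
    )
    return(estimate_from_2x2(tab))
  }
  if (ests) {
    if (any(!is.finite(d$variance)) || any(d$variance <= 0)) {
      abort(sprintf("Non-positive variance in %s.", path))
    }
    return(univariable_estimates(
      d$beta, d$variance, source = "literature",
      study_id = if ("study_id" %in% names(d)) d$study_id else NULL
    ))
  }
  abort(sprintf(
    "Unrecognised literature header in %s: need study_id,a,b,c,d or study_id,beta,variance.",
    path
  ))
}

#' Write results with embedded provenance
#'
#' Writes a result table to CSV (with `#`-prefixed header lines carrying
#' the configuration and seed, so the file is self-describing yet still
#' machine-readable with `readr::read_csv(comment = "#")`) or to JSON
#' (config and results as one object). Deterministic column order: the
#' table is written as-is.
#'
#' @param results A non-empty data frame, e.g. `tidy(run_scenario(...))`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param config Optional named list (or `scenario_config`) recorded with
#'   the output.
#' @param seed Optional seed recorded with the output.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_results(data.frame(metric = "mse", value = 0.05), f, seed = 1)
#' readr::read_csv(f, comment = "#", show_col_types = FALSE)
#' @export
write_results <- function(results, path, format = c("csv", "json"),
                          config = NULL, seed = NULL) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("`results` must be a non-empty data frame.")
  }
  cfg <- if (!is.null(config)) unclass(config) else list()
  if (!is.null(seed)) cfg$seed <- seed
  ok <- tryCatch({
    if (format == "csv") {
      hdr <- character(0)
      if (length(cfg) > 0) {
        kept <- cfg[!vapply(cfg, is.null, logical(1))]
        hdr <- sprintf("# %s: %s", names(kept),
                       vapply(kept, function(v) paste(format(v), collapse = ","),
                              character(1)))
      }
      con <- file(path, "w")
      on.exit(close(con), add = TRUE)
      writeLines(hdr, con)
      utils::write.csv(results, con, row.names = FALSE)
    } else {
      jsonlite::write_json(
        list(config = cfg, results = results), path,
        auto_unbox = TRUE, digits = NA, na = "null"
      )
    }
    TRUE
  }, error = function(e) {
    abort(sprintf("Failed to write results to %s: %s", path,
                  conditionMessage(e)))
  })
  invisible(path)
}
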