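#' Write a result bundle to a plain-text store
#'
#' Persists pipeline outputs to a directory of TSV tables (tidy tables as
#' is; arrays in long format) with a JSON sidecar carrying the
#' configuration, seed, package version, and a manifest. Everything is
#' plain text so stores diff and re-read cleanly.
#'
#' @param bundle Named list of tibbles/data frames and
#'   `roi_timeseries`/`encoding_model` objects.
#' @param path Output directory (created if needed).
#' @param config The [pipeline_config()] used to produce the bundle.
#' @return `path`, invisibly.
#' @export
write_store <- function(bundle, path, config = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (name in names(bundle)) {
    obj <- bundle[[name]]
    tbl <- if (inherits(obj, "roi_timeseries")) {
      manifest[[name]] <- list(type = "roi_timeseries",
                               zscored = obj$zscored, tr = obj$tr)
      tidy(obj)
    } else if (inherits(obj, "encoding_model")) {
      manifest[[name]] <- list(type = "encoding_model",
                               basis = obj$basis[c("centers", "size_constant",
                                                   "exponent", "mode")])
      tidy(obj)
    } else {
      manifest[[name]] <- list(type = "table")
      as.data.frame(obj)
    }
    utils::write.table(tbl, file.path(path, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  sidecar <- list(
    package = "wmiem",
    version = as.character(utils::packageVersion("wmiem")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    manifest = manifest
  )
  jsonlite::write_json(sidecar, file.path(path, "store.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a table back from a store
#'
#' @param path Store directory.
#' @param name Table name (without extension).
#' @return A tibble.
#' @export
read_store_table <- function(path, name) {
  f <- file.path(path, paste0(name, ".tsv"))
  if (!file.exists(f)) stop(sprintf("no table '%s' in store %s", name, path))
  tibble::as_tibble(utils::read.table(f, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Validate a result store
#'
#' Checks the store's schema (sidecar present and parseable, every
#' manifest entry backed by a TSV), provenance (config and seed recorded),
#' and stored-type invariants: z-scored time series must have per-run
#' voxel mean ~0 and SD ~1; trial tables must satisfy the design
#' invariants (7 present / 3 absent per run, each bin once, jitter bound).
#'
#' @param path Store directory.
#' @return A tibble of class `wm_store_report` with `check`, `status`
#'   (`"ok"`, `"warning"`, `"error"`), `detail`.
#' @export
validate_store <- function(path) {
  add <- function(report, check, status, detail = "") {
    dplyr::bind_rows(report, tibble::tibble(check = check, status = status,
                                            detail = detail))
  }
  report <- tibble::tibble(check = character(), status = character(),
                           detail = character())
  if (!dir.exists(path)) stop(sprintf("store %s does not exist", path))

  sidecar_file <- file.path(path, "store.json")
  if (!file.exists(sidecar_file)) {
    report <- add(report, "sidecar", "error", "store.json missing")
    class(report) <- c("wm_store_report", class(report))
    return(report)
  }
  sidecar <- jsonlite::read_json(sidecar_file)
  report <- add(report, "sidecar", "ok")
  if (is.null(sidecar$config) || is.null(sidecar$config$seed)) {
    report <- add(report, "provenance", "warning",
                  "no config/seed recorded in sidecar")
  } else {
    report <- add(report, "provenance", "ok")
  }

  for (name in names(sidecar$manifest)) {
    entry <- sidecar$manifest[[name]]
    f <- file.path(path, paste0(name, ".tsv"))
    if (!file.exists(f)) {
      report <- add(report, name, "error", "manifest entry has no TSV")
      next
    }
    tbl <- read_store_table(path, name)
    if (identical(entry$type, "roi_timeseries") && isTRUE(entry$zscored)) {
      stats <- tbl |>
        dplyr::group_by(.data$run_id, .data$voxel) |>
        dplyr::summarise(mu = mean(.data$activation),
                         sd = stats::sd(.data$activation) *
                           sqrt((dplyr::n() - 1) / dplyr::n()),
                         .groups = "drop")
      ok <- all(abs(stats$mu) < 1e-6) && all(abs(stats$sd - 1) < 1e-6)
      report <- add(report, name, if (ok) "ok" else "error",
                    if (ok) "" else "z-scoring invariant violated")
    } else if (identical(entry$type, "table") &&
               all(c("condition", "run_id", "distractor_bin") %in%
                     names(tbl))) {
      ok <- check_design_invariants(tbl)
      report <- add(report, name, if (ok) "ok" else "error",
                    if (ok) "" else "trial-design invariants violated")
    } else {
      report <- add(report, name, "ok")
    }
  }
  class(report) <- c("wm_store_report", class(report))
  report
}

check_design_invariants <- function(trials) {
  per_run <- split(trials, paste(trials$participant_id, trials$run_id))
  all(vapply(per_run, function(r) {
    pres <- r$condition == "distractor_present"
    sum(pres) == 7 && sum(!pres) == 3 &&
      setequal(r$distractor_bin[pres], 1:7) &&
      all(is.na(r$distractor_bin[!pres]))
  }, logical(1))) &&
    all(is.na(trials$relative_distractor_angle) |
          abs(abs(wrap_angle(trials$relative_distractor_angle)) -
                default_bin_centers()[trials$distractor_bin]) <= 12 + 1e-9,
        na.rm = TRUE)
}
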