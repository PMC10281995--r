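## File-level pipeline wrappers: each stage reads/writes CSV (UTF-8,
## header rows mandatory) and echoes its configuration, so runs are
## reproducible from their recorded sidecars.  A thin command-line
## dispatcher over these functions ships in inst/cli/rhipem.

#' Read study summaries from CSV
#'
#' Columns: \code{study_id}, \code{level}, \code{position_scope},
#' \code{group_members} (semicolon-separated, empty unless the scope is
#' a group), \code{metric}, \code{central_value}, \code{central_kind},
#' \code{sample_size}, \code{min_threshold_g}.  Rows that fail
#' validation are reported with their line numbers.
#'
#' @param path CSV path.
#' @return A \code{study_records} table.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) abort_io(paste0("studies file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ## surface row-level problems with their file line (header is line 1)
  bad_level <- which(!df$level %in% pem_levels())
  if (length(bad_level)) {
    abort_io(paste0("malformed level token on line ",
                    paste(bad_level + 1, collapse = ", "), " of ", path))
  }
  bad_metric <- which(!df$metric %in% pem_metrics())
  if (length(bad_metric)) {
    abort_io(paste0("malformed metric token on line ",
                    paste(bad_metric + 1, collapse = ", "), " of ", path))
  }
  study_records(df)
}

#' Build a PEM from a studies CSV and write it out
#'
#' Reads study summaries, builds the position-exposure matrix and writes
#' it as CSV, together with a build report listing group expansions and
#' imputed cells.
#'
#' @param studies_csv Input path (see [read_studies()]).
#' @param out Output CSV path for the PEM.
#' @return The \code{"pem"} object, invisibly.  The build report is a
#'   plain-text file at \code{paste0(out, ".log")}.
#' @export
run_build_pem <- function(studies_csv, out) {
  records <- read_studies(studies_csv)
  n_groups <- sum(nzchar(records$group_members))
  pem <- build_pem(records)
  write_pem(pem, out)
  imputed <- as.data.frame(pem)[pem$imputed, c("level", "position", "metric")]
  lines <- c(
    paste0("rhipem build-pem ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("input: ", studies_csv, " (", nrow(records), " records, ",
           n_groups, " group-scoped)"),
    paste0("imputed cells: ", nrow(imputed)),
    if (nrow(imputed)) paste0("  ", imputed$level, " ", imputed$position,
                              " ", imputed$metric)
  )
  writeLines(lines, paste0(out, ".log"))
  invisible(pem)
}

#' Compute exposure indices for a careers CSV and write them out
#'
#' One output row per donor with CHII, CHII-G, CHII-R, their scaled
#' views, the season count and the number of imputed PEM cells used.
#' Donors with unrecognized level tokens are reported and skipped; the
#' run continues with the remaining donors.
#'
#' @param careers_csv Input careers CSV (see [read_careers()]).
#' @param pem_csv PEM CSV path (see [read_pem()]); defaults to the
#'   packaged matrix when \code{NULL}.
#' @param out Output CSV path.
#' @return The indices data frame, invisibly.
#' @export
run_compute_indices <- function(careers_csv, pem_csv = NULL, out) {
  careers <- read_careers(careers_csv)
  pem <- if (is.null(pem_csv)) football_pem() else read_pem(pem_csv)
  bad <- !careers$level %in% lookup_levels()
  failures <- character(0)
  if (any(bad)) {
    failures <- unique(careers$donor_id[bad])
    warning(paste0("skipping donor(s) with unrecognized level tokens: ",
                   paste(failures, collapse = ", ")))
    careers <- careers[!careers$donor_id %in% failures, , drop = FALSE]
  }
  idx <- compute_indices_cohort(careers, pem)
  utils::write.csv(idx, out, row.names = FALSE)
  if (length(failures)) {
    writeLines(c("donors skipped (unrecognized level):", failures),
               paste0(out, ".log"))
  }
  invisible(idx)
}

#' Simulate a cohort bundle to a directory
#'
#' Wraps [simulate_cohort()] and [write_cohort()]: generates a seeded
#' synthetic cohort against a PEM and writes \code{donors.csv},
#' \code{careers.csv}, \code{nft.csv} and the \code{params.yaml}
#' sidecar.  Re-running with the same parameters reproduces the files
#' byte-identically.
#'
#' @param params A [cohort_params()] object (or a YAML path to one,
#'   e.g. a previous run's sidecar).
#' @param out_dir Output directory.
#' @param pem_csv Optional PEM CSV; defaults to the packaged matrix.
#' @return The \code{"donor_cohort"} object, invisibly.
#' @export
run_simulate <- function(params, out_dir, pem_csv = NULL) {
  if (is.character(params)) {
    raw <- yaml::read_yaml(params)
    raw$position_probs <- unlist(raw$position_probs)
    params <- do.call(cohort_params, raw[setdiff(names(raw), "")])
  }
  pem <- if (is.null(pem_csv)) football_pem() else read_pem(pem_csv)
  cohort <- simulate_cohort(params, pem)
  write_cohort(cohort, out_dir)
  invisible(cohort)
}

#' Fit the model grid on a cohort bundle and write result tables
#'
#' Reads a cohort bundle, runs the exposure-outcome grid and the
#' pairwise comparisons among screened exposures for both binary
#' outcomes, and writes \code{results.csv} and \code{comparisons.csv}
#' into \code{out_dir} with a YAML sidecar echoing the analysis
#' settings.
#'
#' @param cohort_dir Directory holding a cohort bundle.
#' @param out_dir Output directory.
#' @param n_boot,k,seed,alpha Analysis settings (see
#'   [fit_exposure_grid()]).
#' @return A list with \code{results} and \code{comparisons}, invisibly.
#' @export
run_fit <- function(cohort_dir, out_dir, n_boot = 2000, k = 10, seed = 1,
                    alpha = 0.0083) {
  cohort <- read_cohort(cohort_dir)
  donors <- cohort$donors
  grid <- fit_exposure_grid(donors, n_boot = n_boot, k = k, seed = seed,
                            alpha = alpha)
  cmp <- do.call(rbind, lapply(c("cte_status", "cte_severity"), function(oc) {
    d <- compare_exposure_models(donors, grid, outcome = oc,
                                 n_boot = n_boot, seed = seed)
    if (nrow(d)) cbind(outcome = oc, d) else NULL
  }))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(grid$results, file.path(out_dir, "results.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cmp)) {
    utils::write.csv(cmp, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE, na = "")
  }
  yaml::write_yaml(list(n_boot = n_boot, k = k, seed = seed, alpha = alpha,
                        n_donors = nrow(donors),
                        package_version = as.character(utils::packageVersion("rhipem"))),
                   file.path(out_dir, "fit.yaml"))
  if (length(grid$skipped)) {
    writeLines(paste(names(grid$skipped), grid$skipped, sep = ": "),
               file.path(out_dir, "skipped.log"))
  }
  invisible(list(results = grid$results, comparisons = cmp))
}
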