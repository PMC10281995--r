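## Position-exposure matrix (PEM) construction.
##
## A PEM maps (level of play) x (position or overall) x (metric) to a
## weighted-average annual exposure pooled from helmet-sensor studies,
## each study weighted in proportion to its sample size.  Cells with no
## direct study data are imputed from the level's overall row.

#' Validate a table of study-level helmet-sensor summaries
#'
#' Each row is one central-tendency summary abstracted from a published
#' helmet-sensor study: a level of play, a position scope (a single
#' position code, \code{"overall"}, or a named position group with an
#' explicit member list), a metric, the reported central value and the
#' study's sample size.  Means and medians are pooled identically;
#' \code{central_kind} is retained as provenance only.
#'
#' @param records Data frame with columns \code{study_id}, \code{level},
#'   \code{position_scope}, \code{group_members} (semicolon-separated
#'   position codes, empty unless \code{position_scope} is a group name),
#'   \code{metric}, \code{central_value}, \code{central_kind}
#'   (\code{"mean"} or \code{"median"}), \code{sample_size} and optionally
#'   \code{min_threshold_g} (default 10, metadata only).
#' @return The validated data frame with class \code{"study_records"}.
#' @export
#' @examples
#' recs <- data.frame(
#'   study_id = "s1", level = "high_school", position_scope = "LB",
#'   group_members = "", metric = "hits_per_season",
#'   central_value = 460, central_kind = "mean", sample_size = 35
#' )
#' study_records(recs)
study_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_invalid("'records' must be a non-empty data frame of study summaries")
  }
  needed <- c("study_id", "level", "position_scope", "metric",
              "central_value", "sample_size")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    abort_invalid(paste0("study records are missing columns: ",
                         paste(miss, collapse = ", ")))
  }
  if (!"group_members" %in% names(records)) records$group_members <- ""
  if (!"central_kind" %in% names(records)) records$central_kind <- "mean"
  if (!"min_threshold_g" %in% names(records)) records$min_threshold_g <- 10
  records$group_members[is.na(records$group_members)] <- ""

  bad_level <- !records$level %in% pem_levels()
  if (any(bad_level)) {
    abort_invalid(paste0("unrecognized level token(s): ",
                         paste(unique(records$level[bad_level]), collapse = ", "),
                         " (rows ", paste(which(bad_level), collapse = ", "), ")"))
  }
  if (any(!records$metric %in% pem_metrics())) {
    abort_invalid(paste0("unrecognized metric token(s): ",
                         paste(setdiff(unique(records$metric), pem_metrics()),
                               collapse = ", ")))
  }
  v <- records$central_value
  if (any(is.na(v)) || any(!is.finite(v)) || any(v < 0)) {
    abort_invalid("central_value must be finite and nonnegative for every record")
  }
  n <- records$sample_size
  if (any(is.na(n)) || any(n < 1) || any(n != round(n))) {
    abort_invalid("sample_size must be a positive integer for every record (no default weight is assumed)")
  }
  if (any(!records$central_kind %in% c("mean", "median"))) {
    abort_invalid("central_kind must be 'mean' or 'median'")
  }
  is_group <- nzchar(records$group_members)
  known <- records$position_scope %in% c("overall", pem_positions())
  if (any(!known & !is_group)) {
    abort_invalid(paste0(
      "position_scope must be 'overall', a position code, or a named group ",
      "with group_members listed; offending rows: ",
      paste(which(!known & !is_group), collapse = ", ")))
  }
  ## youth studies report team-wide averages only
  youth_pos <- records$level == "youth" & records$position_scope != "overall"
  if (any(youth_pos)) {
    abort_invalid("youth records must have position_scope = 'overall' (no youth position-level data exist)")
  }
  class(records) <- c("study_records", class(records))
  records
}

#' Expand position-group records into per-position records
#'
#' Studies that report aggregate values for a named position group (for
#' example \code{"non-speed"} covering offensive and defensive line) are
#' replaced by one record per member position, each carrying the group's
#' value and sample size unchanged.  Overall and single-position records
#' pass through untouched.
#'
#' @param records A \code{study_records} table (see [study_records()]).
#' @return A \code{study_records} table with no group rows remaining.
#' @export
#' @examples
#' recs <- study_records(data.frame(
#'   study_id = "s1", level = "high_school", position_scope = "non-speed",
#'   group_members = "OL;DL", metric = "hits_per_season",
#'   central_value = 800, central_kind = "mean", sample_size = 20
#' ))
#' expand_groups(recs)
expand_groups <- function(records) {
  records <- study_records(as.data.frame(records))
  is_group <- nzchar(records$group_members)
  if (!any(is_group)) return(records)

  members <- strsplit(records$group_members[is_group], ";", fixed = TRUE)
  members <- lapply(members, function(m) trimws(m[nzchar(trimws(m))]))
  if (any(lengths(members) == 0)) {
    abort_invalid("group record with empty member list")
  }
  bad <- setdiff(unlist(members), pem_positions())
  if (length(bad)) {
    abort_invalid(paste0("group members outside the position vocabulary: ",
                         paste(bad, collapse = ", ")))
  }
  grp <- records[is_group, , drop = FALSE]
  expanded <- grp[rep(seq_len(nrow(grp)), lengths(members)), , drop = FALSE]
  expanded$position_scope <- unlist(members)
  expanded$group_members <- ""
  out <- rbind(records[!is_group, , drop = FALSE], expanded)
  rownames(out) <- NULL
  class(out) <- unique(c("study_records", class(out)))
  out
}

weighted_pool <- function(values, sizes) sum(sizes * values) / sum(sizes)

#' Build a position-exposure matrix from study records
#'
#' Pools study summaries into per-cell weighted averages, each study's
#' estimate weighted in proportion to its sample size.  Group records are
#' expanded first (see [expand_groups()]).  The level's \code{overall}
#' cell is taken from overall-scoped reports when any exist; when a level
#' and metric has only position-specific reports, the overall cell pools
#' all of them, sample-size weighted.  Position cells with no direct
#' records are filled from the level overall cell and flagged
#' \code{imputed}.
#'
#' @param records A \code{study_records} table.
#' @return An object of class \code{"pem"}: a data frame with one row per
#'   (level, position, metric) cell and columns \code{value},
#'   \code{n_total}, \code{n_studies}, \code{imputed}.
#' @export
#' @examples
#' recs <- study_records(data.frame(
#'   study_id = c("a", "b", "c"),
#'   level = "high_school",
#'   position_scope = c("LB", "LB", "overall"),
#'   group_members = "",
#'   metric = "hits_per_season",
#'   central_value = c(100, 200, 500),
#'   central_kind = "mean",
#'   sample_size = c(10, 30, 50)
#' ))
#' pem <- build_pem(recs)
#' pem_lookup(pem, "high_school", "LB", "hits_per_season")$value # 175
build_pem <- function(records) {
  records <- expand_groups(records)

  grid <- expand.grid(
    level = pem_levels(),
    position = c("overall", pem_positions()),
    metric = pem_metrics(),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[order(match(grid$metric, pem_metrics()),
                     match(grid$level, pem_levels()),
                     match(grid$position, c("overall", pem_positions()))), ]
  rownames(grid) <- NULL

  pool_cell <- function(level, position, metric) {
    sel <- records$level == level & records$metric == metric &
      records$position_scope == position
    if (position == "overall" && !any(sel)) {
      ## no team-wide reports: pool every position at this level instead
      sel <- records$level == level & records$metric == metric
    }
    if (!any(sel)) return(NULL)
    r <- records[sel, , drop = FALSE]
    list(value = weighted_pool(r$central_value, r$sample_size),
         n_total = sum(r$sample_size),
         n_studies = length(unique(r$study_id)))
  }

  ## every (level, metric) must have at least one record to seed imputation
  for (lev in pem_levels()) {
    for (met in pem_metrics()) {
      if (!any(records$level == lev & records$metric == met)) {
        abort_build(paste0("no study records for level '", lev,
                           "', metric '", met,
                           "': the overall pool cannot be formed"))
      }
    }
  }

  cells <- lapply(seq_len(nrow(grid)), function(i) {
    pool_cell(grid$level[i], grid$position[i], grid$metric[i])
  })
  grid$value <- vapply(cells, function(c) if (is.null(c)) NA_real_ else c$value, 0)
  grid$n_total <- vapply(cells, function(c) if (is.null(c)) NA_real_ else c$n_total, 0)
  grid$n_studies <- vapply(cells, function(c) if (is.null(c)) NA_real_ else c$n_studies, 0)
  grid$imputed <- is.na(grid$value)

  new_pem(grid)
}

## Fill position cells lacking direct data from the level overall row and
## finish the object.  `cells` must hold every (level, overall, metric)
## value; youth position rows always impute to youth overall.
new_pem <- function(cells) {
  stopifnot(all(c("level", "position", "metric", "value", "imputed") %in% names(cells)))
  for (lev in pem_levels()) {
    for (met in pem_metrics()) {
      ov <- cells$value[cells$level == lev & cells$position == "overall" &
                          cells$metric == met]
      if (length(ov) != 1 || is.na(ov)) {
        abort_build(paste0("missing overall cell for level '", lev,
                           "', metric '", met, "'"))
      }
      fill <- is.na(cells$value) & cells$level == lev & cells$metric == met
      cells$value[fill] <- ov
      cells$imputed[fill] <- TRUE
    }
  }
  if (any(cells$value <= 0)) {
    abort_build("all PEM cell values must be strictly positive")
  }
  if (!"n_total" %in% names(cells)) cells$n_total <- NA_real_
  if (!"n_studies" %in% names(cells)) cells$n_studies <- NA_real_
  cells$n_total[cells$imputed] <- NA_real_
  cells$n_studies[cells$imputed] <- NA_real_
  structure(cells, class = c("pem", "data.frame"))
}

#' @export
print.pem <- function(x, ...) {
  cat("Position-exposure matrix:",
      sum(!x$imputed), "directly pooled cells,",
      sum(x$imputed), "imputed from level overall rows\n")
  for (met in pem_metrics()) {
    cat("\n", met, "\n", sep = "")
    sub <- x[x$metric == met, ]
    wide <- stats::reshape(
      sub[, c("level", "position", "value")],
      idvar = "position", timevar = "level", direction = "wide"
    )
    names(wide) <- sub("^value\\.", "", names(wide))
    print(wide, row.names = FALSE)
  }
  invisible(x)
}

#' Look up a PEM cell, applying the level-mapping rules
#'
#' Lookup is total for recognized levels: semi-professional and
#' professional play resolve to the college row (no helmet-sensor data
#' exist above college), youth play always resolves to the youth overall
#' row, and positions absent from the matrix (kickers, punters, unknown)
#' resolve to the level's overall row.
#'
#' @param pem A \code{"pem"} object.
#' @param level One of \code{"youth"}, \code{"high_school"},
#'   \code{"college"}, \code{"semi_professional"}, \code{"professional"}.
#' @param position A position code, \code{"overall"}, or any token for an
#'   unknown/other position.
#' @param metric One of [pem_metrics()].
#' @return A one-row data frame with \code{value}, \code{n_total},
#'   \code{n_studies}, \code{imputed}, \code{mapped_from_level} (the
#'   requested level when it was resolved to another row, else \code{NA})
#'   and \code{position_mapped_to_overall}.
#' @export
#' @examples
#' pem <- football_pem()
#' pem_lookup(pem, "professional", "DL", "hits_per_season")$value # 840.9
#' pem_lookup(pem, "youth", "LB", "hits_per_season")$value        # 206.4
pem_lookup <- function(pem, level, position, metric) {
  if (!inherits(pem, "pem")) abort_invalid("'pem' must be a pem object")
  if (length(level) != 1 || !level %in% lookup_levels()) {
    abort_invalid(paste0("unrecognized level token: '", paste(level, collapse = ","), "'"))
  }
  if (!metric %in% pem_metrics()) {
    abort_invalid(paste0("unrecognized metric token: '", metric, "'"))
  }
  eff_level <- level
  mapped_from <- NA_character_
  if (level %in% c("semi_professional", "professional")) {
    eff_level <- "college"
    mapped_from <- level
  }
  eff_pos <- position
  pos_to_overall <- FALSE
  if (eff_level == "youth" && !identical(position, "overall")) {
    eff_pos <- "overall"
    pos_to_overall <- TRUE
  } else if (!position %in% c("overall", pem_positions())) {
    eff_pos <- "overall"
    pos_to_overall <- TRUE
  }
  row <- pem[pem$level == eff_level & pem$position == eff_pos &
               pem$metric == metric, , drop = FALSE]
  stopifnot(nrow(row) == 1)
  data.frame(
    value = row$value, n_total = row$n_total, n_studies = row$n_studies,
    imputed = row$imputed, mapped_from_level = mapped_from,
    position_mapped_to_overall = pos_to_overall,
    stringsAsFactors = FALSE
  )
}

## File formats --------------------------------------------------------------

#' Read and write PEM tables as CSV
#'
#' The on-disk format has one row per cell with columns \code{level},
#' \code{position}, \code{metric}, \code{value}, \code{n_total},
#' \code{n_studies}, \code{imputed}.  A blank \code{value} marks a cell
#' with no direct study data; it is imputed from the level overall row on
#' load.
#'
#' @param path Path to a CSV file.
#' @return \code{read_pem()} returns a \code{"pem"} object;
#'   \code{write_pem()} invisibly returns \code{path}.
#' @export
read_pem <- function(path) {
  if (!file.exists(path)) abort_io(paste0("PEM file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("level", "position", "metric", "value")
  if (!all(needed %in% names(df))) {
    abort_io(paste0("PEM file ", path, " lacks required columns: ",
                    paste(setdiff(needed, names(df)), collapse = ", ")))
  }
  if (!"n_total" %in% names(df)) df$n_total <- NA_real_
  if (!"n_studies" %in% names(df)) df$n_studies <- NA_real_
  df$value <- as.numeric(df$value)
  df$imputed <- if ("imputed" %in% names(df)) as.logical(df$imputed) else FALSE
  df$imputed[is.na(df$value)] <- TRUE
  new_pem(df[, c("level", "position", "metric", "value",
                 "n_total", "n_studies", "imputed")])
}

#' @param pem A \code{"pem"} object.
#' @rdname read_pem
#' @export
write_pem <- function(pem, path) {
  if (!inherits(pem, "pem")) abort_invalid("'pem' must be a pem object")
  utils::write.csv(as.data.frame(pem), path, row.names = FALSE, na = "")
  invisible(path)
}

#' The packaged football position-exposure matrix
#'
#' Loads the PEM of weighted average annual exposures aggregated from
#' published helmet-sensor studies of youth, high-school and collegiate
#' football, shipped with the package: average annual head-impact counts,
#' mean per-hit linear acceleration (g) and mean per-hit rotational
#' acceleration (rad/s^2) by level of play and position.  Cells the
#' literature does not cover (all youth position rows; a few collegiate
#' rotational cells) are imputed from the level's overall row and flagged.
#'
#' @return A \code{"pem"} object.
#' @export
#' @examples
#' pem <- football_pem()
#' pem_lookup(pem, "high_school", "LB", "hits_per_season")$value # 460.2
football_pem <- function() {
  path <- system.file("extdata", "football_pem.csv", package = "rhipem")
  if (!nzchar(path)) abort_io("packaged PEM fixture not found")
  read_pem(path)
}
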