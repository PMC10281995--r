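## Cumulative head impact indices (CHII, CHII-G, CHII-R) and NFT burden.
##
## For a career of y seasons, with h_n the PEM annual hit count, g_n the
## mean per-hit linear acceleration and r_n the mean per-hit rotational
## acceleration for the level and position played in season n:
##   CHII   = sum_n h_n          (estimated lifetime head impacts)
##   CHII-G = sum_n h_n * g_n    (estimated lifetime cumulative g-force)
##   CHII-R = sum_n h_n * r_n    (estimated lifetime rad/s^2)
## A season played at two positions contributes the mean of the two
## per-position annual indices.

#' Validate a career history
#'
#' A career history is an ordered table of seasons, one row per season,
#' each with a level of play and one or two positions.
#'
#' @param career Data frame with columns \code{season_order} (1..y,
#'   consecutive), \code{level} and \code{position1}; optionally
#'   \code{position2} (blank or \code{NA} for single-position seasons) and
#'   \code{donor_id}.
#' @return The validated data frame with class \code{"career_history"}.
#'   Zero-row input is allowed (an empty career).
#' @export
career_history <- function(career) {
  if (!is.data.frame(career)) abort_invalid("'career' must be a data frame")
  if (nrow(career) == 0) {
    for (col in c("season_order", "level", "position1", "position2")) {
      if (!col %in% names(career)) career[[col]] <- character(0)
    }
    class(career) <- c("career_history", class(career))
    return(career)
  }
  needed <- c("season_order", "level", "position1")
  miss <- setdiff(needed, names(career))
  if (length(miss)) {
    abort_invalid(paste0("career is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!"position2" %in% names(career)) career$position2 <- NA_character_
  career$position2[!is.na(career$position2) & !nzchar(career$position2)] <- NA_character_
  ord <- sort(career$season_order)
  if (!identical(as.integer(ord), seq_len(nrow(career)))) {
    abort_invalid("season_order must be the consecutive integers 1..y")
  }
  bad <- !career$level %in% lookup_levels()
  if (any(bad)) {
    abort_invalid(paste0("unrecognized level token in season(s) ",
                         paste(career$season_order[bad], collapse = ", "),
                         ": ", paste(unique(career$level[bad]), collapse = ", ")))
  }
  if (any(is.na(career$position1) | !nzchar(career$position1))) {
    abort_invalid("every season needs at least one position (use 'unknown' if unrecorded)")
  }
  career <- career[order(career$season_order), , drop = FALSE]
  rownames(career) <- NULL
  class(career) <- unique(c("career_history", class(career)))
  career
}

## Resolved per-(level, position) annual values for fast vectorized lookup.
## Returns a data.frame keyed by "level|position" over all recognized
## levels x (positions + overall + unknown).
pem_resolution_table <- function(pem) {
  combos <- expand.grid(
    level = lookup_levels(),
    position = c("overall", pem_positions(), "unknown"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(combos)), function(i) {
    h <- pem_lookup(pem, combos$level[i], combos$position[i], "hits_per_season")
    g <- pem_lookup(pem, combos$level[i], combos$position[i], "linear_accel")
    r <- pem_lookup(pem, combos$level[i], combos$position[i], "rotational_accel")
    data.frame(
      hits = h$value, lin = g$value, rot = r$value,
      any_imputed = h$imputed | g$imputed | r$imputed,
      mapped = !is.na(h$mapped_from_level),
      pos_overall = h$position_mapped_to_overall
    )
  })
  out <- cbind(combos, do.call(rbind, res))
  rownames(out) <- paste(out$level, out$position, sep = "|")
  out
}

#' Annual exposure for one season
#'
#' The annual index for a season is formed per position first (hits;
#' hits x linear acceleration; hits x rotational acceleration) and then
#' averaged over the season's one or two positions.
#'
#' @param level Level token (see [pem_lookup()] for the mapping rules).
#' @param positions Character vector of 1--2 position codes (more are
#'   accepted with a warning and averaged equally).
#' @param pem A \code{"pem"} object.
#' @param metric One of \code{"hits_per_season"}, \code{"linear_accel"},
#'   \code{"rotational_accel"}.  For the two intensity metrics the value
#'   returned is the intensity-weighted annual index (hits x intensity),
#'   not the bare per-hit intensity.
#' @return A nonnegative scalar.
#' @export
#' @examples
#' pem <- football_pem()
#' annual_exposure("high_school", "LB", pem, "hits_per_season")      # 460.2
#' annual_exposure("high_school", c("LB", "DL"), pem, "hits_per_season") # 621.25
annual_exposure <- function(level, positions, pem, metric) {
  if (length(positions) == 0) abort_invalid("at least one position is required")
  if (length(positions) > 2) {
    warning("season lists more than 2 positions; averaging over all of them")
  }
  per_pos <- vapply(positions, function(p) {
    h <- pem_lookup(pem, level, p, "hits_per_season")$value
    if (metric == "hits_per_season") return(h)
    h * pem_lookup(pem, level, p, metric)$value
  }, 0)
  mean(per_pos)
}

#' Cumulative head impact indices for one career
#'
#' Sums the per-season annual indices over a career to produce the
#' lifetime cumulative head impact index (CHII, hits), cumulative linear
#' acceleration (CHII-G, summed g-force) and cumulative rotational
#' acceleration (CHII-R, summed rad/s^2), together with the scaled views
#' used for reporting effect sizes (per 1,000 hits, per 10,000 g, per
#' 1,000,000 rad/s^2).
#'
#' @param career A [career_history()] table (or data frame coercible to one).
#' @param pem A \code{"pem"} object.
#' @return A list of class \code{"exposure_indices"} with elements
#'   \code{chii}, \code{chii_g}, \code{chii_r}, the scaled views
#'   \code{chii_per_1000}, \code{chii_g_per_10000}, \code{chii_r_per_1e6},
#'   \code{n_seasons}, and provenance counts
#'   \code{n_imputed_cells_used}, \code{n_mapped_seasons}.
#' @export
#' @examples
#' pem <- football_pem()
#' career <- data.frame(
#'   season_order = 1:3,
#'   level = c("high_school", "high_school", "college"),
#'   position1 = c("LB", "DL", "DL")
#' )
#' compute_indices(career, pem)$chii  # 2083.4
compute_indices <- function(career, pem) {
  career <- career_history(as.data.frame(career))
  if (nrow(career) == 0) {
    return(structure(list(chii = 0, chii_g = 0, chii_r = 0,
                          chii_per_1000 = 0, chii_g_per_10000 = 0,
                          chii_r_per_1e6 = 0, n_seasons = 0L,
                          n_imputed_cells_used = 0L, n_mapped_seasons = 0L),
                     class = "exposure_indices"))
  }
  res <- pem_resolution_table(pem)
  season_vals <- function(metric_col) {
    vapply(seq_len(nrow(career)), function(i) {
      positions <- c(career$position1[i], career$position2[i])
      positions <- positions[!is.na(positions)]
      keys <- paste(career$level[i],
                    ifelse(positions %in% c(pem_positions(), "overall"),
                           positions, "unknown"), sep = "|")
      if (metric_col == "hits") mean(res[keys, "hits"])
      else mean(res[keys, "hits"] * res[keys, metric_col])
    }, 0)
  }
  chii <- sum(season_vals("hits"))
  chii_g <- sum(season_vals("lin"))
  chii_r <- sum(season_vals("rot"))

  prov_keys <- unlist(lapply(seq_len(nrow(career)), function(i) {
    positions <- c(career$position1[i], career$position2[i])
    positions <- positions[!is.na(positions)]
    paste(career$level[i],
          ifelse(positions %in% c(pem_positions(), "overall"),
                 positions, "unknown"), sep = "|")
  }))
  structure(list(
    chii = chii, chii_g = chii_g, chii_r = chii_r,
    chii_per_1000 = chii / 1000,
    chii_g_per_10000 = chii_g / 10000,
    chii_r_per_1e6 = chii_r / 1e6,
    n_seasons = nrow(career),
    n_imputed_cells_used = sum(res[prov_keys, "any_imputed"]),
    n_mapped_seasons = sum(vapply(seq_len(nrow(career)), function(i) {
      res[paste(career$level[i], "overall", sep = "|"), "mapped"]
    }, FALSE))
  ), class = "exposure_indices")
}

#' @export
print.exposure_indices <- function(x, ...) {
  cat(sprintf(
    "Cumulative exposure over %d season(s):\n  CHII   %12.1f hits\n  CHII-G %12.1f g (summed)\n  CHII-R %12.1f rad/s^2 (summed)\n",
    x$n_seasons, x$chii, x$chii_g, x$chii_r))
  invisible(x)
}

#' Cumulative exposure indices for a cohort of careers
#'
#' @param careers Data frame with one row per (donor, season): columns
#'   \code{donor_id}, \code{season_order}, \code{level}, \code{position1},
#'   optionally \code{position2}.
#' @param pem A \code{"pem"} object.
#' @return Data frame with one row per donor: the three indices, their
#'   scaled views, \code{n_seasons} and \code{n_imputed_cells_used}.
#'   Donors appear in order of first appearance in \code{careers}.
#' @export
compute_indices_cohort <- function(careers, pem) {
  if (nrow(careers) == 0) {
    return(data.frame(donor_id = character(0), chii = numeric(0),
                      chii_g = numeric(0), chii_r = numeric(0),
                      chii_per_1000 = numeric(0), chii_g_per_10000 = numeric(0),
                      chii_r_per_1e6 = numeric(0), n_seasons = integer(0),
                      n_imputed_cells_used = integer(0)))
  }
  if (!"donor_id" %in% names(careers)) abort_invalid("'careers' needs a donor_id column")
  if (!"position2" %in% names(careers)) careers$position2 <- NA_character_
  careers$position2[!is.na(careers$position2) & !nzchar(careers$position2)] <- NA_character_
  bad <- !careers$level %in% lookup_levels()
  if (any(bad)) {
    abort_invalid(paste0("unrecognized level token for donor(s) ",
                         paste(unique(careers$donor_id[bad]), collapse = ", ")))
  }
  res <- pem_resolution_table(pem)
  norm_pos <- function(p) ifelse(is.na(p), NA_character_,
                                 ifelse(p %in% c(pem_positions(), "overall"), p, "unknown"))
  k1 <- paste(careers$level, norm_pos(careers$position1), sep = "|")
  k2 <- ifelse(is.na(careers$position2), NA_character_,
               paste(careers$level, norm_pos(careers$position2), sep = "|"))
  two <- !is.na(k2)
  row_metric <- function(col) {
    v1 <- if (col == "hits") res[k1, "hits"] else res[k1, "hits"] * res[k1, col]
    v2 <- rep(NA_real_, length(k2))
    v2[two] <- if (col == "hits") res[k2[two], "hits"] else res[k2[two], "hits"] * res[k2[two], col]
    ifelse(two, (v1 + v2) / 2, v1)
  }
  hits <- row_metric("hits"); lin <- row_metric("lin"); rot <- row_metric("rot")
  imput <- res[k1, "any_imputed"] + ifelse(two, res[k2, "any_imputed"], 0)

  ids <- unique(careers$donor_id)
  f <- factor(careers$donor_id, levels = ids)
  out <- data.frame(
    donor_id = ids,
    chii = as.numeric(tapply(hits, f, sum)),
    chii_g = as.numeric(tapply(lin, f, sum)),
    chii_r = as.numeric(tapply(rot, f, sum)),
    n_seasons = as.integer(tapply(hits, f, length)),
    n_imputed_cells_used = as.integer(tapply(imput, f, sum)),
    stringsAsFactors = FALSE
  )
  out$chii_per_1000 <- out$chii / 1000
  out$chii_g_per_10000 <- out$chii_g / 10000
  out$chii_r_per_1e6 <- out$chii_r / 1e6
  out[, c("donor_id", "chii", "chii_g", "chii_r", "chii_per_1000",
          "chii_g_per_10000", "chii_r_per_1e6", "n_seasons",
          "n_imputed_cells_used")]
}

#' NFT burden sum over the 11-region panel
#'
#' Sums semi-quantitative neurofibrillary-tangle scores (0--3) across the
#' 11 brain regions implicated in CTE (see [nft_regions()]).  Following
#' the complete-case rule, the sum is only defined when every region was
#' evaluated: any missing region yields \code{NA}, signalling that the
#' donor is excluded from NFT-burden models (no imputation).
#'
#' @param panel Named numeric vector or one-row data frame with one entry
#'   per region in [nft_regions()]; \code{NA} marks a missing region.
#' @return Integer 0--33, or \code{NA} when any region is missing.
#' @export
#' @examples
#' p <- setNames(rep(3, 11), nft_regions())
#' nft_burden(p)  # 33
#' p["CA1"] <- NA
#' nft_burden(p)  # NA
nft_burden <- function(panel) {
  if (is.data.frame(panel)) panel <- unlist(panel[1, , drop = TRUE])
  miss <- setdiff(nft_regions(), names(panel))
  if (length(miss)) {
    abort_invalid(paste0("panel lacks region(s): ", paste(miss, collapse = ", ")))
  }
  scores <- as.numeric(panel[nft_regions()])
  ok <- !is.na(scores)
  if (any(!scores[ok] %in% 0:3)) {
    abort_invalid("NFT scores must be integers in 0..3")
  }
  if (!all(ok)) return(NA_integer_)
  as.integer(sum(scores))
}

## Careers / indices file formats -------------------------------------------

#' Read a cohort careers table from CSV
#'
#' Expected columns: \code{donor_id}, \code{season_order}, \code{level},
#' \code{position1}, \code{position2} (blank allowed); one row per season.
#'
#' @param path CSV path.
#' @return Data frame of seasons.
#' @export
read_careers <- function(path) {
  if (!file.exists(path)) abort_io(paste0("careers file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(donor_id = "character"))
  needed <- c("donor_id", "season_order", "level", "position1")
  if (!all(needed %in% names(df))) {
    abort_io(paste0("careers file lacks columns: ",
                    paste(setdiff(needed, names(df)), collapse = ", ")))
  }
  if (!"position2" %in% names(df)) df$position2 <- NA_character_
  df$position2[!is.na(df$position2) & !nzchar(df$position2)] <- NA_character_
  df
}
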