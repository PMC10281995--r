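## Seeded synthetic data: helmet-sensor study sets and brain-donor cohorts.
##
## Analyses of this kind run on restricted brain-bank data; these
## generators produce cohorts with the same statistical structure so every
## downstream stage is testable.  Each concern (study values, careers,
## outcomes, NFT panels, concussions, missingness) draws from its own
## named RNG stream derived from the master seed, so toggling one feature
## does not shift the others.

## truncated-normal draws via inverse CDF, vectorized
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Parameters for simulating a helmet-sensor study literature
#'
#' @param target_pem A \code{"pem"} object whose directly-pooled (non
#'   imputed) cells define the true per-cell exposures.
#' @param studies_per_cell Number of simulated studies per cell.
#' @param sample_size_range Integer interval (length 2) for per-study
#'   athlete counts.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   on study central values around the target cell (0 = exact).
#' @param seed Integer master seed.
#' @return A list of class \code{"study_sim_params"}.
#' @export
study_sim_params <- function(target_pem, studies_per_cell = 3,
                             sample_size_range = c(20, 80),
                             noise_cv = 0.1, seed = 1) {
  if (!inherits(target_pem, "pem")) abort_invalid("'target_pem' must be a pem object")
  if (studies_per_cell < 1) abort_invalid("studies_per_cell must be >= 1")
  if (noise_cv < 0) abort_invalid("noise_cv must be >= 0")
  if (length(sample_size_range) != 2 || sample_size_range[1] > sample_size_range[2] ||
      sample_size_range[1] < 1) {
    abort_invalid("sample_size_range must be a nonempty positive interval")
  }
  structure(list(target_pem = target_pem, studies_per_cell = studies_per_cell,
                 sample_size_range = sample_size_range, noise_cv = noise_cv,
                 seed = seed), class = "study_sim_params")
}

#' Simulate study-level helmet-sensor summaries around a target PEM
#'
#' For every directly-pooled cell of the target matrix, emits
#' \code{studies_per_cell} study records with central values drawn around
#' the target (multiplicative Gaussian noise with the given coefficient
#' of variation, truncated positive) and sample sizes uniform on the
#' configured range.  With \code{noise_cv = 0}, [build_pem()] on the
#' result reproduces the target matrix.
#'
#' @param params A [study_sim_params()] object.
#' @return A \code{study_records} table.
#' @export
simulate_studies <- function(params) {
  stopifnot(inherits(params, "study_sim_params"))
  pem <- params$target_pem
  cells <- as.data.frame(pem)[!pem$imputed, , drop = FALSE]
  k <- params$studies_per_cell
  with_seed(derive_seed(params$seed, "studies"), {
    n_rec <- nrow(cells) * k
    rows <- cells[rep(seq_len(nrow(cells)), each = k), , drop = FALSE]
    noise <- if (params$noise_cv == 0) rep(1, n_rec) else {
      pmax(1e-6, stats::rnorm(n_rec, 1, params$noise_cv))
    }
    out <- data.frame(
      study_id = sprintf("sim%04d", seq_len(n_rec)),
      level = rows$level,
      position_scope = rows$position,
      group_members = "",
      metric = rows$metric,
      central_value = rows$value * noise,
      central_kind = "mean",
      sample_size = sample(seq(params$sample_size_range[1],
                               params$sample_size_range[2]),
                           n_rec, replace = TRUE),
      min_threshold_g = 10,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    study_records(out)
  })
}

#' Parameters for simulating a brain-donor cohort
#'
#' Defaults emulate the structure of a football brain-donor case series:
#' age of first exposure averaging 11.3 years (SD 3.4, at least 5),
#' career duration averaging 12.5 years (SD 5.9, at least 1 season),
#' age at death averaging about 59.7 years (SD 20.1, within 13--100 and
#' never before the end of the career), heavy-tailed informant-reported
#' concussion counts (median 20), roughly 18% of donors missing at least
#' one NFT region, and CTE status/severity following age-adjusted
#' logistic models in years of play with odds ratios near 1.15 and 1.14
#' per year.  Location parameters are for the underlying (pre-truncation)
#' normals, chosen so the realized truncated means hit the targets.
#'
#' @param n_donors Number of donors.
#' @param seed Integer master seed.
#' @param age_first_mean,age_first_sd,age_first_min Underlying normal for
#'   age of first exposure (years), truncated at \code{age_first_min}.
#' @param duration_mean,duration_sd,duration_min Underlying normal for
#'   career duration (seasons), truncated at \code{duration_min}.
#' @param age_death_mean,age_death_sd,age_death_range Underlying normal
#'   for age at death (years), truncated to \code{age_death_range} and
#'   floored at the age the career ended.
#' @param p_advance_college,p_advance_professional,p_semi_professional
#'   Level-progression stops: probability of advancing past high school,
#'   of advancing past college, and (among the latter) of topping out at
#'   semi-professional rather than professional play.
#' @param position_probs Named probabilities over the eight position
#'   codes for the donor's primary position.
#' @param p_two_positions Per-season probability of playing a second
#'   position.
#' @param beta0_status,beta_exp_status,beta_age_status CTE-status
#'   logistic model: intercept, log-odds per year of play, log-odds per
#'   year of age at death.
#' @param beta0_severity,beta_exp_severity,beta_age_severity Same for the
#'   severity (high vs low stage) model among CTE-positive donors.
#' @param nft_intercept,nft_beta_duration,nft_beta_age,nft_sd Linear
#'   model for the NFT burden sum (0--33) before rounding/clipping.
#' @param concussion_meanlog,concussion_sdlog Lognormal informant
#'   concussion counts.
#' @param p_missing_region Per-donor probability of missing at least one
#'   NFT region; when missing, 1--3 random regions are lost.
#' @return A list of class \code{"cohort_params"}.
#' @export
cohort_params <- function(n_donors, seed = 1,
                          age_first_mean = 11.0, age_first_sd = 3.4,
                          age_first_min = 5,
                          duration_mean = 12.1, duration_sd = 5.9,
                          duration_min = 1,
                          age_death_mean = 60.0, age_death_sd = 20.1,
                          age_death_range = c(13, 100),
                          p_advance_college = 0.95,
                          p_advance_professional = 0.92,
                          p_semi_professional = 0.087,
                          position_probs = c(DB = 60, DL = 86, LB = 73,
                                             OL = 98, QB = 30, RB = 72,
                                             TE = 25, WR = 20) / 464,
                          p_two_positions = 0.25,
                          beta0_status = -2.47,
                          beta_exp_status = log(1.15),
                          beta_age_status = 0.03,
                          beta0_severity = -3.9,
                          beta_exp_severity = log(1.14),
                          beta_age_severity = 0.05,
                          nft_intercept = -2.8,
                          nft_beta_duration = 0.47,
                          nft_beta_age = 0.15,
                          nft_sd = 6,
                          concussion_meanlog = log(20),
                          concussion_sdlog = 1.8,
                          p_missing_region = 0.18) {
  if (n_donors < 0) abort_invalid("n_donors must be >= 0")
  if (any(c(p_advance_college, p_advance_professional, p_semi_professional,
            p_two_positions, p_missing_region) < 0 |
          c(p_advance_college, p_advance_professional, p_semi_professional,
            p_two_positions, p_missing_region) > 1)) {
    abort_invalid("probabilities must lie in [0, 1]")
  }
  if (any(c(age_first_sd, duration_sd, age_death_sd, nft_sd,
            concussion_sdlog) <= 0)) {
    abort_invalid("standard deviations must be positive")
  }
  if (abs(sum(position_probs) - 1) > 1e-8 ||
      !setequal(names(position_probs), pem_positions())) {
    abort_invalid("position_probs must be a probability vector over the 8 position codes")
  }
  structure(as.list(environment()), class = "cohort_params")
}

level_rank <- function(levels) {
  unname(c(youth = 1, high_school = 2, college = 3,
           semi_professional = 4, professional = 5)[levels])
}

rank_level <- function(rank) {
  c("youth", "high_school", "college", "semi_professional", "professional")[rank]
}

#' Simulate season-by-season career histories
#'
#' Draws, for each donor, an age of first exposure and a career duration
#' (truncated normals), assigns each season a level of play from the
#' donor's age that year (under 14 youth, 14--17 high school, 18--21
#' college, 22 and older professional) capped at the donor's attained
#' highest level drawn from the progression stops, and samples one or
#' two positions per season around a donor-level primary position.
#'
#' @param params A [cohort_params()] object.
#' @return A list with \code{careers} (one row per donor-season:
#'   \code{donor_id}, \code{season_order}, \code{level}, \code{position1},
#'   \code{position2}) and \code{donors} (one row per donor:
#'   \code{donor_id}, \code{age_first_exposure}, \code{duration},
#'   \code{highest_level}, \code{primary_position_at_highest_level},
#'   \code{speed_flag}).
#' @export
simulate_careers <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_donors
  empty <- list(
    careers = data.frame(donor_id = character(0), season_order = integer(0),
                         level = character(0), position1 = character(0),
                         position2 = character(0), stringsAsFactors = FALSE),
    donors = data.frame(donor_id = character(0), age_first_exposure = integer(0),
                        duration = integer(0), highest_level = character(0),
                        primary_position_at_highest_level = character(0),
                        speed_flag = character(0), stringsAsFactors = FALSE)
  )
  if (n == 0) return(empty)
  with_seed(derive_seed(params$seed, "careers"), {
    age_first <- round(rtnorm(n, params$age_first_mean, params$age_first_sd,
                              lower = params$age_first_min))
    duration <- round(rtnorm(n, params$duration_mean, params$duration_sd,
                             lower = params$duration_min))
    duration <- pmax(duration, params$duration_min)

    adv_col <- stats::runif(n) < params$p_advance_college
    adv_pro <- stats::runif(n) < params$p_advance_professional
    semi <- stats::runif(n) < params$p_semi_professional
    cap <- ifelse(!adv_col, 2L,
                  ifelse(!adv_pro, 3L, ifelse(semi, 4L, 5L)))

    primary <- sample(names(params$position_probs), n, replace = TRUE,
                      prob = params$position_probs)

    donor_id <- sprintf("D%05d", seq_len(n))
    idx <- rep(seq_len(n), duration)
    season_order <- sequence(duration)
    age <- age_first[idx] + season_order - 1L
    bracket <- ifelse(age < 14, 1L, ifelse(age < 18, 2L, ifelse(age < 22, 3L, 5L)))
    realized <- pmin(bracket, cap[idx])
    level <- rank_level(realized)

    pos1 <- primary[idx]
    n_rows <- length(idx)
    has2 <- stats::runif(n_rows) < params$p_two_positions
    other <- vapply(pos1[has2], function(p) {
      sample(setdiff(pem_positions(), p), 1)
    }, "")
    pos2 <- rep(NA_character_, n_rows)
    pos2[has2] <- other

    careers <- data.frame(donor_id = donor_id[idx], season_order = season_order,
                          level = level, position1 = pos1, position2 = pos2,
                          stringsAsFactors = FALSE)
    highest <- rank_level(as.integer(tapply(realized, factor(idx, seq_len(n)), max)))
    donors <- data.frame(
      donor_id = donor_id,
      age_first_exposure = as.integer(age_first),
      duration = as.integer(duration),
      highest_level = highest,
      primary_position_at_highest_level = primary,
      speed_flag = ifelse(primary %in% non_speed_positions(),
                          "non_speed", "speed"),
      stringsAsFactors = FALSE
    )
    list(careers = careers, donors = donors)
  })
}

## split a burden sum uniformly over 11 regions capped at 3 each:
## choose `burden` of the 33 available score units at random
decompose_burden <- function(burden) {
  counts <- tabulate(sample(rep(seq_len(11), 3), burden), nbins = 11)
  names(counts) <- nft_regions()
  counts
}

#' Simulate a brain-donor cohort
#'
#' Generates careers via [simulate_careers()], computes the three
#' cumulative exposure indices against the supplied PEM, then draws CTE
#' status from an age-adjusted logistic model in years of play, CTE
#' stage (low/high) among CTE-positive donors from a second logistic,
#' an NFT burden sum linear in years of play and age (Gaussian noise,
#' rounded and clipped to 0--33, decomposed uniformly over the 11-region
#' panel), lognormal informant concussion counts, and per-donor region
#' missingness.  Fully reproducible from the seed in \code{params}.
#'
#' @param params A [cohort_params()] object.
#' @param pem A \code{"pem"} object used for the exposure indices.
#' @return A list of class \code{"donor_cohort"} with \code{donors} (one
#'   row per donor: covariates, outcomes and exposure indices),
#'   \code{careers}, and \code{nft} (11 region columns, \code{NA} =
#'   missing).
#' @export
simulate_cohort <- function(params, pem) {
  stopifnot(inherits(params, "cohort_params"))
  if (!inherits(pem, "pem")) abort_invalid("'pem' must be a pem object")
  n <- params$n_donors
  cc <- simulate_careers(params)
  donors <- cc$donors
  if (n == 0) {
    nft <- as.data.frame(matrix(integer(0), nrow = 0, ncol = 11,
                                dimnames = list(NULL, nft_regions())))
    nft <- cbind(data.frame(donor_id = character(0)), nft)
    donors$age_at_death <- numeric(0); donors$cte_status <- character(0)
    donors$cte_stage <- character(0); donors$concussion_count <- integer(0)
    donors$nft_burden <- integer(0)
    return(structure(list(donors = donors, careers = cc$careers, nft = nft,
                          params = params), class = "donor_cohort"))
  }
  idx <- compute_indices_cohort(cc$careers, pem)
  donors <- merge(donors, idx, by = "donor_id", sort = FALSE)
  donors <- donors[order(donors$donor_id), ]
  rownames(donors) <- NULL

  last_age <- donors$age_first_exposure + donors$duration - 1

  with_seed(derive_seed(params$seed, "outcomes"), {
    donors$age_at_death <- pmax(
      rtnorm(n, params$age_death_mean, params$age_death_sd,
             lower = params$age_death_range[1],
             upper = params$age_death_range[2]),
      last_age)
    donors$age_at_death <- round(donors$age_at_death, 1)

    p_cte <- stats::plogis(params$beta0_status +
                             params$beta_exp_status * donors$duration +
                             params$beta_age_status * donors$age_at_death)
    cte <- stats::rbinom(n, 1, p_cte) == 1
    donors$cte_status <- ifelse(cte, "present", "absent")

    p_high <- stats::plogis(params$beta0_severity +
                              params$beta_exp_severity * donors$duration +
                              params$beta_age_severity * donors$age_at_death)
    high <- stats::rbinom(n, 1, p_high) == 1
    donors$cte_stage <- ifelse(cte, ifelse(high, "high", "low"), NA_character_)
  })

  nft_mat <- with_seed(derive_seed(params$seed, "nft"), {
    mu <- params$nft_intercept +
      params$nft_beta_duration * donors$duration +
      params$nft_beta_age * donors$age_at_death
    burden <- pmin(33, pmax(0, round(stats::rnorm(n, mu, params$nft_sd))))
    t(vapply(burden, decompose_burden, integer(11)))
  })

  donors$concussion_count <- with_seed(derive_seed(params$seed, "concussions"), {
    as.integer(round(stats::rlnorm(n, params$concussion_meanlog,
                                   params$concussion_sdlog)))
  })

  nft_mat <- with_seed(derive_seed(params$seed, "missingness"), {
    lose <- stats::runif(n) < params$p_missing_region
    for (i in which(lose)) {
      k <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
      nft_mat[i, sample(11, k)] <- NA_integer_
    }
    nft_mat
  })

  donors$nft_burden <- ifelse(rowSums(is.na(nft_mat)) > 0, NA_integer_,
                              as.integer(rowSums(nft_mat)))
  nft <- cbind(data.frame(donor_id = donors$donor_id, stringsAsFactors = FALSE),
               as.data.frame(nft_mat))
  structure(list(donors = donors, careers = cc$careers, nft = nft,
                 params = params), class = "donor_cohort")
}

#' @export
print.donor_cohort <- function(x, ...) {
  n <- nrow(x$donors)
  cat("Synthetic donor cohort:", n, "donors,",
      nrow(x$careers), "donor-seasons\n")
  if (n > 0) {
    cat(sprintf("  CTE prevalence %.2f; mean duration %.1f seasons; mean age at death %.1f\n",
                mean(x$donors$cte_status == "present"),
                mean(x$donors$duration), mean(x$donors$age_at_death)))
  }
  invisible(x)
}

#' Write / read a cohort bundle as CSV files
#'
#' \code{write_cohort()} writes \code{donors.csv}, \code{careers.csv} and
#' \code{nft.csv} into \code{dir}, plus a \code{params.yaml} sidecar
#' echoing the generator parameters and seed so the bundle can be
#' regenerated byte-identically.  \code{read_cohort()} reads the bundle
#' back.
#'
#' @param cohort A \code{"donor_cohort"} object.
#' @param dir Output directory (created if needed).
#' @return \code{write_cohort()} invisibly returns \code{dir};
#'   \code{read_cohort()} returns a \code{"donor_cohort"} list (without
#'   generator parameters unless the sidecar is present).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "donor_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$donors, file.path(dir, "donors.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$careers, file.path(dir, "careers.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$nft, file.path(dir, "nft.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$params)) {
    p <- cohort$params
    p$position_probs <- as.list(p$position_probs)
    ## full precision so a sidecar-driven rerun is bit-identical
    yaml::write_yaml(unclass(p), file.path(dir, "params.yaml"),
                     precision = 17)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, c("donors.csv", "careers.csv", "nft.csv"))
  if (!all(file.exists(paths))) {
    abort_io(paste0("cohort bundle incomplete in ", dir,
                    " (need donors.csv, careers.csv, nft.csv)"))
  }
  donors <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  careers <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  nft <- utils::read.csv(paths[3], stringsAsFactors = FALSE, check.names = FALSE)
  params <- NULL
  side <- file.path(dir, "params.yaml")
  if (file.exists(side)) {
    params <- yaml::read_yaml(side)
    params$position_probs <- unlist(params$position_probs)
    class(params) <- "cohort_params"
  }
  structure(list(donors = donors, careers = careers, nft = nft,
                 params = params), class = "donor_cohort")
}
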