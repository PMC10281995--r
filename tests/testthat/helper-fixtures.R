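# Shared builders for toy study sets, careers and donor tables.

# Minimal record set covering every (level, metric) overall pool, so toy
# tests can add position-level records without tripping the missing-pool
# check.
base_overall_records <- function(value = 50, n = 5) {
  grid <- expand.grid(level = pem_levels(), metric = pem_metrics(),
                      stringsAsFactors = FALSE)
  data.frame(
    study_id = paste0("base", seq_len(nrow(grid))),
    level = grid$level, position_scope = "overall", group_members = "",
    metric = grid$metric, central_value = value, central_kind = "mean",
    sample_size = n, stringsAsFactors = FALSE
  )
}

toy_record <- function(study_id, level, scope, metric, value, n,
                       members = "") {
  data.frame(study_id = study_id, level = level, position_scope = scope,
             group_members = members, metric = metric, central_value = value,
             central_kind = "mean", sample_size = n, stringsAsFactors = FALSE)
}

# Independent pooled-mean oracle mirroring the documented build rule:
# position cells pool matching records; the overall cell uses
# overall-scoped records when any exist, otherwise pools everything at
# the level and metric.
oracle_cell <- function(records, level, position, metric) {
  records <- expand_groups(study_records(records))
  sel <- which(records$level == level & records$metric == metric &
                 records$position_scope == position)
  if (position == "overall" && length(sel) == 0) {
    sel <- which(records$level == level & records$metric == metric)
  }
  if (length(sel) == 0) return(NA_real_)
  num <- 0; den <- 0
  for (i in sel) {
    num <- num + records$sample_size[i] * records$central_value[i]
    den <- den + records$sample_size[i]
  }
  num / den
}

# Brute-force exposure-index oracle: explicit loop over seasons and
# positions using pem_lookup() only.
oracle_indices <- function(career, pem) {
  chii <- 0; chii_g <- 0; chii_r <- 0
  for (i in seq_len(nrow(career))) {
    positions <- c(career$position1[i], career$position2[i])
    positions <- positions[!is.na(positions) & nzchar(positions)]
    h <- g <- r <- numeric(0)
    for (p in positions) {
      hv <- pem_lookup(pem, career$level[i], p, "hits_per_season")$value
      h <- c(h, hv)
      g <- c(g, hv * pem_lookup(pem, career$level[i], p, "linear_accel")$value)
      r <- c(r, hv * pem_lookup(pem, career$level[i], p, "rotational_accel")$value)
    }
    chii <- chii + mean(h); chii_g <- chii_g + mean(g); chii_r <- chii_r + mean(r)
  }
  list(chii = chii, chii_g = chii_g, chii_r = chii_r)
}

# Random career generator for property tests.
random_career <- function(n_seasons, seed) {
  set.seed(seed)
  pos_pool <- c(pem_positions(), "unknown")
  pos1 <- sample(pos_pool, n_seasons, replace = TRUE)
  pos2 <- ifelse(runif(n_seasons) < 0.4,
                 sample(pos_pool, n_seasons, replace = TRUE), NA_character_)
  data.frame(
    season_order = seq_len(n_seasons),
    level = sample(c("youth", "high_school", "college",
                     "semi_professional", "professional"),
                   n_seasons, replace = TRUE),
    position1 = pos1, position2 = pos2, stringsAsFactors = FALSE
  )
}

# All-pairs AUC oracle (ties count half).
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# Donor table for a 2x2 design: binary exposure coded through duration.
donors_2x2 <- function(a, b, c, d) {
  data.frame(
    cte_status = rep(c("present", "absent", "present", "absent"),
                     c(a, b, c, d)),
    duration = rep(c(1, 1, 0, 0), c(a, b, c, d)),
    age_at_death = 60,
    stringsAsFactors = FALSE
  )
}
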