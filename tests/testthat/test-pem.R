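# Position-exposure matrix construction: group expansion, sample-size
# weighted pooling, imputation, level mapping and the packaged fixture.

test_that("group records expand to one record per member position", {
  recs <- study_records(rbind(
    base_overall_records(),
    toy_record("grp", "high_school", "non-speed", "hits_per_season",
               800, 20, members = "OL;DL")
  ))
  out <- expand_groups(recs)
  grp <- out[out$study_id == "grp", ]
  expect_setequal(grp$position_scope, c("OL", "DL"))
  expect_equal(grp$central_value, c(800, 800))
  expect_equal(grp$sample_size, c(20, 20))
  expect_false(any(nzchar(out$group_members)))

  # no group records: identity
  plain <- study_records(base_overall_records())
  expect_equal(as.data.frame(expand_groups(plain)), as.data.frame(plain))

  # singleton group collapses to a single-position record
  single <- study_records(rbind(
    base_overall_records(),
    toy_record("s", "college", "lone", "hits_per_season", 300, 10,
               members = "LB")
  ))
  out2 <- expand_groups(single)
  expect_equal(out2$position_scope[out2$study_id == "s"], "LB")

  empty_members <- rbind(
    base_overall_records(),
    toy_record("e", "college", "grp", "hits_per_season", 300, 10,
               members = " ; ")
  )
  expect_error(expand_groups(empty_members), class = "rhipem_invalid_input")
})

test_that("cells are sample-size weighted means of contributing studies", {
  recs <- rbind(
    base_overall_records(),
    toy_record("a", "high_school", "LB", "hits_per_season", 100, 10),
    toy_record("b", "high_school", "LB", "hits_per_season", 200, 30)
  )
  pem <- build_pem(study_records(recs))
  cell <- pem_lookup(pem, "high_school", "LB", "hits_per_season")
  expect_equal(cell$value, 175)  # (100*10 + 200*30) / 40
  row <- as.data.frame(pem)
  row <- row[row$level == "high_school" & row$position == "LB" &
               row$metric == "hits_per_season", ]
  expect_equal(row$n_total, 40)
  expect_equal(row$n_studies, 2)

  # single study: cell equals the study value
  one <- rbind(base_overall_records(),
               toy_record("z", "college", "QB", "linear_accel", 23.4, 12))
  expect_equal(pem_lookup(build_pem(study_records(one)),
                          "college", "QB", "linear_accel")$value, 23.4)

  # cells without direct records impute the level overall value
  cell2 <- pem_lookup(pem, "high_school", "WR", "hits_per_season")
  expect_true(cell2$imputed)
  expect_equal(cell2$value, 50)  # base overall value
})

test_that("build_pem rejects empty input and names a missing pool", {
  expect_error(build_pem(data.frame()), class = "rhipem_invalid_input")
  partial <- base_overall_records()
  partial <- partial[!(partial$level == "college" &
                         partial$metric == "rotational_accel"), ]
  err <- expect_error(build_pem(study_records(partial)),
                      class = "rhipem_build_error")
  expect_match(conditionMessage(err), "college")
  expect_match(conditionMessage(err), "rotational_accel")
})

test_that("pooling invariants hold and match a brute-force oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n_extra <- sample(1:10, 1)
    extra <- do.call(rbind, lapply(seq_len(n_extra), function(i) {
      toy_record(paste0("r", i),
                 sample(c("high_school", "college"), 1),
                 sample(c(pem_positions(), "overall"), 1),
                 sample(pem_metrics(), 1),
                 runif(1, 10, 2000), sample(1:500, 1))
    }))
    recs <- rbind(base_overall_records(runif(1, 10, 100)), extra)
    pem <- build_pem(study_records(recs))
    df <- as.data.frame(pem)
    for (j in sample(nrow(df), 8)) {
      expected <- oracle_cell(recs, df$level[j], df$position[j], df$metric[j])
      if (is.na(expected)) next  # imputed cell
      expect_equal(df$value[j], expected, tolerance = 1e-12)
    }
    # weighted mean bounded by contributing values
    for (j in which(!df$imputed)) {
      sub <- expand_groups(study_records(recs))
      sel <- sub$level == df$level[j] & sub$metric == df$metric[j] &
        sub$position_scope == df$position[j]
      if (df$position[j] == "overall" && !any(sel)) {
        sel <- sub$level == df$level[j] & sub$metric == df$metric[j]
      }
      vals <- sub$central_value[sel]
      expect_gte(df$value[j], min(vals) - 1e-9)
      expect_lte(df$value[j], max(vals) + 1e-9)
    }
  }
})

test_that("cell values are invariant to rescaling all sample sizes", {
  recs <- rbind(
    base_overall_records(),
    toy_record("a", "high_school", "LB", "hits_per_season", 120, 7),
    toy_record("b", "high_school", "LB", "hits_per_season", 340, 13)
  )
  scaled <- recs
  scaled$sample_size <- scaled$sample_size * 17
  p1 <- build_pem(study_records(recs))
  p2 <- build_pem(study_records(scaled))
  expect_equal(p1$value, p2$value, tolerance = 1e-12)

  # identical-value pool collapses to that value exactly
  same <- rbind(base_overall_records(),
                toy_record("x", "college", "TE", "hits_per_season", 77.7, 3),
                toy_record("y", "college", "TE", "hits_per_season", 77.7, 91))
  expect_identical(pem_lookup(build_pem(study_records(same)),
                              "college", "TE", "hits_per_season")$value, 77.7)
})

test_that("lookup is total and applies the level-mapping rules", {
  pem <- football_pem()
  for (level in c("youth", "high_school", "college",
                  "semi_professional", "professional")) {
    for (pos in c(pem_positions(), "overall", "kicker")) {
      for (metric in pem_metrics()) {
        cell <- pem_lookup(pem, level, pos, metric)
        expect_true(is.finite(cell$value) && cell$value > 0)
      }
    }
  }
  pro_dl <- pem_lookup(pem, "professional", "DL", "hits_per_season")
  expect_equal(pro_dl$value, 840.9)
  expect_equal(pro_dl$mapped_from_level, "professional")
  expect_equal(pem_lookup(pem, "youth", "LB", "hits_per_season")$value, 206.4)
  hs_lb <- pem_lookup(pem, "high_school", "LB", "hits_per_season")
  expect_equal(hs_lb$value, 460.2)
  expect_false(hs_lb$imputed)
  expect_error(pem_lookup(pem, "varsity", "LB", "hits_per_season"),
               class = "rhipem_invalid_input")
})

test_that("the packaged matrix carries the published cell values", {
  pem <- football_pem()
  expect_equal(pem_lookup(pem, "college", "DL", "linear_accel")$value, 21.0)
  expect_equal(pem_lookup(pem, "high_school", "WR", "rotational_accel")$value,
               2223.8)
  wr_rot <- pem_lookup(pem, "college", "WR", "rotational_accel")
  expect_true(wr_rot$imputed)
  expect_equal(wr_rot$value, 1574.2)  # college overall rotational row
  expect_equal(pem_lookup(pem, "high_school", "overall", "hits_per_season")$value,
               538.7)
  # youth rows exist only as overall; every youth position cell is imputed
  df <- as.data.frame(pem)
  youth_pos <- df[df$level == "youth" & df$position != "overall", ]
  expect_true(all(youth_pos$imputed))
  expect_true(all(df$value > 0))
})

test_that("write/read round-trip reproduces all cells bit-identically", {
  pem <- football_pem()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_pem(pem, tmp)
  back <- read_pem(tmp)
  expect_identical(as.data.frame(back)$value, as.data.frame(pem)$value)
  expect_identical(back$imputed, pem$imputed)
  expect_error(read_pem("no/such/file.csv"), class = "rhipem_io_error")
})

test_that("youth position-level study records are rejected", {
  bad <- rbind(base_overall_records(),
               toy_record("y", "youth", "LB", "hits_per_season", 100, 5))
  expect_error(study_records(bad), class = "rhipem_invalid_input")
  # missing sample size is an error, never a default weight
  nas <- base_overall_records()
  nas$sample_size[3] <- NA
  expect_error(study_records(nas), class = "rhipem_invalid_input")
})
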