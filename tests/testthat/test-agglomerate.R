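test_that("standardization freezes a reusable scaler and guards zero variance", {
  sch <- tiny_schema()
  rec <- data.frame(area_ha = c(1, 2, 3), temperature = c(10, 20, 30),
                    slope = c(5, 5, 5))
  expect_warning(s <- standardize_covariates(rec, sch), "zero-variance")
  expect_equal(unname(s$z[, "slope"]), c(0, 0, 0))
  expect_equal(unname(s$z[, "temperature"]), (c(10, 20, 30) - 20) / 10)

  # already standardized input is unchanged (idempotent up to the scaler)
  z2 <- standardize_covariates(
    data.frame(area_ha = s$z[, 1], temperature = s$z[, 2], slope = 0),
    sch, vars = c("area_ha", "temperature"))
  expect_equal(unname(z2$z), unname(s$z[, 1:2]))

  # projecting new units through the frozen scaler
  new <- data.frame(area_ha = 2, temperature = 40, slope = 5)
  zn <- standardize_covariates(new, sch, scaler = s$scaler)
  expect_equal(unname(zn$z[1, "temperature"]), 2)
  expect_error(standardize_covariates(data.frame(area_ha = NA_real_,
                                                 temperature = 1, slope = 1),
                                      sch), "missing")
})

test_that("merging sums summables and area-weights the rest", {
  sch <- tiny_schema()
  a <- list(area_ha = 30, temperature = 18, slope = 4, gain_ha = 2)
  b <- list(area_ha = 10, temperature = 22, slope = 8, gain_ha = 1)
  m <- merge_units(a, b, sch)
  expect_equal(m$area_ha, 40)
  expect_equal(m$temperature, (30 * 18 + 10 * 22) / 40)  # 19
  expect_equal(m$gain_ha, 3)

  # identical records: average of equal values is the value
  m2 <- merge_units(list(area_ha = 10, temperature = 20, slope = 1, gain_ha = 0),
                    list(area_ha = 10, temperature = 20, slope = 1, gain_ha = 0),
                    sch)
  expect_equal(m2$area_ha, 20)
  expect_equal(m2$temperature, 20)

  # empty agglomerate: merge is the unit itself
  expect_equal(merge_units(NULL, b, sch)[names(b)], b)
  expect_error(merge_units(list(area_ha = 0, temperature = 1, slope = 1,
                                gain_ha = 0),
                           list(area_ha = 0, temperature = 1, slope = 1,
                                gain_ha = 0), sch), "positive")
})

test_that("greedy agglomeration follows the accept/stop rules", {
  sch <- tiny_schema()
  scaler <- list(mean = c(area_ha = 0, temperature = 0, slope = 0),
                 sd = c(area_ha = 10, temperature = 1, slope = 1))
  tgt <- data.frame(territory_id = 1L, area_ha = 100, temperature = 20,
                    slope = 10, gain_ha = 0)

  # one candidate identical in non-summables and area: distance 0 at once
  cand <- data.frame(territory_id = 2L, area_ha = 100, temperature = 20,
                     slope = 10, gain_ha = 1)
  a <- build_agglomerate(tgt, cand, sch, scaler)
  expect_equal(a$member_ids, 2L)
  expect_equal(tail(a$trace$step_distances, 1), 0)

  # hand-traced 3-candidate instance: A seeds, A+B improves and overshoots
  cands <- data.frame(territory_id = c(10L, 11L, 12L),
                      area_ha = c(60, 60, 500),
                      temperature = c(20, 20, 20), slope = c(10, 10, 10),
                      gain_ha = 0)
  a2 <- build_agglomerate(tgt, cands, sch, scaler)
  expect_equal(sort(a2$member_ids), c(10L, 11L))
  expect_equal(a2$trace$stop_reason, "area_exceeded")
  expect_equal(a2$merged$area_ha, 120)

  # trace distances strictly decrease up to the stop
  set.seed(8)
  for (i in 1:10) {
    cnd <- tiny_records(12, seed = i)
    t0 <- tiny_records(1, seed = 100 + i, role = "treatment", id0 = 0L)
    t0$area_ha <- t0$area_ha * 8
    sc <- standardize_covariates(rbind(t0, cnd)[, sch$distance_vars], sch)$scaler
    ag <- build_agglomerate(t0, cnd, sch, sc)
    expect_true(all(diff(ag$trace$step_distances) < 0))
    # convexity: merged non-summables inside the members' range
    mem <- cnd[cnd$territory_id %in% ag$member_ids, ]
    for (v in sch$non_summable) {
      expect_gte(ag$merged[[v]], min(mem[[v]]) - 1e-9)
      expect_lte(ag$merged[[v]], max(mem[[v]]) + 1e-9)
    }
    expect_equal(ag$merged$area_ha, sum(mem$area_ha))
  }
  expect_error(build_agglomerate(tgt, cands[0, ], sch, scaler), "empty")
})

test_that("greedy final distance never beats the exhaustive best subset", {
  sch <- tiny_schema()
  set.seed(42)
  worse <- 0L
  for (i in 1:40) {
    cnd <- tiny_records(sample(5:10, 1), seed = 1000 + i)
    t0 <- tiny_records(1, seed = 2000 + i, role = "treatment", id0 = 0L)
    t0$area_ha <- t0$area_ha * 5
    sc <- standardize_covariates(rbind(t0, cnd)[, sch$distance_vars], sch)$scaler
    ag <- build_agglomerate(t0, cnd, sch, sc, area_stop = FALSE)
    got <- tail(ag$trace$step_distances, 1)
    best <- oracle_best_subset_distance(t0, cnd, sc, sch)
    expect_gte(got, best - 1e-9)
    if (got > best + 1e-9) worse <- worse + 1L
  }
  # the greedy path is usually, but not always, optimal on tiny pools
  expect_lt(worse, 40L)
})

test_that("matching runs are deterministic, complete and reproducible", {
  g <- generate_territories(synthetic_config(n_treatment = 5, n_control = 300,
                                             seed = 3))
  tr <- g$territories[g$territories$role == "treatment", ]
  co <- g$territories[g$territories$role == "control", ]
  cfg <- match_config(K = 100, n_runs = 3, seed = 17)
  sets <- repeat_matching(tr, co, config = cfg)
  expect_length(sets, 3L)

  # no-drop guarantee, unique members, mass conservation
  for (ms in sets) {
    expect_length(ms$pairs, nrow(tr))
    for (p in ms$pairs) {
      expect_false(any(duplicated(p$member_ids)))
      mem <- co[co$territory_id %in% p$member_ids, ]
      expect_equal(p$merged$area_ha, sum(mem$area_ha))
      expect_equal(p$merged$gain_ha, sum(mem$gain_ha))
    }
  }

  # bitwise-identical rerun under the same master seed
  sets2 <- repeat_matching(tr, co, config = cfg)
  expect_identical(lapply(sets, `[[`, "pairs"), lapply(sets2, `[[`, "pairs"))
  # distinct derived seeds across runs
  expect_length(unique(vapply(sets, `[[`, 0L, "seed")), 3L)

  # single treatment, single control: one 1-member agglomerate (the
  # one-unit reference population degenerates to zero variance, warned)
  expect_warning(s1 <- run_matching(tr[1, ], co[1, ], config = match_config(K = 5)),
                 "zero-variance")
  expect_length(s1$pairs, 1L)
  expect_equal(s1$pairs[[1]]$member_ids, co$territory_id[1])

  expect_error(run_matching(tr, rbind(co, tr), config = cfg), "disjoint")
})
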