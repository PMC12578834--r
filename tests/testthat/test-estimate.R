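test_that("optimal full matching handles the elementary cases", {
  d1 <- matrix(3.2, 1, 1, dimnames = list("t1", "c1"))
  r1 <- optimal_full_match(d1)
  expect_equal(r1$total_distance, 3.2)
  expect_equal(length(unique(r1$strata$stratum)), 1L)

  # unique zero-distance partners are matched exactly
  d0 <- matrix(1, 3, 3) + diag(-1, 3)
  dimnames(d0) <- list(paste0("t", 1:3), paste0("c", 1:3))
  r0 <- optimal_full_match(d0)
  expect_equal(r0$total_distance, 0)
  expect_equal(r0$pairs$control_id[match(paste0("t", 1:3), r0$pairs$treated_id)],
               paste0("c", 1:3))

  expect_error(optimal_full_match(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("min-cost-flow full matching equals brute-force enumeration", {
  set.seed(31)
  for (i in 1:60) {
    nt <- sample(1:4, 1); nc <- sample(1:4, 1)
    d <- matrix(round(stats::runif(nt * nc, 0, 10), 3), nt, nc)
    got <- optimal_full_match(d)
    expect_equal(got$total_distance, oracle_full_match_distance(d),
                 tolerance = 1e-9,
                 label = sprintf("instance %d (%dx%d)", i, nt, nc))
    # structural invariants of the full match
    st <- got$strata
    expect_setequal(st$unit_id[st$role == "treated"], paste0("t", seq_len(nt)))
    for (s in unique(st$stratum)) {
      expect_gte(sum(st$role == "treated" & st$stratum == s), 1L)
      expect_gte(sum(st$role == "control" & st$stratum == s), 1L)
    }
    expect_true(all(got$weights[st$unit_id[st$role == "treated"]] == 1))
    expect_true(all(got$weights > 0))
  }
})

test_that("common-support trimming drops controls outside the treated range", {
  zt <- matrix(c(0, 1, 0, 1), 2, 2)
  zc <- rbind(c(0.5, 0.5), c(5, 5), c(0.2, 0.9))
  d <- matrix(1, 2, 3)
  r <- optimal_full_match(d, common_support = TRUE, z_treated = zt,
                          z_control = zc)
  expect_equal(r$n_discarded, 1L)
  expect_equal(sum(r$strata$role == "control"), 2L)
})

test_that("outcome model matches closed-form weighted least squares", {
  d <- data.frame(treat = c(1, 1, 1, 0, 0, 0),
                  x = c(1, 2, 3, 1.5, 2.5, 3.5),
                  y = c(9, 11, 13, 3, 5, 7),
                  w = c(1, 1, 1, 0.5, 1, 1.5))
  fit <- fit_outcome_model(d, "y", "x", weights = d$w)
  X <- cbind(1, d$treat, d$x)
  W <- diag(d$w)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% d$y)
  expect_equal(unname(coef(fit)), as.numeric(beta), tolerance = 1e-10)

  # outcome = 5 x treatment exactly
  d2 <- data.frame(treat = rep(c(1, 0), 4), x = rep(1:4, each = 2),
                   y = 5 * rep(c(1, 0), 4))
  f2 <- fit_outcome_model(d2, "y", "x")
  expect_equal(unname(coef(f2)["treat"]), 5)
  expect_equal(att_g_computation(f2, d2), 5)

  d2$x2 <- 2 * d2$x  # exactly collinear column
  expect_error(fit_outcome_model(d2, "y", c("x", "x2")), "collinear")
})

test_that("cluster-robust variance reduces to known cases", {
  set.seed(9)
  d <- data.frame(treat = rep(c(1, 0), 10), x = stats::rnorm(20))
  d$y <- 2 * d$treat + d$x + stats::rnorm(20)
  fit <- fit_outcome_model(d, "y", "x")

  # one unit per cluster: CR0 equals the HC0 heteroskedasticity sandwich
  V_cl <- sandwich::vcovCL(fit, cluster = seq_len(20), type = "HC0",
                           cadjust = FALSE)
  V_hc <- sandwich::vcovHC(fit, type = "HC0")
  expect_equal(V_cl, V_hc, tolerance = 1e-10)
  se <- cluster_robust_se(fit, seq_len(20), d, cr_type = "CR0")
  expect_equal(se, sqrt(V_hc["treat", "treat"]), tolerance = 1e-10)

  # two-cluster toy example against the hand-computed sandwich
  d3 <- data.frame(treat = c(1, 1, 0, 0), y = c(3, 5, 1, 3))
  f3 <- stats::lm(y ~ treat, data = d3)
  cl <- c("a", "a", "b", "b")
  X <- cbind(1, d3$treat)
  u <- stats::residuals(f3)
  meat <- matrix(0, 2, 2)
  for (g in unique(cl)) {
    sg <- t(X[cl == g, , drop = FALSE]) %*% u[cl == g]
    meat <- meat + sg %*% t(sg)
  }
  bread <- solve(t(X) %*% X)
  V_hand <- bread %*% meat %*% bread
  expect_equal(unname(sandwich::vcovCL(f3, cluster = cl, type = "HC0",
                                       cadjust = FALSE)),
               V_hand, tolerance = 1e-10)

  # all residuals zero: SE 0
  d4 <- data.frame(treat = c(1, 1, 0, 0), y = c(4, 4, 1, 1))
  f4 <- suppressWarnings(stats::lm(y ~ treat, data = d4))
  expect_equal(suppressWarnings(
    cluster_robust_se(f4, c(1, 2, 1, 2), d4, cr_type = "CR0")), 0,
    tolerance = 1e-8)

  expect_error(cluster_robust_se(fit, rep(1, 20), d), "single cluster")
})

test_that("end-to-end ATT on identical groups is zero and outcomes are isolated", {
  g <- generate_territories(synthetic_config(n_treatment = 12, n_control = 400,
                                             seed = 12))
  tr <- g$territories[g$territories$role == "treatment", ]
  co <- g$territories[g$territories$role == "control", ]
  cfg <- match_config(K = 200, n_runs = 1, seed = 5)
  s <- run_matching(tr, co, config = cfg)

  # force identical outcomes on both sides: estimate must be exactly 0
  s0 <- s
  tr0 <- tr
  tr0$gain_ha <- 7
  s0$merged$gain_ha <- 7
  a0 <- suppressWarnings(estimate_att(s0, tr0, "gain_ha", config = cfg))
  expect_equal(a0$estimate, 0, tolerance = 1e-8)

  ag <- estimate_att(s, tr, "gain_ha", config = cfg)
  ar <- estimate_att(s, tr, "reversal_ha", config = cfg)
  expect_equal(ag$outcome_name, "gain_ha")
  expect_equal(ar$outcome_name, "reversal_ha")
  expect_false(isTRUE(all.equal(ag$estimate, ar$estimate)))
  expect_equal(ag$n_treated, 12L)
  expect_true(ag$p_value >= 0 && ag$p_value <= 1)
  expect_equal(ag$method, "agglomerate_OFM")
  expect_equal(estimate_att(s, tr, "gain_ha",
                            config = match_config(K = 200, ofm = FALSE))$method,
               "agglomerate_pair")
})

test_that("the estimator is doubly robust on synthetic data", {
  # (a) outcome model correct, matching skipped: regress on the full
  # unmatched sample
  bias_a <- sapply(c(200, 2000), function(n) {
    ests <- sapply(1:8, function(i) {
      g <- generate_territories(synthetic_config(n_treatment = 20,
                                                 n_control = n, seed = 300 + i))
      d <- g$territories
      d$treat <- as.integer(d$role == "treatment")
      f <- fit_outcome_model(d, "gain_ha", covariate_schema()$distance_vars)
      att_g_computation(f, d)
    })
    mean(ests) - 10
  })
  expect_lt(abs(bias_a[2]), 1)

  # (b) ideal matching, outcome model omits the key covariate (area): the
  # design adjustment alone carries the estimate.  Controls are synthetic
  # twins of the treated units (identical covariates, no treatment effect).
  sch <- covariate_schema()
  rate <- synthetic_config()$gain_model$intercept
  ests_b <- sapply(1:8, function(i) {
    g <- generate_territories(synthetic_config(seed = 500 + i))
    tr <- g$territories[g$territories$role == "treatment", ]
    set.seed(600 + i)
    twins <- tr[, sch$distance_vars]
    twins$gain_ha <- twins$area_ha * rate + stats::rnorm(nrow(twins), 0, 5)
    dat <- rbind(data.frame(treat = 1, tr[, c(sch$distance_vars, "gain_ha")]),
                 data.frame(treat = 0, twins))
    f <- fit_outcome_model(dat, "gain_ha", sch$non_summable)
    att_g_computation(f, dat)
  })
  expect_lt(abs(mean(ests_b) - 10), 1.5)
})
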