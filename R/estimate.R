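#' Fit the outcome regression on a matched sample
#'
#' Weighted least squares of the outcome on a treatment indicator plus the
#' matching covariates, the regression half of the doubly-robust estimator
#' (matching supplies the design half).  The design matrix is checked for
#' full rank before fitting; rank deficiency is an error naming the
#' collinear columns.
#'
#' @param data matched-sample data.frame containing `outcome`, `treat_col`
#'   and the covariates.
#' @param outcome outcome column name.
#' @param covariates character vector of covariate column names.
#' @param weights optional observation weights (e.g. full-matching weights).
#' @param treat_col name of the 0/1 treatment indicator column.
#' @return fitted `lm` object.
#' @export
fit_outcome_model <- function(data, outcome, covariates,
                              weights = NULL, treat_col = "treat") {
  f <- stats::reformulate(c(treat_col, covariates), response = outcome)
  X <- stats::model.matrix(f, data)
  q <- qr(X)
  if (q$rank < ncol(X))
    stop("rank-deficient outcome design; collinear columns: ",
         paste(colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]], collapse = ", "))
  if (is.null(weights)) return(stats::lm(f, data = data))
  data$.w <- weights
  stats::lm(f, data = data, weights = .w)
}

# model-matrix contrast rows for g-computation: mean over treated units of
# x(treat = 1) - x(treat = 0)
.att_contrast <- function(model, data, treat_col = "treat") {
  treated <- data[data[[treat_col]] == 1, , drop = FALSE]
  tt <- stats::delete.response(stats::terms(model))
  d1 <- treated; d1[[treat_col]] <- 1
  d0 <- treated; d0[[treat_col]] <- 0
  X1 <- stats::model.matrix(tt, d1)
  X0 <- stats::model.matrix(tt, d0)
  colMeans(X1 - X0)
}

#' ATT by g-computation over the treated units
#'
#' Average, over treated units at their observed covariates, of the model
#' prediction under treatment minus the prediction under control (the
#' average marginal comparison).  For a linear model with a plain additive
#' treatment term this equals the treatment coefficient exactly.
#'
#' @param model fitted outcome model from [fit_outcome_model()].
#' @param data the matched-sample data the model was fitted on.
#' @param treat_col treatment indicator column name.
#' @return scalar ATT estimate, in outcome units (hectares).
#' @export
att_g_computation <- function(model, data, treat_col = "treat") {
  as.numeric(.att_contrast(model, data, treat_col) %*% stats::coef(model))
}

#' Cluster-robust standard error of the ATT contrast
#'
#' Sandwich variance with cluster-level score aggregation, propagated to
#' the g-computation contrast.  `CR1` (default) applies the usual
#' G/(G-1)-style degrees-of-freedom correction, the standard choice at the
#' few-dozen cluster counts a matched sample yields; `CR0` is the plain
#' clustered sandwich with no small-sample adjustment; `CR2` the
#' leverage-based adjustment; all via [sandwich::vcovCL()].
#'
#' @param model fitted outcome model.
#' @param clusters vector of cluster ids (matching stratum or pair ids),
#'   one per observation.
#' @param data matched-sample data (for the contrast).
#' @param cr_type `"CR1"` (default), `"CR0"` or `"CR2"`.
#' @param treat_col treatment indicator column name.
#' @return scalar standard error.
#' @export
cluster_robust_se <- function(model, clusters, data,
                              cr_type = c("CR1", "CR0", "CR2"),
                              treat_col = "treat") {
  cr_type <- match.arg(cr_type)
  if (length(unique(clusters)) < 2L)
    stop("cluster-robust variance is unidentified with a single cluster")
  V <- switch(cr_type,
              CR0 = sandwich::vcovCL(model, cluster = clusters,
                                     type = "HC0", cadjust = FALSE),
              CR1 = sandwich::vcovCL(model, cluster = clusters,
                                     type = "HC1", cadjust = TRUE),
              CR2 = sandwich::vcovCL(model, cluster = clusters,
                                     type = "HC2", cadjust = FALSE))
  ct <- .att_contrast(model, data, treat_col)
  sqrt(as.numeric(ct %*% V %*% ct))
}

#' Doubly-robust ATT estimate for one matched set
#'
#' Assembles the matched sample (treatment territories and their
#' agglomerated controls), optionally re-matches it by
#' [optimal_full_match()] on the standardized covariates, fits the outcome
#' regression, and returns the g-computation ATT with a cluster-robust
#' standard error (clusters: full-matching strata, or treatment-agglomerate
#' pairs when OFM is off) and a two-sided p-value from a t reference with
#' G-1 degrees of freedom (G = number of clusters).  Each call
#' estimates one outcome for one treatment regime; effects fitted under
#' different treatment conditions are not comparable across calls.
#'
#' @param matched a `matched_set` from [run_matching()].
#' @param treatments data.frame of treatment territory records.
#' @param outcome `"gain_ha"` or `"reversal_ha"`.
#' @param schema a [covariate_schema()].
#' @param config a [match_config()]; `ofm`, `common_support` and `cr_type`
#'   are honoured.
#' @return object of class `att_result`.
#' @export
estimate_att <- function(matched, treatments, outcome = "gain_ha",
                         schema = covariate_schema(),
                         config = match_config()) {
  vars <- schema$distance_vars
  tm <- treatments[match(sapply(matched$pairs, `[[`, "target_id"),
                         treatments$territory_id), , drop = FALSE]
  cm <- matched$merged
  td <- data.frame(unit_id = as.character(tm$territory_id), treat = 1,
                   pair = as.character(tm$territory_id),
                   tm[, c(vars, outcome)])
  cd <- data.frame(unit_id = paste0("agg:", cm$target_id), treat = 0,
                   pair = as.character(cm$target_id),
                   cm[, c(vars, outcome)])
  dat <- rbind(td, cd)

  ofm <- NULL
  if (isTRUE(config$ofm)) {
    zt <- standardize_covariates(tm, schema, scaler = matched$scaler)$z
    zc <- standardize_covariates(cm, schema, scaler = matched$scaler)$z
    dmat <- sqrt(outer(rowSums(zt^2), rep(1, nrow(zc))) +
                   outer(rep(1, nrow(zt)), rowSums(zc^2)) -
                   2 * zt %*% t(zc))
    dmat[!is.finite(dmat) | dmat < 0] <- 0
    rownames(dmat) <- td$unit_id; colnames(dmat) <- cd$unit_id
    ofm <- optimal_full_match(dmat, common_support = isTRUE(config$common_support),
                              z_treated = zt, z_control = zc)
    kept <- dat$unit_id %in% ofm$unit_id
    dat <- dat[kept, , drop = FALSE]
    dat$cluster <- ofm$strata$stratum[match(dat$unit_id, ofm$strata$unit_id)]
    dat$w <- as.numeric(ofm$weights[dat$unit_id])
  } else {
    dat$cluster <- dat$pair
    dat$w <- 1
  }

  fit <- fit_outcome_model(dat, outcome, vars, weights = dat$w)
  est <- att_g_computation(fit, dat)
  se <- cluster_robust_se(fit, dat$cluster, dat, cr_type = config$cr_type)
  df <- length(unique(dat$cluster)) - 1L   # t reference with G-1 df
  p <- if (!is.finite(se)) NA_real_
       else if (se > 0) 2 * stats::pt(-abs(est / se), df)
       else as.numeric(est == 0)
  structure(list(estimate = est, se = se, df = df,
                 p_value = p,
                 n_treated = sum(dat$treat == 1),
                 n_control_units = sum(dat$treat == 0),
                 estimand = "ATT", outcome_name = outcome,
                 method = if (isTRUE(config$ofm)) "agglomerate_OFM"
                          else "agglomerate_pair",
                 common_support = isTRUE(config$common_support),
                 cr_type = config$cr_type,
                 model = fit, ofm = ofm),
            class = "att_result")
}

#' @export
print.att_result <- function(x, ...) {
  cat("ATT (", x$outcome_name, ", ", x$method, "): ",
      format(x$estimate, digits = 5), " ha  [SE ",
      format(x$se, digits = 4), ", p = ",
      format.pval(x$p_value, digits = 3), "]  n_treated = ",
      x$n_treated, "\n", sep = "")
  invisible(x)
}

#' Effect-size stability across repeated matching runs
#'
#' Computes the ATT on every matching run and compares the mean across runs
#' with the estimate from the mini-max-selected run, as a guard against
#' results idiosyncratic to a single stochastic run.
#'
#' @param matched_sets list of `matched_set` objects from
#'   [repeat_matching()].
#' @param treatments treatment records.
#' @param chosen_run_id run selected by [select_minimax()].
#' @inheritParams estimate_att
#' @return list with `per_run` (data.frame run_id, estimate, se), `mean_att`,
#'   `chosen_att` and `abs_difference`.
#' @export
att_stability <- function(matched_sets, treatments, chosen_run_id,
                          outcome = "gain_ha", schema = covariate_schema(),
                          config = match_config()) {
  per_run <- do.call(rbind, lapply(matched_sets, function(ms) {
    a <- estimate_att(ms, treatments, outcome, schema, config)
    data.frame(run_id = ms$run_id, estimate = a$estimate, se = a$se)
  }))
  chosen <- per_run$estimate[per_run$run_id == chosen_run_id]
  list(per_run = per_run, mean_att = mean(per_run$estimate),
       chosen_att = chosen,
       abs_difference = abs(mean(per_run$estimate) - chosen))
}
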