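#' Standardized mean difference
#'
#' `(mean(treat) - mean(control)) / scale_sd`.  By ATT convention the scale
#' is the treatment-group standard deviation from the *unmatched* sample, so
#' matched and unmatched SMDs of a covariate share a denominator and are
#' directly comparable; when `scale_sd` is omitted the SD of `treat_values`
#' is used.  `|SMD| <= 0.1` is the conventional balance threshold.
#'
#' @param treat_values,control_values numeric vectors.
#' @param scale_sd positive scalar denominator.
#' @param treat_weights,control_weights optional observation weights
#'   (e.g. full-matching stratum weights).
#' @return scalar SMD.
#' @export
#' @examples
#' smd(c(4, 6), c(3, 5), scale_sd = 2)  # (5 - 4) / 2 = 0.5
smd <- function(treat_values, control_values, scale_sd = NULL,
                treat_weights = NULL, control_weights = NULL) {
  if (!length(treat_values) || !length(control_values))
    stop("both groups must be non-empty")
  wmean <- function(x, w) if (is.null(w)) mean(x) else sum(w * x) / sum(w)
  if (is.null(scale_sd)) scale_sd <- stats::sd(treat_values)
  if (!is.finite(scale_sd) || scale_sd <= 0)
    stop("scale_sd must be positive; handle zero-variance covariates upstream")
  (wmean(treat_values, treat_weights) -
     wmean(control_values, control_weights)) / scale_sd
}

# eCDF / eQQ / kernel-density tables for one covariate, plot-ready
.distribution_tables <- function(tv, cv, probs = seq(0.01, 0.99, by = 0.01)) {
  grid <- sort(unique(c(tv, cv)))
  list(ecdf = data.frame(x = grid,
                         treat = stats::ecdf(tv)(grid),
                         control = stats::ecdf(cv)(grid)),
       eqq = data.frame(p = probs,
                        treat = as.numeric(stats::quantile(tv, probs)),
                        control = as.numeric(stats::quantile(cv, probs))),
       density = {
         dt <- stats::density(tv); dc <- stats::density(cv)
         data.frame(x = c(dt$x, dc$x), y = c(dt$y, dc$y),
                    group = rep(c("treat", "control"),
                                c(length(dt$x), length(dc$x))))
       })
}

#' Covariate balance of one matching run
#'
#' Computes, for every distance covariate, the SMD between treatment
#' territories and their agglomerated controls on the matched sample
#' (pair-weighted by default; stratum-weighted when an [optimal_full_match()]
#' result is supplied) alongside the unmatched SMD between treatments and the
#' raw control pool.  The denominator is always the treatment-group SD from
#' the unmatched sample.  Covariates with zero treated-group variance are
#' reported as NA and excluded from `max_abs_smd`.
#'
#' @param matched a `matched_set` from [run_matching()].
#' @param treatments,controls the unmatched records the set was built from.
#' @param schema a [covariate_schema()].
#' @param ofm optional `ofm_result`; its stratum weights replace plain pair
#'   weights for the matched-sample means.
#' @param distributions logical: attach eCDF/eQQ/kernel-density tables per
#'   covariate (data only; plotting is left to the user).
#' @return object of class `balance_report`: data.frame `table` (covariate,
#'   smd_unmatched, smd_matched), `max_abs_smd`, `run_id`, and optionally
#'   `distributions`.
#' @export
balance_report <- function(matched, treatments, controls,
                           schema = covariate_schema(), ofm = NULL,
                           distributions = FALSE) {
  vars <- schema$distance_vars
  tm <- treatments[match(sapply(matched$pairs, `[[`, "target_id"),
                         treatments$territory_id), , drop = FALSE]
  cm <- matched$merged
  tw <- cw <- NULL
  if (!is.null(ofm)) {
    tw <- ofm$weights[match(tm$territory_id, ofm$unit_id)]
    cw <- ofm$weights[match(paste0("agg:", cm$target_id), ofm$unit_id)]
  }
  res <- lapply(vars, function(v) {
    s <- stats::sd(tm[[v]])
    if (!is.finite(s) || s == 0) return(c(NA_real_, NA_real_))
    c(smd(tm[[v]], controls[[v]], scale_sd = s),
      smd(tm[[v]], cm[[v]], scale_sd = s,
          treat_weights = tw, control_weights = cw))
  })
  tab <- data.frame(covariate = vars,
                    smd_unmatched = vapply(res, `[`, 0, 1L),
                    smd_matched = vapply(res, `[`, 0, 2L))
  out <- list(run_id = matched$run_id, table = tab,
              max_abs_smd = max(abs(tab$smd_matched), na.rm = TRUE))
  if (distributions)
    out$distributions <- stats::setNames(lapply(vars, function(v)
      .distribution_tables(tm[[v]], cm[[v]])), vars)
  structure(out, class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report, run", x$run_id, "- max |SMD| =",
      format(x$max_abs_smd, digits = 4), "\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Prognostic-score balance
#'
#' Fits an ordinary least-squares model of the outcome on the distance
#' covariates among *control-pool* units only, then reports the SMD of its
#' predictions between the matched treatment territories and their
#' agglomerates.  Balance on the prognostic score summarizes balance on the
#' outcome-relevant combination of covariates.
#'
#' @param matched a `matched_set`.
#' @param treatments,controls unmatched records.
#' @param outcome outcome column name (`"gain_ha"` or `"reversal_ha"`).
#' @param schema a [covariate_schema()].
#' @return scalar SMD of predicted outcomes (scale: SD of the treated
#'   predictions).
#' @export
prognostic_balance <- function(matched, treatments, controls,
                               outcome = "gain_ha",
                               schema = covariate_schema()) {
  if (nrow(controls) < 2L) stop("need at least 2 control units")
  f <- stats::reformulate(schema$distance_vars, response = outcome)
  X <- stats::model.matrix(f, controls)
  if (qr(X)$rank < ncol(X))
    stop("singular prognostic design; reduce or decorrelate the covariates")
  fit <- stats::lm(f, data = controls)
  tm <- treatments[match(sapply(matched$pairs, `[[`, "target_id"),
                         treatments$territory_id), , drop = FALSE]
  pt <- stats::predict(fit, newdata = tm)
  pc <- stats::predict(fit, newdata = matched$merged)
  s <- stats::sd(pt)
  if (!is.finite(s) || s == 0) return(0)
  smd(pt, pc, scale_sd = s)
}

#' Mini-max selection across repeated matching runs
#'
#' Among repeated stochastic matching runs, selects the run whose worst
#' (maximum absolute) covariate SMD is smallest; exact ties go to the lowest
#' `run_id`.  The selected run is the one whose outcomes are reported; the
#' others quantify the stochastic spread.
#'
#' @param reports list of [balance_report()] objects.
#' @return list of class `minimax_selection` with `chosen_run_id`,
#'   `criterion_value` and `all_run_criteria` (named by run id).
#' @export
select_minimax <- function(reports) {
  if (!length(reports)) stop("no balance reports supplied")
  crit <- vapply(reports, `[[`, 0, "max_abs_smd")
  ids <- vapply(reports, `[[`, 0L, "run_id")
  best <- which(crit == min(crit))
  best <- best[which.min(ids[best])]
  structure(list(chosen_run_id = ids[best],
                 criterion_value = crit[best],
                 all_run_criteria = stats::setNames(crit, ids)),
            class = "minimax_selection")
}

#' @export
print.minimax_selection <- function(x, ...) {
  cat("Mini-max selection over", length(x$all_run_criteria), "runs: run",
      x$chosen_run_id, "with max |SMD| =",
      format(x$criterion_value, digits = 4), "\n")
  invisible(x)
}
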