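#' Read a territory table
#'
#' Reads a delimited territory table (CSV with header) and applies the
#' standard inclusion rules: rows missing any covariate are excluded (with
#' a reported count), as are territories smaller than 0.1 ha.  The excluded
#' counts are attached as attributes `n_excluded_missing` and
#' `n_excluded_small` and reported via `message()`.
#'
#' @param path CSV path with columns `territory_id`, `regime`, `role`,
#'   `area_ha`, the nine non-summable covariates, `gain_ha`, `reversal_ha`.
#' @param schema a [covariate_schema()].
#' @param min_area_ha inclusion threshold in hectares.
#' @return data.frame of territory records.
#' @export
read_territory_table <- function(path, schema = covariate_schema(),
                                 min_area_ha = 0.1) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("territory_id", "regime", "role", schema$distance_vars,
                schema$outcomes)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("territory table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (v in c(schema$distance_vars, schema$outcomes))
    x[[v]] <- as.numeric(x[[v]])
  has_na <- !stats::complete.cases(x[, schema$distance_vars, drop = FALSE])
  x <- x[!has_na, , drop = FALSE]
  too_small <- x$area_ha < min_area_ha
  x <- x[!too_small, , drop = FALSE]
  rownames(x) <- NULL
  message(sum(has_na), " row(s) excluded for missing covariates; ",
          sum(too_small), " excluded below ", min_area_ha, " ha")
  attr(x, "n_excluded_missing") <- sum(has_na)
  attr(x, "n_excluded_small") <- sum(too_small)
  x
}

#' Write matched-set membership and merged-covariate tables
#'
#' Writes a long membership table (`run_id`, `treatment_id`, `member_rank`,
#' `control_id`) covering every run, plus one merged-covariate CSV per run
#' under `dir/merged/`.
#'
#' @param matched_sets list of `matched_set` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the membership table.
#' @export
write_matched_sets <- function(matched_sets, dir) {
  dir.create(file.path(dir, "merged"), showWarnings = FALSE, recursive = TRUE)
  members <- do.call(rbind, lapply(matched_sets, function(ms)
    do.call(rbind, lapply(ms$pairs, function(p)
      if (length(p$member_ids))
        data.frame(run_id = ms$run_id, treatment_id = p$target_id,
                   member_rank = seq_along(p$member_ids),
                   control_id = p$member_ids)))))
  rownames(members) <- NULL
  utils::write.csv(members, file.path(dir, "members.csv"), row.names = FALSE)
  for (ms in matched_sets)
    utils::write.csv(ms$merged,
                     file.path(dir, "merged",
                               sprintf("merged_run_%03d.csv", ms$run_id)),
                     row.names = FALSE)
  invisible(members)
}

# run manifest: enough to reproduce a cli_match call bit-for-bit
.write_manifest <- function(path, territory_csv, out_dir, cfg) {
  manifest <- list(tool = "agglomatch",
                   version = as.character(utils::packageVersion("agglomatch")),
                   created = format(Sys.time(), tz = "UTC"),
                   territory_csv = normalizePath(territory_csv),
                   out_dir = normalizePath(out_dir),
                   config = list(K = cfg$K, n_runs = cfg$n_runs,
                                 seed = cfg$seed, ofm = cfg$ofm,
                                 common_support = cfg$common_support,
                                 cr_type = cfg$cr_type))
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}
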