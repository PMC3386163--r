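#' Read a quantitative feature table
#'
#' Two-column tab-delimited text (protein ID, numeric value), one feature
#' per run, with an optional header row (detected when the second field of
#' the first non-comment line is not numeric) and `#` comments. Duplicate
#' IDs and non-finite values are rejected.
#'
#' @param path file path.
#' @param name feature name (defaults to the header, if any).
#' @param units free-text units.
#' @return named numeric vector with attributes `feature_name` and `units`.
#' @export
read_feature_table <- function(path, name = NULL, units = "") {
  lines <- ph_read_lines(path)
  if (length(lines) == 0L) ph_validation_error(sprintf("feature table '%s' is empty", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    ph_format_error(sprintf("feature table '%s': line %d does not have 2 tab-separated columns",
                            path, attr(lines, "line_numbers")[bad[1L]]))
  first_val <- suppressWarnings(as.numeric(parts[[1L]][[2L]]))
  if (is.na(first_val)) {
    if (is.null(name)) name <- parts[[1L]][[2L]]
    parts <- parts[-1L]
    if (length(parts) == 0L)
      ph_validation_error(sprintf("feature table '%s' has a header but no data", path))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(vals) || any(!is.finite(vals)))
    ph_format_error(sprintf("feature table '%s': non-numeric or non-finite value for '%s'",
                            path, ids[which(!is.finite(vals))[1L]]))
  if (anyDuplicated(ids))
    ph_validation_error(sprintf("feature table '%s': duplicate protein ID(s): %s", path,
                                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  structure(stats::setNames(vals, ids),
            feature_name = if (is.null(name)) "feature" else name, units = units)
}

#' Box-plot summary of a feature per age stratum
#'
#' For each origin taxon: n, lower quartile, median, mean, upper quartile,
#' and whiskers (the extreme observed values within 1.5 times the
#' interquartile range of the quartiles). Quartiles use the Tukey-hinge
#' (median-of-halves) convention of classic box plots.
#'
#' @param values numeric feature values.
#' @param strata character vector of origin taxa, parallel to `values`.
#' @param strata_order optional ordering of strata for the output (e.g. the
#'   `stratum` column of an `age_db`'s `strata`, root to leaf); defaults to
#'   first appearance.
#' @return data frame with one row per stratum that has observations.
#' @export
per_age_summary <- function(values, strata, strata_order = NULL) {
  values <- as.numeric(values)
  strata <- as.character(strata)
  if (length(values) != length(strata))
    ph_argument_error("'values' and 'strata' must have equal length")
  if (is.null(strata_order)) strata_order <- unique(strata)
  strata_order <- strata_order[strata_order %in% strata]
  rows <- lapply(strata_order, function(s) {
    v <- values[strata == s]
    fn <- stats::fivenum(v)
    q1 <- fn[2L]; q3 <- fn[4L]
    lo_fence <- q1 - 1.5 * (q3 - q1); hi_fence <- q3 + 1.5 * (q3 - q1)
    data.frame(stratum = s, n = length(v),
               q1 = q1, median = fn[3L], mean = mean(v), q3 = q3,
               whisker_low = min(v[v >= lo_fence]),
               whisker_high = max(v[v <= hi_fence]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear trend of a feature against age
#'
#' Ordinary least squares of feature on age (in mya), optionally excluding
#' named age strata (e.g. the most ancient groups, which often do not
#' maintain trends observed among younger proteins).
#'
#' @param ages numeric ages in mya.
#' @param values numeric feature values, parallel to `ages`.
#' @param strata optional origin taxa, parallel to `ages` (required when
#'   `exclude_strata` is nonempty).
#' @param exclude_strata taxa to drop before fitting.
#' @return list with `slope` (feature units per mya), `intercept`, and `n`.
#' @export
linear_trend <- function(ages, values, strata = NULL, exclude_strata = character(0)) {
  ages <- as.numeric(ages); values <- as.numeric(values)
  if (length(ages) != length(values))
    ph_argument_error("'ages' and 'values' must have equal length")
  if (length(exclude_strata)) {
    if (is.null(strata)) ph_argument_error("'strata' needed to exclude strata")
    keep <- !(as.character(strata) %in% exclude_strata)
    ages <- ages[keep]; values <- values[keep]
  }
  if (length(unique(ages)) < 2L)
    ph_validation_error("degenerate input: fewer than 2 distinct ages after exclusion")
  fit <- stats::lm(values ~ ages)
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]), n = length(ages))
}

#' Correlate protein age with a quantitative feature
#'
#' Joins an age database with a feature table by protein ID, computes
#' Spearman's rank correlation between age (mya) and the feature, a
#' per-stratum box-plot summary ordered root to leaf, and optionally an OLS
#' trend with the `exclude_oldest` most ancient strata removed. Proteins
#' missing from either side are dropped with counts reported.
#'
#' @param db an `age_db`.
#' @param features named numeric vector (see [read_feature_table()]).
#' @param exclude_oldest number of most ancient strata to exclude from the
#'   linear trend fit (0 disables exclusion; the correlation always uses
#'   all joined pairs).
#' @param trend fit the linear trend?
#' @return an object of class `age_feature` with `rho`, `p`, `n`,
#'   `n_dropped_no_feature`, `n_dropped_no_age`, `summary` (per-stratum),
#'   and `trend` (or `NULL`).
#' @export
age_feature_analysis <- function(db, features, exclude_oldest = 0L, trend = TRUE) {
  stopifnot(inherits(db, "age_db"))
  if (is.null(names(features)))
    ph_argument_error("'features' must be a named numeric vector")
  if (length(features) == 0L) ph_validation_error("feature table is empty")
  idx <- match(db$ages$protein, names(features))
  joined <- db$ages[!is.na(idx), , drop = FALSE]
  vals <- unname(features[idx[!is.na(idx)]])
  n_dropped_no_feature <- sum(is.na(idx))
  n_dropped_no_age <- sum(!(names(features) %in% db$ages$protein))
  if (nrow(joined) == 0L)
    ph_validation_error("no proteins shared between the age database and the feature table")
  sc <- spearman_correlation(joined$age_mya, vals)
  summ <- per_age_summary(vals, joined$origin, strata_order = db$strata$stratum)
  tr <- NULL
  if (trend) {
    excl <- if (exclude_oldest > 0L)
      utils::head(db$strata$stratum, exclude_oldest) else character(0)
    tr <- tryCatch(
      linear_trend(joined$age_mya, vals, strata = joined$origin,
                   exclude_strata = excl),
      phylostrat_validation_error = function(e) NULL)
  }
  structure(list(
    rho = sc$rho, p = sc$p, n = sc$n, p_method = sc$method,
    n_dropped_no_feature = n_dropped_no_feature,
    n_dropped_no_age = n_dropped_no_age,
    feature_name = attr(features, "feature_name"),
    summary = summ, trend = tr, exclude_oldest = exclude_oldest,
    species = db$species, method = db$method
  ), class = "age_feature")
}

#' @export
print.age_feature <- function(x, ...) {
  nm <- if (is.null(x$feature_name)) "feature" else x$feature_name
  cat(sprintf("Age-feature analysis (%s, %s ages; feature: %s)\n",
              x$species, x$method, nm))
  cat(sprintf("  Spearman rho = %.4g, two-sided p = %.4g (n = %d, %s)\n",
              x$rho, x$p, x$n, x$p_method))
  if (x$n_dropped_no_feature || x$n_dropped_no_age)
    cat(sprintf("  dropped: %d proteins without a feature value, %d feature rows without an age\n",
                x$n_dropped_no_feature, x$n_dropped_no_age))
  if (!is.null(x$trend))
    cat(sprintf("  linear trend: %.4g per mya (intercept %.4g, n = %d%s)\n",
                x$trend$slope, x$trend$intercept, x$trend$n,
                if (x$exclude_oldest > 0)
                  sprintf(", %d oldest strata excluded", x$exclude_oldest) else ""))
  cat("  per-stratum summary (root -> leaf):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an age-feature result
#'
#' `#` summary block (rho, p, n, dropped counts, trend) followed by the
#' tab-delimited per-stratum summary table, root to leaf.
#'
#' @param x an `age_feature`.
#' @param path output path.
#' @param extra_header optional additional `#` header lines.
#' @export
write_feature_analysis <- function(x, path, extra_header = character(0)) {
  stopifnot(inherits(x, "age_feature"))
  hdr <- c(
    sprintf("#phylostrat\t%s", as.character(utils::packageVersion("phylostrat"))),
    extra_header,
    sprintf("#species\t%s", x$species),
    sprintf("#ages_method\t%s", x$method),
    sprintf("#rho\t%s", ph_num(x$rho)),
    sprintf("#p\t%s", ph_num(x$p)),
    sprintf("#n\t%d", x$n),
    sprintf("#dropped_no_feature\t%d", x$n_dropped_no_feature),
    sprintf("#dropped_no_age\t%d", x$n_dropped_no_age)
  )
  if (!is.null(x$trend))
    hdr <- c(hdr,
             sprintf("#trend_slope_per_mya\t%s", ph_num(x$trend$slope)),
             sprintf("#trend_intercept\t%s", ph_num(x$trend$intercept)),
             sprintf("#trend_n\t%d", x$trend$n))
  cols <- names(x$summary)
  body <- do.call(paste, c(lapply(x$summary, function(col) {
    if (is.numeric(col)) ph_num(col) else as.character(col)
  }), sep = "\t"))
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}
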