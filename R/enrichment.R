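#' Compare the age distributions of two protein sets
#'
#' The core enrichment analysis: resolves both protein lists against an age
#' database, tests for an overall shift between the two age distributions
#' with the two-sided Mann-Whitney U test, and tests each age stratum (taxon
#' of origin) for enrichment with Fisher's exact test on the 2x2 table
#' `[[in set1 & in stratum, in set1 & not], [in set2 & in stratum, in set2 &
#' not]]`.
#'
#' `set2 = NULL` compares `set1` against the background of all proteins in
#' the database (the proteome). When `set1` is a subset of `set2` (including
#' the proteome case), the sets are disjointified first: `set1` is tested
#' against `set2` minus `set1`, which keeps the Fisher margins valid.
#' Partially overlapping sets (neither disjoint nor nested) are rejected.
#' Missing IDs are reported, never silently dropped.
#'
#' @param set1 a `protein_list` or character vector of IDs.
#' @param set2 a second list, or `NULL` for the whole-proteome background.
#' @param db an `age_db`.
#' @param bh if `TRUE`, Benjamini-Hochberg adjusted q-values are added to
#'   the per-stratum table (raw p-values remain primary).
#' @return an object of class `age_enrichment` with elements `table`
#'   (per-stratum counts, odds ratios, p-values, significance stars),
#'   `U`, `p_overall`, `n1`, `n2`, `missing1`, `missing2`,
#'   `disjointified`, `species`, `method`.
#' @export
compare_age_sets <- function(set1, set2 = NULL, db, bh = FALSE) {
  stopifnot(inherits(db, "age_db"))
  res1 <- lookup_ages(db, set1)
  if (is.null(set2)) {
    set2 <- protein_list(db$ages$protein)
    res2 <- list(ages = db$ages, missing = character(0))
  } else {
    res2 <- lookup_ages(db, set2)
  }
  ids1 <- unique(res1$ages$protein)
  ids2 <- unique(res2$ages$protein)
  if (length(ids1) == 0L || length(ids2) == 0L)
    ph_validation_error("a protein set is empty after resolving IDs against the age database")
  disjointified <- FALSE
  if (all(ids1 %in% ids2)) {
    ids2 <- setdiff(ids2, ids1)
    disjointified <- TRUE
    if (length(ids2) == 0L)
      ph_validation_error(
        "degenerate background: second set is empty after removing the first set")
  } else if (length(intersect(ids1, ids2))) {
    ph_validation_error(
      "sets overlap but neither contains the other; use disjoint sets or a subset/background")
  }
  a1 <- db$ages[match(ids1, db$ages$protein), , drop = FALSE]
  a2 <- db$ages[match(ids2, db$ages$protein), , drop = FALSE]
  u <- mann_whitney_u(a1$age_mya, a2$age_mya)

  strata <- db$strata                      # root -> leaf
  n1 <- nrow(a1); n2 <- nrow(a2)
  per <- lapply(seq_len(nrow(strata)), function(i) {
    s <- strata$stratum[i]
    k1 <- sum(a1$origin == s); k2 <- sum(a2$origin == s)
    f <- fisher_exact_2x2(matrix(c(k1, n1 - k1, k2, n2 - k2), 2L, byrow = TRUE))
    data.frame(stratum = s, age_mya = strata$age_mya[i],
               n1 = k1, n2 = k2, odds_ratio = f$odds_ratio, p = f$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  if (bh) tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$stars <- significance_stars(tab$p)
  rownames(tab) <- NULL
  structure(list(
    table = tab, U = u$U, p_overall = u$p, u_method = u$method,
    n1 = n1, n2 = n2, mean1 = mean(a1$age_mya), mean2 = mean(a2$age_mya),
    missing1 = res1$missing, missing2 = res2$missing,
    disjointified = disjointified, species = db$species, method = db$method
  ), class = "age_enrichment")
}

# reporting convention: * < 0.05, ** < 0.01, *** < 0.001
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.age_enrichment <- function(x, ...) {
  cat(sprintf("Protein age enrichment (%s, %s ages)\n", x$species, x$method))
  cat(sprintf("  set sizes: %d vs %d%s\n", x$n1, x$n2,
              if (x$disjointified) " (background disjointified)" else ""))
  if (length(x$missing1) || length(x$missing2))
    cat(sprintf("  missing IDs: %d in set1, %d in set2\n",
                length(x$missing1), length(x$missing2)))
  cat(sprintf("  mean age: %.1f vs %.1f mya\n", x$mean1, x$mean2))
  cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.4g (%s)\n",
              x$U, x$p_overall, x$u_method))
  cat("  per-stratum Fisher tests (root -> leaf):\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an enrichment result
#'
#' Tab-delimited per-stratum table preceded by a `#` summary block; missing
#' IDs go to a sidecar file (`<path>.missing.txt`) when present.
#'
#' @param x an `age_enrichment`.
#' @param path output path.
#' @param extra_header optional additional `#` header lines.
#' @export
write_enrichment <- function(x, path, extra_header = character(0)) {
  stopifnot(inherits(x, "age_enrichment"))
  hdr <- c(
    sprintf("#phylostrat\t%s", as.character(utils::packageVersion("phylostrat"))),
    extra_header,
    sprintf("#species\t%s", x$species),
    sprintf("#ages_method\t%s", x$method),
    sprintf("#n1\t%d", x$n1), sprintf("#n2\t%d", x$n2),
    sprintf("#mean1_mya\t%s", ph_num(x$mean1)),
    sprintf("#mean2_mya\t%s", ph_num(x$mean2)),
    sprintf("#U\t%s", ph_num(x$U)),
    sprintf("#p_overall\t%s", ph_num(x$p_overall)),
    sprintf("#disjointified\t%s", tolower(as.character(x$disjointified)))
  )
  cols <- names(x$table)
  body <- do.call(paste, c(lapply(x$table, function(col) {
    if (is.numeric(col)) ph_num(col) else as.character(col)
  }), sep = "\t"))
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  if (length(x$missing1) || length(x$missing2)) {
    writeLines(c(if (length(x$missing1)) paste0("set1\t", x$missing1),
                 if (length(x$missing2)) paste0("set2\t", x$missing2)),
               paste0(path, ".missing.txt"))
  }
  invisible(path)
}
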