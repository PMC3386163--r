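test_that("Spearman correlation reproduces its worked examples", {
  expect_equal(spearman_correlation(1:3, c(10, 20, 30))$rho, 1.0)
  expect_equal(spearman_correlation(1:3, c(3, 1, 2))$rho, -0.5)
  # ties: rho equals rank-then-Pearson with midranks
  x <- c(1, 1, 2, 3); y <- c(4, 7, 7, 9)
  expect_equal(spearman_correlation(x, y)$rho,
               stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_correlation(c(1, 1, 1), 1:3),
               class = "phylostrat_validation_error")
  expect_error(spearman_correlation(1:2, 1:2), class = "phylostrat_argument_error")
})

test_that("rho always equals the rank-then-Pearson oracle", {
  withr::local_seed(51)
  for (i in 1:25) {
    n <- sample(3:40, 1L)
    x <- sample(0:10, n, replace = TRUE)
    y <- stats::rnorm(n)
    if (length(unique(x)) < 2L) next
    r <- spearman_correlation(x, y)
    expect_equal(r$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(r$rho, stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("exact permutation p-values match full enumeration at small n", {
  withr::local_seed(52)
  for (i in 1:12) {
    n <- sample(4:6, 1L)
    x <- sample(1:20, n)
    y <- sample(1:6, n, replace = TRUE)            # ties exercised
    if (length(unique(y)) < 2L) next
    r <- spearman_correlation(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p, spearman_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("large-n p-values follow the t approximation", {
  withr::local_seed(53)
  x <- stats::rnorm(30); y <- x + stats::rnorm(30, sd = 2)
  r <- spearman_correlation(x, y)
  tstat <- r$rho * sqrt((30 - 2) / (1 - r$rho^2))
  expect_equal(r$p, 2 * stats::pt(-abs(tstat), 28), tolerance = 1e-12)
})

test_that("spearman is invariant under strictly monotone transforms", {
  withr::local_seed(54)
  x <- stats::runif(15, 0, 1000); y <- stats::rnorm(15)
  r0 <- spearman_correlation(x, y)
  r1 <- spearman_correlation(log1p(x), y)
  r2 <- spearman_correlation(x, exp(y))
  expect_equal(r0$rho, r1$rho)
  expect_equal(r0$rho, r2$rho)
  expect_equal(r0$p, r1$p)
})

test_that("box summaries use Tukey hinges with 1.5 IQR whiskers", {
  s <- per_age_summary(c(1, 2, 3, 4, 100), rep("X", 5))
  expect_equal(s$q1, 2); expect_equal(s$median, 3); expect_equal(s$q3, 4)
  expect_equal(s$whisker_high, 4)     # 100 is outside Q3 + 1.5 IQR
  expect_equal(s$whisker_low, 1)
  expect_equal(s$mean, 22)

  s1 <- per_age_summary(7, "X")
  expect_true(all(unlist(s1[c("q1", "median", "mean", "q3",
                              "whisker_low", "whisker_high")]) == 7))
  s2 <- per_age_summary(c(1, 2, 3), rep("X", 3))
  expect_equal(s2$median, 2); expect_equal(s2$mean, 2)
})

test_that("box summary invariants: ordering and whiskers within data range", {
  withr::local_seed(55)
  vals <- stats::rlnorm(200)
  strat <- sample(c("S1", "S2", "S3"), 200, replace = TRUE)
  s <- per_age_summary(vals, strat, strata_order = c("S3", "S1", "S2"))
  expect_equal(s$stratum, c("S3", "S1", "S2"))
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  expect_true(all(s$whisker_low >= tapply(vals, strat, min)[s$stratum]))
  expect_true(all(s$whisker_high <= tapply(vals, strat, max)[s$stratum]))
})

test_that("linear trends recover exact fits and reject degenerate input", {
  ages <- c(0, 100, 300, 700, 1200)
  tr <- linear_trend(ages, 0.28 * ages + 100)
  expect_equal(tr$slope, 0.28, tolerance = 1e-12)
  expect_equal(tr$intercept, 100, tolerance = 1e-9)
  tr2 <- linear_trend(c(0, 100), c(0, 50))
  expect_equal(tr2$slope, 0.5); expect_equal(tr2$intercept, 0)
  expect_error(linear_trend(rep(500, 4), 1:4), class = "phylostrat_validation_error")
  # exclusion of ancient strata changes the fit data
  tr3 <- linear_trend(c(0, 10, 2000), c(0, 5, 9999),
                      strata = c("Y", "Y", "Old"), exclude_strata = "Old")
  expect_equal(tr3$slope, 0.5)
  expect_equal(tr3$n, 2L)
})

test_that("feature tables read with optional headers and reject duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\tlength", "p1\t100", "p2\t250.5"), f)
  ft <- read_feature_table(f)
  expect_equal(as.numeric(ft), c(100, 250.5))
  expect_equal(attr(ft, "feature_name"), "length")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\t100", "p1\t200"), f2)
  expect_error(read_feature_table(f2), class = "phylostrat_validation_error")
})

test_that("age_feature_analysis joins by ID and reports drops", {
  tr <- toy_tree()
  db <- make_age_db(paste0("p", 1:12),
                    rep(c("A", "AB", "Root"), each = 4), tr, "A")
  feats <- stats::setNames(db$ages$age_mya + 10, db$ages$protein)
  res <- age_feature_analysis(db, feats[sample(length(feats))])
  expect_equal(res$rho, 1.0)                      # feature = age exactly + 10
  expect_equal(res$n, 12L)
  expect_equal(res$summary$stratum, c("Root", "AB", "A"))
  # drop a few features and add a stranger
  feats2 <- c(feats[1:9], stranger = 1)
  res2 <- age_feature_analysis(db, feats2)
  expect_equal(res2$n_dropped_no_feature, 3L)
  expect_equal(res2$n_dropped_no_age, 1L)
})

test_that("feature = a*age + noise recovers the slope and a positive rho", {
  withr::local_seed(56)
  tr <- simulate_tree(16, seed = 57)
  sim <- simulate_families(tr, 800, 0.1, seed = 58)
  sp <- tree_leaves(tr)[1]
  db <- protein_ages(tr, sim$families, species = sp)
  a_true <- 0.28
  feats <- stats::setNames(a_true * db$ages$age_mya + stats::rnorm(nrow(db$ages), 100, 30),
                           db$ages$protein)
  res <- age_feature_analysis(db, feats)
  expect_gt(res$rho, 0)
  expect_lt(res$p, 0.01)
  fit <- stats::lm(feats ~ db$ages$age_mya)
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(res$trend$slope - a_true), 3 * se)
})
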