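test_that("Mann-Whitney U reproduces its worked examples", {
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p, 1.0)
  r <- mann_whitney_u(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  r2 <- mann_whitney_u(1, 2)
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 1.0)
  expect_error(mann_whitney_u(numeric(0), 1), class = "phylostrat_argument_error")
})

test_that("U statistics are antisymmetric and p-values symmetric", {
  withr::local_seed(41)
  for (i in 1:20) {
    x <- sample(0:500, sample(3:15, 1L), replace = TRUE)
    y <- sample(0:500, sample(3:15, 1L), replace = TRUE)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$U + b$U, length(x) * length(y))
    expect_equal(a$p, b$p)
  }
})

test_that("exact U p-values match full enumeration of rank splits", {
  withr::local_seed(42)
  for (i in 1:40) {
    n1 <- sample(1:6, 1L); n2 <- sample(1:(12 - n1), 1L)
    vals <- sample(1:1000, n1 + n2)        # untied
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    r <- mann_whitney_u(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p, mwu_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("tied/large samples agree with the reference normal approximation", {
  withr::local_seed(43)
  for (i in 1:15) {
    x <- sample(c(0, 100, 500, 1500), 40, replace = TRUE)
    y <- sample(c(0, 100, 500, 1500), 35, replace = TRUE)
    r <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(r$U, unname(ref$statistic))
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher's exact test reproduces its worked examples", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p,
               34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 0, 5), 2, byrow = TRUE))$p, 1.0)
  r <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(r$p, 2 / 252, tolerance = 1e-12)
  expect_equal(r$odds_ratio, Inf)
  expect_equal(fisher_exact_2x2(matrix(c(2, 4, 1, 3), 2, byrow = TRUE))$odds_ratio,
               6 / 4)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "phylostrat_argument_error")
})

test_that("Fisher p-values match enumeration and the stats reference", {
  withr::local_seed(44)
  for (i in 1:60) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    p <- fisher_exact_2x2(tab)$p
    expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
})

test_that("identical sets degenerate and disjoint equal-age sets are null", {
  tr <- toy_tree()
  db <- make_age_db(paste0("p", 1:10),
                    rep(c("A", "AB", "Root"), c(4, 3, 3)), tr, "A")
  expect_error(compare_age_sets(paste0("p", 1:10), paste0("p", 1:10), db),
               class = "phylostrat_validation_error")
  # disjoint sets with identical age multisets
  db2 <- make_age_db(paste0("q", 1:8),
                     rep(c("A", "Root"), 4), tr, "A")
  res <- compare_age_sets(c("q1", "q2"), c("q3", "q4"), db2)
  expect_equal(res$p_overall, 1.0)
  or <- res$table$odds_ratio
  expect_true(all(or[is.finite(or)] == 1))
  expect_equal(res$table$p, rep(1, nrow(res$table)))
})

test_that("stratum counting against a proteome background disjointifies", {
  tr <- toy_tree()
  db <- make_age_db(paste0("p", 1:10),
                    rep(c("A", "Root"), each = 5), tr, "A")
  res <- compare_age_sets("p1", NULL, db)       # p1 aged 0 at leaf A
  expect_true(res$disjointified)
  row_a <- res$table[res$table$stratum == "A", ]
  expect_equal(c(row_a$n1, row_a$n2), c(1, 4))  # table [[1,0],[4,5]]
  expect_equal(res$n1 + res$n2, 10)
  # margins: per-stratum counts sum to set sizes
  expect_equal(sum(res$table$n1), res$n1)
  expect_equal(sum(res$table$n2), res$n2)
})

test_that("partially overlapping sets are rejected; missing IDs are reported", {
  tr <- toy_tree()
  db <- make_age_db(paste0("p", 1:6), rep(c("A", "Root"), 3), tr, "A")
  expect_error(compare_age_sets(c("p1", "p2"), c("p2", "p3"), db),
               class = "phylostrat_validation_error")
  res <- compare_age_sets(c("p1", "ghost"), c("p2", "p4"), db)
  expect_equal(res$missing1, "ghost")
  expect_equal(res$n1, 1)
})

test_that("stratum tables are invariant to input list ordering", {
  tr <- simulate_tree(8, seed = 71)
  sim <- simulate_families(tr, 60, 0.15, seed = 72)
  sp <- tree_leaves(tr)[1]
  db <- protein_ages(tr, sim$families, species = sp)
  ids <- db$ages$protein
  set1 <- ids[seq(1, length(ids), 2)]
  r1 <- compare_age_sets(set1, NULL, db)
  r2 <- compare_age_sets(rev(set1), NULL, db)
  expect_equal(r1$table, r2$table)
  expect_equal(r1$p_overall, r2$p_overall)
})

test_that("BH q-values are added behind the flag and stars follow p", {
  tr <- toy_tree()
  db <- make_age_db(paste0("p", 1:40),
                    rep(c("A", "AB", "Root", "A"), 10), tr, "A")
  res <- compare_age_sets(paste0("p", 1:10), NULL, db, bh = TRUE)
  expect_true("q" %in% names(res$table))
  expect_equal(res$table$q, stats::p.adjust(res$table$p, "BH"))
  expect_true(all(res$table$stars[res$table$p >= 0.05] == ""))
})
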