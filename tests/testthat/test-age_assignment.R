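test_that("Dollo origins date proteins by the family MRCA", {
  tr <- toy_tree()
  fams <- family_table(data.frame(
    family = c("F1", "F1", "F2"), species = c("A", "B", "A"),
    protein = c("p1", "p2", "solo")))
  db <- protein_ages(tr, fams, species = "A")
  expect_equal(db$ages$origin[db$ages$protein == "p1"], "AB")
  expect_equal(db$ages$age_mya[db$ages$protein == "p1"], 100)
  expect_equal(db$ages$age_mya[db$ages$protein == "solo"], 0)  # singleton family
})

test_that("multi-gain Wagner dates each protein by its own present segment", {
  tr <- toy_tree()
  fams <- family_table(data.frame(
    family = c("F4", "F4"), species = c("A", "D"), protein = c("a4", "d4")))
  db <- protein_ages(tr, fams, species = "A", method = "wagner", gain_penalty = 1)
  expect_equal(db$ages$origin[db$ages$protein == "a4"], "A")
  expect_equal(db$ages$age_mya[db$ages$protein == "a4"], 0)
  # the same family under Dollo dates to the root
  dbd <- protein_ages(tr, fams, species = "A", method = "dollo")
  expect_equal(dbd$ages$origin[dbd$ages$protein == "a4"], "Root")
})

test_that("Dollo gives all members one origin; Wagner may split by species", {
  withr::local_seed(21)
  tr <- simulate_tree(10, seed = 22)
  sim <- simulate_families(tr, 50, 0.2, seed = 23)
  for (f in sample(rownames(sim$matrix), 10L)) {
    row <- sim$matrix[f, ]
    lab <- dollo_reconstruct(row, tr, family = f)
    present <- names(row)[row == 1]
    origins <- vapply(present, function(sp) {
      path <- leaf_to_root_path(tr, sp)
      st <- lab$state[path]
      top <- which(st == 0L)
      if (length(top)) path[top[1L] - 1L] else path[length(path)]
    }, "")
    expect_length(unique(origins), 1L)
    expect_equal(unique(unname(origins)), mrca(tr, present))
  }
})

test_that("origin ages always lie on the species' leaf-to-root path", {
  tr <- simulate_tree(12, seed = 31)
  sim <- simulate_families(tr, 40, 0.15, seed = 32)
  sp <- tree_leaves(tr)[1]
  for (m in c("dollo", "wagner")) {
    db <- protein_ages(tr, sim$families, species = sp, method = m)
    path <- leaf_to_root_path(tr, sp)
    expect_true(all(db$ages$origin %in% path))
    expect_true(all(db$ages$age_mya %in% tr$ages[phylostrat:::node_id(tr, path)]))
  }
})

test_that("a labeling that contradicts the leaf's own presence is an error", {
  tr <- toy_tree()
  fams <- family_table(data.frame(family = "F1", species = "A", protein = "p1"))
  bad <- dollo_reconstruct(c(A = 0, B = 1, C = 0, D = 0), tr, family = "F1")
  expect_error(assign_protein_ages(list(F1 = bad), fams, tr, "A"),
               class = "phylostrat_validation_error")
  expect_error(assign_protein_ages(list(), fams, tr, "A"),
               class = "phylostrat_argument_error")
})

test_that("proteome entries outside the family database get the no_family leaf age", {
  tr <- toy_tree()
  fams <- family_table(data.frame(family = "F1", species = c("A", "B"),
                                  protein = c("p1", "p2")))
  db <- protein_ages(tr, fams, species = "A", proteome = c("p1", "orphan"))
  orph <- db$ages[db$ages$protein == "orphan", ]
  expect_equal(orph$origin, "A")
  expect_equal(orph$age_mya, 0)
  expect_equal(orph$flag, "no_family")
})

test_that("domain strategies take max/min ages with leafward tie-breaks", {
  tr <- toy_tree()
  dom <- data.frame(domain = c("d1", "d2", "d3"),
                    taxon = c("AB", "Root", "A"))
  pd <- data.frame(protein = c("p", "p", "q", "r", "r"),
                   domain = c("d1", "d2", "d3", "d1", "d1"))
  old <- domain_based_ages(dom, pd, "oldest", tr, "A", proteome = c("p", "q", "r", "z"))
  yng <- domain_based_ages(dom, pd, "youngest", tr, "A", proteome = c("p", "q", "r", "z"))
  a <- function(db, id) db$ages$age_mya[db$ages$protein == id]
  expect_equal(a(old, "p"), 500); expect_equal(a(yng, "p"), 100)
  expect_equal(a(old, "q"), a(yng, "q"))              # single domain agrees
  expect_equal(a(old, "r"), a(yng, "r"))
  expect_equal(a(old, "z"), 0)                        # no predicted domains
  expect_equal(old$ages$flag[old$ages$protein == "z"], "no_domains")
})

test_that("domain age ties resolve to the more leafward taxon", {
  tr <- parse_species_tree("((A,B)AB,C)Root;",
                           ages = c(AB = 100, Root = 100))
  dom <- data.frame(domain = c("d1", "d2"), taxon = c("Root", "AB"))
  pd <- data.frame(protein = c("p", "p"), domain = c("d1", "d2"))
  db <- domain_based_ages(dom, pd, "oldest", tr, "A")
  expect_equal(db$ages$origin, "AB")
})

test_that("off-path domain taxa are rejected", {
  tr <- toy_tree()
  dom <- data.frame(domain = "d1", taxon = "CD")
  pd <- data.frame(protein = "p", domain = "d1")
  expect_error(domain_based_ages(dom, pd, "oldest", tr, "A"),
               class = "phylostrat_validation_error")
})

test_that("lookup partitions into matched and missing without dropping", {
  tr <- toy_tree()
  db <- make_age_db(c("p1", "p2"), c("AB", "Root"), tr, "A")
  res <- lookup_ages(db, c("p1", "pX"))
  expect_equal(res$ages$protein, "p1")
  expect_equal(res$missing, "pX")
  empty <- lookup_ages(db, character(0))
  expect_equal(nrow(empty$ages), 0L)
  expect_equal(empty$missing, character(0))
  full <- lookup_ages(db, c("p2", "p1"))
  expect_equal(full$ages$protein, c("p2", "p1"))   # input order preserved
  expect_length(full$missing, 0L)
})

test_that("GAF symbol aliases are used as lookup fallback", {
  tr <- toy_tree()
  db <- make_age_db(c("SYMBOL1", "p2"), c("AB", "Root"), tr, "A")
  pl <- protein_list(c("Q111", "p2"), aliases = c(Q111 = "SYMBOL1"))
  res <- lookup_ages(db, pl)
  expect_equal(res$ages$protein, c("SYMBOL1", "p2"))
  expect_length(res$missing, 0L)
})

test_that("age databases round-trip bit-exactly through files", {
  tr <- simulate_tree(8, seed = 61)
  sim <- simulate_families(tr, 25, 0.1, seed = 62)
  db <- protein_ages(tr, sim$families, species = tree_leaves(tr)[2],
                     method = "wagner", gain_penalty = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_age_db(db, f)
  db2 <- read_age_db(f)
  expect_equal(db2$ages, db$ages)
  expect_equal(db2$strata, db$strata)
  expect_equal(db2$db_name, db$db_name)
  expect_identical(readLines(f), {write_age_db(db2, f); readLines(f)})
})
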