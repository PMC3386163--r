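#' Simulate a dated species tree
#'
#' Generates a random rooted tree with strictly decreasing ages from the
#' root to the leaves (leaves at 0), by repeatedly joining random subsets of
#' active lineages and placing each new ancestor a random interval above its
#' oldest child. With `polytomy = TRUE` at least one join takes three
#' children, mirroring unresolved nodes in real dated trees. Deterministic
#' for a given seed; the caller's RNG state is untouched.
#'
#' @param n_leaves number of leaf species (>= 2), labeled `s1..sN`.
#' @param seed integer random seed (mandatory: every simulated input must be
#'   replayable).
#' @param polytomy inject one multifurcation when possible.
#' @return a `species_tree`.
#' @export
simulate_tree <- function(n_leaves, seed, polytomy = FALSE) {
  if (!is.numeric(n_leaves) || length(n_leaves) != 1L || n_leaves < 2L)
    ph_argument_error("'n_leaves' must be an integer >= 2")
  n_leaves <- as.integer(n_leaves)
  with_seed(seed, {
    newick <- stats::setNames(paste0("s", seq_len(n_leaves)), NULL)
    ages <- stats::setNames(numeric(n_leaves), newick)
    active <- newick
    active_age <- numeric(n_leaves)
    k <- 0L
    did_poly <- !polytomy
    while (length(active) > 1L) {
      size <- 2L
      if (!did_poly && length(active) >= 3L) { size <- 3L; did_poly <- TRUE }
      pick <- sample.int(length(active), size)
      k <- k + 1L
      lab <- paste0("N", k)
      age <- max(active_age[pick]) + stats::runif(1L, 20, 150)
      merged <- paste0("(", paste(active[pick], collapse = ","), ")", lab)
      ages[lab] <- age
      active <- c(active[-pick], merged)
      active_age <- c(active_age[-pick], age)
    }
    parse_species_tree(paste0(active, ";"), ages = ages)
  })
}

#' Simulate protein families with known gain/loss histories
#'
#' Each family originates at a node sampled from the tree (uniformly by
#' default); every branch strictly below the origin is then independently
#' lost with probability `loss_prob` (no regain, so the true history is
#' Dollo-consistent by construction). The family is present in exactly the
#' leaves under its origin not separated from it by a lost branch. Families
#' whose descendants are all lost are discarded and regenerated, so presence
#' rows are never all-zero. One member protein per present species is
#' emitted, named `<family>|<species>`.
#'
#' @param tree a `species_tree`.
#' @param n_families number of families to simulate (>= 0).
#' @param loss_prob per-branch loss probability in `[0, 1)`.
#' @param seed integer random seed.
#' @param origin_weights optional named nonnegative sampling weights over
#'   node labels (default uniform over all nodes).
#' @return an object of class `simulated_history`: list with `tree`,
#'   `families` (a `family_table`, or `NULL` when `n_families = 0`),
#'   `matrix` (presence matrix), `truth` (data frame: family, true origin,
#'   comma-separated lost branches), and `params`.
#' @export
simulate_families <- function(tree, n_families, loss_prob, seed,
                              origin_weights = NULL) {
  stopifnot(inherits(tree, "species_tree"))
  if (!is.numeric(n_families) || n_families < 0L)
    ph_argument_error("'n_families' must be >= 0")
  n_families <- as.integer(n_families)
  if (!is.numeric(loss_prob) || loss_prob < 0 || loss_prob >= 1)
    ph_argument_error("'loss_prob' must be in [0, 1)")
  w <- rep(1, tree$n_nodes)
  if (!is.null(origin_weights)) {
    w <- rep(0, tree$n_nodes)
    ids <- node_id(tree, names(origin_weights))
    w[ids] <- as.numeric(origin_weights)
    if (any(w < 0) || sum(w) == 0)
      ph_argument_error("'origin_weights' must be nonnegative with a positive sum")
  }
  leaves <- tree_leaves(tree)
  with_seed(seed, {
    fam_rows <- vector("list", n_families)
    truth <- vector("list", n_families)
    mat <- matrix(0L, nrow = n_families, ncol = length(leaves),
                  dimnames = list(if (n_families) paste0("F", seq_len(n_families)), leaves))
    for (i in seq_len(n_families)) {
      fam <- paste0("F", i)
      repeat {
        origin <- sample.int(tree$n_nodes, 1L, prob = w)
        # survival flags below the origin, in preorder so parents resolve first
        alive <- logical(tree$n_nodes)
        alive[origin] <- TRUE
        lost <- character(0)
        for (v in tree$preorder) {
          p <- tree$parent[v]
          if (v == origin || p == 0L || !alive[p]) next
          if (in_subtree(tree, v, origin)) {
            if (stats::runif(1L) < loss_prob) lost <- c(lost, tree$labels[v])
            else alive[v] <- TRUE
          }
        }
        present <- which(alive[seq_len(tree$n_tips)])
        if (length(present)) break          # extinction: regenerate family
      }
      mat[i, present] <- 1L
      fam_rows[[i]] <- data.frame(family = fam, species = leaves[present],
                                  protein = paste0(fam, "|", leaves[present]),
                                  stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(family = fam, origin = tree$labels[origin],
                               losses = paste(lost, collapse = ","),
                               stringsAsFactors = FALSE)
    }
    structure(list(
      tree = tree,
      families = if (n_families) family_table(do.call(rbind, fam_rows)) else NULL,
      matrix = mat,
      truth = if (n_families) do.call(rbind, truth) else
        data.frame(family = character(0), origin = character(0),
                   losses = character(0), stringsAsFactors = FALSE),
      params = list(n_families = n_families, loss_prob = loss_prob,
                    seed = as.integer(seed),
                    origin_weights = origin_weights)
    ), class = "simulated_history")
  })
}

# is v in the subtree rooted at node a?
in_subtree <- function(tree, v, a) {
  while (v != 0L) {
    if (v == a) return(TRUE)
    v <- tree$parent[v]
  }
  FALSE
}

#' @export
print.simulated_history <- function(x, ...) {
  cat(sprintf("Simulated gain/loss history: %d families on %d leaves (loss prob %g, seed %d)\n",
              x$params$n_families, x$tree$n_tips, x$params$loss_prob, x$params$seed))
  invisible(x)
}

#' Write a simulated data set
#'
#' Writes the tree (Newick + age table), the family table, and the truth
#' table (family, true origin, lost branches) to a directory, in the
#' package's standard exchange formats.
#'
#' @param sim a `simulated_history`.
#' @param dir output directory (created if needed).
#' @param header optional `#` header lines prepended to the tabular files.
#' @return named character vector of paths.
#' @export
write_simulation <- function(sim, dir, header = character(0)) {
  stopifnot(inherits(sim, "simulated_history"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             ages = file.path(dir, "node_ages.tsv"),
             families = file.path(dir, "families.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_species_tree(sim$tree, paths[["tree"]], paths[["ages"]])
  fam <- sim$families
  fam_lines <- if (is.null(fam)) character(0) else
    paste(fam$family, fam$species, fam$protein, sep = "\t")
  writeLines(c(header, "# family\tspecies\tprotein", fam_lines), paths[["families"]])
  writeLines(c(header,
               sprintf("# seed\t%d\tloss_prob\t%s", sim$params$seed,
                       ph_num(sim$params$loss_prob)),
               "# family\ttrue_origin\tlosses",
               paste(sim$truth$family, sim$truth$origin, sim$truth$losses, sep = "\t")),
             paths[["truth"]])
  invisible(paths)
}
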