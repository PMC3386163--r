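#' Parse a rooted, dated species tree
#'
#' Builds the dated species tree that defines the age scale for all protein
#' age analyses. The tree is read from a Newick string (internal node labels
#' are used as taxon names for age strata) and node ages in millions of years
#' (mya) are taken either from a supplied label/age table or derived from
#' branch lengths with extant leaves fixed at age 0.
#'
#' Unlabeled internal nodes are auto-named `node_<preorder-index>`
#' deterministically, so age reports are stable across runs. The tree is
#' treated as rooted as written; no rerooting is performed. Polytomies are
#' permitted.
#'
#' When both an age table and branch lengths are available, the table is
#' authoritative; a disagreement larger than 1e-6 mya between a table entry
#' and the branch-length-derived age is a validation error.
#'
#' @param text a Newick string (one tree, terminated by `;`).
#' @param ages optional node ages: a named numeric vector (names are node
#'   labels, values are ages in mya) or a two-column data frame
#'   (label, age_mya). Leaves not mentioned default to age 0.
#' @return an object of class `species_tree`.
#' @examples
#' tr <- parse_species_tree("((A,B)AB,(C,D)CD)Root;",
#'                          ages = c(AB = 100, CD = 150, Root = 500))
#' mrca(tr, c("A", "B"))
#' leaf_to_root_path(tr, "A")
#' @export
parse_species_tree <- function(text, ages = NULL) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    ph_argument_error("'text' must be a single Newick string")
  check_newick_balance(text)
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) ph_parse_error(sprintf("malformed Newick: %s", conditionMessage(e)))
  )
  if (is.null(phy) || !inherits(phy, "phylo"))
    ph_parse_error("malformed Newick: could not read a tree from input")
  build_species_tree(phy, ages)
}

#' Read a species tree from files
#'
#' File-based counterpart of [parse_species_tree()]: reads the Newick file
#' and, optionally, a tab-delimited age table (column 1 = node label,
#' column 2 = age in mya; `#` comment lines ignored).
#'
#' @param newick_path path to a Newick file.
#' @param age_table_path optional path to the node age table.
#' @return an object of class `species_tree`.
#' @export
read_species_tree <- function(newick_path, age_table_path = NULL) {
  ph_check_file(newick_path)
  text <- paste(readLines(newick_path, warn = FALSE), collapse = "")
  ages <- if (!is.null(age_table_path)) read_age_table(age_table_path)
  parse_species_tree(text, ages = ages)
}

#' @rdname read_species_tree
#' @param path path to a tab-delimited node age table.
#' @return `read_age_table` returns a named numeric vector of ages (mya).
#' @export
read_age_table <- function(path) {
  lines <- ph_read_lines(path)
  if (length(lines) == 0L) ph_format_error(sprintf("age table '%s' is empty", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    ph_format_error(sprintf("age table '%s': line %d does not have 2 tab-separated columns",
                            path, attr(lines, "line_numbers")[bad[1L]]))
  labs <- vapply(parts, `[[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(vals))
    ph_format_error(sprintf("age table '%s': non-numeric age for node '%s'",
                            path, labs[which(is.na(vals))[1L]]))
  if (anyDuplicated(labs))
    ph_validation_error(sprintf("age table '%s': duplicate node label(s): %s", path,
                                paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  stats::setNames(vals, labs)
}

# Report the character offset of the first unbalanced parenthesis.
check_newick_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") { depth <- depth + 1L; stack <- c(stack, i) }
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        ph_parse_error(sprintf("malformed Newick: unmatched ')' at character offset %d", i))
      stack <- stack[-length(stack)]
    }
  }
  if (depth > 0L)
    ph_parse_error(sprintf("malformed Newick: unmatched '(' at character offset %d", stack[1L]))
  invisible(TRUE)
}

# Assemble the species_tree structure from an ape phylo object.
build_species_tree <- function(phy, ages = NULL) {
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  root <- n_tip + 1L
  parent <- integer(n_all)
  children <- vector("list", n_all)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    parent[ch] <- p
    children[[p]] <- c(children[[p]], ch)
  }
  # deterministic preorder (children in stored edge order)
  preorder <- integer(n_all)
  stack <- root; k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; preorder[k] <- v
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  pre_rank <- integer(n_all); pre_rank[preorder] <- seq_len(n_all)

  labels <- character(n_all)
  labels[seq_len(n_tip)] <- phy$tip.label
  nl <- phy$node.label
  if (is.null(nl)) nl <- rep("", phy$Nnode)
  nl[is.na(nl)] <- ""
  labels[root:n_all] <- nl
  unlab <- which(!nzchar(labels))
  if (length(unlab)) labels[unlab] <- sprintf("node_%d", pre_rank[unlab])
  if (anyDuplicated(labels))
    ph_validation_error(sprintf("duplicate node label(s): %s",
                                paste(unique(labels[duplicated(labels)]), collapse = ", ")))

  ages_vec <- resolve_node_ages(phy, labels, children, preorder, n_tip, ages)

  # monotone nesting of dates
  for (v in seq_len(n_all)) {
    p <- parent[v]
    if (p != 0L && ages_vec[p] < ages_vec[v] - 1e-9)
      ph_validation_error(sprintf(
        "dating error: node '%s' (%.6g mya) is older than its parent '%s' (%.6g mya)",
        labels[v], ages_vec[v], labels[p], ages_vec[p]))
  }
  if (any(ages_vec < 0))
    ph_validation_error("dating error: negative node age(s)")

  structure(list(
    phylo = phy, n_tips = n_tip, n_nodes = n_all, root = root,
    labels = labels, ages = ages_vec, parent = parent,
    children = children, preorder = preorder,
    index = stats::setNames(seq_len(n_all), labels)
  ), class = "species_tree")
}

resolve_node_ages <- function(phy, labels, children, preorder, n_tip, ages) {
  n_all <- length(labels)
  have_bl <- !is.null(phy$edge.length) && !anyNA(phy$edge.length)
  bl_ages <- NULL
  if (have_bl) {
    el <- numeric(n_all)
    el[phy$edge[, 2L]] <- phy$edge.length
    bl_ages <- numeric(n_all)
    for (v in rev(preorder)) {
      kids <- children[[v]]
      if (length(kids)) bl_ages[v] <- max(bl_ages[kids] + el[kids])
    }
  }
  tab <- NULL
  if (!is.null(ages)) {
    if (is.data.frame(ages)) {
      if (ncol(ages) < 2L) ph_argument_error("age table must have two columns (label, age_mya)")
      tab <- stats::setNames(as.numeric(ages[[2L]]), as.character(ages[[1L]]))
    } else if (is.numeric(ages) && !is.null(names(ages))) {
      tab <- ages
    } else ph_argument_error("'ages' must be a named numeric vector or a (label, age) data frame")
    unknown <- setdiff(names(tab), labels)
    if (length(unknown))
      ph_validation_error(sprintf("age table names unknown node(s): %s",
                                  paste(unknown, collapse = ", ")))
  }
  if (is.null(tab) && is.null(bl_ages))
    ph_validation_error("no node ages available: supply an age table or branch lengths")

  out <- numeric(n_all)                  # leaves default to 0
  if (!is.null(bl_ages)) out <- bl_ages
  if (!is.null(tab)) {
    idx <- match(names(tab), labels)
    if (!is.null(bl_ages)) {
      off <- abs(bl_ages[idx] - unname(tab))
      if (any(off > 1e-6)) {
        j <- which(off > 1e-6)[1L]
        ph_validation_error(sprintf(
          "age table disagrees with branch lengths for node '%s' (%.8g vs %.8g mya)",
          names(tab)[j], unname(tab)[j], bl_ages[idx[j]]))
      }
    }
    out[idx] <- unname(tab)
    internal <- setdiff(seq_len(n_all), seq_len(n_tip))
    missing <- internal[!(labels[internal] %in% names(tab))]
    if (is.null(bl_ages) && length(missing))
      ph_validation_error(sprintf("no age for internal node(s): %s",
                                  paste(labels[missing], collapse = ", ")))
  }
  out
}

node_id <- function(tree, label, what = "node") {
  id <- tree$index[label]
  if (anyNA(id))
    ph_lookup_error(sprintf("unknown %s label(s): %s", what,
                            paste(label[is.na(id)], collapse = ", ")))
  unname(id)
}

#' Tree accessors
#'
#' `tree_leaves` returns the canonical leaf order used for all presence
#' matrices and phylogenetic profiles; `node_age` returns a node's age in mya.
#'
#' @param tree a `species_tree`.
#' @param label node label(s).
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "species_tree"))
  tree$labels[seq_len(tree$n_tips)]
}

#' @rdname tree_leaves
#' @export
node_age <- function(tree, label) {
  stopifnot(inherits(tree, "species_tree"))
  unname(tree$ages[node_id(tree, label)])
}

# internal: node ids from a leaf (or node) up to the root
path_ids <- function(tree, v) {
  out <- v
  while (tree$parent[v] != 0L) {
    v <- tree$parent[v]
    out <- c(out, v)
  }
  out
}

#' Path from a leaf to the root
#'
#' Returns the node labels on the path from a leaf species up to the root,
#' leaf first, root last. These nodes are the only possible origins (age
#' strata) for a protein of that species.
#'
#' @param tree a `species_tree`.
#' @param leaf_label a leaf (species) label.
#' @return character vector of node labels, leaf first.
#' @export
leaf_to_root_path <- function(tree, leaf_label) {
  stopifnot(inherits(tree, "species_tree"))
  if (length(leaf_label) != 1L) ph_argument_error("'leaf_label' must be a single label")
  v <- node_id(tree, leaf_label, "leaf")
  if (v > tree$n_tips) ph_lookup_error(sprintf("'%s' is not a leaf", leaf_label))
  tree$labels[path_ids(tree, v)]
}

#' Most recent common ancestor of a set of leaves
#'
#' `mrca(tree, x)` for a single leaf is the leaf itself; for several leaves it
#' is the deepest node ancestral to all of them. Under Dollo parsimony a
#' family's origin is the MRCA of all species in which it is observed.
#'
#' @param tree a `species_tree`.
#' @param leaf_labels nonempty character vector of leaf labels.
#' @return the MRCA node label.
#' @export
mrca <- function(tree, leaf_labels) {
  stopifnot(inherits(tree, "species_tree"))
  if (length(leaf_labels) == 0L) ph_argument_error("'leaf_labels' must be nonempty")
  leaf_labels <- unique(leaf_labels)
  ids <- node_id(tree, leaf_labels, "leaf")
  if (any(ids > tree$n_tips))
    ph_lookup_error(sprintf("not leaf label(s): %s",
                            paste(leaf_labels[ids > tree$n_tips], collapse = ", ")))
  tree$labels[mrca_id(tree, ids)]
}

# internal: MRCA on node ids via path intersection (handles polytomies)
mrca_id <- function(tree, ids) {
  common <- path_ids(tree, ids[1L])
  for (v in ids[-1L]) common <- intersect(common, path_ids(tree, v))
  common[1L]  # paths are leaf->root; first common element is the deepest
}

#' Age strata along a species' path
#'
#' The named taxa on the leaf-to-root path of a species, ordered root to
#' leaf, with their ages. These are the discrete age categories used in
#' enrichment tables.
#'
#' @param tree a `species_tree`.
#' @param species a leaf label.
#' @return data frame with columns `stratum` and `age_mya`, root first.
#' @export
age_strata <- function(tree, species) {
  labs <- rev(leaf_to_root_path(tree, species))
  data.frame(stratum = labs, age_mya = unname(tree$ages[node_id(tree, labs)]),
             stringsAsFactors = FALSE)
}

#' Write a species tree to files
#'
#' Serializes the topology (with all node labels) as Newick and the node ages
#' as a two-column tab-delimited table, the same formats [read_species_tree()]
#' accepts; a parse round-trip reproduces the node set, topology, and ages.
#'
#' @param tree a `species_tree`.
#' @param newick_path output Newick path.
#' @param age_table_path output age table path.
#' @export
write_species_tree <- function(tree, newick_path, age_table_path) {
  stopifnot(inherits(tree, "species_tree"))
  phy <- tree$phylo
  phy$node.label <- tree$labels[(tree$n_tips + 1L):tree$n_nodes]
  phy$edge.length <- NULL
  ape::write.tree(phy, file = newick_path)
  writeLines(c("# node label\tage_mya",
               paste(tree$labels, ph_num(tree$ages), sep = "\t")),
             age_table_path)
  invisible(c(newick_path, age_table_path))
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("Dated species tree: %d leaves, %d internal nodes\n",
              x$n_tips, x$n_nodes - x$n_tips))
  cat(sprintf("  root: %s (%.6g mya)\n", x$labels[x$root], x$ages[x$root]))
  nl <- tree_leaves(x)
  cat(sprintf("  leaves: %s%s\n", paste(utils::head(nl, 8L), collapse = ", "),
              if (length(nl) > 8L) ", ..." else ""))
  invisible(x)
}
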