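#' Ancestral presence/absence reconstruction
#'
#' Infers a family's history of gains and losses on the species tree from
#' its presence pattern at the leaves. Two algorithms are available:
#'
#' * **Dollo parsimony** ([dollo_reconstruct()]) assumes the family was
#'   gained exactly once, so its origin is the most recent common ancestor
#'   (MRCA) of all species in which it is observed, with losses explaining
#'   any absences inside that clade.
#' * **Asymmetric Wagner parsimony** ([wagner_reconstruct()]) allows
#'   multiple gains and losses and minimizes total cost
#'   `gain_penalty * #gains + loss_penalty * #losses`. The loss penalty is
#'   the fixed reference (1); the gain penalty is relative to it, default 1.
#'
#' Both return an `ancestral_labeling`: a 0/1 state for every node, the
#' implied gain and loss events (a gain is a node in state 1 whose parent is
#' in state 0, counting a present root as a gain; a loss is the reverse),
#' and the total cost.
#'
#' @param row named 0/1 presence vector over all tree leaves (any order).
#' @param tree a `species_tree`.
#' @param gain_penalty positive cost of a 0 to 1 transition along a branch.
#' @param loss_penalty positive cost of a 1 to 0 transition (reference 1).
#' @param family optional family ID recorded in the result.
#' @return an object of class `ancestral_labeling` with elements `family`,
#'   `state` (named integer over node labels), `gains`, `losses` (label
#'   vectors), `cost`, `method`, `gain_penalty`, `loss_penalty`.
#' @name reconstruction
NULL

# validate and order a presence row to the tree's canonical leaf order
check_presence_row <- function(row, tree) {
  leaves <- tree_leaves(tree)
  if (tree$n_tips < 2L)
    ph_argument_error("reconstruction requires a tree with at least 2 leaves")
  if (is.logical(row)) row <- as.integer(row)
  if (is.null(names(row)) || !setequal(names(row), leaves))
    ph_argument_error("presence row must be named by exactly the tree's leaf labels")
  row <- row[leaves]
  if (!all(row %in% c(0L, 1L))) ph_argument_error("presence row must be 0/1")
  if (sum(row) == 0L) ph_argument_error("presence row is all-zero: family observed nowhere")
  as.integer(row)
}

check_costs <- function(gain_penalty, loss_penalty) {
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!ok(gain_penalty) || !ok(loss_penalty))
    ph_argument_error("gain and loss penalties must be single positive finite numbers")
}

# events + cost implied by a full state labeling
labeling_events <- function(state, tree, gain_penalty, loss_penalty) {
  gains <- losses <- integer(0)
  for (v in seq_len(tree$n_nodes)) {
    p <- tree$parent[v]
    ps <- if (p == 0L) 0L else state[p]   # a present root counts as a root gain
    if (state[v] == 1L && ps == 0L) gains <- c(gains, v)
    if (state[v] == 0L && ps == 1L) losses <- c(losses, v)
  }
  list(gains = gains, losses = losses,
       cost = gain_penalty * length(gains) + loss_penalty * length(losses))
}

new_labeling <- function(tree, state, method, gain_penalty, loss_penalty, family) {
  ev <- labeling_events(state, tree, gain_penalty, loss_penalty)
  structure(list(
    family = family,
    state = stats::setNames(as.integer(state), tree$labels),
    gains = tree$labels[ev$gains],
    losses = tree$labels[ev$losses],
    cost = ev$cost, method = method,
    gain_penalty = gain_penalty, loss_penalty = loss_penalty
  ), class = "ancestral_labeling")
}

#' @rdname reconstruction
#' @export
dollo_reconstruct <- function(row, tree, gain_penalty = 1, loss_penalty = 1,
                              family = NA_character_) {
  stopifnot(inherits(tree, "species_tree"))
  check_costs(gain_penalty, loss_penalty)
  row <- check_presence_row(row, tree)
  present <- which(row == 1L)
  g <- mrca_id(tree, present)

  # has_present[v]: subtree of v contains a present leaf
  has_present <- logical(tree$n_nodes)
  has_present[present] <- TRUE
  for (v in rev(tree$preorder)) {
    kids <- tree$children[[v]]
    if (length(kids) && any(has_present[kids])) has_present[v] <- TRUE
  }
  # in_gain[v]: v is in the subtree rooted at the gain node
  in_gain <- logical(tree$n_nodes)
  in_gain[g] <- TRUE
  for (v in tree$preorder) {
    p <- tree$parent[v]
    if (p != 0L && in_gain[p]) in_gain[v] <- TRUE
  }
  # minimal-loss Dollo labeling: present iff on a path from the gain node to
  # a present leaf; losses land on the highest absent branches in the clade
  state <- as.integer(in_gain & has_present)
  new_labeling(tree, state, "dollo", gain_penalty, loss_penalty, family)
}

#' @rdname reconstruction
#' @export
wagner_reconstruct <- function(row, tree, gain_penalty = 1, loss_penalty = 1,
                               family = NA_character_) {
  stopifnot(inherits(tree, "species_tree"))
  check_costs(gain_penalty, loss_penalty)
  row <- check_presence_row(row, tree)

  trans <- matrix(c(0, gain_penalty, loss_penalty, 0), nrow = 2L, byrow = TRUE)
  # cost[s+1, v]: min cost of v's subtree given v in state s (Sankoff)
  cost <- matrix(Inf, nrow = 2L, ncol = tree$n_nodes)
  for (v in seq_len(tree$n_tips)) cost[row[v] + 1L, v] <- 0
  for (v in rev(tree$preorder)) {
    kids <- tree$children[[v]]
    if (!length(kids)) next
    for (s in 0:1) {
      acc <- 0
      for (ch in kids)
        acc <- acc + min(cost[1L, ch] + trans[s + 1L, 1L],
                         cost[2L, ch] + trans[s + 1L, 2L])
      cost[s + 1L, v] <- acc
    }
  }
  root <- tree$root
  tot0 <- cost[1L, root]
  tot1 <- cost[2L, root] + gain_penalty   # a present root is a gain on the stem
  state <- integer(tree$n_nodes)
  state[root] <- if (tot0 <= tot1) 0L else 1L   # ties toward absence
  for (v in tree$preorder) {
    for (ch in tree$children[[v]]) {
      c0 <- cost[1L, ch] + trans[state[v] + 1L, 1L]
      c1 <- cost[2L, ch] + trans[state[v] + 1L, 2L]
      state[ch] <- if (c0 <= c1) 0L else 1L     # ties toward absence
    }
  }
  lab <- new_labeling(tree, state, "wagner", gain_penalty, loss_penalty, family)
  stopifnot(isTRUE(all.equal(lab$cost, min(tot0, tot1))))
  lab
}

#' Exhaustive minimum-cost reconstruction (testing oracle)
#'
#' Enumerates every assignment of 0/1 states to the internal nodes (leaves
#' fixed to the observed presence row) and returns the exact minimum cost
#' together with all optimal labelings. Exponential in the number of
#' internal nodes; intended as an independent oracle for
#' [wagner_reconstruct()] on small trees.
#'
#' @inheritParams reconstruction
#' @return list with `cost` (exact optimum) and `labelings` (list of named
#'   0/1 state vectors attaining it).
#' @export
brute_force_reconstruct <- function(row, tree, gain_penalty = 1, loss_penalty = 1) {
  stopifnot(inherits(tree, "species_tree"))
  check_costs(gain_penalty, loss_penalty)
  row <- check_presence_row(row, tree)
  internal <- setdiff(seq_len(tree$n_nodes), seq_len(tree$n_tips))
  k <- length(internal)
  if (k > 20L) ph_argument_error("tree too large for exhaustive enumeration (> 20 internal nodes)")
  best <- Inf; best_states <- list()
  state <- integer(tree$n_nodes)
  state[seq_len(tree$n_tips)] <- row
  for (code in 0:(2^k - 1L)) {
    state[internal] <- bitwAnd(bitwShiftR(code, seq_len(k) - 1L), 1L)
    ev <- labeling_events(state, tree, gain_penalty, loss_penalty)
    if (ev$cost < best - 1e-12) {
      best <- ev$cost
      best_states <- list(stats::setNames(state, tree$labels))
    } else if (abs(ev$cost - best) <= 1e-12) {
      best_states <- c(best_states, list(stats::setNames(state, tree$labels)))
    }
  }
  list(cost = best, labelings = best_states)
}

#' @export
print.ancestral_labeling <- function(x, ...) {
  cat(sprintf("Ancestral labeling (%s)%s\n", x$method,
              if (!is.na(x$family)) paste0(" for family ", x$family) else ""))
  cat(sprintf("  gains: %s\n", paste(x$gains, collapse = ", ")))
  cat(sprintf("  losses: %s\n",
              if (length(x$losses)) paste(x$losses, collapse = ", ") else "(none)"))
  cat(sprintf("  cost: %g (gain penalty %g, loss penalty %g)\n",
              x$cost, x$gain_penalty, x$loss_penalty))
  invisible(x)
}

#' Write reconstruction results
#'
#' Tab-delimited: family ID, origin node label(s), cost, gains, losses
#' (comma-separated lists).
#'
#' @param labelings list of `ancestral_labeling` objects.
#' @param path output path.
#' @param header optional `#` header lines.
#' @export
write_reconstructions <- function(labelings, path, header = character(0)) {
  rows <- vapply(labelings, function(l) {
    paste(if (is.na(l$family)) "" else l$family,
          paste(l$gains, collapse = ","),
          ph_num(l$cost),
          paste(l$gains, collapse = ","),
          paste(l$losses, collapse = ","), sep = "\t")
  }, "")
  writeLines(c(header, "# family\torigin\tcost\tgains\tlosses", rows), path)
  invisible(path)
}
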