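# Shared fixtures and independent oracles for the test suite.

# canonical 4-leaf example tree
toy_tree <- function() {
  parse_species_tree("((A,B)AB,(C,D)CD)Root;",
                     ages = c(AB = 100, CD = 150, Root = 500))
}

# age database built directly from (protein, origin) assignments
make_age_db <- function(ids, origins, tree, species, method = "dollo") {
  ages <- data.frame(
    protein = ids, species = species, family = "none", origin = origins,
    age_mya = vapply(origins, function(o) node_age(tree, o), 0),
    method = method, flag = "", stringsAsFactors = FALSE
  )
  phylostrat:::new_age_db(ages, species, tree, method, "test")
}

# random presence row over the tree's leaves (at least one present)
random_presence_row <- function(tree, p = 0.5) {
  leaves <- tree_leaves(tree)
  repeat {
    row <- stats::setNames(stats::rbinom(length(leaves), 1L, p), leaves)
    if (sum(row) > 0L) return(row)
  }
}

# --- independent statistical oracles (enumeration / closed form) ---------

# exact two-sided Mann-Whitney p by enumerating all C(N, n1) rank splits
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(N, n1)
  us <- colSums(matrix(seq_len(N)[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  u_min <- min(u_obs, n1 * (N - n1) - u_obs)
  min(1, 2 * mean(us <= u_min))
}

# two-sided Fisher p by direct hypergeometric enumeration via lchoose
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; c2 <- b + d; N <- r1 + c_ + d
  kk <- max(0, r1 - c2):min(r1, c1)
  lp <- lchoose(c1, kk) + lchoose(c2, r1 - kk) - lchoose(c1 + c2, r1)
  probs <- exp(lp)
  pobs <- exp(lchoose(c1, a) + lchoose(c2, r1 - a) - lchoose(c1 + c2, r1))
  min(1, sum(probs[probs <= pobs * (1 + 1e-12)]))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# exact two-sided Spearman p by full permutation enumeration (n <= 6)
spearman_enum_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- all_perms(length(x))
  rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# copy the packaged toy data set into a fresh directory; returns the dir
toy_fixture_dir <- function() {
  src <- system.file("extdata", "toy", package = "phylostrat")
  dst <- withr::local_tempdir(.local_envir = parent.frame())
  file.copy(list.files(src, full.names = TRUE), dst)
  dst
}
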