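#' Estimate phylogenetic ages for the proteins of a species
#'
#' The central fitting function. Given a dated species tree and a protein
#' family table, it reconstructs each relevant family's gain/loss history
#' (Dollo or asymmetric Wagner parsimony) and assigns every protein of the
#' focal species the branch on the path between its species and the root on
#' which its family first appeared. The reported age (in mya) is the
#' divergence-time lower bound of that origin taxon.
#'
#' Under multi-gain Wagner reconstructions, "first appeared" is the top of
#' the contiguous present segment containing the protein's leaf: the unique
#' gain event on the leaf-to-root path that explains this protein's
#' presence. Proteins listed in `proteome` but absent from the family table
#' are dated to their own leaf (age 0) and flagged `no_family` so downstream
#' analyses can exclude them.
#'
#' @param tree a `species_tree`.
#' @param families a `family_table` (see [read_family_table()]).
#' @param species the focal leaf species whose proteins are dated.
#' @param method `"dollo"` or `"wagner"`.
#' @param gain_penalty,loss_penalty Wagner cost scheme (loss is the fixed
#'   reference 1; the gain penalty is relative to it, default 1). Ignored by
#'   Dollo except for cost reporting.
#' @param proteome optional character vector / `protein_list` of all protein
#'   IDs of the species; IDs not covered by the family table get the
#'   `no_family` convention above.
#' @param restrict_to_tree passed to [build_presence_matrix()].
#' @param db_name name of the family database, recorded in metadata.
#' @return an object of class `age_db`; see [lookup_ages()],
#'   [write_age_db()], [compare_age_sets()], [age_feature_analysis()].
#' @examples
#' tr <- parse_species_tree("((A,B)AB,(C,D)CD)Root;",
#'                          ages = c(AB = 100, CD = 150, Root = 500))
#' fams <- family_table(data.frame(
#'   family = c("F1", "F1", "F2"), species = c("A", "B", "C"),
#'   protein = c("p1", "p2", "p3")))
#' db <- protein_ages(tr, fams, species = "A")
#' db$ages
#' @export
protein_ages <- function(tree, families, species,
                         method = c("dollo", "wagner"),
                         gain_penalty = 1, loss_penalty = 1,
                         proteome = NULL, restrict_to_tree = FALSE,
                         db_name = "user") {
  stopifnot(inherits(tree, "species_tree"), inherits(families, "family_table"))
  method <- match.arg(method)
  check_costs(gain_penalty, loss_penalty)
  if (!species %in% tree_leaves(tree))
    ph_lookup_error(sprintf("species '%s' is not a leaf of the tree", species))
  mat <- build_presence_matrix(families, tree, restrict_to_tree = restrict_to_tree)
  fam_here <- unique(families$family[families$species == species])
  fam_here <- fam_here[fam_here %in% rownames(mat)]
  labelings <- lapply(fam_here, function(f) {
    if (method == "dollo")
      dollo_reconstruct(mat[f, ], tree, gain_penalty, loss_penalty, family = f)
    else
      wagner_reconstruct(mat[f, ], tree, gain_penalty, loss_penalty, family = f)
  })
  names(labelings) <- fam_here
  db <- assign_protein_ages(labelings, families, tree, species,
                            method = method, db_name = db_name,
                            gain_penalty = gain_penalty, loss_penalty = loss_penalty)
  if (!is.null(proteome)) {
    extra <- setdiff(as.character(proteome), db$ages$protein)
    if (length(extra)) {
      add <- data.frame(protein = extra, species = species,
                        family = "none", origin = species, age_mya = 0,
                        method = method, flag = "no_family",
                        stringsAsFactors = FALSE)
      db$ages <- rbind(db$ages, add)
      rownames(db$ages) <- NULL
    }
  }
  db
}

#' Convert family reconstructions into per-protein ages
#'
#' Lower-level counterpart of [protein_ages()] for precomputed labelings.
#' For each protein of `species`, the origin is the most ancestral node N on
#' its leaf-to-root path such that every node from the leaf up to N is in
#' state 1 in its family's labeling.
#'
#' @param labelings named list (by family ID) of `ancestral_labeling`s,
#'   covering every family with a member in `species`.
#' @param fams a `family_table`.
#' @param tree a `species_tree`.
#' @param species focal leaf species.
#' @param method,db_name,gain_penalty,loss_penalty metadata recorded in the
#'   result.
#' @return an object of class `age_db`.
#' @export
assign_protein_ages <- function(labelings, fams, tree, species,
                                method = "dollo", db_name = "user",
                                gain_penalty = 1, loss_penalty = 1) {
  stopifnot(inherits(tree, "species_tree"), inherits(fams, "family_table"))
  members <- fams[fams$species == species, , drop = FALSE]
  need <- unique(members$family)
  missing <- setdiff(need, names(labelings))
  if (length(missing))
    ph_argument_error(sprintf("no labeling supplied for family(ies): %s",
                              paste(missing, collapse = ", ")))
  path <- leaf_to_root_path(tree, species)
  origin_of <- vapply(need, function(f) {
    st <- labelings[[f]]$state[path]
    if (st[1L] != 1L)
      ph_validation_error(sprintf(
        "inconsistent labeling for family '%s': leaf '%s' marked absent", f, species))
    top <- which(st == 0L)
    if (length(top)) path[top[1L] - 1L] else path[length(path)]
  }, "")
  ages <- data.frame(
    protein = members$protein,
    species = species,
    family  = members$family,
    origin  = unname(origin_of[members$family]),
    age_mya = unname(tree$ages[node_id(tree, unname(origin_of[members$family]))]),
    method  = method,
    flag    = "",
    stringsAsFactors = FALSE
  )
  rownames(ages) <- NULL
  new_age_db(ages, species, tree, method, db_name, gain_penalty, loss_penalty)
}

new_age_db <- function(ages, species, tree, method, db_name,
                       gain_penalty = NA_real_, loss_penalty = NA_real_,
                       strata = NULL) {
  if (is.null(strata)) strata <- age_strata(tree, species)
  structure(list(
    ages = ages, species = species, method = method, db_name = db_name,
    gain_penalty = gain_penalty, loss_penalty = loss_penalty,
    strata = strata
  ), class = "age_db")
}

#' Domain-based protein ages
#'
#' Assigns each protein the age of its oldest or youngest annotated domain,
#' an alternative to family-based dating. Domain ages are supplied as a
#' (domain, taxon) table; each cited taxon must be an ancestor of the focal
#' species (a node on its leaf-to-root path), and the domain's age is that
#' taxon's tree age. Age ties between domains are resolved toward the more
#' leafward taxon. Proteins with no predicted domains are considered
#' specific to their species (origin = leaf, age 0, flag `no_domains`).
#'
#' @param domain_ages data frame with columns `domain`, `taxon`.
#' @param protein_domains data frame with columns `protein`, `domain`
#'   (one row per predicted domain; proteins may repeat).
#' @param strategy `"oldest"` or `"youngest"`.
#' @param tree a `species_tree`.
#' @param species focal leaf species.
#' @param proteome optional vector of all protein IDs; IDs without domain
#'   annotations get the no-domain convention.
#' @return an object of class `age_db` (method `domain_oldest` or
#'   `domain_youngest`).
#' @export
domain_based_ages <- function(domain_ages, protein_domains,
                              strategy = c("oldest", "youngest"),
                              tree, species, proteome = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(tree, "species_tree"))
  if (!all(c("domain", "taxon") %in% names(domain_ages)))
    ph_argument_error("'domain_ages' needs columns 'domain' and 'taxon'")
  if (!all(c("protein", "domain") %in% names(protein_domains)))
    ph_argument_error("'protein_domains' needs columns 'protein' and 'domain'")
  path <- leaf_to_root_path(tree, species)      # leaf first
  off_path <- setdiff(unique(as.character(domain_ages$taxon)), path)
  if (length(off_path))
    ph_validation_error(sprintf(
      "domain taxa not ancestral to species '%s': %s",
      species, paste(off_path, collapse = ", ")))
  unknown <- setdiff(unique(as.character(protein_domains$domain)),
                     as.character(domain_ages$domain))
  if (length(unknown))
    ph_validation_error(sprintf("domains without an age: %s",
                                paste(unknown, collapse = ", ")))
  depth <- stats::setNames(seq_along(path), path)   # 1 = leaf (most leafward)
  dom_taxon <- stats::setNames(as.character(domain_ages$taxon),
                               as.character(domain_ages$domain))
  dom_age <- stats::setNames(unname(tree$ages[node_id(tree, unname(dom_taxon))]),
                             names(dom_taxon))
  method <- paste0("domain_", strategy)
  prots <- unique(as.character(protein_domains$protein))
  pick <- function(p) {
    doms <- unique(as.character(protein_domains$domain[protein_domains$protein == p]))
    a <- dom_age[doms]
    ext <- if (strategy == "oldest") max(a) else min(a)
    cand <- dom_taxon[doms[a == ext]]
    cand[which.min(depth[cand])]       # tie: more leafward taxon
  }
  origin <- vapply(prots, pick, "")
  ages <- data.frame(
    protein = prots, species = species, family = "none",
    origin = unname(origin),
    age_mya = unname(tree$ages[node_id(tree, unname(origin))]),
    method = method, flag = "", stringsAsFactors = FALSE
  )
  if (!is.null(proteome)) {
    extra <- setdiff(as.character(proteome), prots)
    if (length(extra))
      ages <- rbind(ages, data.frame(
        protein = extra, species = species, family = "none",
        origin = species, age_mya = 0, method = method, flag = "no_domains",
        stringsAsFactors = FALSE))
  }
  rownames(ages) <- NULL
  new_age_db(ages, species, tree, method, db_name = "domains")
}

#' Look up ages for a protein list
#'
#' Partitions a protein list into matched age records and missing IDs.
#' Missing IDs are reported, never silently dropped (missingness is data,
#' not failure). For GAF-derived lists, lookups try the primary DB object
#' ID first and fall back to the symbol alias.
#'
#' @param db an `age_db`.
#' @param proteins a `protein_list` or character vector of IDs.
#' @return list with `ages` (data frame of matched records, in input order)
#'   and `missing` (character vector of unmatched IDs).
#' @export
lookup_ages <- function(db, proteins) {
  stopifnot(inherits(db, "age_db"))
  ids <- as.character(proteins)
  aliases <- attr(proteins, "aliases")
  if (length(ids) == 0L)
    return(list(ages = db$ages[0L, , drop = FALSE], missing = character(0)))
  idx <- match(ids, db$ages$protein)
  if (!is.null(aliases) && anyNA(idx)) {
    miss <- is.na(idx)
    idx[miss] <- match(unname(aliases[ids[miss]]), db$ages$protein)
  }
  matched <- db$ages[idx[!is.na(idx)], , drop = FALSE]
  rownames(matched) <- NULL
  list(ages = matched, missing = ids[is.na(idx)])
}

#' @export
print.age_db <- function(x, ...) {
  cat(sprintf("Protein age database: %s, %d proteins\n", x$species, nrow(x$ages)))
  cat(sprintf("  method: %s (family db: %s", x$method, x$db_name))
  if (!is.na(x$gain_penalty))
    cat(sprintf("; gain penalty %g, loss penalty %g", x$gain_penalty, x$loss_penalty))
  cat(")\n")
  cat(sprintf("  mean age: %.1f mya; strata: %s -> %s\n",
              mean(x$ages$age_mya), x$strata$stratum[1L],
              x$strata$stratum[nrow(x$strata)]))
  invisible(x)
}

#' @export
summary.age_db <- function(object, ...) {
  s <- object$strata
  counts <- vapply(s$stratum, function(l) sum(object$ages$origin == l), 0L)
  out <- data.frame(stratum = s$stratum, age_mya = s$age_mya,
                    n_proteins = unname(counts), stringsAsFactors = FALSE)
  structure(list(species = object$species, method = object$method,
                 n = nrow(object$ages), mean_age = mean(object$ages$age_mya),
                 median_age = stats::median(object$ages$age_mya),
                 strata = out),
            class = "summary.age_db")
}

#' @export
print.summary.age_db <- function(x, ...) {
  cat(sprintf("Protein ages for %s (%s): n = %d, mean %.1f mya, median %.1f mya\n",
              x$species, x$method, x$n, x$mean_age, x$median_age))
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' @export
plot.age_db <- function(x, ...) {
  s <- summary(x)$strata
  graphics::barplot(s$n_proteins, names.arg = s$stratum, las = 2,
                    ylab = "proteins", main = sprintf("Protein origins: %s (%s)",
                                                      x$species, x$method), ...)
  invisible(x)
}

#' Write / read an age database file
#'
#' Tab-delimited with a `#` header carrying the metadata (species, family
#' database, algorithm, cost scheme, age strata) followed by one row per
#' protein: protein ID, species, family, origin taxon, age (mya), method,
#' flag. The read/write pair round-trips bit-exactly.
#'
#' @param db an `age_db`.
#' @param path file path.
#' @param extra_header optional additional `#` header lines (e.g. a CLI run
#'   configuration).
#' @export
write_age_db <- function(db, path, extra_header = character(0)) {
  stopifnot(inherits(db, "age_db"))
  hdr <- c(
    sprintf("#phylostrat\t%s", as.character(utils::packageVersion("phylostrat"))),
    extra_header,
    sprintf("#species\t%s", db$species),
    sprintf("#db_name\t%s", db$db_name),
    sprintf("#method\t%s", db$method),
    sprintf("#gain_penalty\t%s", ph_num(db$gain_penalty)),
    sprintf("#loss_penalty\t%s", ph_num(db$loss_penalty)),
    sprintf("#stratum\t%s\t%s", db$strata$stratum, ph_num(db$strata$age_mya))
  )
  body <- paste(db$ages$protein, db$ages$species, db$ages$family, db$ages$origin,
                ph_num(db$ages$age_mya), db$ages$method, db$ages$flag, sep = "\t")
  writeLines(c(hdr, "protein\tspecies\tfamily\torigin\tage_mya\tmethod\tflag", body),
             path)
  invisible(path)
}

#' @rdname write_age_db
#' @export
read_age_db <- function(path) {
  ph_check_file(path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  meta <- strsplit(hdr, "\t", fixed = TRUE)
  key <- vapply(meta, function(p) sub("^#", "", p[[1L]]), "")
  val1 <- vapply(meta, function(p) if (length(p) >= 2L) p[[2L]] else "", "")
  get1 <- function(k) { i <- which(key == k); if (length(i)) val1[i[1L]] else NA_character_ }
  strat_i <- which(key == "stratum")
  strata <- data.frame(
    stratum = vapply(meta[strat_i], `[[`, "", 2L),
    age_mya = as.numeric(vapply(meta[strat_i], `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  if (length(body) < 1L || body[1L] != "protein\tspecies\tfamily\torigin\tage_mya\tmethod\tflag")
    ph_format_error(sprintf("'%s' is not an age database file", path))
  body <- body[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) c(p, rep("", 7L - length(p))))
  ages <- data.frame(
    protein = vapply(parts, `[[`, "", 1L),
    species = vapply(parts, `[[`, "", 2L),
    family  = vapply(parts, `[[`, "", 3L),
    origin  = vapply(parts, `[[`, "", 4L),
    age_mya = as.numeric(vapply(parts, `[[`, "", 5L)),
    method  = vapply(parts, `[[`, "", 6L),
    flag    = vapply(parts, `[[`, "", 7L),
    stringsAsFactors = FALSE
  )
  structure(list(
    ages = ages, species = get1("species"), method = get1("method"),
    db_name = get1("db_name"),
    gain_penalty = suppressWarnings(as.numeric(get1("gain_penalty"))),
    loss_penalty = suppressWarnings(as.numeric(get1("loss_penalty"))),
    strata = strata
  ), class = "age_db")
}
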