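#' Read a protein family table
#'
#' A family database is a partition of all proteins in all species of the
#' tree into evolutionarily related families. The exchange format is
#' 3-column tab-delimited text: family ID, species label, protein ID;
#' `#` comment lines are ignored. Duplicate membership lines are collapsed;
#' a (species, protein) pair appearing in two different families violates
#' the partition and is an error.
#'
#' @param path path to the family table file.
#' @return an object of class `family_table`: a data frame with columns
#'   `family`, `species`, `protein` (one row per membership).
#' @export
read_family_table <- function(path) {
  lines <- ph_read_lines(path)
  lnos <- attr(lines, "line_numbers")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    ph_format_error(sprintf(
      "family table '%s': line %d has %d tab-separated columns, expected 3",
      path, lnos[bad[1L]], lengths(parts)[bad[1L]]))
  df <- data.frame(
    family  = vapply(parts, `[[`, "", 1L),
    species = vapply(parts, `[[`, "", 2L),
    protein = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  family_table(df)
}

#' Construct a family table from a data frame
#'
#' @param df data frame with columns `family`, `species`, `protein`.
#' @return an object of class `family_table`.
#' @export
family_table <- function(df) {
  if (!all(c("family", "species", "protein") %in% names(df)))
    ph_argument_error("family table needs columns 'family', 'species', 'protein'")
  df <- df[c("family", "species", "protein")]
  df[] <- lapply(df, as.character)
  df <- unique(df)
  if (nrow(df) == 0L) ph_validation_error("family table is empty")
  key <- paste(df$species, df$protein, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    offending <- df[dup, , drop = FALSE]
    p <- offending[1L, ]
    fams <- unique(df$family[key == paste(p$species, p$protein, sep = "\r")])
    ph_validation_error(sprintf(
      "partition violated: protein '%s' (species '%s') belongs to families %s",
      p$protein, p$species, paste(fams, collapse = " and ")))
  }
  rownames(df) <- NULL
  class(df) <- c("family_table", "data.frame")
  df
}

#' @export
print.family_table <- function(x, ...) {
  cat(sprintf("Protein family table: %d families, %d proteins, %d species\n",
              length(unique(x$family)), nrow(x), length(unique(x$species))))
  invisible(x)
}

#' Build a binary presence/absence matrix
#'
#' Row `f`, column `s` is 1 iff family `f` has at least one member protein
#' in species `s` (copy number is collapsed to presence). Columns are the
#' tree's leaves in canonical order; rows keep the families' order of first
#' appearance.
#'
#' @param fams a `family_table`.
#' @param tree a `species_tree`.
#' @param restrict_to_tree if `TRUE`, memberships in species absent from the
#'   tree are dropped (families left with no species are removed); if `FALSE`
#'   (default) such species are a coverage error, because silently
#'   restricting species changes ages.
#' @return integer 0/1 matrix, families x leaf species.
#' @export
build_presence_matrix <- function(fams, tree, restrict_to_tree = FALSE) {
  stopifnot(inherits(fams, "family_table"), inherits(tree, "species_tree"))
  leaves <- tree_leaves(tree)
  off <- setdiff(unique(fams$species), leaves)
  if (length(off)) {
    if (!restrict_to_tree)
      ph_validation_error(sprintf(
        "species in family table but not in tree: %s",
        paste(sort(off), collapse = ", ")))
    fams <- fams[fams$species %in% leaves, , drop = FALSE]
    if (nrow(fams) == 0L)
      ph_validation_error("no family memberships remain after restricting to tree leaves")
  }
  fam_ids <- unique(fams$family)
  m <- matrix(0L, nrow = length(fam_ids), ncol = length(leaves),
              dimnames = list(fam_ids, leaves))
  m[cbind(match(fams$family, fam_ids), match(fams$species, leaves))] <- 1L
  m
}

#' Phylogenetic profile of a protein
#'
#' The presence/absence pattern of a protein's family across the tree's leaf
#' species, in canonical leaf order. Returns `NULL` for a protein not
#' assigned to any family (the caller decides how to treat unassigned
#' proteins; [protein_ages()] dates them to their own leaf).
#'
#' @param matrix presence matrix from [build_presence_matrix()].
#' @param species species label of the protein.
#' @param protein protein ID.
#' @param fams the `family_table` the matrix was built from.
#' @return named integer 0/1 vector over leaf species, or `NULL`.
#' @export
phylogenetic_profile <- function(matrix, species, protein, fams) {
  stopifnot(inherits(fams, "family_table"))
  hit <- fams$family[fams$species == species & fams$protein == protein]
  if (length(hit) == 0L) return(NULL)
  matrix[hit[1L], ]
}

#' Read a protein list (plain text or GAF 2.0)
#'
#' Plain mode: one protein ID per line (`#` comments allowed). GAF 2.0 mode:
#' `!`-prefixed header lines are skipped and each annotation row must have at
#' least 15 tab-separated columns; column 2 (DB object ID) is the primary
#' identifier and column 3 (symbol) is retained as a fallback alias used by
#' [lookup_ages()]. IDs are deduplicated keeping first-appearance order;
#' matching is exact (no case folding).
#'
#' @param path path to the list file.
#' @param format `"auto"` (GAF if the file starts with `!` lines),
#'   `"plain"`, or `"gaf"`.
#' @param species optional source species label, carried as an attribute.
#' @return an object of class `protein_list`: a character vector of IDs with
#'   attributes `aliases` (named character, ID -> symbol; GAF only) and
#'   `species`.
#' @export
read_protein_list <- function(path, format = c("auto", "plain", "gaf"),
                              species = NA_character_) {
  format <- match.arg(format)
  ph_check_file(path)
  raw <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- raw[nzchar(trimws(raw))]
    format <- if (length(first) && startsWith(first[1L], "!")) "gaf" else "plain"
  }
  if (format == "plain") {
    ids <- trimws(raw)
    ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
    ids <- ids[!duplicated(ids)]
    aliases <- stats::setNames(character(0), character(0))
  } else {
    rows <- raw[nzchar(trimws(raw)) & !startsWith(raw, "!")]
    parts <- strsplit(rows, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 15L)
    if (length(bad))
      ph_format_error(sprintf(
        "GAF file '%s': row %d has %d columns, expected >= 15",
        path, bad[1L], lengths(parts)[bad[1L]]))
    ids <- vapply(parts, `[[`, "", 2L)
    sym <- vapply(parts, `[[`, "", 3L)
    keep <- !duplicated(ids)
    aliases <- stats::setNames(sym[keep], ids[keep])
    ids <- ids[keep]
  }
  if (length(ids) == 0L)
    ph_validation_error(sprintf("protein list '%s' is empty after parsing", path))
  protein_list(ids, aliases = aliases, species = species)
}

#' @rdname read_protein_list
#' @param ids character vector of protein IDs.
#' @param aliases optional named character vector (ID -> alias).
#' @export
protein_list <- function(ids, aliases = NULL, species = NA_character_) {
  ids <- as.character(ids)
  ids <- ids[!duplicated(ids)]
  if (length(ids) == 0L) ph_validation_error("protein list is empty")
  structure(ids, aliases = aliases, species = species, class = "protein_list")
}

#' @export
print.protein_list <- function(x, ...) {
  cat(sprintf("Protein list: %d IDs%s\n", length(x),
              if (!is.na(attr(x, "species"))) paste0(" (", attr(x, "species"), ")") else ""))
  invisible(x)
}

#' Write phylogenetic profiles
#'
#' Tab-delimited output: a header row of leaf names, then one row per
#' protein (protein ID followed by one 0/1 per leaf in canonical order).
#'
#' @param profiles matrix of 0/1 rows (rownames = protein IDs) or a single
#'   named profile vector.
#' @param path output path.
#' @param header optional character vector of `#` header lines to prepend.
#' @export
write_profiles <- function(profiles, path, header = character(0)) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L,
    dimnames = list("protein", names(profiles)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("protein", colnames(profiles)), collapse = "\t"), con)
  writeLines(paste(rownames(profiles),
                   apply(profiles, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}
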