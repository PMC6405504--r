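#' Parse a phylogenetic tree from text
#'
#' Reads a rooted tree with branch lengths from a Newick string or from the
#' text of a NEXUS file (TREES block, with or without a TRANSLATE table) and
#' validates it: unique tip labels, branch lengths present and non-negative.
#' Quoted and underscore-escaped labels are normalized to plain strings.
#'
#' @param text character scalar holding the tree description.
#' @param dialect `"newick"` or `"nexus"`.
#' @return An [ape::phylo] object.
#' @seealso [read_phylo_tree()] to read from a file path, [write_tree_text()].
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' check_ultrametric(tr)
#' @export
parse_tree <- function(text, dialect = c("newick", "nexus")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(text), length(text) == 1L)
  if (dialect == "newick") {
    tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
    if (is.null(tr))
      stop("malformed Newick near character ",
           regexpr("[^(),:;A-Za-z0-9_.' \\t\\n-]", text)[1],
           ": check parentheses and terminating semicolon", call. = FALSE)
  } else {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    tr <- tryCatch(ape::read.nexus(tf), error = function(e)
      stop("malformed NEXUS TREES block: ", conditionMessage(e), call. = FALSE))
    if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  }
  validate_tree(tr)
}

#' Read a tree from a Newick or NEXUS file
#'
#' @param path file path.
#' @param dialect `"auto"` (sniff `#NEXUS` header), `"newick"` or `"nexus"`.
#' @return An [ape::phylo] object, validated as in [parse_tree()].
#' @export
read_phylo_tree <- function(path, dialect = c("auto", "newick", "nexus")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (dialect == "auto")
    dialect <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) "nexus" else "newick"
  parse_tree(txt, dialect)
}

#' Serialize a tree to Newick text
#'
#' @param tree an [ape::phylo] object.
#' @param digits significant digits for branch lengths.
#' @return Newick string.
#' @export
write_tree_text <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must all be present and >= 0", call. = FALSE)
  tree$tip.label <- gsub("_", " ", tree$tip.label)
  tree
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' A chronogram should have every tip at the same distance from the root;
#' dating software leaves small rounding noise, hence the relative tolerance.
#'
#' @param tree an [ape::phylo] object with >= 2 tips.
#' @param rel_tol maximum allowed `|depth(tip) - mean depth| / mean depth`.
#' @return list with `ultrametric` (logical) and `max_rel_dev` (numeric).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("need >= 2 tips", call. = FALSE)
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  m <- mean(d)
  if (m <= 0) stop("zero-depth tree: all branch lengths are 0", call. = FALSE)
  dev <- max(abs(d - m)) / m
  list(ultrametric = dev <= rel_tol, max_rel_dev = dev)
}

#' Prune a tree to a set of taxa
#'
#' Induced subtree on `taxa`: dropped lineages are removed, unbranched internal
#' nodes are suppressed with their branch lengths summed, so path lengths among
#' retained tips (and ultrametricity) are preserved.
#'
#' @param tree an [ape::phylo] object.
#' @param taxa character vector of tip labels to keep (>= 2).
#' @return the pruned [ape::phylo] object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(taxa) < 2L) stop("need >= 2 taxa after pruning", call. = FALSE)
  ape::keep.tip(tree, taxa)
}

#' Resolve polytomies into a binary tree
#'
#' Multifurcations are broken arbitrarily (order driven by `seed`) into
#' bifurcations separated by zero-length branches, the standard treatment of
#' soft polytomies before computing contrasts.
#'
#' @param tree an [ape::phylo] object.
#' @param seed integer seed controlling the arbitrary resolution order.
#' @return a binary [ape::phylo] object.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (is_rooted_binary(tree)) return(tree)
  message("resolving polytomies arbitrarily (seed = ", seed, ")")
  with_seed(seed, ape::multi2di(tree, random = TRUE))
}

#' Read a caste trait table
#'
#' Expects a CSV with header `species,worker_mm,male_mm,queen_mm[,genus,source]`,
#' decimal points, and empty cells or `"NA"` for missing values.  Species labels
#' are whitespace-normalized.  Validation: unique species; every non-missing
#' size strictly positive; each row carries at least one of male/queen.
#'
#' @param path CSV file path.
#' @return a `data.frame` with columns `species`, `worker_mm`, `male_mm`,
#'   `queen_mm` and, when present in the file, `genus` and `source`.
#' @examples
#' traits <- read_trait_table(system.file("extdata", "meliponini_traits.csv",
#'                                        package = "phylorensch"))
#' nrow(traits)  # 44 taxa
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("species", "worker_mm", "male_mm", "queen_mm")
  if (!all(need %in% names(tab)))
    stop("trait table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  tab$species <- squish(tab$species)
  if (any(!nzchar(tab$species))) stop("empty species label", call. = FALSE)
  if (anyDuplicated(tab$species))
    stop("duplicate species: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "),
         call. = FALSE)
  for (col in c("worker_mm", "male_mm", "queen_mm")) {
    v <- as.numeric(tab[[col]])
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop("non-positive ", col, " in row(s): ",
           paste(tab$species[bad], collapse = ", "), call. = FALSE)
    tab[[col]] <- v
  }
  none <- is.na(tab$male_mm) & is.na(tab$queen_mm)
  if (any(none))
    stop("rows with neither male nor queen size: ",
         paste(tab$species[none], collapse = ", "), call. = FALSE)
  tab
}

squish <- function(x) gsub("\\s+", " ", trimws(x))

# canonical form used to match tree tips against table rows: case-insensitive,
# underscores and spaces equivalent
canonical_label <- function(x) tolower(gsub("[_ ]+", " ", trimws(x)))

#' Match a tree and a trait table on species labels
#'
#' Labels are compared case-insensitively with underscores and spaces treated
#' as equivalent.  Tips without a trait row and rows without a tip are dropped
#' with a warning (the analysis prunes rather than fails); the returned tree is
#' pruned to the overlap and the table is reordered to the tree's tip order.
#'
#' @param tree an [ape::phylo] object.
#' @param traits a trait `data.frame` as from [read_trait_table()].
#' @return list with elements `tree`, `traits`, `dropped_tips`, `dropped_rows`.
#' @export
match_tree_traits <- function(tree, traits) {
  key_tip <- canonical_label(tree$tip.label)
  key_row <- canonical_label(traits$species)
  keep <- intersect(key_tip, key_row)
  if (length(keep) < 2L)
    stop("fewer than 2 taxa shared between tree and trait table", call. = FALSE)
  dropped_tips <- tree$tip.label[!key_tip %in% keep]
  dropped_rows <- traits$species[!key_row %in% keep]
  if (length(dropped_tips))
    warning("dropping ", length(dropped_tips), " tip(s) without trait data: ",
            paste(dropped_tips, collapse = ", "), call. = FALSE)
  if (length(dropped_rows))
    warning("dropping ", length(dropped_rows), " trait row(s) not in tree: ",
            paste(dropped_rows, collapse = ", "), call. = FALSE)
  tree2 <- prune_to_taxa(tree, tree$tip.label[key_tip %in% keep])
  traits2 <- traits[match(canonical_label(tree2$tip.label), key_row), , drop = FALSE]
  rownames(traits2) <- NULL
  list(tree = tree2, traits = traits2,
       dropped_tips = dropped_tips, dropped_rows = dropped_rows)
}

# rooted, fully bifurcating: every internal node has exactly two children
# (ape::is.binary also accepts unrooted basal trifurcations, which the
# contrasts recursion cannot use)
is_rooted_binary <- function(tree) {
  tree$Nnode == length(tree$tip.label) - 1L
}
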