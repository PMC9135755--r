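#' Read and validate a Newick phylogeny
#'
#' Wraps [ape::read.tree()] with the validation the downstream comparative
#' methods rely on: unique non-empty tip labels, finite non-negative branch
#' lengths, a connected topology. Polytomies are preserved.
#'
#' @param path path to a file holding one Newick string, or the string itself
#'   via `text`.
#' @param text optional Newick string (used instead of `path`).
#' @param require_lengths require branch lengths (needed for any phylogenetic
#'   regression); default `TRUE`.
#' @return an [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(path = NULL, text = NULL, require_lengths = TRUE) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) {
      stop("file not found: ", path, call. = FALSE)
    }
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  # cheap structural pre-check so malformed input reports a character offset
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("malformed Newick: unbalanced ')' at character offset ", i,
           call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' by character offset ",
         length(chars), call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick: no tree parsed", call. = FALSE)
  validate_phylogeny(tree, require_lengths = require_lengths)
  tree
}

#' Write a phylogeny to Newick
#' @param tree a `"phylo"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_phylogeny <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  tl <- tree$tip.label
  if (any(!nzchar(tl))) stop("empty tip label", call. = FALSE)
  if (anyDuplicated(tl)) {
    stop("duplicate tip labels: ",
         paste(unique(tl[duplicated(tl)]), collapse = ", "), call. = FALSE)
  }
  if (require_lengths) {
    bl <- tree$edge.length
    if (is.null(bl)) stop("tree has no branch lengths", call. = FALSE)
    if (any(!is.finite(bl))) stop("non-finite branch length", call. = FALSE)
    if (any(bl < 0)) {
      stop("negative branch length (", min(bl), ")", call. = FALSE)
    }
  }
  invisible(tree)
}

#' Align a phylogeny and a trait table to their shared species
#'
#' Prunes the tree to the species present in the table and drops table rows
#' whose species are absent from the tree, reporting what was removed. The
#' operation is idempotent.
#'
#' @param tree a `"phylo"` object.
#' @param table a [trait_table()].
#' @param quiet suppress the dropped-taxa message.
#' @return a list with elements `tree`, `table`, `dropped_tips` (tips pruned
#'   from the tree) and `dropped_rows` (row ids removed from the table).
#' @export
align_taxa <- function(tree, table, quiet = FALSE) {
  validate_phylogeny(tree, require_lengths = FALSE)
  sp <- species_of(table)
  shared <- intersect(tree$tip.label, unique(sp))
  if (length(shared) == 0L) {
    stop("no species shared between tree and table", call. = FALSE)
  }
  dropped_tips <- setdiff(tree$tip.label, shared)
  dropped_rows <- rownames(table)[!sp %in% shared]
  if (length(dropped_tips)) tree <- ape::keep.tip(tree, shared)
  tab <- table[sp %in% shared, , drop = FALSE]
  if (!quiet && (length(dropped_tips) || length(dropped_rows))) {
    message("align_taxa: dropped ", length(dropped_tips), " tip(s) and ",
            length(dropped_rows), " table row(s) not shared")
  }
  list(tree = tree, table = tab,
       dropped_tips = dropped_tips, dropped_rows = dropped_rows)
}

#' Extract a monophyletic subset
#'
#' Returns the clade spanned by the most recent common ancestor of `tip_set`
#' (with all its descendants) together with the matching trait-table rows.
#' Used to check that conclusions are stable across smaller monophyletic
#' groups.
#'
#' @param tree a `"phylo"` object.
#' @param table a [trait_table()] (optional).
#' @param tip_set character vector of tip labels, all present in the tree.
#' @return a list with `tree` (the clade) and `table` (matching rows, or
#'   `NULL` if no table was given).
#' @export
subset_clade <- function(tree, table = NULL, tip_set) {
  missing <- setdiff(tip_set, tree$tip.label)
  if (length(missing)) {
    stop("tips not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(tip_set) < 2L) stop("need at least two tips", call. = FALSE)
  if (setequal(tip_set, tree$tip.label)) {
    clade <- tree
  } else {
    mrca <- ape::getMRCA(tree, tip_set)
    root <- ape::Ntip(tree) + 1L
    clade <- if (mrca == root) tree else ape::extract.clade(tree, mrca)
  }
  tab <- NULL
  if (!is.null(table)) {
    tab <- table[species_of(table) %in% clade$tip.label, , drop = FALSE]
  }
  list(tree = clade, table = tab)
}
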