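# Genus/species taxonomy tree with unit branch lengths, used for Faith's
# phylogenetic diversity on synthetic communities.

#' Tree-safe feature label
#'
#' Species names contain spaces and parentheses; newick labels cannot.
#'
#' @param x character vector of species names.
#' @return sanitized labels.
#' @export
tree_label <- function(x) gsub("[ ()']", "_", x)

#' Build a genus/species taxonomy tree
#'
#' Nests species under their genus with unit branch lengths (root -> genus
#' -> species); a genus with a single species attaches directly to the root
#' with branch length 2, preserving total root-to-tip depth.
#'
#' @param species character vector of species names.
#' @param genus parallel vector of genus names.
#' @return an [ape::read.tree()] phylo object; tip labels are
#'   [tree_label()]-sanitized species names.
#' @export
build_taxonomy_tree <- function(species, genus) {
  stopifnot(length(species) == length(genus), !anyDuplicated(species))
  lab <- tree_label(species)
  by_genus <- split(lab, genus)
  parts <- vapply(names(by_genus), function(g) {
    tips <- by_genus[[g]]
    if (length(tips) == 1) sprintf("%s:2", tips)
    else sprintf("(%s)%s:1", paste0(tips, ":1", collapse = ","),
                 tree_label(g))
  }, character(1))
  if (length(parts) == 1 && length(by_genus[[1]]) > 1) {
    nw <- sprintf("(%s)root;",
                  paste0(by_genus[[1]], ":2", collapse = ","))
  } else if (length(parts) == 1) {
    stopf("cannot build a tree from a single species")
  } else {
    nw <- sprintf("(%s)root;", paste(parts, collapse = ","))
  }
  tr <- ape::read.tree(text = nw)
  tr$root.edge <- 0  # mark as rooted for Faith's PD (polytomy at the root)
  tr
}
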