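#' The six-species primate phylogeny
#'
#' Returns the fixed rooted topology used throughout the package:
#' `(((((human, chimp), rhesus), marmoset), (mouse_lemur, bushbaby)))`, i.e.
#' human and chimpanzee form the shallowest split (the "ape" clade here, the
#' hominini pair of the study design), rhesus macaque joins them as the
#' Catarrhini, marmoset completes the Haplorrhini, and the two lemuriform
#' species (mouse lemur, bushbaby) form the Strepsirrhini outgroup.
#'
#' Branch lengths are expected substitutions per site. The defaults are scaled
#' so that, under the Jukes-Cantor substitution process used by
#' [simulate_msa()], the expected human-chimp mismatch fraction is about 0.01
#' and human-mouse lemur about 0.15, preserving the ordering of divergences
#' across the phylogeny.
#'
#' @param branch_scale Non-negative multiplier applied to every branch length.
#'
#' @return An object of class `species_tree`: a list with
#'   \describe{
#'     \item{edges}{tibble with columns `branch` (node name), `parent`,
#'       `length`; internal nodes are named `ape`, `catarrhini`,
#'       `haplorrhini`, `strepsirrhini`, and the root is `root`.}
#'     \item{species}{character vector of the six leaf names.}
#'   }
#' @export
#' @examples
#' tr <- species_tree()
#' tree_path(tr, "human")
species_tree <- function(branch_scale = 1) {
  stopifnot(is.numeric(branch_scale), branch_scale >= 0, is.finite(branch_scale))
  edges <- tibble(
    branch = c("human", "chimp", "ape", "rhesus", "catarrhini", "marmoset",
               "haplorrhini", "strepsirrhini", "mouse_lemur", "bushbaby"),
    parent = c("ape", "ape", "catarrhini", "catarrhini", "haplorrhini",
               "haplorrhini", "root", "root", "strepsirrhini", "strepsirrhini"),
    length = c(0.005, 0.005, 0.010, 0.015, 0.015, 0.030,
               0.025, 0.030, 0.082, 0.082) * branch_scale
  )
  structure(
    list(edges = edges,
         species = c("human", "chimp", "rhesus", "marmoset",
                     "mouse_lemur", "bushbaby")),
    class = "species_tree"
  )
}

#' @export
print.species_tree <- function(x, ...) {
  cat("<species_tree> 6 leaves:", paste(x$species, collapse = ", "), "\n")
  cat("branches:\n")
  print(as.data.frame(x$edges), row.names = FALSE)
  invisible(x)
}

#' Root-to-leaf branch path
#'
#' @param tree A [species_tree()].
#' @param leaf A leaf (species) name.
#' @return Character vector of branch names from the branch leaving the root
#'   down to the terminal branch of `leaf`.
#' @export
tree_path <- function(tree, leaf) {
  stopifnot(inherits(tree, "species_tree"), leaf %in% tree$species)
  parent_of <- setNames(tree$edges$parent, tree$edges$branch)
  path <- character()
  node <- leaf
  while (node != "root") {
    path <- c(node, path)
    node <- parent_of[[node]]
  }
  path
}

#' Species descending from a branch
#'
#' @param tree A [species_tree()].
#' @param branch A branch name (`"root"` gives all six species).
#' @return Character vector of leaf species below (and including) `branch`.
#' @export
tree_species_below <- function(tree, branch) {
  stopifnot(inherits(tree, "species_tree"))
  if (branch == "root") return(tree$species)
  stopifnot(branch %in% tree$edges$branch)
  tree$species[map_lgl(tree$species, function(sp) branch %in% tree_path(tree, sp))]
}

#' Patristic distance between two leaves
#'
#' @param tree A [species_tree()].
#' @param a,b Leaf names.
#' @return Sum of branch lengths on the path connecting `a` and `b`.
#' @export
tree_distance <- function(tree, a, b) {
  pa <- tree_path(tree, a)
  pb <- tree_path(tree, b)
  shared <- intersect(pa, pb)
  len <- setNames(tree$edges$length, tree$edges$branch)
  sum(len[setdiff(pa, shared)]) + sum(len[setdiff(pb, shared)])
}
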