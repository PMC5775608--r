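#' Dated species trees
#'
#' A `species_tree` wraps a rooted, ultrametric [ape::read.tree()] phylogeny
#' whose branch lengths are in millions of years (MY). Node ages (MYa) are
#' computed from leaf depths; a root edge, when present, is exposed as the
#' `"stem"` branch so that insertion events predating the crown radiation
#' have a branch to live on. Branches are identified by the clade below
#' them: tip label for terminal branches, sorted tip labels joined with `+`
#' for internal ones, `"stem"` for the root edge.
#'
#' @param x An `ape` `phylo` object, or a Newick string.
#' @param tol Absolute tolerance (MY) on leaf depth differences when
#'   validating ultrametricity.
#' @return An object of class `species_tree` with elements `phylo`,
#'   `root_age`, `ages` (named by node number) and `branches` (a tibble with
#'   `branch_id`, `parent_age`, `child_age`, `length`, `tips` list-column).
#' @export
#' @examples
#' tr <- species_tree("((A:6,B:6):24,C:30);")
#' tr$root_age
species_tree <- function(x, tol = 1e-6) {
  phy <- if (inherits(x, "phylo")) x else ape::read.tree(text = x)
  if (is.null(phy)) stop("species_tree: could not parse Newick input")
  if (is.null(phy$edge.length)) stop("species_tree: branch lengths required")
  n_tip <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  tip_depth <- depths[seq_len(n_tip)]
  if (diff(range(tip_depth)) > tol) {
    off <- phy$tip.label[abs(tip_depth - stats::median(tip_depth)) > tol / 2]
    stop("species_tree: tree is not ultrametric (tolerance ", tol,
         "); offending leaves: ", paste(off, collapse = ", "))
  }
  root_age <- max(tip_depth)
  ages <- root_age - depths           # node ages in MYa, leaves ~0
  ages[seq_len(n_tip)] <- 0
  root_node <- n_tip + 1L

  tips_below <- function(node) {
    if (node <= n_tip) return(phy$tip.label[node])
    sort(phy$tip.label[unlist(phangorn_free_descendants(phy, node))])
  }
  edge_rows <- lapply(seq_len(nrow(phy$edge)), function(i) {
    parent <- phy$edge[i, 1L]
    child <- phy$edge[i, 2L]
    tips <- tips_below(child)
    tibble::tibble(
      branch_id = if (child <= n_tip) phy$tip.label[child]
                  else paste(tips, collapse = "+"),
      parent_node = parent, child_node = child,
      parent_age = ages[parent], child_age = ages[child],
      length = phy$edge.length[i], tips = list(tips)
    )
  })
  branches <- dplyr::bind_rows(edge_rows)
  stem_len <- phy$root.edge %||% 0
  branches <- dplyr::bind_rows(
    tibble::tibble(branch_id = "stem", parent_node = NA_integer_,
                   child_node = root_node,
                   parent_age = root_age + stem_len, child_age = root_age,
                   length = stem_len, tips = list(sort(phy$tip.label))),
    branches
  )
  if (anyDuplicated(branches$branch_id)) {
    stop("species_tree: duplicated branch ids; tip labels must be unique")
  }
  structure(list(phylo = phy, root_age = root_age, ages = ages,
                 branches = branches, n_tip = n_tip),
            class = "species_tree")
}

# tip numbers below an internal node, without extra deps
phangorn_free_descendants <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- phy$edge[phy$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  list(out)
}

#' @rdname species_tree
#' @param path Path to a Newick file.
#' @export
read_species_tree <- function(path, tol = 1e-6) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("read_species_tree: could not parse ", path)
  species_tree(phy, tol = tol)
}

#' Default six-species catarrhine tree
#'
#' Human, chimpanzee, gorilla, orangutan, gibbon and rhesus macaque with
#' split ages of 7, 10, 17, 20 and 30 MYa and a 13 MY stem above the crown
#' (root age of the crown 30 MYa, stem reaching back to 43 MYa) — the
#' configuration used throughout examples and simulations.
#'
#' @return A `species_tree`.
#' @export
default_catarrhini_tree <- function() {
  species_tree(paste0(
    "(((((human:7,chimp:7):3,gorilla:10):7,orangutan:17):3,",
    "gibbon:20):10,rhesus:30):13;"
  ))
}

#' @export
print.species_tree <- function(x, ...) {
  cat("<species_tree> ", x$n_tip, " tips, root age ", x$root_age, " MYa",
      if ((x$phylo$root.edge %||% 0) > 0)
        paste0(" (+", x$phylo$root.edge, " MY stem)"), "\n", sep = "")
  cat("  tips: ", paste(sort(x$phylo$tip.label), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# branch directly above the smallest clade containing `tips`
stem_branch_of <- function(tree, tips) {
  tips <- unique(tips)
  stopifnot(all(tips %in% tree$phylo$tip.label))
  br <- tree$branches
  covering <- br[vapply(br$tips, function(tp) all(tips %in% tp), logical(1)), ]
  covering$branch_id[which.min(lengths(covering$tips))]
}

tips_of_branch <- function(tree, branch_id) {
  tree$branches$tips[[match(branch_id, tree$branches$branch_id)]]
}

# branch ids strictly below `branch_id` (its child clade's internal edges)
descendant_branches <- function(tree, branch_id) {
  tips <- tips_of_branch(tree, branch_id)
  br <- tree$branches
  sub <- br$branch_id != branch_id &
    vapply(br$tips, function(tp) all(tp %in% tips), logical(1))
  br$branch_id[sub]
}

# preorder branch ids (stem first, then root-to-tip)
preorder_branches <- function(tree) {
  br <- tree$branches
  ord <- order(-br$parent_age, -br$child_age, br$branch_id)
  br$branch_id[ord]
}
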