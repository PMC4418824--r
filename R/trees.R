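# Tree I/O, tree samples, clade queries, and a neighbor-joining builder.
#
# Trees are ape "phylo" objects throughout.  The MC statistic requires
# rooted trees; unrooted inputs are midpoint-rooted with a warning because
# monophyly is only defined on rooted trees.

#' Construct a tree sample
#'
#' An ordered collection of rooted trees over one tip set, such as a
#' Bayesian posterior or bootstrap sample.
#'
#' @param trees A list of `phylo` trees (or a `multiPhylo`).
#' @param provenance Free-text label, e.g. `"posterior"` or `"bootstrap"`.
#' @return An object of class `tree_sample` (a list of rooted `phylo`).
#' @export
tree_sample <- function(trees, provenance = "unknown") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)  # read.nexus compresses labels
  }
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("tree sample is empty")
  trees <- lapply(trees, ensure_rooted)
  tips <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips)) {
      stop("tree ", i, " has a different tip set from tree 1")
    }
  }
  structure(trees, class = "tree_sample", provenance = provenance)
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("<tree_sample> %d trees, %d tips (%s)\n", length(x),
              length(x[[1L]]$tip.label), attr(x, "provenance")))
  invisible(x)
}

#' Midpoint-root a tree if it is not already rooted
#'
#' Trees whose root node has more than two children are ambiguous in Newick:
#' they may be unrooted, or rooted with a hard basal polytomy.  When branch
#' lengths are available the tree is midpoint-rooted (with a warning);
#' without branch lengths the basal polytomy is kept and treated as hard.
#'
#' @param tree A `phylo`.
#' @return A rooted `phylo`.
#' @export
ensure_rooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.rooted(tree)) return(tree)
  if (is.null(tree$edge.length)) {
    warning("tree without branch lengths has a basal polytomy; ",
            "treating it as a hard rooted polytomy")
    return(tree)
  }
  warning("unrooted tree midpoint-rooted; monophyly depends on the root position")
  phangorn::midpoint(tree)
}

#' Read a tree or tree sample from Newick or NEXUS
#'
#' NEXUS translate tables are honoured (via [ape::read.nexus()]).  The first
#' `floor(burnin_fraction * N)` trees are discarded, matching the usual
#' treatment of MCMC output.
#'
#' @param path File path.  Format is auto-detected (`#NEXUS` magic) unless
#'   `format` is given.
#' @param burnin_fraction Fraction of leading trees to discard, in `[0, 1)`.
#' @param format `"auto"`, `"newick"` or `"nexus"`.
#' @param provenance Label stored on the sample.
#' @return A [tree_sample()].
#' @export
read_tree_sample <- function(path, burnin_fraction = 0,
                             format = c("auto", "newick", "nexus"),
                             provenance = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  n <- length(trees)
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must be in [0, 1)")
  }
  drop <- floor(burnin_fraction * n)
  if (drop >= n) stop("burn-in removes every tree")
  trees <- trees[(drop + 1L):n]
  tree_sample(trees, provenance = provenance %||% format)
}

#' All clades of a rooted tree
#'
#' Returns one tip set per node: singletons for the leaves, the descendant
#' tip set for every internal node (the root clade is the full tip set).
#'
#' @param tree A rooted `phylo`.
#' @return A list of character vectors of tip labels.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' clades(tr)
#' @export
clades <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  ids <- seq_len(n + tree$Nnode)
  desc <- phangorn::Descendants(tree, ids, type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining (via [ape::nj()]); the unrooted
#' result is midpoint-rooted on return.  For an additive matrix the source
#' topology and branch lengths are recovered exactly.
#'
#' This is a lightweight builder for simulations and convenience; it is not
#' a substitute for likelihood or Bayesian tree inference.
#'
#' @param dm A symmetric distance matrix with taxa as dimnames (e.g. an
#'   `evo_dist`), `n >= 3`.
#' @return A rooted `phylo`.
#' @export
neighbor_joining <- function(dm) {
  m <- unclass(as.matrix(dm))
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0  # NJ can emit tiny negatives on noisy data
  phangorn::midpoint(tr)
}
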