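# Monophyletic-clade (MC) phylogeny-trait association statistic.
#
# For a trait state, MC is the size of the largest clade (descendant tip set
# of some node, leaves included) whose tips all carry that state.  It is a
# topology-only statistic: branch lengths never enter.  Association is
# judged against a tip-permutation null over a tree sample: each replicate
# shuffles the tip->state assignment (state counts preserved) and records
# the replicate's mean MC across the sample.

# Precompute the postorder structure of a tree once, so MC can be evaluated
# cheaply for many trait vectors (replicate shuffles evaluate as one matrix
# accumulation over the edges).
.mc_machine <- function(tree, all_taxa) {
  stopifnot(inherits(tree, "phylo"))
  # basal polytomies are treated as hard; the root is the node the tree
  # declares, so use tree_sample()/ensure_rooted() to root unrooted input
  missing <- setdiff(tree$tip.label, all_taxa)
  if (length(missing)) {
    stop("tips missing from trait assignment: ", paste(missing, collapse = ", "))
  }
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  nn <- ntip + po$Nnode
  # clade sizes by the same accumulation used for state counts
  sizes <- c(rep(1, ntip), rep(0, po$Nnode))
  e <- po$edge
  for (k in seq_len(nrow(e))) sizes[e[k, 1L]] <- sizes[e[k, 1L]] + sizes[e[k, 2L]]
  list(edge = e, ntip = ntip, n_nodes = nn, sizes = sizes,
       tip_index = match(po$tip.label, all_taxa))
}

# tipstate: logical matrix (length(all_taxa) x R). Returns integer vector of
# MC values, one per column.
.mc_eval <- function(machine, tipstate) {
  R <- ncol(tipstate)
  counts <- matrix(0, machine$n_nodes, R)
  counts[seq_len(machine$ntip), ] <- tipstate[machine$tip_index, , drop = FALSE]
  e <- machine$edge
  for (k in seq_len(nrow(e))) {
    counts[e[k, 1L], ] <- counts[e[k, 1L], ] + counts[e[k, 2L], ]
  }
  pure <- (counts == machine$sizes) * machine$sizes  # recycled down columns
  as.integer(apply(pure, 2L, max))
}

.check_state <- function(traits, state) {
  if (!state %in% unclass(traits)) {
    stop("state '", state, "' is absent from the trait assignment")
  }
}

#' Monophyletic-clade size statistic for one tree
#'
#' The size of the largest clade whose tips all carry `state`.  Singleton
#' leaves count as clades of size 1, so MC >= 1 whenever the state is
#' present.  Branch lengths are ignored.
#'
#' @param tree A rooted `phylo`; every tip must appear in `traits`.
#' @param traits A [trait_assignment()].
#' @param state The trait state tested.
#' @return An integer in `[1, #tips with the state]`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' tra <- trait_assignment(c(A = "M", B = "M", C = "N", D = "N"))
#' mc_statistic(tr, tra, "M")  # 2
#' @export
mc_statistic <- function(tree, traits, state) {
  .check_state(traits, state)
  machine <- .mc_machine(tree, names(traits))
  tipstate <- matrix(unclass(traits) == state, ncol = 1L)
  .mc_eval(machine, tipstate)
}

#' Brute-force MC statistic (independent oracle)
#'
#' Same contract as [mc_statistic()], computed by naively enumerating every
#' node's descendant tip set by reachability over the edge list.  Intended
#' for small trees (<= a few dozen tips) and for cross-validation.
#'
#' @inheritParams mc_statistic
#' @return An integer.
#' @export
mc_statistic_bruteforce <- function(tree, traits, state) {
  .check_state(traits, state)
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing)) {
    stop("tips missing from trait assignment: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  in_state <- unclass(traits)[tree$tip.label] == state
  best <- 0L
  for (node in seq_len(ntip + tree$Nnode)) {
    # expand the descendant set of `node` by repeated sweeps over the edges
    members <- node
    repeat {
      add <- tree$edge[tree$edge[, 1L] %in% members, 2L]
      new <- setdiff(add, members)
      if (!length(new)) break
      members <- c(members, new)
    }
    tips <- members[members <= ntip]
    if (length(tips) && all(in_state[tips])) best <- max(best, length(tips))
  }
  as.integer(best)
}

#' Observed MC over a tree sample
#'
#' Mean and central 95% quantile interval of [mc_statistic()] across the
#' trees of a sample, capturing phylogenetic uncertainty.
#'
#' @param trees A [tree_sample()].
#' @inheritParams mc_statistic
#' @return A list: `mean`, `ci` (length-2), `per_tree` (integer vector).
#' @export
mc_observed <- function(trees, traits, state) {
  stopifnot(inherits(trees, "tree_sample"))
  per_tree <- vapply(trees, mc_statistic, integer(1),
                     traits = traits, state = state)
  list(mean = mean(per_tree),
       ci = unname(quantile(per_tree, c(0.025, 0.975))),
       per_tree = per_tree)
}

#' MC phylogeny-trait association test
#'
#' Tests whether tips carrying `state` cluster on the phylogeny more than
#' expected by chance.  Each null replicate shuffles the tip->trait
#' assignment uniformly (state counts preserved) and is evaluated on the
#' full tree sample (the replicate's mean MC); the test is one-sided because
#' only a higher-than-expected MC indicates phylogeny-trait association.
#' `p = (1 + #\{null mean >= observed mean\}) / (1 + n_replicates)`.
#'
#' @param trees A [tree_sample()].
#' @param traits A [trait_assignment()] covering every tip.
#' @param state The trait state tested.
#' @param n_replicates Number of null shuffles (default 1000).
#' @param seed Optional integer seed.
#' @param null_summary `"mean"` (default) or `"median"`: how the expected MC
#'   is summarised from the replicate means.
#' @param replicate_mode `"full_sample"` (default; each shuffle evaluated on
#'   every tree) or `"single_tree"` (each shuffle evaluated on one tree drawn
#'   uniformly from the sample).
#' @return An `mc_result` list: `state`, `observed_mc`, `observed_ci`,
#'   `expected_mc`, `null_ci`, `p_value`, `n_replicates`, `n_trees`,
#'   `null_summary`, `seed`.
#' @export
mc_test <- function(trees, traits, state, n_replicates = 1000L, seed = NULL,
                    null_summary = c("mean", "median"),
                    replicate_mode = c("full_sample", "single_tree")) {
  null_summary <- match.arg(null_summary)
  replicate_mode <- match.arg(replicate_mode)
  stopifnot(inherits(trees, "tree_sample"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  .check_state(traits, state)
  all_taxa <- names(traits)
  machines <- lapply(trees, .mc_machine, all_taxa = all_taxa)
  obs_vec <- unclass(traits) == state
  observed <- vapply(machines, function(mach)
    .mc_eval(mach, matrix(obs_vec, ncol = 1L)), integer(1))
  if (!is.null(seed)) set.seed(seed)
  R <- as.integer(n_replicates)
  shuffles <- vapply(seq_len(R), function(b) sample(obs_vec),
                     logical(length(obs_vec)))  # taxa x R
  if (replicate_mode == "full_sample") {
    null_per_tree <- vapply(machines, function(mach) .mc_eval(mach, shuffles),
                            integer(R))  # R x n_trees
    null_means <- if (R == 1L) mean(null_per_tree) else rowMeans(null_per_tree)
  } else {
    pick <- sample.int(length(machines), R, replace = TRUE)
    null_means <- vapply(seq_len(R), function(b)
      as.numeric(.mc_eval(machines[[pick[b]]], shuffles[, b, drop = FALSE])),
      numeric(1))
  }
  obs_mean <- mean(observed)
  p <- (1 + sum(null_means >= obs_mean - 1e-9)) / (1 + R)
  expected <- if (null_summary == "mean") mean(null_means) else median(null_means)
  structure(list(state = state,
                 observed_mc = obs_mean,
                 observed_ci = unname(quantile(observed, c(0.025, 0.975))),
                 expected_mc = expected,
                 null_ci = unname(quantile(null_means, c(0.025, 0.975))),
                 p_value = p,
                 n_replicates = R,
                 n_trees = length(trees),
                 null_summary = null_summary,
                 seed = seed),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("MC phylogeny-trait association test\n")
  cat(sprintf("  state: %s   trees: %d   replicates: %d\n",
              x$state, x$n_trees, x$n_replicates))
  cat(sprintf("  observed MC = %.2f [%.2f, %.2f]\n",
              x$observed_mc, x$observed_ci[1], x$observed_ci[2]))
  cat(sprintf("  expected MC = %.2f [%.2f, %.2f] (null %s)\n",
              x$expected_mc, x$null_ci[1], x$null_ci[2], x$null_summary))
  cat(sprintf("  P = %s (one-sided)\n", format.pval(x$p_value, digits = 4)))
  invisible(x)
}
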