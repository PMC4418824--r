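# Synthetic-data generation: Yule trees, sequence evolution by exact
# continuous-time Markov chains, binary traits with tunable phylogenetic
# signal, and bootstrap pseudo tree samples.
#
# Every generator is a pure function of its seed.  A single root seed fans
# out to per-stage seeds via split_seed(), so stages can be re-run
# independently and composite simulations remain bit-reproducible.

#' Derive independent sub-seeds from one root seed
#'
#' Seeds the R generator with `seed` and draws `n` integers uniformly from
#' `[1, 2^31 - 2]`.  Used by composite simulators so each stage gets its own
#' reproducible stream.
#'
#' @param seed Integer root seed (or `NULL` for non-reproducible draws).
#' @param n Number of sub-seeds.
#' @return An integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n)
}

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: two lineages from the root, exponential waiting
#' times with total rate `k * birth_rate` for `k` extant lineages, a
#' uniformly chosen lineage splitting at each event, plus one final waiting
#' interval after the n-th lineage appears.  Branch lengths are in time
#' units.
#'
#' @param n_tips Number of tips (`>= 2`).
#' @param birth_rate Speciation rate (`> 0`).
#' @param seed Optional integer seed.
#' @return A rooted binary `phylo` with tips `t1 ... tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2L, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  # node bookkeeping with provisional ids; root = internal id 1
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  next_internal <- 1L
  # active lineages: parent internal id and start time
  act_parent <- c(1L, 1L)
  act_start <- c(0, 0)
  t_now <- 0
  while (length(act_parent) < n_tips) {
    k <- length(act_parent)
    t_now <- t_now + rexp(1L, rate = k * birth_rate)
    i <- sample.int(k, 1L)
    next_internal <- next_internal + 1L
    parent <- c(parent, act_parent[i])
    child <- c(child, next_internal)
    elen <- c(elen, t_now - act_start[i])
    act_parent <- c(act_parent[-i], next_internal, next_internal)
    act_start <- c(act_start[-i], t_now, t_now)
  }
  t_now <- t_now + rexp(1L, rate = n_tips * birth_rate)
  # pendant edges to the present
  n_int <- next_internal
  tip_ids <- n_int + seq_len(n_tips)
  parent <- c(parent, act_parent)
  child <- c(child, tip_ids)
  elen <- c(elen, t_now - act_start)
  # remap to ape numbering: tips 1..n, internals n+1..
  remap <- integer(n_int + n_tips)
  remap[tip_ids] <- seq_len(n_tips)
  remap[seq_len(n_int)] <- n_tips + seq_len(n_int)
  # assign labels uniformly at random: Yule tip labels are exchangeable,
  # and creation order would otherwise leak depth structure into the labels
  tr <- list(edge = cbind(remap[parent], remap[child]),
             edge.length = elen,
             tip.label = paste0("t", sample.int(n_tips)),
             Nnode = n_int)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

# Rate matrix for the Tamura (1992) model, order A C G T; kappa = 1 and
# theta = 0.5 gives JC69, theta = 0.5 gives K2P.  Normalised to one
# expected substitution per unit branch length.
.t92_rate_matrix <- function(kappa = 1, theta = 0.5) {
  stopifnot(kappa > 0, theta > 0, theta < 1)
  pi <- c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2, T = (1 - theta) / 2)
  ts <- matrix(c(NA, 1, kappa, 1,
                 1, NA, 1, kappa,
                 kappa, 1, NA, 1,
                 1, kappa, 1, NA), 4, 4, byrow = TRUE)
  Q <- ts * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  list(Q = Q / scale, pi = pi)
}

# Exact transition probabilities P(t) = expm(Q t) via eigendecomposition.
.transition_probs <- function(Q, t) {
  eg <- eigen(Q)
  P <- Re(eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

.model_params <- function(model, kappa, theta) {
  switch(model,
    JC69 = list(kappa = 1, theta = 0.5),
    K2P = list(kappa = kappa, theta = 0.5),
    T92 = list(kappa = kappa, theta = theta))
}

#' Evolve a nucleotide alignment on a tree
#'
#' Site-independent continuous-time Markov chain: the root sequence is
#' drawn from the model's stationary distribution and each branch applies
#' the exact matrix-exponential transition probabilities for its length
#' times `rate_multiplier`.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param length Number of sites (`>= 1`).
#' @param model `"JC69"`, `"K2P"` or `"T92"`.
#' @param kappa Transition/transversion rate ratio (K2P, T92).
#' @param theta Equilibrium GC content (T92).
#' @param rate_multiplier Scales all branch lengths (`> 0`).
#' @param seed Optional integer seed.
#' @return A DNA [alignment()], one sequence per tip.
#' @export
evolve_alignment <- function(tree, length, model = c("JC69", "K2P", "T92"),
                             kappa = 2, theta = 0.5, rate_multiplier = 1,
                             seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"), length >= 1L, rate_multiplier > 0,
            !is.null(tree$edge.length))
  if (!is.null(seed)) set.seed(seed)
  par <- .model_params(model, kappa, theta)
  rm <- .t92_rate_matrix(par$kappa, par$theta)
  ntip <- base::length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  states <- matrix(NA_integer_, ntip + tr$Nnode, length)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, length, replace = TRUE, prob = rm$pi)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    P <- .transition_probs(rm$Q, tr$edge.length[k] * rate_multiplier)
    parent_states <- states[p, ]
    out <- integer(length)
    for (s in 1:4) {
      idx <- which(parent_states == s)
      if (base::length(idx)) {
        out[idx] <- sample.int(4L, base::length(idx), replace = TRUE,
                               prob = P[s, ])
      }
    }
    states[ch, ] <- out
  }
  bases <- c("A", "C", "G", "T")
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                function(row) paste(bases[row], collapse = ""))
  names(seqs) <- tr$tip.label
  alignment(seqs, alphabet = "dna")
}

#' Simulate a coevolving (or independent) ligand/receptor alignment pair
#'
#' Both alignments evolve by independent site processes; under
#' `coevolving = TRUE` they share one Yule tree (inducing correlated
#' distance matrices, the mirror-tree signal), under `coevolving = FALSE`
#' the receptor evolves on a freshly simulated tree of its own (the null
#' control).
#'
#' @param n_tips Number of taxa (default 20).
#' @param len_ligand,len_receptor Alignment lengths (defaults 300 / 1200,
#'   i.e. short ligand vs long receptor coding regions).
#' @param birth_rate Yule speciation rate.
#' @param rate_ligand,rate_receptor Substitution-rate multipliers.
#' @param model,kappa,theta Substitution model as in [evolve_alignment()].
#' @param coevolving Share one tree (`TRUE`) or use independent trees.
#' @param seed Optional root seed (fans out via [split_seed()]).
#' @return A list: `ligand`, `receptor` (alignments), `tree` (the ligand
#'   tree), `receptor_tree` (identical to `tree` when coevolving), `seed`.
#' @export
simulate_coevolving_pair <- function(n_tips = 20L, len_ligand = 300L,
                                     len_receptor = 1200L, birth_rate = 1,
                                     rate_ligand = 0.1, rate_receptor = 0.1,
                                     model = "JC69", kappa = 2, theta = 0.5,
                                     coevolving = TRUE, seed = NULL) {
  seeds <- split_seed(seed, 4L)
  tree <- simulate_yule_tree(n_tips, birth_rate, seed = seeds[1L])
  receptor_tree <- if (coevolving) tree else {
    simulate_yule_tree(n_tips, birth_rate, seed = seeds[2L])
  }
  ligand <- evolve_alignment(tree, len_ligand, model, kappa, theta,
                             rate_multiplier = rate_ligand, seed = seeds[3L])
  receptor <- evolve_alignment(receptor_tree, len_receptor, model, kappa,
                               theta, rate_multiplier = rate_receptor,
                               seed = seeds[4L])
  list(ligand = ligand, receptor = receptor, tree = tree,
       receptor_tree = receptor_tree, seed = seed)
}

#' Simulate a binary trait on a tree
#'
#' Two-state continuous-time Markov chain with transition rates
#' `rate01` (state0 -> state1) and `rate10`; the root state is drawn from
#' the stationary distribution.  Low rates produce strong phylogenetic
#' signal (tips inherit the root state in blocks); high rates approach
#' independent coin flips.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param rate01,rate10 Transition rates (`> 0`).
#' @param seed Optional integer seed.
#' @param states Labels for the two states (default `c("0", "1")`).
#' @return A [trait_assignment()] over the tree's tips.
#' @export
simulate_binary_trait <- function(tree, rate01 = 0.5, rate10 = 0.5,
                                  seed = NULL, states = c("0", "1")) {
  stopifnot(inherits(tree, "phylo"), rate01 > 0, rate10 > 0,
            length(states) == 2L, !is.null(tree$edge.length))
  if (!is.null(seed)) set.seed(seed)
  s <- rate01 + rate10
  pi1 <- rate01 / s
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")
  node_state <- integer(ntip + tr$Nnode)  # 0/1
  node_state[ntip + 1L] <- as.integer(runif(1L) < pi1)
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    decay <- exp(-s * tr$edge.length[k])
    p1 <- pi1 + (node_state[p] - pi1) * decay  # P(child = 1 | parent)
    node_state[ch] <- as.integer(runif(1L) < p1)
  }
  out <- trait_assignment(setNames(states[node_state[seq_len(ntip)] + 1L],
                                   tr$tip.label),
                          valid_states = states)
  attr(out, "root_state") <- states[node_state[ntip + 1L] + 1L]
  out
}

#' Bootstrap pseudo tree sample from an alignment
#'
#' Stands in for a Bayesian posterior: each tree is built by neighbor
#' joining on the distance matrix of a column-resampled alignment.
#'
#' @param aln A DNA [alignment()] with `>= 3` taxa.
#' @param model Distance model passed to [distance_matrix()].
#' @param n_trees Number of bootstrap trees (`>= 1`).
#' @param seed Optional integer seed.
#' @param include_original Prepend the tree built from the unresampled
#'   alignment (default `FALSE`).
#' @return A [tree_sample()] with provenance `"bootstrap"`.
#' @export
bootstrap_tree_sample <- function(aln, model = "jc69", n_trees = 100L,
                                  seed = NULL, include_original = FALSE) {
  stopifnot(n_trees >= 1L)
  if (!is.null(seed)) set.seed(seed)
  m <- aln_matrix(aln)
  ns <- ncol(m)
  build <- function(cols) {
    seqs <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    neighbor_joining(distance_matrix(alignment(seqs), model = model))
  }
  trees <- lapply(seq_len(n_trees), function(b)
    build(sample.int(ns, ns, replace = TRUE)))
  if (include_original) trees <- c(list(build(seq_len(ns))), trees)
  tree_sample(trees, provenance = "bootstrap")
}
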