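# Shared fixtures built in code.

# rooted caterpillar ((((t1,t2),t3),...),tn) with unit branch lengths
make_caterpillar <- function(n) {
  txt <- "(t1:1,t2:1)"
  for (i in seq_len(n - 2L) + 2L) txt <- sprintf("(%s:1,t%d:1)", txt, i)
  ape::read.tree(text = paste0(txt, ";"))
}

# random rooted binary tree with branch lengths bounded away from zero
random_rooted_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  tr
}

# random binary trait over a tree's tips, both states guaranteed present
random_binary_traits <- function(tree, states = c("A", "B")) {
  n <- length(tree$tip.label)
  st <- sample(states, n, replace = TRUE)
  if (length(unique(st)) == 1L) st[sample.int(n, 1L)] <- setdiff(states, st[1L])
  trait_assignment(setNames(st, tree$tip.label), valid_states = states)
}

# replace stop codons in-frame so simulated DNA translates cleanly
sanitize_stops <- function(dna) {
  n <- nchar(dna)
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  codons[codons %in% c("TAA", "TAG", "TGA")] <-
    sub("^T", "C", codons[codons %in% c("TAA", "TAG", "TGA")])
  paste(codons, collapse = "")
}

# a complete, consistent set of pipeline input files in `dir`
make_pipeline_inputs <- function(dir, seed = 2024L) {
  seeds <- split_seed(seed, 6L)
  tree <- simulate_yule_tree(12L, 1, seed = seeds[1L])
  ligand <- evolve_alignment(tree, 27L, "JC69", rate_multiplier = 0.05,
                             seed = seeds[2L])
  receptor <- evolve_alignment(tree, 300L, "JC69", rate_multiplier = 0.05,
                               seed = seeds[3L])
  ligand <- alignment(vapply(unclass(ligand), sanitize_stops, character(1)))
  receptor <- alignment(vapply(unclass(receptor), sanitize_stops, character(1)))
  traits <- simulate_binary_trait(tree, 0.2, 0.2, seed = seeds[4L],
                                  states = c("non-monogamous", "monogamous"))
  if (length(unique(unclass(traits))) == 1L) {
    st <- unclass(traits)
    st[1L] <- setdiff(c("non-monogamous", "monogamous"), st[1L])
    traits <- trait_assignment(st)
  }
  trees <- bootstrap_tree_sample(receptor, "jc69", n_trees = 4L,
                                 seed = seeds[5L])
  paths <- list(
    ligand_fasta = file.path(dir, "ligand.fasta"),
    receptor_fasta = file.path(dir, "receptor.fasta"),
    tree_file = file.path(dir, "trees.nwk"),
    trait_csv = file.path(dir, "traits.csv"),
    domain_csv = file.path(dir, "domains.csv"))
  write_fasta(ligand, paths$ligand_fasta)
  write_fasta(receptor, paths$receptor_fasta)
  ape::write.tree(structure(unclass(trees), class = "multiPhylo"),
                  file = paths$tree_file)
  write_trait_table(traits, paths$trait_csv)
  write.csv(data.frame(label = c("N-term", "TM1", "C-term"),
                       start = c(1L, 21L, 61L), end = c(20L, 60L, 100L)),
            paths$domain_csv, row.names = FALSE, quote = FALSE)
  c(paths,
    list(reference_taxon = tree$tip.label[1L],
         state = "monogamous", seed = seeds[6L],
         tree = tree, traits = traits))
}
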