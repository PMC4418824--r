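# End-to-end orchestration: distances -> coevolution, tree sample + traits
# -> MC test, ligand translation -> peptide profiles, receptor translation
# -> substitution records and per-domain proportions, one JSON summary.
#
# No stage mutates another stage's inputs; all intermediates are files in
# out_dir.  Results never carry timestamps (re-running an identical config
# and seed is byte-identical); the run manifest, which does carry a
# timestamp and input hashes, is written separately.

.pipeline_defaults <- function() {
  list(model = "k2p", gamma_alpha = NULL, gaps = "pairwise",
       n_permutations = 999L, n_replicates = 1000L, seed = 1L,
       burnin_fraction = 0, state = "monogamous", reference_pH = 7.3,
       min_group_size = 2L)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", name, "]: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full ligand/receptor analysis pipeline
#'
#' Executes every analysis stage on one dataset and writes machine-readable
#' outputs: distance matrices (CSV), the mirror-tree coevolution result
#' (JSON), the MC phylogeny-trait result (JSON), peptide physicochemistry
#' profiles (CSV), substitution records and per-domain proportions (CSV),
#' and a single `summary.json` combining all result blocks.  A
#' `run_manifest.json` records input paths, MD5 hashes, parameters and the
#' package version.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `ligand_fasta`, `receptor_fasta`, `tree_file`, `trait_csv`,
#'   `reference_taxon` (required); `domain_csv`, `model` (`"p"`, `"jc69"`,
#'   `"k2p"`, `"t92"`; default `"k2p"`), `gamma_alpha`, `gaps`,
#'   `n_permutations`, `n_replicates`, `seed`, `burnin_fraction`, `state`,
#'   `reference_pH` (optional; defaults as in the vignette).
#' @param out_dir Output directory (created if needed).
#' @param dry_run Validate inputs and return the execution plan without
#'   computing.
#' @return Invisibly, a list with all result blocks (and `files`, the paths
#'   written).
#' @export
run_full_pipeline <- function(config, out_dir, dry_run = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  required <- c("ligand_fasta", "receptor_fasta", "tree_file", "trait_csv",
                "reference_taxon")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("config is missing required entr",
         if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "))
  }
  input_stage <- c(ligand_fasta = "seq_io", receptor_fasta = "seq_io",
                   tree_file = "phylo_trait", trait_csv = "phylo_trait",
                   domain_csv = "substitution_analysis")
  for (key in names(input_stage)) {
    if (key == "domain_csv" && is.null(cfg$domain_csv)) next
    if (!file.exists(cfg[[key]])) {
      stop("pipeline stage [", input_stage[[key]], "]: input file not found for ",
           key, ": ", cfg[[key]])
    }
  }
  plan <- list(
    stages = c("seq_io", "evo_distance", "mirror_coevolution", "phylo_trait",
               "peptide_chem", "substitution_analysis", "summary"),
    parameters = cfg)
  if (dry_run) {
    message("dry run: inputs validated; stages: ",
            paste(plan$stages, collapse = " -> "))
    return(invisible(plan))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(cfg$seed, 2L)
  files <- list()

  ligand <- .stage("seq_io", read_fasta(cfg$ligand_fasta, alphabet = "dna"))
  receptor <- .stage("seq_io", read_fasta(cfg$receptor_fasta, alphabet = "dna"))
  traits <- .stage("phylo_trait", read_trait_table(cfg$trait_csv))
  trees <- .stage("phylo_trait",
                  read_tree_sample(cfg$tree_file,
                                   burnin_fraction = cfg$burnin_fraction))
  annotation <- .stage("substitution_analysis",
                       read_domain_annotation(cfg$domain_csv))

  dm_lig <- .stage("evo_distance",
                   distance_matrix(ligand, model = cfg$model,
                                   gamma_alpha = cfg$gamma_alpha,
                                   gaps = cfg$gaps))
  dm_rec <- .stage("evo_distance",
                   distance_matrix(receptor, model = cfg$model,
                                   gamma_alpha = cfg$gamma_alpha,
                                   gaps = cfg$gaps))
  files$dm_ligand <- file.path(out_dir, "distances_ligand.csv")
  files$dm_receptor <- file.path(out_dir, "distances_receptor.csv")
  write_distance_csv(dm_lig, files$dm_ligand)
  write_distance_csv(dm_rec, files$dm_receptor)

  coevo <- .stage("mirror_coevolution",
                  mirror_correlation(dm_lig, dm_rec,
                                     n_permutations = cfg$n_permutations,
                                     seed = seeds[1L]))
  coevo_block <- coevo[c("r", "slope", "intercept", "n_pairs", "p_parametric",
                         "p_permutation", "n_permutations", "alternative")]
  coevo_block$n_shared_taxa <- length(coevo$taxa)
  coevo_block$distance_model <- cfg$model
  files$coevolution <- file.path(out_dir, "coevolution.json")
  jsonlite::write_json(coevo_block, files$coevolution, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  mc <- .stage("phylo_trait",
               mc_test(trees, traits, state = cfg$state,
                       n_replicates = cfg$n_replicates, seed = seeds[2L]))
  mc_block <- mc[c("state", "observed_mc", "observed_ci", "expected_mc",
                   "null_ci", "p_value", "n_replicates", "n_trees",
                   "null_summary")]
  files$mc <- file.path(out_dir, "mc_test.json")
  jsonlite::write_json(mc_block, files$mc, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  peptides <- .stage("peptide_chem", {
    prot <- translate_alignment(ligand)
    peptide_profile(prot, reference_pH = cfg$reference_pH)
  })
  files$peptides <- file.path(out_dir, "peptide_profiles.csv")
  write.csv(peptides, files$peptides, row.names = FALSE, quote = FALSE)

  subs <- .stage("substitution_analysis", {
    prot_rec <- translate_alignment(receptor)
    props <- substitution_proportions(prot_rec, cfg$reference_taxon,
                                      annotation = annotation)
    recs <- attr(props, "records")
    all_recs <- do.call(rbind, lapply(names(recs), function(tx) {
      if (!nrow(recs[[tx]])) return(NULL)
      cbind(taxon = tx, as.data.frame(recs[[tx]]))
    }))
    # group species by whether their ligand peptide equals the reference's
    lig_prot <- unclass(translate_alignment(ligand))
    groups <- NULL
    gtest <- NULL
    if (cfg$reference_taxon %in% names(lig_prot) &&
        "N-term" %in% colnames(props)) {
      consensus <- lig_prot[[cfg$reference_taxon]]
      shared <- intersect(rownames(props), names(lig_prot))
      same <- shared[lig_prot[shared] == consensus]
      diff <- setdiff(shared, same)
      groups <- list(consensus_ligand = same, variant_ligand = diff)
      if (length(same) >= cfg$min_group_size &&
          length(diff) >= cfg$min_group_size) {
        gtest <- group_proportion_test(props[diff, "N-term"],
                                       props[same, "N-term"])
      }
    }
    list(proportions = props, records = all_recs, groups = groups,
         group_test = gtest)
  })
  files$substitutions <- file.path(out_dir, "substitution_records.csv")
  files$proportions <- file.path(out_dir, "domain_proportions.csv")
  if (!is.null(subs$records)) {
    write.csv(subs$records, files$substitutions, row.names = FALSE)
  } else {
    write.csv(data.frame(taxon = character(), column = integer(),
                         ref = character(), alt = character(),
                         domain = character(), verdict = character(),
                         changed = character()),
              files$substitutions, row.names = FALSE)
  }
  write.csv(data.frame(taxon = rownames(subs$proportions),
                       as.data.frame(subs$proportions), check.names = FALSE),
            files$proportions, row.names = FALSE)

  summary_block <- list(
    distances = list(model = cfg$model, gaps = cfg$gaps,
                     gamma_alpha = cfg$gamma_alpha,
                     n_taxa_ligand = length(ligand),
                     n_taxa_receptor = length(receptor)),
    coevolution = coevo_block,
    mc = mc_block,
    peptides = list(n = nrow(peptides),
                    n_distinct = length(unique(peptides$sequence)),
                    reference_pH = cfg$reference_pH),
    substitutions = list(
      n_records = if (is.null(subs$records)) 0L else nrow(subs$records),
      n_radical = if (is.null(subs$records)) 0L else
        sum(subs$records$verdict == "radical"),
      group_test = subs$group_test))
  files$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_block, files$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  inputs <- c(cfg$ligand_fasta, cfg$receptor_fasta, cfg$tree_file,
              cfg$trait_csv,
              if (!is.null(cfg$domain_csv)) cfg$domain_csv)
  manifest <- list(
    inputs = data.frame(path = inputs, md5 = unname(tools::md5sum(inputs))),
    parameters = cfg[setdiff(names(cfg), required)],
    package_version = as.character(utils::packageVersion("oxtkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  files$manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(coevolution = coevo, mc = mc, peptides = peptides,
                 substitutions = subs, summary = summary_block,
                 files = files))
}
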