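# End-to-end demo pipeline: simulate -> qc -> mask/filter -> likelihood
# mapping on original and permuted data -> gene-tree quartet support ->
# ancestral characters, with a checksum manifest making runs comparable.

#' Default pipeline configuration
#'
#' A flat list of per-stage settings with the published thresholds as
#' defaults (RCFV mask at 0.1 inclusive; decisive rule all-taxa / <30%
#' ambiguous / >=500 sites) and desk-scale simulation sizes. Override any
#' entry via the `config` argument of [run_pipeline()] or a YAML file with
#' the same structure.
#'
#' @return nested list of settings.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_taxa = 20L, height = 1, alphabet = "NT", shape = 1,
                    partition_lengths = c(p1 = 900L, p2 = 800L, p3 = 700L),
                    occupancy = 0.9,
                    shift = list(n_taxa = 3L, weight = 1, partitions = "p1"),
                    n_gene_trees = 100L, eps = 0.2,
                    n_characters = 20L, k_states = 3L, char_rate = 0.5),
    qc = list(rcfv_threshold = 0.1, max_ambiguous_fraction = 0.30,
              min_sites = 500L),
    fclm = list(cap = 40L, min_sites = 30L, shape = 1,
                permutations = c("columnwise", "rowwise", "maskonly")),
    qsupport = list(cap_per_edge = 200L),
    charmap = list(n_histories = 500L)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full congruence-assessment pipeline on simulated data
#'
#' Stages, in order: (1) simulate a species tree, a partitioned alignment
#' with compositional shifts and an occupancy mask, gene trees and discrete
#' characters; (2) supermatrix QC: pairwise symmetry tests, per-partition
#' RCFV, completeness, RCFV masking and the decisive filter; (3) four-cluster
#' likelihood mapping on the original alignment and on each requested
#' permutation scheme, for groups read off a true internal split; (4)
#' per-edge quartet support of the species tree against the gene trees;
#' (5) parsimony mapping, Mk model selection and stochastic character
#' mapping of the first simulated character. Every artifact is written under
#' `out_dir` and listed with its MD5 checksum in `manifest.json`; a rerun
#' with the same configuration reproduces the manifest byte-for-byte.
#'
#' @param config list overriding [default_config()] entries, or a YAML file
#'   path with the same structure.
#' @param out_dir output directory (created; must be empty or absent).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(p) { files <<- c(files, p); p }
  seed <- as.integer(cfg$seed)

  # -- stage 1: synthetic data ------------------------------------------
  sim <- cfg$simulate
  tree <- simulate_tree(sim$n_taxa, height = sim$height,
                        seed = substream_seed(seed, "tree"))
  model <- subst_model(sim$alphabet, shape = sim$shape)
  shift <- NULL
  if (!is.null(sim$shift) && sim$shift$n_taxa > 0) {
    k <- model$k
    f <- rep(1, k); f[seq_len(ceiling(k / 2))] <- 3  # skewed target freqs
    shift <- list(taxa = tree$tip.label[seq_len(sim$shift$n_taxa)],
                  freqs = f / sum(f), weight = sim$shift$weight,
                  partitions = sim$shift$partitions)
  }
  aln <- simulate_alignment(tree, unlist(sim$partition_lengths), model,
                            shift = shift, occupancy = sim$occupancy,
                            seed = substream_seed(seed, "alignment"))
  gts <- simulate_gene_trees(tree, sim$eps, sim$n_gene_trees,
                             seed = substream_seed(seed, "genetrees"))
  mk_true <- mk_model(letters[seq_len(sim$k_states)], "ER", sim$char_rate)
  chars <- simulate_characters(tree, mk_true, sim$n_characters,
                               seed = substream_seed(seed, "characters"))
  ape::write.tree(tree, add(file.path(out_dir, "species_tree.nwk")))
  write_alignment(aln, add(file.path(out_dir, "alignment.fasta")), "fasta")
  write_partitions(aln$partitions, add(file.path(out_dir, "partitions.txt")))
  ape::write.tree(gts, add(file.path(out_dir, "gene_trees.nwk")))
  write_character_matrix(chars, add(file.path(out_dir, "characters.tsv")))

  # -- stage 2: supermatrix QC ------------------------------------------
  crit <- filter_criteria(max_ambiguous_fraction = cfg$qc$max_ambiguous_fraction,
                          min_sites = cfg$qc$min_sites,
                          rcfv_threshold = cfg$qc$rcfv_threshold)
  sym <- pairwise_symmetry(aln)
  .write_tsv(sym$pairs, add(file.path(out_dir, "qc_bowker_pairs.tsv")))
  comp <- completeness(aln)
  masked <- mask_by_rcfv(aln, crit)
  .write_tsv(masked$report, add(file.path(out_dir, "qc_rcfv.tsv")))
  dec <- decisive_filter(aln, crit)
  .write_tsv(dec$report, add(file.path(out_dir, "qc_decisive.tsv")))
  .write_json(list(C_a = comp$C_a, median_bowker_p = sym$median_p,
                   n_partitions_masked = sum(masked$report$masked),
                   n_partitions_decisive = length(dec$surviving)),
              add(file.path(out_dir, "qc_summary.json")))

  # -- stage 3: likelihood mapping, original + permutations -------------
  grouping <- groups_from_split(tree, aln)
  write_grouping(grouping, add(file.path(out_dir, "groups.tsv")))
  fclm_res <- list()
  fclm_res$original <- run_hypothesis(aln, grouping, cap = cfg$fclm$cap,
                                      seed = substream_seed(seed, "fclm-original"),
                                      min_sites = cfg$fclm$min_sites,
                                      shape = cfg$fclm$shape)
  for (scheme in cfg$fclm$permutations) {
    paln <- switch(scheme,
                   columnwise = scheme_columnwise(aln, substream_seed(seed, "perm-col")),
                   rowwise = scheme_rowwise(aln, substream_seed(seed, "perm-row")),
                   maskonly = scheme_mask_only(aln, substream_seed(seed, "perm-mask")),
                   stop_phylocong(sprintf("unknown permutation scheme '%s'", scheme),
                                  "phylocong_argument_error"))
    fclm_res[[scheme]] <- run_hypothesis(paln, grouping, cap = cfg$fclm$cap,
                                         seed = substream_seed(seed, paste0("fclm-", scheme)),
                                         min_sites = cfg$fclm$min_sites,
                                         shape = cfg$fclm$shape)
  }
  .write_json(lapply(fclm_res, function(s)
    list(label = s$label, n_evaluated = s$n_evaluated, n_skipped = s$n_skipped,
         region_pct = as.list(round(s$region_pct, 4)))),
    add(file.path(out_dir, "fclm_summary.json")))

  # -- stage 4: gene-tree quartet support -------------------------------
  qs <- edge_quartet_support(tree, gts, cap_per_edge = cfg$qsupport$cap_per_edge,
                             seed = substream_seed(seed, "qsupport"))
  .write_tsv(qs$edges, add(file.path(out_dir, "quartet_support.tsv")))
  ape::write.tree(qs$tree, add(file.path(out_dir, "quartet_support.nwk")))

  # -- stage 5: ancestral characters ------------------------------------
  pars <- sankoff_matrix(tree, chars)
  .write_tsv(data.frame(character = chars$characters, score = pars$scores),
             add(file.path(out_dir, "parsimony_scores.tsv")))
  if (!is.null(pars$apomorphies))
    .write_tsv(pars$apomorphies, add(file.path(out_dir, "apomorphies.tsv")))
  sel <- mk_model_select(tree, chars)
  .write_tsv(sel$table, add(file.path(out_dir, "mk_model_selection.tsv")))
  scm <- scm_sample(tree, chars, sel$fits[[sel$best_aic]],
                    n_histories = cfg$charmap$n_histories,
                    seed = substream_seed(seed, "scm"), char = 1L)
  node_tab <- data.frame(node = rownames(scm$node_freq),
                         round(scm$node_freq, 6))
  .write_tsv(node_tab, add(file.path(out_dir, "scm_node_probabilities.tsv")))

  # -- manifest ----------------------------------------------------------
  manifest <- list(package = "phylocong",
                   config = cfg,
                   files = lapply(setNames(nm = basename(files)), function(f)
                     unname(tools::md5sum(file.path(out_dir, f)))))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(tree = tree, alignment = aln, gene_trees = gts,
                 characters = chars, symmetry = sym, completeness = comp,
                 masked = masked, decisive = dec, fclm = fclm_res,
                 qsupport = qs, parsimony = pars, mk_selection = sel,
                 scm = scm, manifest = manifest, out_dir = out_dir))
}
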