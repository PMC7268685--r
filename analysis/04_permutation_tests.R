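#!/usr/bin/env Rscript
# Stage 4: likelihood mapping on signal-destroying permutations.
#
# Each scheme keeps a different confounder and destroys the rest:
#   columnwise  - keeps column state multisets (site-rate profile),
#                 destroys tree signal and lineage composition
#   rowwise     - keeps per-taxon composition (SRH-violation structure),
#                 destroys shared site patterns
#   maskonly    - keeps only the coverage pattern
# Support surviving a permutation is, by construction, not phylogenetic.
library(phylocong)

seed <- 20260920L
data_dir <- "results/data"
out <- "results/fclm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

aln <- read_alignment(file.path(data_dir, "alignment.fasta"), alphabet = "NT")
aln <- set_partitions(aln, read_partitions(file.path(data_dir, "partitions.txt")))
tree <- read_tree(file.path(data_dir, "species_tree.nwk"))
grouping <- groups_from_split(tree, aln)

schemes <- list(columnwise = scheme_columnwise,
                rowwise = scheme_rowwise,
                maskonly = scheme_mask_only)
summaries <- list()
for (nm in names(schemes)) {
  perm <- schemes[[nm]](aln, substream_seed(seed, paste0("perm-", nm)))
  write_alignment(perm, file.path(out, sprintf("alignment_%s.fasta", nm)), "fasta")
  res <- run_hypothesis(perm, grouping, cap = 200L,
                        seed = substream_seed(seed, paste0("fclm-", nm)))
  summaries[[nm]] <- list(alpha = res$alpha, n_evaluated = res$n_evaluated,
                          region_pct = as.list(round(res$region_pct, 4)))
  cat(sprintf("%-10s corners %5.1f / %5.1f / %5.1f %%  centre %4.1f %%\n", nm,
              res$region_pct["C1"], res$region_pct["C2"], res$region_pct["C3"],
              res$region_pct["CTR"]))
  write.table(res$quartets, file.path(out, sprintf("quartets_%s.tsv", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
jsonlite::write_json(summaries, file.path(out, "summary_permutations.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Corner support should collapse toward uniform on permuted data;\n")
cat("any residual corner excess tracks the confounder each scheme preserves.\n")
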