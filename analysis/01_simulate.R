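#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data set every later stage consumes.
#
# The generator emulates the structures the diagnostics are designed to
# detect: a partitioned alignment with gamma rate variation, a
# compositional shift on three lineages confined to partition p1 (an SRH
# violation), non-random taxon occupancy, gene trees with NNI discordance
# around the species tree, and discrete characters evolved under an
# equal-rates Mk model on the same tree.
library(phylocong)

seed <- 20260920L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tree <- simulate_tree(20, height = 1, seed = substream_seed(seed, "tree"))
# pin the most balanced internal split at 0.3 substitutions/site so one
# split carries known, strong signal for the likelihood-mapping stage
tree <- strengthen_split(tree, internal_length = 0.3)$tree
model <- subst_model("NT", shape = 1)
shift <- list(taxa = tree$tip.label[1:3], freqs = c(.375, .125, .375, .125),
              weight = 1, partitions = "p1")
# structured, non-random coverage: taxa 4-6 lack partition p3 entirely;
# light per-site dropout adds ambiguity texture everywhere
occupancy <- matrix(1, 20, 3, dimnames = list(tree$tip.label, c("p1", "p2", "p3")))
occupancy[tree$tip.label[4:6], "p3"] <- 0
aln <- simulate_alignment(tree, c(p1 = 900L, p2 = 800L, p3 = 700L), model,
                          shift = shift, occupancy = occupancy,
                          site_dropout = 0.03,
                          seed = substream_seed(seed, "alignment"))
gene_trees <- simulate_gene_trees(tree, eps = 0.2, n = 100,
                                  seed = substream_seed(seed, "genetrees"))
chars <- simulate_characters(tree, mk_model(c("a", "b", "c"), "ER", 0.5), 20,
                             seed = substream_seed(seed, "characters"))

ape::write.tree(tree, file.path(out, "species_tree.nwk"))
write_alignment(aln, file.path(out, "alignment.fasta"), "fasta")
write_partitions(aln$partitions, file.path(out, "partitions.txt"))
ape::write.tree(gene_trees, file.path(out, "gene_trees.nwk"))
write_character_matrix(chars, file.path(out, "characters.tsv"))

cat(sprintf("Simulated %d taxa x %d sites (%d partitions), %d gene trees, %d characters\n",
            nrow(aln$mat), ncol(aln$mat), length(aln$partitions$entries),
            length(gene_trees), length(chars$characters)))
cat(sprintf("Data written under %s (master seed %d)\n", out, seed))
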