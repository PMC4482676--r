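#!/usr/bin/env Rscript
## Phylogenetic signal of every community trait on the framework tree built
## from the table's taxonomy: parsimony steps, CI/RI, Blomberg's K, Pagel's
## lambda.

suppressMessages(library(fruitsignals))
dir.create("results", showWarnings = FALSE)

d <- madagascar_fruit_traits()
tree <- tree_from_taxonomy(d)
ape::write.tree(tree, "results/framework_tree.nwk")

tab <- phylo_signal_table(d, tree = tree, n_perm = 1000, seed = 42)
print(tab, digits = 3)
write.csv(tab, "results/phylo_signal.csv", row.names = FALSE)

cat("\nFindings:\n")
cat(sprintf(" * consistency indices %.2f-%.2f: extensive homoplasy for every trait\n",
            min(tab$ci), max(tab$ci)))
sig <- tab$trait[tab$k_p < 0.05]
cat(sprintf(" * K randomization flags %s on this framework tree (p < 0.05);\n",
            paste(sig, collapse = ", ")))
cat("   the published analysis, on its own species-level tree, reported no\n")
cat("   significant signal for any trait -- K and lambda are sensitive to\n")
cat("   tree topology and branch lengths (see vignette)\n")
cat("Wrote results/phylo_signal.csv and results/framework_tree.nwk\n")
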