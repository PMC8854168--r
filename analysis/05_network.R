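#!/usr/bin/env Rscript
# Step 5 — expression, coexpression/PPI network and module statistics for
# the candidate genes prioritized in step 3.
#
# Simulates a stage-profiled expression matrix and a block-structured PPI
# table over the candidate genes, builds the merged functional network,
# and computes the statistics reported for such networks: typed degrees,
# the degree-versus-pleiotropy Spearman correlation, module-membership
# enrichment per disorder, and the trend of network membership with the
# number of sharing disorders. The generator does not couple network
# degree or module membership to pleiotropy, so the correlation and trend
# statistics here exercise the machinery on null data (their power is
# checked against planted signals in the test suite).

suppressPackageStartupMessages(library(dnmcross))
dir.create("results", showWarnings = FALSE)

tada <- utils::read.delim("results/tada_genes.tsv")
cand <- tada[tada$candidate, ]
if (nrow(cand) < 20) stop("too few candidates; rerun steps 1-3")

set.seed(20260926)
ex <- simulate_expression(nrow(cand), n_samples = 60, k_modules = 2,
                          noise_sd = 0.5)
# re-key simulated genes to the candidate gene ids
rownames(ex$expr) <- cand$gene
ex$modules$gene <- cand$gene
ppi <- simulate_ppi(cand$gene, ex$modules, p_within = 0.015,
                    p_between = 0.002)

coexpr <- coexpression_edges(ex$expr, threshold = 0.8)
ppi_kept <- filter_ppi(ppi, min_score = 400)
ann <- data.frame(gene = cand$gene, n_disorders = cand$n_disorders,
                  tier = cand$tier)
net <- merge_network(coexpr, ppi_kept, ann)
utils::write.table(net$edges, "results/network_edges.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(net$nodes, "results/network_nodes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("network: %d of %d candidates connected (%.1f%%), %d edges\n",
            sum(net$nodes$in_network), nrow(net$nodes),
            100 * mean(net$nodes$in_network), nrow(net$edges)))
for (ty in c("coexpression", "ppi")) {
  r <- degree_vs_shared(net, ty)
  cat(sprintf("degree vs shared disorders (%s): rho %.2f, p %.2g\n",
              ty, r$rho, r$p))
}

# module enrichment of each disorder's best candidates, against the
# candidate background
enr <- do.call(rbind, lapply(split(cand$gene, cand$best_disorder), function(g) {
  if (length(g) < 5) return(NULL)
  module_enrichment(g, ex$modules, cand$gene)
}))
utils::write.table(enr, "results/module_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

trend <- shared_trend_test(net$nodes$in_network, net$nodes$n_disorders)
cat(sprintf("network membership vs shared disorders: slope %.2f, p %.2g%s\n",
            trend$slope, trend$p,
            if (trend$separation) " (Firth fit)" else ""))
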