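#!/usr/bin/env Rscript
# Step 1 — generate the synthetic multi-cohort trio study.
#
# The generator emulates the curated five-disorder compendium: trio counts
# per cohort, marginal per-trio DNM class rates matching the control
# cohort, log-normal per-gene mutability, and gamma-Poisson risk genes
# partially shared across disorders. Everything downstream (02-05) runs
# off the tables written here.

suppressPackageStartupMessages(library(dnmcross))

outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

config <- sim_config(seed = 20260926)
write_sim_config(config, file.path(outdir, "config.yaml"))

study <- simulate_study(config)

write_dnm_table(study$records, file.path(outdir, "dnms.tsv"))
utils::write.table(study$universe[, c("gene", "mu_lof", "mu_dmis",
                                      "mu_tmis", "mu_syn")],
                   file.path(outdir, "gene_rates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(cohort = names(study$trio_counts),
                              n_trios = as.integer(study$trio_counts)),
                   file.path(outdir, "trios.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
truth_cols <- grep("^(gene$|risk_|gamma_)", names(study$universe), value = TRUE)
utils::write.table(study$universe[, truth_cols],
                   file.path(outdir, "risk_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

n_risk <- sum(rowSums(as.matrix(
  study$universe[, grep("^risk_", names(study$universe))])) > 0)
cat(sprintf("simulated %d DNM records over %d genes (%d risk genes) in %d cohorts\n",
            nrow(study$records), config$n_genes, n_risk,
            length(study$trio_counts)))
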