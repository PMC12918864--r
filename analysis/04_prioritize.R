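#!/usr/bin/env Rscript
# Stage 4: the candidate prioritization cascade on the outlet-4 hits.
#
# Five conjunctive filters: significantly enriched in outlet 4; annotated
# with a whitelisted functional category (cytoskeleton, adhesion &
# migration, cell cycle, signaling); top tercile of cell-line expression;
# member-guide fold change > 100; and log-rank p < 0.05 on BOTH overall and
# progression-free survival under expression trichotomization (bottom vs
# top tercile of patients). Expression, categories and patient cohorts are
# simulated so the planted strong knockout carries matching signal.

library(mechscreen)

seed <- 1L
out <- "results/screen"
o4 <- read.delim(file.path(out, "enrichment_outlet4.tsv"))
planted <- read.csv(file.path(out, "planted_effects.csv"))$gene
genes <- sort(o4$gene)

expr <- simulate_expression(genes, high_genes = planted, seed = seed)
write.csv(data.frame(gene = names(expr), value = expr),
          file.path(out, "expression.csv"), row.names = FALSE)
terciles <- expression_terciles(expr)
cats <- simulate_categories(genes,
                            forced = setNames(rep("cytoskeleton",
                                                  length(planted)), planted),
                            seed = seed)
write.csv(cats, file.path(out, "categories.csv"), row.names = FALSE)

enriched <- o4$gene[o4$status == "enriched"]
surv <- lapply(seq_along(enriched), function(i) {
  hr <- if (enriched[i] %in% planted) 2 else 1
  os <- simulate_survival_cohort(300, hr_top = hr, seed = seed + 10 * i)
  pfs <- simulate_survival_cohort(300, base_median_months = 12, hr_top = hr,
                                  seed = seed + 10 * i + 5)
  list(OS = survival_tercile_test(os, "OS"),
       PFS = survival_tercile_test(pfs, "PFS"))
})
names(surv) <- enriched

cand <- filter_candidates(o4, cats, terciles, surv,
                          candidate_filter_config(outlet = "outlet4"))
write.table(cand, file.path(out, "candidates.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

final <- cand[cand$candidate, ]
cat(sprintf("Cascade: %d genes in -> %d enriched -> %d final candidate(s).\n",
            nrow(cand), sum(cand$pass_enriched), nrow(final)))
if (nrow(final)) {
  cat("Final candidates (median survival differences in months, low - high expression):\n")
  print(final[, c("gene", "max_guide_FC", "os_p", "os_median_diff",
                  "pfs_p", "pfs_median_diff")], digits = 3, row.names = FALSE)
}
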