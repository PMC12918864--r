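#!/usr/bin/env Rscript
# Stage 1: simulate the mechanical CRISPR screen with known ground truth.
#
# A 200-gene x 4-guide library stands in for the genome-scale one; five
# genes are planted as stiffening knockouts enriched in outlet 4 (one of
# them strongly enough to clear the downstream >100-fold guide filter), and
# counts for 1 inlet + 2 outlets x 3 replicates are drawn from the NB
# sorting model at 100 reads/guide. Reads are written as per-sample FASTQ.

library(mechscreen)

seed <- 1L
out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- make_guide_library(n_genes = 200, guides_per_gene = 4, seed = seed)
write_guide_library(lib, file.path(out, "library.csv"))

planted <- sprintf("GENE%04d", 1:5)
effects <- list(outlet4 = setNames(c(600, rep(8, 4)), planted))
truth <- screen_truth(lib, effects = effects, dispersion = 0.05, seed = seed)

design <- screen_design(c("outlet4", "outlet5"), replicates = 3)
sim <- simulate_screen_counts(lib, design, truth,
                              depth = 100 * nrow(lib), seed = seed)
# bulky read data goes under scratch/; results/ keeps the small tables
paths <- write_screen_fastq(lib, sim$counts, "scratch/screen_fastq",
                            seed = seed)
manifest <- data.frame(sample = design$sample, role = design$condition,
                       replicate = design$replicate,
                       path = file.path("scratch/screen_fastq",
                                        basename(paths[design$sample])))
write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE,
          quote = FALSE)
write_count_matrix(sim$counts, file.path(out, "true_counts.tsv"))
write.csv(data.frame(gene = planted, outlet = "outlet4",
                     multiplier = effects$outlet4),
          file.path(out, "planted_effects.csv"), row.names = FALSE)

cat(sprintf("Simulated %d guides x %d samples (%s total reads); planted %d\n",
            nrow(sim$counts), ncol(sim$counts),
            format(sum(sim$counts), big.mark = ","), length(planted)),
    "stiffening knockouts in outlet 4. FASTQ under scratch/screen_fastq.\n")
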