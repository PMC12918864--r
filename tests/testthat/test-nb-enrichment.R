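test_that("gene summing is exact, conserving and permutation invariant", {
  lib <- data.frame(guide_id = c("a1", "a2", "b1"),
                    gene = c("A", "A", "B"),
                    protospacer = c("AC", "GT", "CA"))
  cnt <- matrix(c(3L, 4L, 5L), ncol = 1, dimnames = list(c("a1", "a2", "b1"), "s"))
  got <- sum_gene_counts(cnt, lib)
  expect_equal(got["A", "s"], 7L)
  expect_equal(colSums(got), colSums(cnt))
  perm <- cnt[c(3, 1, 2), , drop = FALSE]
  expect_identical(sum_gene_counts(perm, lib), got)
  orphan <- rbind(cnt, matrix(1L, 1, 1, dimnames = list("zz", "s")))
  expect_error(sum_gene_counts(orphan, lib), "zz")
})

test_that("size factors follow median-of-ratios and match DESeq2", {
  set.seed(5)
  m <- matrix(rnbinom(400, mu = 100, size = 10) + 1L, ncol = 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  s <- size_factors(m)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-12)
  # identical columns: all factors 1
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(size_factors(same)), rep(1, 3))
  # tripled column: ratio 3
  trip <- cbind(s1 = m[, 1], s2 = 3L * m[, 1])
  s2 <- size_factors(trip)
  expect_equal(unname(s2[2] / s2[1]), 3, tolerance = 1e-12)
  # gene reordering leaves s unchanged
  expect_equal(size_factors(m[sample(nrow(m)), ]), s)
  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(s / exp(mean(log(s))), ref / exp(mean(log(ref))),
               tolerance = 1e-10)
})

test_that("dispersion estimation recovers the generative regime", {
  set.seed(6)
  n_g <- 1000; reps <- 4
  cond <- rep(c("inlet", "outlet"), each = reps)
  mu <- rep(1200, n_g)
  # NB at alpha = 0.1
  m_nb <- matrix(rnbinom(n_g * 2 * reps, mu = mu, size = 1 / 0.1), nrow = n_g,
                 dimnames = list(paste0("g", 1:n_g), NULL))
  colnames(m_nb) <- paste0("s", 1:8)
  s <- rep(1, 8); names(s) <- colnames(m_nb)
  a_nb <- estimate_dispersions(m_nb, s, cond)
  expect_gt(median(a_nb), 0.05)
  expect_lt(median(a_nb), 0.2)
  expect_true(all(a_nb >= 1e-8))
  # Poisson counts: gene-wise MoM medians at the floor
  m_po <- matrix(rpois(n_g * 2 * reps, 1200), nrow = n_g,
                 dimnames = dimnames(m_nb))
  a_po <- estimate_dispersions(m_po, s, cond)
  expect_equal(median(attr(a_po, "alpha_mom")), 1e-8)
  expect_lt(median(a_po), 1e-3)
})

test_that("Wald test is symmetric and recovers a planted enrichment", {
  lib <- make_guide_library(200, 4, seed = 7)
  eff <- c(GENE0003 = 8)
  tr <- screen_truth(lib, effects = list(outlet4 = eff), dispersion = 0.05,
                     seed = 7)
  des <- screen_design("outlet4", replicates = 4)
  sim <- simulate_screen_counts(lib, des, tr, depth = 300 * nrow(lib))
  gc_ <- sum_gene_counts(sim$counts, lib)
  fit <- nb_wald_test(gc_, des$condition, outlet = "outlet4")
  row <- fit[fit$gene == "GENE0003", ]
  expect_equal(row$log2FC, 3, tolerance = 0.3)
  expect_lt(row$padj, 0.001)
  # swapping condition labels negates log2FC, preserves p
  cond_sw <- ifelse(des$condition == "inlet", "outlet4", "inlet")
  fit_sw <- nb_wald_test(gc_, cond_sw, outlet = "outlet4")
  expect_equal(fit_sw$log2FC, -fit$log2FC, tolerance = 1e-6)
  expect_equal(fit_sw$pvalue, fit$pvalue, tolerance = 1e-6)
})

test_that("all-zero genes are excluded and reported", {
  m <- matrix(c(0L, 0L, 0L, 0L, 5L, 6L, 7L, 8L), nrow = 2, byrow = TRUE,
              dimnames = list(c("gZ", "gA"), paste0("s", 1:4)))
  fit <- nb_wald_test(m, c("inlet", "inlet", "outlet4", "outlet4"),
                      outlet = "outlet4",
                      s = setNames(rep(1, 4), colnames(m)),
                      alpha = c(gZ = 0.01, gA = 0.01))
  expect_equal(attr(fit, "excluded"), "gZ")
  expect_false("gZ" %in% fit$gene)
})

test_that("guide fold changes follow the pseudocount formula", {
  lib <- data.frame(guide_id = c("g1", "g2"), gene = c("A", "B"),
                    protospacer = c("AC", "GT"))
  cnt <- matrix(c(2L, 10L, 250L, 10L), nrow = 2,
                dimnames = list(c("g1", "g2"), c("in1", "out1")))
  fc <- guide_fold_changes(cnt, lib, c("inlet", "outlet4"), outlet = "outlet4",
                           s = c(in1 = 1, out1 = 1))
  expect_equal(fc$guide$fc[fc$guide$guide_id == "g1"], 250.5 / 2.5)
  expect_gt(fc$gene[["A"]], 100)
  # equal normalized means: FC = 1
  eq <- matrix(c(5L, 5L), nrow = 1, dimnames = list("g1", c("a", "b")))
  fce <- guide_fold_changes(eq, lib[1, ], c("inlet", "outlet4"), "outlet4",
                            s = c(a = 1, b = 1))
  expect_equal(unname(fce$guide$fc), 1)
  # common depth rescaling is absorbed by size factors
  cnt2 <- cnt; cnt2[, 2] <- cnt2[, 2] * 4L
  fc2 <- guide_fold_changes(cnt2, lib, c("inlet", "outlet4"), "outlet4",
                            s = c(in1 = 1, out1 = 4))
  expect_equal(fc2$guide$fc, fc$guide$fc)
})

test_that("hit classification partitions genes and respects the threshold", {
  fit <- data.frame(gene = c("A", "B", "C"), base_mean = 1,
                    log2FC = c(2, -2, 0.1), SE = 1, wald_z = 1,
                    pvalue = c(1e-6, 1e-6, 0.5),
                    padj = c(1e-5, 1e-5, 0.7), flag = "")
  got <- classify_hits(fit, threshold = 0.001)
  expect_equal(got$status, c("enriched", "depleted", "ns"))
  expect_equal(sum(attr(got, "summary")), nrow(fit))
  all_ns <- classify_hits(transform(fit, padj = 1), threshold = 0.001)
  expect_true(all(all_ns$status == "ns"))
})

test_that("per-sample depth rescaling does not change the test decisions", {
  fx <- tiny_screen(n_genes = 60, reps = 3, depth = 60 * 4 * 200, seed = 31)
  gc_ <- sum_gene_counts(fx$counts, fx$lib)
  fit1 <- nb_wald_test(gc_, fx$design$condition, outlet = "outlet4")
  scaled <- gc_
  scaled[, 1] <- scaled[, 1] * 3L
  fit2 <- nb_wald_test(scaled, fx$design$condition, outlet = "outlet4")
  # size factors absorb the depth change; log2FC stays close
  expect_equal(fit2$log2FC, fit1$log2FC, tolerance = 0.2)
})
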