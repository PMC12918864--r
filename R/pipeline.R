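## Deterministic per-stage seed derived from the global seed, so any stage
## can be replayed in isolation. Kept below 2^31.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 131 + sum(utf8ToInt(stage))) %% 2147483647)
}

write_checksums <- function(dir) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "checksums.txt"]
  sums <- tools::md5sum(files)
  writeLines(paste(unname(sums), substring(files, nchar(dir) + 2L)),
             file.path(dir, "checksums.txt"))
}

#' Run the end-to-end synthetic screen pipeline
#'
#' Simulates a screen with known ground truth, writes per-sample FASTQ,
#' quantifies guides back from the reads, runs QC, tests every outlet
#' against the inlet with the NB Wald model, and applies the prioritization
#' cascade against (simulated or supplied) expression, category and survival
#' tables. All artifacts are written under `out_dir` together with MD5
#' checksums and a run log carrying the derived per-stage seeds.
#'
#' @param config A list. Recognized keys (defaults in parentheses):
#'   `n_genes` (200), `guides_per_gene` (4), `outlets`
#'   (`c("outlet4","outlet5")`), `replicates` (3), `effects` (named list of
#'   per-outlet gene multiplier vectors), `dispersion` (0.05), `depth_per_guide`
#'   (100), `read_length` (50), `threshold` (0.001), `seed` (1),
#'   `out_dir` (required), `filter_config` ([candidate_filter_config()] with
#'   the first configured outlet), `n_patients` (300), `hr_candidate` (2),
#'   `write_fastq` (TRUE; FALSE skips the FASTQ round trip and counts from
#'   the simulated matrix directly).
#' @return Invisibly, a list with `library`, `truth`, `counts`, `qc`,
#'   `enrichment`, `candidates`, `paths`.
#' @export
run_screen_pipeline <- function(config) {
  defaults <- list(n_genes = 200L, guides_per_gene = 4L,
                   outlets = c("outlet4", "outlet5"), replicates = 3L,
                   effects = list(), dispersion = 0.05,
                   depth_per_guide = 100, read_length = 50L,
                   threshold = 0.001, seed = 1L, n_patients = 300L,
                   hr_candidate = 2, write_fastq = TRUE)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("run_screen_pipeline: config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("mechscreen %s | R %s", as.character(utils::packageVersion("mechscreen")),
       paste(R.version$major, R.version$minor, sep = "."))
  logf("global seed %d", cfg$seed)

  run_stage <- function(name, fun) {
    logf("stage %s: seed %d", name, stage_seed(cfg$seed, name))
    tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  library <- run_stage("library", function()
    make_guide_library(cfg$n_genes, cfg$guides_per_gene,
                       seed = stage_seed(cfg$seed, "library")))
  write_guide_library(library, file.path(cfg$out_dir, "library.csv"))

  truth <- run_stage("truth", function()
    screen_truth(library, effects = cfg$effects, dispersion = cfg$dispersion,
                 seed = stage_seed(cfg$seed, "truth")))
  design <- screen_design(cfg$outlets, replicates = cfg$replicates)
  depth <- cfg$depth_per_guide * nrow(library)
  sim <- run_stage("counts", function()
    simulate_screen_counts(library, design, truth, depth = depth,
                           seed = stage_seed(cfg$seed, "counts")))

  if (isTRUE(cfg$write_fastq)) {
    fq_dir <- file.path(cfg$out_dir, "fastq")
    paths <- run_stage("fastq", function()
      write_screen_fastq(library, sim$counts, fq_dir,
                         read_length = cfg$read_length,
                         seed = stage_seed(cfg$seed, "fastq")))
    manifest <- data.frame(sample = design$sample, role = design$condition,
                           replicate = design$replicate,
                           path = basename(unname(paths[design$sample])),
                           stringsAsFactors = FALSE)
    utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    quant <- run_stage("count", function()
      count_guides(paths[design$sample], library))
    counts <- quant$counts
    map_stats <- quant$stats
  } else {
    counts <- sim$counts
    map_stats <- NULL
  }
  write_count_matrix(counts, file.path(cfg$out_dir, "counts.tsv"))

  qc <- run_stage("qc", function() sample_qc(counts, map_stats))
  utils::write.table(qc, file.path(cfg$out_dir, "qc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  enrich <- run_stage("enrich", function()
    enrichment_analysis(counts, library, design$condition,
                        outlets = cfg$outlets, threshold = cfg$threshold))
  for (ot in names(enrich))
    utils::write.table(enrich[[ot]],
                       file.path(cfg$out_dir, paste0("enrichment_", ot, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  target_outlet <- if (!is.null(cfg$filter_config)) cfg$filter_config$outlet
                   else cfg$outlets[1L]
  planted <- names(cfg$effects[[target_outlet]])
  planted <- planted[cfg$effects[[target_outlet]] > 1]
  genes <- sort(unique(library$gene))
  expr <- run_stage("expression", function()
    simulate_expression(genes, high_genes = planted,
                        seed = stage_seed(cfg$seed, "expression")))
  terciles <- expression_terciles(expr)
  cats <- run_stage("categories", function()
    simulate_categories(genes,
                        forced = stats::setNames(rep("cytoskeleton",
                                                     length(planted)), planted),
                        seed = stage_seed(cfg$seed, "categories")))
  surv <- run_stage("survival", function() {
    tested <- enrich[[target_outlet]]$gene[enrich[[target_outlet]]$status == "enriched"]
    out <- lapply(seq_along(tested), function(i) {
      hr <- if (tested[i] %in% planted) cfg$hr_candidate else 1
      os <- simulate_survival_cohort(cfg$n_patients, hr_top = hr,
                                     seed = stage_seed(cfg$seed, paste0("os", i)))
      pfs <- simulate_survival_cohort(cfg$n_patients, base_median_months = 12,
                                      hr_top = hr,
                                      seed = stage_seed(cfg$seed, paste0("pfs", i)))
      list(OS = survival_tercile_test(os, "OS"),
           PFS = survival_tercile_test(pfs, "PFS"))
    })
    stats::setNames(out, tested)
  })
  fcfg <- if (!is.null(cfg$filter_config)) cfg$filter_config
          else candidate_filter_config(outlet = target_outlet)
  candidates <- run_stage("prioritize", function()
    filter_candidates(enrich, cats, terciles, surv, fcfg))
  if (nrow(candidates))
    utils::write.table(candidates, file.path(cfg$out_dir, "candidates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  write_checksums(cfg$out_dir)
  logf("done: %d candidate gene(s)", sum(candidates$candidate %||% logical(0)))
  invisible(list(library = library, truth = truth, counts = counts, qc = qc,
                 enrichment = enrich, candidates = candidates,
                 paths = list(out_dir = cfg$out_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Self-contained demonstration run
#'
#' Simulates and analyzes a small screen (200 genes x 4 guides, inlet + 2
#' outlets x 3 replicates), 20 force curves at two stiffness levels, and 100
#' device tracks in two groups, writing everything under `dir`. With
#' `plant_effects = TRUE` (default) five genes are planted enriched in
#' outlet 4 — one dominant knockout (sorting weight 600, strong enough to
#' clear the >100-fold guide filter after outlet renormalization) and four
#' 8-fold knockouts; with `FALSE` the screen is a null run.
#'
#' @param seed Integer seed.
#' @param dir Workspace directory (default: a tempdir subdirectory).
#' @param plant_effects Plant enriched genes and matching survival effects.
#' @return Invisibly, a list with the screen pipeline result plus `afm`
#'   (modulus group comparison) and `tracks` (track group comparison,
#'   outlet fractions).
#' @export
run_demo <- function(seed = 1L, dir = file.path(tempdir(),
                                                paste0("mechscreen_demo_", seed)),
                     plant_effects = TRUE) {
  planted <- sprintf("GENE%04d", 1:5)
  effects <- if (plant_effects)
    list(outlet4 = stats::setNames(c(600, rep(8, 4)), planted)) else list()
  screen <- run_screen_pipeline(list(
    n_genes = 200L, guides_per_gene = 4L, outlets = c("outlet4", "outlet5"),
    replicates = 3L, effects = effects, depth_per_guide = 100,
    seed = seed, out_dir = dir))

  # AFM arm: 10 soft + 10 stiff synthetic cells
  afm_seed <- stage_seed(seed, "afm")
  fit_group <- function(E, offs) vapply(seq_len(10L), function(i) {
    cv <- simulate_force_curve(E_r = E, z0 = 2000, noise_sd = 5,
                               baseline_slope = 0.002,
                               seed = afm_seed + offs + i)
    analyze_curve(cv)$E_r
  }, 0)
  afm <- compare_modulus_groups(fit_group(800, 0), fit_group(2000, 100))

  # Track arm: 50 control + 50 stiff-shifted cells
  geom <- ridge_geometry(n_ridges = 6L)
  trk_seed <- stage_seed(seed, "tracks")
  soft <- simulate_tracks(geom, 50L, deflection_model(mean = 0, sd = 2),
                          pos_noise = 0.5, seed = trk_seed)
  stiff <- simulate_tracks(geom, 50L, deflection_model(mean = 3, sd = 4),
                           pos_noise = 0.5, seed = trk_seed + 1L)
  m_soft <- all_track_metrics(soft$tracks, geom, fps = 2500)
  m_stiff <- all_track_metrics(stiff$tracks, geom, fps = 2500)
  tracks <- list(comparison = summarize_track_groups(m_soft, m_stiff),
                 outlet_fractions = list(control = outlet_fractions(m_soft),
                                         shifted = outlet_fractions(m_stiff)))
  summary_path <- file.path(dir, "demo_summary.txt")
  n_hit <- sum(screen$candidates$candidate %||% logical(0))
  writeLines(c(
    sprintf("demo seed %d", seed),
    sprintf("screen: %d guides x %d samples, %d candidate gene(s)",
            nrow(screen$counts), ncol(screen$counts), n_hit),
    sprintf("afm: Welch p = %.3g, exceedance = %.2f", afm$welch_p,
            afm$exceedance_b),
    sprintf("tracks: deflection Welch p = %.3g", tracks$comparison$deflection$welch_p)
  ), summary_path)
  invisible(c(screen, list(afm = afm, tracks = tracks)))
}
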