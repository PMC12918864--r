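#' Assign expression terciles
#'
#' Rank-based split of genes into bottom / middle / top thirds of
#' expression. Group sizes differ by at most one for any n; ties are broken
#' by stable input order toward the lower tercile. All-equal expression is
#' an error (terciles undefined).
#'
#' @param expr Named numeric vector (names = genes) with >= 3 finite values.
#' @return Named character vector in `{"bottom","middle","top"}`.
#' @export
expression_terciles <- function(expr) {
  expr <- expr[is.finite(expr)]
  if (length(expr) < 3L) stop("expression_terciles: need >= 3 finite values")
  if (length(unique(expr)) == 1L)
    stop("expression_terciles: all values equal, terciles undefined")
  n <- length(expr)
  k <- n %/% 3L; r <- n %% 3L
  sizes <- c(bottom = k + (r >= 1L), middle = k + (r >= 2L), top = k)
  ord <- order(expr)  # stable: ties keep input order, filling lower terciles first
  lab <- rep(c("bottom", "middle", "top"), times = sizes)
  out <- character(n)
  out[ord] <- lab
  stats::setNames(out, names(expr))
}

#' Tercile-split survival comparison for one gene
#'
#' Trichotomizes patients by the gene's expression and compares the bottom
#' against the top tercile (the middle is discarded) with a log-rank test.
#' The reported median difference is `median(low-expression group) -
#' median(high-expression group)` in months; undefined medians are flagged
#' but the test is still reported.
#'
#' @param clinical Data.frame with columns `time_months`, `event` (0/1) and
#'   `expression` (one row per patient).
#' @param endpoint Label carried into the result (e.g. `"OS"`, `"PFS"`).
#' @return A `survival_comparison` list: `endpoint`, `median_low`,
#'   `median_high`, `median_diff`, `logrank_chi2`, `logrank_p`, `n_low`,
#'   `n_high`, `flags`.
#' @export
survival_tercile_test <- function(clinical, endpoint = "OS") {
  need <- c("time_months", "event", "expression")
  if (!all(need %in% names(clinical)))
    stop("survival_tercile_test: expected columns ", paste(need, collapse = ","))
  terc <- expression_terciles(stats::setNames(clinical$expression,
                                              seq_len(nrow(clinical))))
  low <- clinical[terc == "bottom", ]
  high <- clinical[terc == "top", ]
  if (nrow(low) < 2L || nrow(high) < 2L)
    stop("survival_tercile_test: need >= 2 patients per tercile")
  lr <- logrank_test(low$time_months, low$event, high$time_months, high$event)
  km_low <- km_estimate(low$time_months, low$event)
  km_high <- km_estimate(high$time_months, high$event)
  flags <- character(0)
  if (is.na(km_low$median) || is.na(km_high$median))
    flags <- c(flags, "undefined-median")
  if (lr$degenerate) flags <- c(flags, "no-events")
  structure(list(endpoint = endpoint,
                 median_low = km_low$median, median_high = km_high$median,
                 median_diff = km_low$median - km_high$median,
                 logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 n_low = nrow(low), n_high = nrow(high), flags = flags),
            class = "survival_comparison")
}

#' Candidate filter configuration
#'
#' The prioritization cascade applied to enrichment results: functional
#' category whitelist, required expression tercile, minimum member-guide
#' fold change, required outlet, and a survival significance level that both
#' overall and progression-free survival must meet.
#'
#' @param categories Whitelisted functional categories.
#' @param expression_tercile Required tercile (default `"top"`).
#' @param min_fold_change Minimum max-guide fold change (default 100).
#' @param outlet Required outlet (default `"outlet4"`).
#' @param survival_alpha Significance level for OS and PFS log-rank tests.
#' @return A `candidate_filter_config` list.
#' @export
candidate_filter_config <- function(categories = c("cytoskeleton",
                                                   "adhesion & migration",
                                                   "cell cycle", "signaling"),
                                    expression_tercile = "top",
                                    min_fold_change = 100,
                                    outlet = "outlet4",
                                    survival_alpha = 0.05) {
  stopifnot(min_fold_change > 0, survival_alpha > 0,
            expression_tercile %in% c("top", "middle", "bottom"))
  structure(list(categories = categories,
                 expression_tercile = expression_tercile,
                 min_fold_change = min_fold_change, outlet = outlet,
                 survival_alpha = survival_alpha),
            class = "candidate_filter_config")
}

#' Apply the hit-prioritization cascade
#'
#' Conjunction of five filters over the required outlet's enrichment table:
#' significantly enriched; annotated with a whitelisted functional category;
#' in the required expression tercile; max member-guide fold change above
#' the threshold; and log-rank p below alpha on both OS and PFS. A gene
#' missing from the category, tercile or survival tables fails that filter
#' explicitly (`"missing"` is recorded), never silently dropped.
#'
#' @param results Classified enrichment table ([classify_hits()]) for the
#'   required outlet, or a named per-outlet list containing it.
#' @param categories Data.frame `gene,category` (multi-row per gene).
#' @param terciles Named tercile labels from [expression_terciles()].
#' @param survival_tests Named list: `survival_tests[[gene]]` is a list with
#'   `OS` and `PFS` [survival_tercile_test()] results.
#' @param config [candidate_filter_config()].
#' @return A `candidate_table` data.frame with per-filter booleans, a
#'   `missing` column naming unavailable lookups, and `candidate` = all
#'   filters passed.
#' @export
filter_candidates <- function(results, categories, terciles, survival_tests,
                              config = candidate_filter_config()) {
  if (is.list(results) && !is.data.frame(results)) {
    if (!config$outlet %in% names(results))
      stop("filter_candidates: no results for outlet ", config$outlet)
    results <- results[[config$outlet]]
  }
  if (nrow(results) == 0L)
    return(structure(data.frame(), class = c("candidate_table", "data.frame")))
  genes <- results$gene
  cat_map <- split(categories$category, categories$gene)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    missing <- character(0)
    pass_enriched <- identical(results$status[i], "enriched")
    cats <- cat_map[[g]]
    if (is.null(cats)) { missing <- c(missing, "category"); pass_cat <- FALSE }
    else pass_cat <- any(cats %in% config$categories)
    terc <- terciles[g]
    if (is.null(terc) || is.na(terc)) { missing <- c(missing, "tercile"); pass_terc <- FALSE }
    else pass_terc <- unname(terc) == config$expression_tercile
    fc <- if ("max_guide_FC" %in% names(results)) results$max_guide_FC[i] else NA_real_
    pass_fc <- is.finite(fc) && fc > config$min_fold_change
    sv <- survival_tests[[g]]
    if (is.null(sv) || is.null(sv$OS) || is.null(sv$PFS)) {
      missing <- c(missing, "survival"); pass_surv <- FALSE
      os_p <- pfs_p <- os_diff <- pfs_diff <- NA_real_
    } else {
      os_p <- sv$OS$logrank_p; pfs_p <- sv$PFS$logrank_p
      os_diff <- sv$OS$median_diff; pfs_diff <- sv$PFS$median_diff
      pass_surv <- os_p < config$survival_alpha & pfs_p < config$survival_alpha
    }
    data.frame(gene = g, outlet = config$outlet, log2FC = results$log2FC[i],
               padj = results$padj[i], max_guide_FC = fc,
               categories = paste(cats, collapse = ";"),
               tercile = if (is.null(terc) || is.na(terc)) NA_character_ else unname(terc),
               os_p = os_p, os_median_diff = os_diff,
               pfs_p = pfs_p, pfs_median_diff = pfs_diff,
               pass_enriched = pass_enriched, pass_category = pass_cat,
               pass_tercile = pass_terc, pass_fold_change = pass_fc,
               pass_survival = pass_surv,
               missing = paste(missing, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$candidate <- out$pass_enriched & out$pass_category & out$pass_tercile &
    out$pass_fold_change & out$pass_survival
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}
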