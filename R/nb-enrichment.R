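#' Sum guide counts to gene level
#'
#' Gene counts are the exact integer sums of member-guide counts, per
#' sample; gene order is lexicographic. Guides missing from the library are
#' an error (listed).
#'
#' @param counts Guide x sample count matrix (rownames = guide ids).
#' @param library Guide library mapping `guide_id` to `gene`.
#' @return Gene x sample integer matrix.
#' @export
sum_gene_counts <- function(counts, library) {
  idx <- match(rownames(counts), library$guide_id)
  if (anyNA(idx))
    stop("sum_gene_counts: guides not in library: ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5L), collapse = ", "))
  gene <- library$gene[idx]
  out <- rowsum(counts, group = gene, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: the reference is the geometric mean
#' across samples for genes with all-positive counts; each sample's factor
#' is the median ratio to the reference, rescaled so the geometric mean of
#' the factors is 1.
#'
#' @param gene_counts Gene x sample count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(gene_counts) {
  logc <- log(gene_counts)
  ok <- rowSums(is.finite(logc)) == ncol(gene_counts)
  if (!any(ok))
    stop("size_factors: no gene has positive counts in every sample; ",
         "a pseudo-reference over nonzero genes would be needed")
  logref <- rowMeans(logc[ok, , drop = FALSE])
  logs <- apply(logc[ok, , drop = FALSE], 2L,
                function(col) stats::median(col - logref))
  s <- exp(logs - mean(logs))
  stats::setNames(s, colnames(gene_counts))
}

#' Gene-wise NB dispersions with a parametric trend
#'
#' Method-of-moments gene dispersions on normalized counts, pooled within
#' condition: `alpha_hat = (var - mean) / mean^2` with the variance pooled
#' across conditions having replicates. A parametric trend
#' `alpha_tr(mu) = a1/mu + a0` is fitted by least squares over the raw
#' (unfloored) estimates of all expressed genes, so the trend is not
#' selection-biased by the floor. The default dispersion used for testing
#' is the trend value, `max(alpha_min, alpha_tr(mu))` — at a handful of
#' replicates the per-gene estimates are far noisier than the parametric
#' fit, and using them directly distorts test calibration.
#' `method = "max"` instead returns the deliberately conservative
#' `max(alpha_hat, alpha_tr(mu))`. No empirical-Bayes shrinkage is applied.
#'
#' @param gene_counts Gene x sample count matrix.
#' @param s Size factors.
#' @param condition Character/factor of per-sample conditions.
#' @param alpha_min Dispersion floor (default 1e-8).
#' @param method `"trend"` (parametric fit, default) or `"max"`
#'   (gene-wise/trend maximum, conservative).
#' @return Named vector of final dispersions, with attributes `alpha_mom`
#'   (floored gene-wise estimates), `trend` (a0, a1) and `base_mean`.
#' @export
estimate_dispersions <- function(gene_counts, s, condition,
                                 alpha_min = 1e-8,
                                 method = c("trend", "max")) {
  method <- match.arg(method)
  condition <- as.factor(condition)
  y <- sweep(gene_counts, 2L, s, "/")
  reps <- table(condition)
  if (all(reps < 2L)) {
    warning("estimate_dispersions: no condition has replicates; ",
            "returning the floor dispersion for every gene")
    a <- rep(alpha_min, nrow(gene_counts))
    names(a) <- rownames(gene_counts)
    return(a)
  }
  use <- names(reps)[reps >= 2L]
  ss <- 0; dfree <- 0
  for (cn in use) {
    yc <- y[, condition == cn, drop = FALSE]
    mc <- rowMeans(yc)
    ss <- ss + rowSums((yc - mc)^2)
    dfree <- dfree + ncol(yc) - 1L
  }
  v <- ss / dfree
  mu <- rowMeans(y)
  raw <- (v - mu) / mu^2
  raw[!is.finite(raw)] <- 0
  fit_genes <- which(mu > 0)
  a0 <- 0; a1 <- 0
  if (length(fit_genes) >= 10L) {
    co <- stats::lm.fit(cbind(1, 1 / mu[fit_genes]),
                        raw[fit_genes])$coefficients
    a0 <- co[1L]; a1 <- co[2L]
    if (a0 < 0) { a0 <- 0; a1 <- max(0, sum(raw[fit_genes] / mu[fit_genes]) /
                                          sum(1 / mu[fit_genes]^2)) }
    if (a1 < 0) { a1 <- 0; a0 <- max(0, mean(raw[fit_genes])) }
  }
  trend <- pmax(alpha_min, a0 + a1 / pmax(mu, .Machine$double.eps))
  alpha_mom <- pmax(alpha_min, raw)
  alpha <- if (method == "trend") trend else pmax(alpha_mom, trend)
  names(alpha) <- rownames(gene_counts)
  attr(alpha, "alpha_mom") <- alpha_mom
  attr(alpha, "trend") <- c(a0 = unname(a0), a1 = unname(a1))
  attr(alpha, "base_mean") <- mu
  alpha
}

## One-gene NB GLM, log mu = log s + b0 + b1*[outlet], by IRLS with
## weights mu/(1 + alpha mu). Returns b, SE(b1), convergence flag.
nb_irls <- function(y, offset, x, alpha, tol = 1e-8, max_iter = 100L) {
  X <- cbind(1, x)
  m0 <- mean(pmax(y[x == 0] / exp(offset[x == 0]), 0)) + 0.1
  m1 <- mean(pmax(y[x == 1] / exp(offset[x == 1]), 0)) + 0.1
  beta <- c(log(m0), log(m1) - log(m0))
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- offset + X %*% beta
    mu <- pmin(exp(eta), 1e12)
    w <- as.vector(mu / (1 + alpha * mu))
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    upd <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(upd) || any(!is.finite(upd))) break
    delta <- max(abs(upd - beta))
    beta <- pmin(pmax(as.vector(upd), -50), 50)
    if (delta < tol) { conv <- TRUE; break }
  }
  mu <- pmin(exp(offset + X %*% beta), 1e12)
  w <- as.vector(mu / (1 + alpha * mu))
  info <- t(X * w) %*% X
  se1 <- tryCatch(sqrt(solve(info)[2L, 2L]), error = function(e) NA_real_)
  list(beta = beta, se1 = se1, converged = conv)
}

#' Gene-level NB Wald test, inlet vs one outlet
#'
#' Fits per gene the negative-binomial log-linear model
#' `log mu_gj = log s_j + b0 + b1 [outlet]` by iteratively reweighted least
#' squares with weights `mu/(1 + alpha mu)`, and tests `b1 = 0` with a Wald
#' z from the observed information. `log2FC = b1 / ln 2`; p-values are
#' two-sided normal and BH-adjusted across genes. Genes with all-zero
#' counts in both conditions are excluded and reported; non-converged fits
#' are flagged with `p = 1`.
#'
#' @param gene_counts Gene x sample count matrix (inlet + one outlet's
#'   samples only).
#' @param condition Per-sample condition labels.
#' @param outlet,inlet The two condition labels being contrasted.
#' @param s Size factors (default: computed from `gene_counts`).
#' @param alpha Dispersions (default: [estimate_dispersions()]).
#' @param alpha_min Dispersion floor.
#' @return An `nb_fit` data.frame: `gene`, `base_mean`, `log2FC`, `SE`,
#'   `wald_z`, `pvalue`, `padj`, `flag`; excluded genes in attribute
#'   `excluded`.
#' @export
nb_wald_test <- function(gene_counts, condition, outlet, inlet = "inlet",
                         s = NULL, alpha = NULL, alpha_min = 1e-8) {
  keep_s <- condition %in% c(inlet, outlet)
  if (!any(condition == inlet) || !any(condition == outlet))
    stop("nb_wald_test: both conditions must be present")
  cnt <- gene_counts[, keep_s, drop = FALSE]
  cond <- condition[keep_s]
  if (is.null(s)) s <- size_factors(cnt)
  if (is.null(alpha)) alpha <- estimate_dispersions(cnt, s, cond, alpha_min)
  x <- as.numeric(cond == outlet)
  offset <- log(s)
  nonzero <- rowSums(cnt) > 0
  excluded <- rownames(cnt)[!nonzero]
  genes <- rownames(cnt)[nonzero]
  n_g <- length(genes)
  log2fc <- se <- zstat <- pval <- numeric(n_g)
  flag <- character(n_g)
  ynorm <- sweep(cnt, 2L, s, "/")
  for (i in seq_len(n_g)) {
    g <- genes[i]
    fit <- nb_irls(as.numeric(cnt[g, ]), offset, x, alpha[[g]])
    b1 <- fit$beta[2L]
    log2fc[i] <- b1 / log(2)
    se[i] <- fit$se1 / log(2)
    if (!fit$converged || !is.finite(fit$se1) || fit$se1 <= 0) {
      flag[i] <- "non-converged"
      zstat[i] <- 0; pval[i] <- 1
    } else {
      zstat[i] <- b1 / fit$se1
      pval[i] <- 2 * stats::pnorm(-abs(zstat[i]))
    }
  }
  out <- data.frame(gene = genes,
                    base_mean = rowMeans(ynorm[nonzero, , drop = FALSE]),
                    log2FC = log2fc, SE = se, wald_z = zstat, pvalue = pval,
                    padj = bh_adjust(pval), flag = flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "outlet") <- outlet
  class(out) <- c("nb_fit", "data.frame")
  out
}

#' Per-guide normalized fold changes
#'
#' `FC = (mean normalized outlet count + pc) / (mean normalized inlet count
#' + pc)` per guide; the gene-level summary is the maximum over member
#' guides (a gene passes a fold-change filter if any of its guides does).
#'
#' @param counts Guide x sample count matrix.
#' @param library Guide library.
#' @param condition Per-sample condition labels.
#' @param outlet,inlet Condition labels contrasted.
#' @param s Size factors for these samples (default: gene-level
#'   median-of-ratios on the summed counts).
#' @param pseudocount Added to both means (default 0.5).
#' @return List with `guide` (data.frame `guide_id,gene,fc`) and `gene`
#'   (named vector of max member-guide FC).
#' @export
guide_fold_changes <- function(counts, library, condition, outlet,
                               inlet = "inlet", s = NULL, pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  keep <- condition %in% c(inlet, outlet)
  cnt <- counts[, keep, drop = FALSE]
  cond <- condition[keep]
  if (is.null(s)) s <- size_factors(sum_gene_counts(cnt, library))
  ynorm <- sweep(cnt, 2L, s, "/")
  m_in <- rowMeans(ynorm[, cond == inlet, drop = FALSE])
  m_out <- rowMeans(ynorm[, cond == outlet, drop = FALSE])
  fc <- (m_out + pseudocount) / (m_in + pseudocount)
  gene <- library$gene[match(rownames(cnt), library$guide_id)]
  gene_fc <- tapply(fc, gene, max)
  list(guide = data.frame(guide_id = rownames(cnt), gene = gene, fc = fc,
                          stringsAsFactors = FALSE, row.names = NULL),
       gene = gene_fc[sort(unique(gene))])
}

#' Classify enrichment hits
#'
#' A gene is `enriched` when `padj < threshold` and `log2FC > 0`,
#' `depleted` when `padj < threshold` and `log2FC < 0`, otherwise `ns`.
#'
#' @param fit An `nb_fit` from [nb_wald_test()].
#' @param threshold Adjusted p-value threshold (default 0.001).
#' @param guide_fc Optional gene-level max guide FC to attach.
#' @return The fit data.frame with `status` (and `max_guide_FC` when given),
#'   plus attribute `summary` (enriched/depleted/ns counts).
#' @export
classify_hits <- function(fit, threshold = 0.001, guide_fc = NULL) {
  status <- rep("ns", nrow(fit))
  status[fit$padj < threshold & fit$log2FC > 0] <- "enriched"
  status[fit$padj < threshold & fit$log2FC < 0] <- "depleted"
  fit$status <- status
  if (!is.null(guide_fc))
    fit$max_guide_FC <- unname(guide_fc[fit$gene])
  attr(fit, "summary") <- c(enriched = sum(status == "enriched"),
                            depleted = sum(status == "depleted"),
                            ns = sum(status == "ns"))
  fit
}

#' Full enrichment analysis, every outlet against the inlet
#'
#' Runs [sum_gene_counts()], then per outlet a separate two-condition
#' [nb_wald_test()] with its own size factors and dispersions, BH within
#' each outlet, plus guide fold changes and hit classification.
#'
#' @param counts Guide x sample count matrix.
#' @param library Guide library.
#' @param condition Per-sample condition labels.
#' @param outlets Outlet labels to test (default: all non-inlet conditions).
#' @param inlet Inlet label.
#' @param threshold Adjusted p-value threshold for hit status.
#' @return Named list of classified `nb_fit` tables, one per outlet, with a
#'   `summary` attribute (per-outlet enriched/depleted counts).
#' @export
enrichment_analysis <- function(counts, library, condition,
                                outlets = NULL, inlet = "inlet",
                                threshold = 0.001) {
  if (is.null(outlets)) outlets <- setdiff(unique(condition), inlet)
  gene_counts <- sum_gene_counts(counts, library)
  res <- lapply(outlets, function(ot) {
    keep <- condition %in% c(inlet, ot)
    fit <- nb_wald_test(gene_counts[, keep, drop = FALSE], condition[keep],
                        outlet = ot, inlet = inlet)
    gfc <- guide_fold_changes(counts[, keep, drop = FALSE], library,
                              condition[keep], outlet = ot, inlet = inlet)
    classify_hits(fit, threshold = threshold, guide_fc = gfc$gene)
  })
  names(res) <- outlets
  summ <- t(vapply(res, function(r) attr(r, "summary"), c(enriched = 0,
                                                          depleted = 0,
                                                          ns = 0)))
  attr(res, "summary") <- summ
  res
}
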