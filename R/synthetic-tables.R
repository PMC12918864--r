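#' Simulate a patient survival cohort stratified by gene expression
#'
#' Patients get a log-normal expression value; survival times are
#' exponential with the top expression tercile's hazard multiplied by
#' `hr_top` (worse prognosis when `hr_top > 1`), administratively censored
#' at `censor_months`.
#'
#' @param n_patients Cohort size.
#' @param base_median_months Median survival of non-top patients (months).
#' @param hr_top Hazard ratio of the top expression tercile vs the rest.
#' @param censor_months Administrative censoring horizon (months).
#' @param seed Integer seed.
#' @return Data.frame `patient_id,time_months,event,expression`.
#' @export
simulate_survival_cohort <- function(n_patients, base_median_months = 24,
                                     hr_top = 1, censor_months = 120,
                                     seed = 1L) {
  stopifnot(n_patients >= 6L, base_median_months > 0, hr_top >= 0)
  set.seed(seed)
  expr <- stats::rlnorm(n_patients, meanlog = 2, sdlog = 0.8)
  terc <- expression_terciles(stats::setNames(expr, seq_len(n_patients)))
  lambda0 <- log(2) / base_median_months
  lambda <- lambda0 * ifelse(terc == "top", hr_top, 1)
  t_event <- stats::rexp(n_patients, rate = lambda)
  time <- pmin(t_event, censor_months)
  data.frame(patient_id = sprintf("P%04d", seq_len(n_patients)),
             time_months = time,
             event = as.integer(t_event <= censor_months),
             expression = expr, stringsAsFactors = FALSE)
}

#' Simulate a gene expression table
#'
#' Log-normal expression values with selected genes forced into the top
#' tercile by a multiplicative boost.
#'
#' @param genes Gene ids.
#' @param high_genes Genes given high expression.
#' @param seed Integer seed.
#' @return Named numeric vector of expression values.
#' @export
simulate_expression <- function(genes, high_genes = character(0), seed = 1L) {
  set.seed(seed)
  e <- stats::rlnorm(length(genes), meanlog = 4, sdlog = 1)
  names(e) <- genes
  e[names(e) %in% high_genes] <- max(e) * (1 + stats::runif(sum(names(e) %in% high_genes)))
  e
}

#' Simulate a gene-to-functional-category table
#'
#' Assigns each gene one of the supplied categories uniformly at random,
#' with selected genes forced into a chosen category.
#'
#' @param genes Gene ids.
#' @param categories Category labels to draw from.
#' @param forced Named character vector `gene = category` overrides.
#' @param seed Integer seed.
#' @return Data.frame `gene,category`.
#' @export
simulate_categories <- function(genes,
                                categories = c("cytoskeleton",
                                               "adhesion & migration",
                                               "cell cycle", "signaling",
                                               "metabolism", "transport",
                                               "DNA/RNA metabolism"),
                                forced = character(0), seed = 1L) {
  set.seed(seed)
  cat <- sample(categories, length(genes), replace = TRUE)
  names(cat) <- genes
  cat[names(forced)] <- forced
  data.frame(gene = genes, category = unname(cat), stringsAsFactors = FALSE)
}
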