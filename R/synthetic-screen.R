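#' Generate a synthetic pooled sgRNA guide library
#'
#' Builds a Brunello-like guide library: `n_genes * guides_per_gene` records
#' with gene ids `GENE0001...`, guide ids `<gene>_g<i>`, and unique random
#' ACGT protospacers. Deterministic under `seed`.
#'
#' @param n_genes Number of genes (positive integer).
#' @param guides_per_gene Guides per gene (positive integer; the real
#'   library carries roughly 4).
#' @param protospacer_length Protospacer length in nt (default 20).
#' @param seed Integer seed.
#' @return A data.frame with columns `guide_id`, `gene`, `protospacer`.
#' @export
make_guide_library <- function(n_genes, guides_per_gene,
                               protospacer_length = 20L, seed = 1L) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, protospacer_length >= 1)
  n <- n_genes * guides_per_gene
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  draw <- function(m) {
    mat <- matrix(sample(bases, m * protospacer_length, replace = TRUE),
                  nrow = m)
    do.call(paste0, asplit(mat, 2L))
  }
  proto <- unique(draw(n))
  tries <- 0L
  while (length(proto) < n) {
    tries <- tries + 1L
    if (tries > 50L)
      stop(sprintf(paste0("make_guide_library: could not draw %d unique ",
                          "protospacers of length %d"), n, protospacer_length))
    proto <- unique(c(proto, draw(n - length(proto))))
  }
  proto <- proto[seq_len(n)]
  gene <- rep(sprintf("GENE%04d", seq_len(n_genes)), each = guides_per_gene)
  guide_id <- paste0(gene, "_g", rep(seq_len(guides_per_gene), times = n_genes))
  data.frame(guide_id = guide_id, gene = gene, protospacer = proto,
             stringsAsFactors = FALSE)
}

#' Describe a screen's sample layout
#'
#' @param outlets Character vector of outlet condition names
#'   (e.g. `c("outlet1", ..., "outlet5")`).
#' @param replicates Replicates per condition (applies to inlet and outlets).
#' @param inlet Name of the inlet condition (default `"inlet"`).
#' @return A `screen_design` data.frame with columns `sample`, `condition`,
#'   `replicate`.
#' @export
screen_design <- function(outlets, replicates = 1L, inlet = "inlet") {
  stopifnot(length(outlets) >= 1L, replicates >= 1L)
  conds <- c(inlet, outlets)
  d <- expand.grid(replicate = seq_len(replicates), condition = conds,
                   stringsAsFactors = FALSE)[, 2:1]
  d$sample <- paste0(d$condition, "_r", d$replicate)
  d <- d[, c("sample", "condition", "replicate")]
  attr(d, "inlet") <- inlet
  class(d) <- c("screen_design", "data.frame")
  d
}

#' Define the generative ground truth of a synthetic screen
#'
#' Inlet guide abundances are drawn log-normal (uneven library
#' representation, so the Gini index is exercised) and normalized to a
#' simplex. Sorting effects are per-outlet multiplicative weight multipliers
#' on a gene's guides; outlet abundance profiles are renormalized so they
#' remain a simplex.
#'
#' @param library Guide library from [make_guide_library()].
#' @param effects Named list: `effects[[outlet]][gene] = multiplier`
#'   (>= 0; 1 = neutral; genes absent from the map are neutral).
#' @param dispersion NB overdispersion alpha used when sampling counts
#'   (variance = mu + alpha mu^2).
#' @param abundance_sdlog Log-normal sd of inlet abundances (default 0.5).
#' @param seed Integer seed.
#' @return A `screen_truth` list with `abundance` (named, sums to 1),
#'   `effects`, `dispersion`, `seed`.
#' @export
screen_truth <- function(library, effects = list(), dispersion = 0.05,
                         abundance_sdlog = 0.5, seed = 1L) {
  stopifnot(is.data.frame(library), nrow(library) >= 1L, dispersion >= 0)
  for (m in effects)
    if (any(!is.finite(m)) || any(m < 0))
      stop("screen_truth: effect multipliers must be finite and >= 0")
  set.seed(seed)
  ab <- stats::rlnorm(nrow(library), meanlog = 0, sdlog = abundance_sdlog)
  ab <- ab / sum(ab)
  names(ab) <- library$guide_id
  structure(list(abundance = ab, effects = effects, dispersion = dispersion,
                 seed = seed),
            class = "screen_truth")
}

## Expected (pre-noise) abundance profile of one condition.
outlet_profile <- function(library, truth, condition, inlet = "inlet") {
  p <- truth$abundance
  if (condition == inlet) return(p)
  eff <- truth$effects[[condition]]
  if (is.null(eff)) return(p)
  mult <- rep(1, nrow(library))
  idx <- match(library$gene, names(eff))
  mult[!is.na(idx)] <- eff[idx[!is.na(idx)]]
  w <- p * mult
  w / sum(w)
}

#' Simulate sgRNA read counts for a mechanical sorting screen
#'
#' Inlet counts are NB with mean `depth * abundance` and the truth's
#' overdispersion; each outlet's expected abundance is the inlet abundance
#' times the gene's sorting-weight multiplier, renormalized, then NB-sampled
#' at the same depth. `dispersion = 0` gives the Poisson limit.
#'
#' @param library Guide library.
#' @param design [screen_design()] object.
#' @param truth [screen_truth()] object.
#' @param depth Expected reads per sample (positive).
#' @param seed Integer seed (defaults to the truth's seed).
#' @return A list with `counts` (guide x sample integer matrix, rownames =
#'   guide ids), `design`, `truth`.
#' @export
simulate_screen_counts <- function(library, design, truth, depth,
                                   seed = truth$seed) {
  stopifnot(inherits(design, "screen_design"), inherits(truth, "screen_truth"))
  if (nrow(library) == 0L) stop("simulate_screen_counts: empty library")
  if (depth <= 0) stop("simulate_screen_counts: depth must be positive")
  inlet <- attr(design, "inlet")
  set.seed(seed)
  n <- nrow(library)
  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(library$guide_id, design$sample))
  alpha <- truth$dispersion
  for (j in seq_len(nrow(design))) {
    mu <- depth * outlet_profile(library, truth, design$condition[j], inlet)
    counts[, j] <- if (alpha < 1e-12) stats::rpois(n, mu)
                   else stats::rnbinom(n, mu = mu, size = 1 / alpha)
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, design = design, truth = truth)
}

#' Write simulated screen counts as per-sample FASTQ files
#'
#' Every read is `anchor + protospacer + random ACGT filler` padded to
#' `read_length`, with a constant quality string ("I"); per-sample record
#' totals equal the count column sums, so quantification can be round-trip
#' checked exactly.
#'
#' @param library Guide library.
#' @param counts Guide x sample count matrix (rownames = guide ids).
#' @param dir Output directory (created if needed).
#' @param anchor Vector anchor preceding the protospacer (default the 19-nt
#'   amplicon anchor `TTGTGGAAAGGACGAAACA`).
#' @param read_length Total read length (>= anchor + protospacer length).
#' @param seed Integer seed (filler bases).
#' @param gzip Write `.fastq.gz` instead of `.fastq`.
#' @return Named character vector of file paths (one per sample).
#' @export
write_screen_fastq <- function(library, counts, dir,
                               anchor = "TTGTGGAAAGGACGAAACA",
                               read_length = 50L, seed = 1L, gzip = FALSE) {
  proto_len <- nchar(library$protospacer[1L])
  if (read_length < nchar(anchor) + proto_len)
    stop(sprintf("write_screen_fastq: read_length %d < anchor (%d) + protospacer (%d)",
                 read_length, nchar(anchor), proto_len))
  if (is.null(rownames(counts)) || !all(rownames(counts) %in% library$guide_id))
    stop("write_screen_fastq: count rownames must be library guide ids")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  n_fill <- read_length - nchar(anchor) - proto_len
  proto <- library$protospacer[match(rownames(counts), library$guide_id)]
  out <- character(ncol(counts))
  names(out) <- colnames(counts)
  for (j in seq_len(ncol(counts))) {
    cnt <- counts[, j]
    seqs <- rep(proto, cnt)
    filler <- if (n_fill > 0 && length(seqs)) {
      m <- matrix(sample(c("A", "C", "G", "T"), length(seqs) * n_fill,
                         replace = TRUE), nrow = length(seqs))
      do.call(paste0, asplit(m, 2L))
    } else rep("", length(seqs))
    reads <- Biostrings::DNAStringSet(paste0(anchor, seqs, filler))
    names(reads) <- sprintf("%s_read%07d", colnames(counts)[j], seq_along(reads))
    path <- file.path(dir, paste0(colnames(counts)[j],
                                  if (gzip) ".fastq.gz" else ".fastq"))
    qual <- Biostrings::BStringSet(rep(strrep("I", read_length), length(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                compress = gzip, qualities = qual)
    out[j] <- path
  }
  out
}

#' Write a guide library CSV
#'
#' Columns `guide_id,gene,protospacer`, uppercase ACGT.
#' @param library Guide library data.frame.
#' @param path Output CSV path.
#' @export
write_guide_library <- function(library, path) {
  utils::write.csv(library[, c("guide_id", "gene", "protospacer")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a guide library CSV
#' @param path CSV with header `guide_id,gene,protospacer`.
#' @return Guide library data.frame.
#' @export
read_guide_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("guide_id", "gene", "protospacer")
  if (!all(need %in% names(lib)))
    stop("read_guide_library: expected columns guide_id,gene,protospacer")
  if (anyDuplicated(lib$protospacer))
    stop("read_guide_library: duplicate protospacers in library")
  lib[, need]
}
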