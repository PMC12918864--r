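#' Amplicon anchor preceding the protospacer
#'
#' 19-nt vector sequence immediately upstream of the 20-nt variable guide
#' region in the sequenced amplicon.
#' @export
SGRNA_ANCHOR <- "TTGTGGAAAGGACGAAACA"

#' Extract the protospacer from a sequencing read
#'
#' Anchored policy: the `length` bases following the first exact occurrence
#' of the anchor; `NA` if the anchor is absent or the read is too short.
#' Positional policy: the first `length` bases of the read.
#'
#' @param reads Character vector of read sequences.
#' @param anchor Anchor sequence (anchored policy).
#' @param length Protospacer length (default 20).
#' @param policy `"anchored"` or `"positional"`.
#' @return Character vector; `NA` marks an unextractable read.
#' @export
extract_protospacer <- function(reads, anchor = SGRNA_ANCHOR, length = 20L,
                                policy = c("anchored", "positional")) {
  policy <- match.arg(policy)
  stopifnot(length >= 1L)
  if (policy == "positional") {
    out <- substr(reads, 1L, length)
    out[nchar(out) < length] <- NA_character_
    return(out)
  }
  pos <- regexpr(anchor, reads, fixed = TRUE)
  start <- pos + nchar(anchor)
  out <- substr(reads, start, start + length - 1L)
  out[pos < 0L | nchar(out) < length] <- NA_character_
  out
}

#' Read a sample manifest
#'
#' CSV with columns `sample,role,replicate,path` assigning each FASTQ its
#' condition role (inlet / outlet1..outlet5) and replicate index.
#'
#' @param path Manifest CSV path.
#' @param base_dir Directory against which relative FASTQ paths resolve
#'   (default: the manifest's directory).
#' @return Data.frame `sample,role,replicate,path`.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "role", "replicate", "path")
  if (!all(need %in% names(m)))
    stop("read_manifest: expected columns sample,role,replicate,path")
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(base_dir, m$path[rel])
  m[, need]
}

#' Count guide-matching reads per sample
#'
#' Extracts protospacers from each sample's FASTQ and tallies exact matches
#' against the library (hash match; no mismatch rescue). Unextracted reads
#' (no anchor / too short) and unmapped extractions are tallied separately,
#' so `mapped + unmapped + unextracted = total` per sample.
#'
#' @param fastq_paths Named character vector (names = sample ids) of FASTQ
#'   paths, plain or gzipped.
#' @param library Guide library (unique protospacers required).
#' @param anchor,policy Passed to [extract_protospacer()].
#' @return A list with `counts` (guide x sample integer matrix) and `stats`
#'   (per-sample data.frame: `total`, `extracted`, `mapped`, `unmapped`,
#'   `unextracted`, `mapping_rate`).
#' @export
count_guides <- function(fastq_paths, library, anchor = SGRNA_ANCHOR,
                         policy = "anchored") {
  if (anyDuplicated(library$protospacer))
    stop("count_guides: duplicate protospacers in library (ambiguous)")
  if (is.null(names(fastq_paths)))
    names(fastq_paths) <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                              basename(fastq_paths))
  proto_len <- nchar(library$protospacer[1L])
  counts <- matrix(0L, nrow = nrow(library), ncol = length(fastq_paths),
                   dimnames = list(library$guide_id, names(fastq_paths)))
  stats_rows <- vector("list", length(fastq_paths))
  for (j in seq_along(fastq_paths)) {
    reads <- as.character(Biostrings::readDNAStringSet(fastq_paths[j],
                                                       format = "fastq"))
    proto <- extract_protospacer(reads, anchor = anchor, length = proto_len,
                                 policy = policy)
    unextracted <- sum(is.na(proto))
    idx <- match(proto, library$protospacer)
    mapped_idx <- idx[!is.na(idx)]
    counts[, j] <- tabulate(mapped_idx, nbins = nrow(library))
    mapped <- length(mapped_idx)
    total <- length(reads)
    stats_rows[[j]] <- data.frame(
      sample = names(fastq_paths)[j], total = total,
      extracted = total - unextracted, mapped = mapped,
      unmapped = total - unextracted - mapped, unextracted = unextracted,
      mapping_rate = if (total > 0) mapped / total else 0,
      stringsAsFactors = FALSE)
  }
  list(counts = counts, stats = do.call(rbind, stats_rows))
}

#' Per-sample quality-control report
#'
#' Summarizes each sample column of a guide count matrix: totals, zero-count
#' guide fraction, mean reads per guide, and the Gini index of the raw
#' counts (zeros included). An all-zero sample gets `NA` Gini and an
#' `all-zero` flag rather than an error.
#'
#' @param counts Guide x sample count matrix.
#' @param mapping_stats Optional `stats` from [count_guides()]; merged in by
#'   sample when given.
#' @return Data.frame, one row per sample.
#' @export
sample_qc <- function(counts, mapping_stats = NULL) {
  if (nrow(counts) < 1L) stop("sample_qc: need >= 1 guide")
  rows <- lapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    allzero <- sum(x) == 0
    data.frame(sample = colnames(counts)[j],
               total_reads = sum(x),
               zero_guide_fraction = mean(x == 0),
               mean_reads_per_guide = mean(x),
               gini = if (allzero) NA_real_ else gini_index(x),
               flag = if (allzero) "all-zero" else "",
               stringsAsFactors = FALSE)
  })
  qc <- do.call(rbind, rows)
  if (!is.null(mapping_stats))
    qc <- merge(qc, mapping_stats, by = "sample", sort = FALSE)
  qc
}

#' Screen coverage arithmetic
#'
#' Expected cells carrying each guide after transduction:
#' `n_cells * infection_efficiency / n_guides`.
#'
#' @param n_cells Cells transduced.
#' @param infection_efficiency Fraction surviving selection with a single
#'   integration, in `[0, 1]`.
#' @param n_guides Library size.
#' @return Cells per guide.
#' @examples
#' coverage(60e6, 0.40, 76441)  # ~314, i.e. ~315 cells/guide
#' @export
coverage <- function(n_cells, infection_efficiency, n_guides) {
  stopifnot(n_guides >= 1, infection_efficiency >= 0,
            infection_efficiency <= 1)
  n_cells * infection_efficiency / n_guides
}

#' Write a guide count matrix TSV
#' @param counts Guide x sample matrix.
#' @param path Output path.
#' @export
write_count_matrix <- function(counts, path) {
  d <- data.frame(guide_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a guide count matrix TSV
#' @param path TSV with a `guide_id` column and one column per sample.
#' @return Integer matrix with guide rownames.
#' @export
read_count_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1L] != "guide_id") stop("read_count_matrix: first column must be guide_id")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d$guide_id
  storage.mode(m) <- "integer"
  m
}
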