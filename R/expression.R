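#' @importFrom stats cor hclust as.dist binom.test p.adjust t.test
NULL

#' Count uniquely assigned fragments per gene
#'
#' A fragment is assigned to a gene iff all of its aligned blocks lie within
#' the gene span on the matching strand; fragments compatible with more than
#' one gene (or none) are left unassigned.
#'
#' @param gal A `GAlignments` of uniquely mapped fragments.
#' @param model A `gene_model`.
#' @return A list of class `sample_counts`: `counts` (named integer vector
#'   over genes), `total` (mapped fragments in the library) and `unassigned`.
#' @export
count_fragments <- function(gal, model) {
  spans <- granges(gal)  # contiguous footprint; gene spans are contiguous
  ov <- findOverlaps(spans, model$genes, type = "within")
  nhit <- tabulate(queryHits(ov), nbins = length(spans))
  ok <- nhit == 1L
  hits <- subjectHits(ov)[queryHits(ov) %in% which(ok)]
  counts <- tabulate(hits, nbins = length(model$genes))
  names(counts) <- names(model$genes)
  structure(list(counts = counts, total = length(gal),
                 unassigned = sum(!ok)),
            class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat("sample_counts: ", sum(x$counts), " assigned / ", x$total,
      " fragments (", x$unassigned, " unassigned) over ",
      length(x$counts), " genes\n", sep = "")
  invisible(x)
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM(g) = count(g) * 1e9 / (libraryTotal * length(g))`, with gene length
#' the exon-union length in bp. Zero counts give zero FPKM; FPKM is invariant
#' to uniform scaling of all counts and the library total.
#'
#' @param counts A `sample_counts`, or a named count vector.
#' @param lengths Named gene lengths in bp (see [gene_lengths()]).
#' @param total Library total mapped fragments (taken from `counts` when it
#'   is a `sample_counts`).
#' @return Named numeric vector of FPKM values.
#' @export
fpkm <- function(counts, lengths, total = NULL) {
  if (inherits(counts, "sample_counts")) {
    if (is.null(total)) total <- counts$total
    counts <- counts$counts
  }
  if (is.null(total) || total <= 0)
    stop("fpkm: library total must be positive", call. = FALSE)
  lengths <- lengths[names(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("fpkm: missing or non-positive gene length", call. = FALSE)
  counts * 1e9 / (total * lengths)
}

#' Sample correlation matrix with hierarchical ordering
#'
#' Pearson correlation between sample columns of an expression (FPKM)
#' matrix, plus a sample ordering from average-linkage hierarchical
#' clustering on `1 - r`. Samples with zero variance yield `NA` entries and
#' are placed last.
#'
#' @param mat Numeric matrix, genes x samples.
#' @return A list: `cor` (samples x samples, unit diagonal), `order`
#'   (sample ordering), `hclust` (the dendrogram object, or `NULL` when
#'   fewer than 3 usable samples).
#' @export
correlation_matrix <- function(mat) {
  if (ncol(mat) < 2L || nrow(mat) < 2L)
    stop("correlation_matrix: need at least 2 samples and 2 genes",
         call. = FALSE)
  sds <- apply(mat, 2L, stats::sd)
  r <- suppressWarnings(cor(mat, method = "pearson"))
  diag(r) <- 1
  usable <- which(sds > 0)
  hc <- NULL
  ord <- seq_len(ncol(mat))
  if (length(usable) >= 3L) {
    hc <- hclust(as.dist(1 - r[usable, usable]), method = "average")
    ord <- c(usable[hc$order], setdiff(ord, usable))
  }
  list(cor = r, order = ord, hclust = hc)
}

#' Differential expression by exact count test
#'
#' Calls differentially expressed genes between two replicated conditions.
#' Fold change is computed from library-size-normalised mean counts with a
#' pseudocount; the p-value is an exact two-sided binomial test of the
#' condition-pooled counts against the library-size proportion (the exact
#' conditional test for a Poisson rate ratio), followed by
#' Benjamini-Hochberg adjustment across genes. A gene is flagged significant
#' when its absolute fold change is at least `fc_cutoff` and its adjusted p
#' at most `fdr_cutoff`.
#'
#' @param counts Integer matrix, genes x samples (or list of
#'   `sample_counts`).
#' @param condition Factor/character of length `ncol(counts)` with exactly
#'   two levels; the second level is the "B" (treatment) condition.
#' @param totals Library totals; defaults to column sums when `counts` is a
#'   matrix.
#' @param fc_cutoff,fdr_cutoff Reporting thresholds (defaults 2 and 0.05).
#' @param pseudocount Added to normalised mean counts for fold-change
#'   computation (default 1 fragment).
#' @return `data.frame` with one row per testable gene: `gene`, `log2fc`,
#'   `pvalue`, `padj`, `direction` ("up"/"down") and `significant`.
#'   All-zero genes are dropped.
#' @export
detect_degs <- function(counts, condition, totals = NULL, fc_cutoff = 2,
                        fdr_cutoff = 0.05, pseudocount = 1) {
  if (is.list(counts) && !is.matrix(counts)) {
    totals <- vapply(counts, function(x) x$total, 1)
    counts <- do.call(cbind, lapply(counts, function(x) x$counts))
  }
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("detect_degs: condition must have exactly two levels", call. = FALSE)
  if (min(table(condition)) < 2L)
    stop("detect_degs: need >= 2 replicates per condition", call. = FALSE)
  if (is.null(totals)) totals <- colSums(counts)
  a <- condition == levels(condition)[1L]
  b <- !a
  tot_a <- sum(totals[a]); tot_b <- sum(totals[b])
  scale_ref <- mean(totals)
  norm <- sweep(counts, 2L, totals / scale_ref, "/")
  mean_a <- rowMeans(norm[, a, drop = FALSE])
  mean_b <- rowMeans(norm[, b, drop = FALSE])
  pooled_a <- rowSums(counts[, a, drop = FALSE])
  pooled_b <- rowSums(counts[, b, drop = FALSE])
  keep <- pooled_a + pooled_b > 0L
  if (!all(keep))
    message("detect_degs: skipping ", sum(!keep), " all-zero gene(s)")
  gene <- rownames(counts)
  if (is.null(gene)) gene <- as.character(seq_len(nrow(counts)))
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  p0 <- tot_b / (tot_a + tot_b)
  pvalue <- rep(NA_real_, nrow(counts))
  idx <- which(keep)
  pvalue[idx] <- vapply(idx, function(i)
    binom.test(pooled_b[i], pooled_a[i] + pooled_b[i], p = p0)$p.value,
    1.0)
  out <- data.frame(gene = gene, log2fc = log2fc, pvalue = pvalue,
                    stringsAsFactors = FALSE)[keep, ]
  out$padj <- p.adjust(out$pvalue, method = "BH")
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  out$significant <- abs(out$log2fc) >= log2(fc_cutoff) &
    !is.na(out$padj) & out$padj <= fdr_cutoff
  rownames(out) <- NULL
  out
}
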