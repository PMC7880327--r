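# ABLIRC-style RIP/CLIP peak calling: cluster overlapping reads, score each
# cluster by its maximum per-base depth, compare against a per-gene
# permutation null of random read placement, and subtract input peaks.

#' Cluster overlapping reads into candidate peaks
#'
#' Reads with at least 1 bp overlap (transitive closure, same strand) form
#' one cluster; each cluster becomes a candidate peak spanning the union of
#' its reads' footprints, with height the maximum per-base depth inside the
#' cluster and `n_reads` the number of clustered reads.
#'
#' @param reads A `GRanges` of read footprints (or a `GAlignments`, whose
#'   ranges are used).
#' @param height One of `"depth"` (default: maximum per-base depth) or
#'   `"count"` (number of reads) as the peak height.
#' @return `GRanges` of candidate peaks with `height` and `n_reads`.
#' @export
cluster_reads <- function(reads, height = c("depth", "count")) {
  height <- match.arg(height)
  if (inherits(reads, "GAlignments")) reads <- granges(reads)
  if (length(reads) == 0L) {
    out <- GRanges(); out$height <- integer(0); out$n_reads <- integer(0)
    return(out)
  }
  # min.gapwidth = 0 merges only true >= 1 bp overlaps, not bookended ranges
  peaks <- reduce(reads, min.gapwidth = 0L)
  peaks$n_reads <- countOverlaps(peaks, reads, minoverlap = 1L)
  if (height == "count") {
    peaks$height <- peaks$n_reads
  } else {
    peaks$height <- NA_integer_
    for (chrom in unique(as.character(seqnames(peaks)))) {
      for (st in unique(as.character(strand(peaks)))) {
        psel <- as.character(seqnames(peaks)) == chrom &
          as.character(strand(peaks)) == st
        if (!any(psel)) next
        rsel <- as.character(seqnames(reads)) == chrom &
          as.character(strand(reads)) == st
        cov <- IRanges::coverage(ranges(reads[rsel]))
        v <- IRanges::Views(cov, ranges(peaks[psel]))
        peaks$height[psel] <- as.integer(viewMaxs(v))
      }
    }
  }
  peaks[order(as.character(seqnames(peaks)), start(peaks))]
}

#' Permutation null of the maximum peak height in a gene
#'
#' Each of `n_sim` simulations places `n_reads` reads of the observed
#' lengths uniformly at random within the gene span and records the maximum
#' per-base depth reached. Reads longer than the span are clamped to it.
#' Follows the current RNG state, so wrap in `set.seed()` for
#' reproducibility.
#'
#' @param n_reads Number of reads to place.
#' @param read_lengths Read length(s); a scalar or one per read.
#' @param span_len Gene span length in bp.
#' @param n_sim Number of simulations (default 500).
#' @return Integer vector of length `n_sim` of simulated maximum heights.
#' @export
permutation_null <- function(n_reads, read_lengths, span_len, n_sim = 500L) {
  if (n_reads <= 0L) return(integer(n_sim))
  read_lengths <- rep_len(as.integer(read_lengths), n_reads)
  if (any(read_lengths > span_len)) {
    warning("permutation_null: read length exceeds gene span; clamped",
            call. = FALSE)
    read_lengths <- pmin(read_lengths, span_len)
  }
  if (length(unique(read_lengths)) == 1L)
    return(.perm_null_max(n_reads, read_lengths[1L], as.integer(span_len),
                          as.integer(n_sim)))
  # mixed lengths: per-simulation coverage maximum
  vapply(seq_len(n_sim), function(s) {
    starts <- 1L + floor(runif(n_reads) * (span_len - read_lengths + 1L))
    max(IRanges::coverage(IRanges(starts, width = read_lengths)))
  }, 1L)
}

#' Call peaks against a per-gene permutation null
#'
#' Assigns reads to genes (footprint within the gene span, matching strand),
#' clusters them into candidate peaks, simulates the per-gene null of random
#' placement (same read number and lengths, uniform within the gene span)
#' `n_sim` times, and scores each candidate with the add-one-smoothed
#' empirical p-value `p = (1 + #[null max >= height]) / (1 + n_sim)`.
#' Candidates with `p < p_cutoff` are flagged significant. IP and input
#' libraries are intended to be called separately with this function.
#'
#' @param reads `GRanges`/`GAlignments` of one library's read footprints.
#' @param model A `gene_model`.
#' @param n_sim Permutations per gene (default 500).
#' @param seed Integer seed controlling the permutation RNG.
#' @param p_cutoff Empirical p-value cutoff (default 0.05).
#' @param height Peak height definition, see [cluster_reads()].
#' @return `GRanges` of candidate peaks with `gene_id`, `height`, `n_reads`,
#'   `pvalue` and `significant`; genes without reads contribute nothing.
#' @export
call_peaks <- function(reads, model, n_sim = 500L, seed = 1L,
                       p_cutoff = 0.05, height = c("depth", "count")) {
  height <- match.arg(height)
  if (inherits(reads, "GAlignments")) reads <- granges(reads)
  ov <- findOverlaps(reads, model$genes, type = "within")
  # drop reads assignable to more than one gene (genes normally disjoint)
  nhit <- tabulate(queryHits(ov), nbins = length(reads))
  ov <- ov[nhit[queryHits(ov)] == 1L]
  assigned <- reads[queryHits(ov)]
  gene_of_read <- subjectHits(ov)

  empty <- function() {
    pk <- GRanges()
    pk$height <- integer(0); pk$n_reads <- integer(0)
    pk$gene_id <- character(0); pk$pvalue <- numeric(0)
    pk$significant <- logical(0)
    pk
  }
  if (length(assigned) == 0L) return(empty())

  # genes are disjoint, so one global clustering pass is per-gene clustering
  peaks <- cluster_reads(assigned, height = height)
  pov <- findOverlaps(peaks, model$genes, type = "within")
  stopifnot(length(pov) == length(peaks))
  peak_gene <- subjectHits(pov)[order(queryHits(pov))]
  peaks$gene_id <- names(model$genes)[peak_gene]

  n_by_gene <- tabulate(gene_of_read, nbins = length(model$genes))
  rl <- unique(width(assigned))
  rl_by_gene <- if (length(rl) == 1L) NULL else
    split(width(assigned), gene_of_read)

  set.seed(seed)
  pvalue <- numeric(length(peaks))
  for (gi in sort(unique(peak_gene))) {
    lens <- if (is.null(rl_by_gene)) rl else rl_by_gene[[as.character(gi)]]
    null <- permutation_null(n_by_gene[gi], lens,
                             width(model$genes)[gi], n_sim)
    sel <- which(peak_gene == gi)
    pvalue[sel] <- vapply(peaks$height[sel], function(h)
      (1 + sum(null >= h)) / (1 + n_sim), 1.0)
  }
  peaks$pvalue <- pvalue
  peaks$significant <- pvalue < p_cutoff
  peaks[order(as.character(seqnames(peaks)), start(peaks))]
}

#' Remove IP peaks that overlap input peaks
#'
#' An IP peak is removed iff it overlaps (>= 1 bp, same strand) any
#' significant input peak; this controls for expression-driven pile-ups
#' present in the total-lysate library.
#'
#' @param ip_peaks Peaks called on an IP library ([call_peaks()] output);
#'   only its significant peaks are retained and filtered.
#' @param input_peaks Peaks called on the matched input library; only its
#'   significant peaks subtract.
#' @return The retained significant IP peaks (`GRanges`).
#' @export
subtract_input <- function(ip_peaks, input_peaks) {
  keep_sig <- function(p)
    if (is.null(p$significant)) p else p[p$significant %in% TRUE]
  ip <- keep_sig(ip_peaks)
  inp <- keep_sig(input_peaks)
  if (length(ip) == 0L || length(inp) == 0L) return(ip)
  ip[!overlapsAny_strand(ip, inp)]
}

overlapsAny_strand <- function(a, b)
  IRanges::overlapsAny(a, b, minoverlap = 1L)  # strand-aware by default

#' Summarise peak overlap between two replicates
#'
#' @param peaks1,peaks2 Called peak sets (`GRanges`).
#' @return List: peak counts `n1`/`n2`, per-set overlapping counts
#'   `n1_overlap`/`n2_overlap`, the exclusive counts, and `fraction` =
#'   `(n1_overlap + n2_overlap) / (n1 + n2)`.
#' @export
replicate_overlap <- function(peaks1, peaks2) {
  o1 <- overlapsAny_strand(peaks1, peaks2)
  o2 <- overlapsAny_strand(peaks2, peaks1)
  n1 <- length(peaks1); n2 <- length(peaks2)
  list(n1 = n1, n2 = n2, n1_overlap = sum(o1), n2_overlap = sum(o2),
       rep1_only = sum(!o1), rep2_only = sum(!o2),
       fraction = if (n1 + n2 > 0) (sum(o1) + sum(o2)) / (n1 + n2) else
         NA_real_)
}

#' Write peaks to BED (plus a TSV with p-values)
#'
#' BED columns: chrom, start, end, name (gene id), score (height), strand.
#'
#' @param peaks Peaks from [call_peaks()] / [subtract_input()].
#' @param path Output BED path; a sibling `.tsv` with full columns is
#'   written alongside.
#' @return Invisibly, `path`.
#' @export
write_peak_bed <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = peaks$gene_id, score = peaks$height,
                   strand = as.character(strand(peaks)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv <- sub("\\.bed$", ".tsv", path)
  full <- cbind(df, pvalue = peaks$pvalue)
  utils::write.table(full, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
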