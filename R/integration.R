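# Integration of binding and splicing results: feature distributions,
# target-gene assignment, bound-vs-regulated overlap, k-mer enrichment.

#' Genomic feature distribution of reads or peaks
#'
#' Assigns each item (read footprint or peak) one feature class by
#' majority overlap with the labeled feature intervals; ties are broken by
#' the label precedence CDS > 5'UTR > 3'UTR > NC exon > intron. Items
#' overlapping no labeled stranded interval are intergenic.
#'
#' @param items `GRanges` (or `GAlignments`) of reads or peaks.
#' @param index A `feature_index` from [derive_features()].
#' @return `data.frame` with one row per feature class: `feature`, `count`,
#'   `fraction` (fractions sum to 1).
#' @export
feature_distribution <- function(items, index) {
  if (inherits(items, "GAlignments")) items <- granges(items)
  feats <- index$features
  stranded <- feats[as.character(strand(feats)) != "*"]
  ov <- findOverlaps(items, stranded)
  assigned <- rep(NA_integer_, length(items))
  if (length(ov)) {
    w <- width(IRanges::pintersect(items[queryHits(ov)],
                                   stranded[subjectHits(ov)]))
    lab <- as.integer(stranded$feature[subjectHits(ov)])
    nlab <- length(FEATURE_LEVELS)
    grp <- (queryHits(ov) - 1L) * nlab + lab
    wsum <- rowsum(w, grp)
    grp_u <- as.integer(rownames(wsum))
    item_u <- (grp_u - 1L) %/% nlab + 1L
    lab_u <- (grp_u - 1L) %% nlab + 1L
    # majority overlap; ties resolved by precedence (lower factor level)
    ord <- order(item_u, -wsum[, 1L], lab_u)
    best <- ord[!duplicated(item_u[ord])]
    assigned[item_u[best]] <- lab_u[best]
  }
  nlev <- length(FEATURE_LEVELS)
  assigned[is.na(assigned)] <- nlev  # intergenic
  counts <- tabulate(assigned, nbins = nlev)
  data.frame(feature = factor(FEATURE_LEVELS, levels = FEATURE_LEVELS),
             count = counts,
             fraction = if (length(items)) counts / length(items) else
               rep(0, nlev))
}

#' Target genes of retained peaks
#'
#' @param peaks Called (input-subtracted) peaks with a `gene_id` column.
#' @return Character vector of unique gene ids carrying at least one peak.
#' @export
target_genes <- function(peaks) {
  if (length(peaks) == 0L) return(character(0))
  sort(unique(peaks$gene_id))
}

#' Overlap of binding targets with regulated-splicing genes
#'
#' @param targets Character vector of bound gene ids.
#' @param rase_genes Character vector of regulated-splicing gene ids.
#' @return List of class `gene_set_overlap`: both sets, the intersection,
#'   and their sizes (ready for a Venn rendering).
#' @export
overlap_with_rase <- function(targets, rase_genes) {
  targets <- unique(targets); rase_genes <- unique(rase_genes)
  inter <- intersect(targets, rase_genes)
  structure(list(bound = targets, rase = rase_genes, intersection = inter,
                 n_bound = length(targets), n_rase = length(rase_genes),
                 n_overlap = length(inter)),
            class = "gene_set_overlap")
}

#' @export
print.gene_set_overlap <- function(x, ...) {
  cat("gene_set_overlap: ", x$n_bound, " bound genes, ", x$n_rase,
      " regulated-splicing genes, ", x$n_overlap, " in common\n", sep = "")
  invisible(x)
}

# strand-aware sequence extraction from an in-memory genome
extract_genome_seq <- function(genome, gr) {
  out <- vector("list", length(gr))
  for (chrom in unique(as.character(seqnames(gr)))) {
    idx <- which(as.character(seqnames(gr)) == chrom)
    seqs <- Biostrings::extractAt(genome[[chrom]], ranges(gr[idx]))
    out[idx] <- as.list(seqs)
  }
  seqs <- DNAStringSet(out)
  minus <- as.character(strand(gr)) == "-"
  if (any(minus)) seqs[minus] <- reverseComplement(seqs[minus])
  seqs
}

#' k-mer enrichment in peak sequences against resampled background
#'
#' Counts k-mer frequencies (occurrences per sequence window) in the peak
#' sequences and in `n_bg` background sets of length-matched windows sampled
#' uniformly from the background regions (typically expressed gene spans
#' outside peaks). The enrichment z-score of each k-mer is
#' `(f_obs - mean(f_bg)) / sd(f_bg)`, with the background mean and standard
#' deviation taken over the resampled sets. Minus-strand intervals are
#' reverse-complemented before counting, so k-mers are read in the
#' transcribed orientation.
#'
#' @param peaks `GRanges` of peak intervals.
#' @param genome `DNAStringSet` genome.
#' @param background `GRanges` of allowed background regions.
#' @param k k-mer length (default 5).
#' @param n_bg Number of background resamples (default 50).
#' @param seed Integer seed for background sampling.
#' @return `data.frame` ranked by decreasing `z`: `kmer`, `f_obs`, `f_bg`,
#'   `sd_bg`, `z`.
#' @export
kmer_enrichment <- function(peaks, genome, background, k = 5L, n_bg = 50L,
                            seed = 1L) {
  if (length(peaks) == 0L)
    stop("kmer_enrichment: no peak intervals", call. = FALSE)
  if (any(width(peaks) < k))
    stop("kmer_enrichment: k exceeds the shortest peak sequence",
         call. = FALSE)
  peak_seqs <- extract_genome_seq(genome, peaks)
  kfreq <- function(seqs) {
    counts <- colSums(oligonucleotideFrequency(seqs, width = k, step = 1L))
    counts / sum(pmax(Biostrings::width(seqs) - k + 1L, 0L))
  }
  f_obs <- kfreq(peak_seqs)
  n_windows <- sum(pmax(Biostrings::width(peak_seqs) - k + 1L, 0L))

  set.seed(seed)
  if (length(background) == 0L)
    stop("kmer_enrichment: empty background", call. = FALSE)
  # each background window is length-matched to one peak, sampled from the
  # background regions wide enough to host it (the widest region if none is)
  bw <- sort(width(background))
  w_want <- pmin(width(peaks), bw[length(bw)])
  n_elig <- length(bw) - findInterval(w_want - 1L, bw)
  f_bg <- matrix(NA_real_, n_bg, 4L^k)
  ord <- order(width(background))
  for (b in seq_len(n_bg)) {
    pick <- length(background) - floor(runif(length(peaks)) * n_elig)
    src <- ord[pick]
    room <- width(background)[src] - w_want + 1L
    off <- floor(runif(length(peaks)) * room)
    win <- GRanges(seqnames(background)[src],
                   IRanges(start(background)[src] + off, width = w_want),
                   strand = strand(background)[src])
    f_bg[b, ] <- kfreq(extract_genome_seq(genome, win))
  }
  mu <- colMeans(f_bg)
  sdv <- apply(f_bg, 2L, stats::sd)
  # floor the background SD at the counting (binomial) error of the
  # observed window total, so rare k-mers cannot get degenerate z-scores
  floor_sd <- sqrt(pmax(mu * (1 - mu), 1 / n_windows) / n_windows)
  z <- (f_obs - mu) / pmax(sdv, floor_sd)
  out <- data.frame(kmer = names(f_obs), f_obs = unname(f_obs),
                    f_bg = unname(mu), sd_bg = unname(sdv), z = unname(z),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z, out$kmer), ]
  rownames(out) <- NULL
  out
}

#' Background regions for motif enrichment
#'
#' Expressed gene spans with called peak intervals excised, the default
#' background for [kmer_enrichment()].
#'
#' @param model A `gene_model`.
#' @param peaks Peak intervals to exclude.
#' @param expressed Optional character vector restricting to expressed
#'   genes (default: all genes).
#' @return `GRanges` of background regions.
#' @export
peak_background <- function(model, peaks, expressed = NULL) {
  g <- model$genes
  if (!is.null(expressed)) g <- g[names(g) %in% expressed]
  GenomicRanges::setdiff(granges(g), granges(peaks))
}
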