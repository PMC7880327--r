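# End-to-end orchestration over a simulated experiment directory, and
# evaluation of every stage against the generator's truth tables.

#' Pool junction counts across samples
#'
#' @param junction_list List of junction `GRanges` (with `count`).
#' @return A single `GRanges` with summed counts (and `known` kept when
#'   present on all inputs).
#' @export
pool_junctions <- function(junction_list) {
  stripped <- lapply(junction_list, function(j) {
    cnt <- j$count
    mcols(j) <- NULL
    j$count <- cnt
    j
  })
  all <- do.call(c, unname(stripped))
  if (length(all) == 0L) return(all)
  key <- junction_key(all)
  tot <- tapply(all$count, key, sum)
  out <- all[!duplicated(key)]
  out$count <- as.integer(tot[junction_key(out)])
  out[order(as.character(seqnames(out)), start(out), end(out))]
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Re-reads the generator's files from disk (GTF annotation and SAM
#' libraries), then runs expression quantification and differential
#' expression, splicing event detection/quantification and regulated-event
#' calling, permutation peak calling on each IP/input library with input
#' subtraction and replicate intersection, and the integrative summaries
#' (feature distributions, target genes, bound-vs-regulated overlap, k-mer
#' enrichment).
#'
#' @param sim A `sim_experiment` returned by [simulate_experiment()].
#' @param n_sim Permutations per gene for peak calling (default 500).
#' @param seed Seed for the permutation and background-sampling RNG
#'   (defaults to the simulation seed).
#' @param min_support Minimum read support for a defined AS ratio.
#' @param k k-mer length for motif enrichment.
#' @return A list with components `model`, `counts`, `fpkm`, `correlation`,
#'   `degs`, `junctions`, `events`, `quant`, `rases`, `peaks` (per-library
#'   calls, per-replicate retained sets, `final` intersected peaks,
#'   `replicate_overlap`), `targets`, `overlap`, `feature_dist`, `kmers`.
#' @export
run_pipeline <- function(sim, n_sim = 500L, seed = NULL,
                         min_support = 10L, k = 5L) {
  if (is.null(seed)) seed <- sim$config$seed
  model <- parse_gtf(sim$files[["gtf"]])
  ann <- annotated_junctions(model)
  glen <- gene_lengths(model)
  index <- derive_features(model, genome_length = sim$config$genome_length)

  ## ---- RNA-seq side -----------------------------------------------------
  libs <- names(sim$rnaseq$files)
  condition <- sim$rnaseq$condition
  evid <- list(); counts <- list(); ungapped_pool <- list()
  for (lb in libs) {
    gal <- read_alignments(sim$rnaseq$files[[lb]])
    counts[[lb]] <- count_fragments(gal, model)
    evid[[lb]] <- sample_evidence(gal, ann)
    ungapped_pool[[lb]] <- evid[[lb]]$ungapped
  }
  count_mat <- do.call(cbind, lapply(counts, function(x) x$counts))
  totals <- vapply(counts, function(x) x$total, 1)
  fpkm_mat <- vapply(libs, function(lb)
    fpkm(counts[[lb]], glen), numeric(length(glen)))
  degs <- detect_degs(count_mat, condition, totals = totals)
  corr <- correlation_matrix(fpkm_mat)

  pooled_j <- pool_junctions(lapply(evid, function(e) e$junctions))
  pooled_ug <- do.call(c, unname(ungapped_pool))
  events <- detect_events(pooled_j, model, alignments = pooled_ug)
  quant <- quantify_events(events, evid, min_support = min_support)
  rases <- detect_rases(quant, condition)

  ## ---- RIP side ---------------------------------------------------------
  rip_reads <- lapply(sim$rip$files, function(f) granges(read_alignments(f)))
  ip_libs <- names(sim$rip$files)[sim$rip$is_ip]
  input_libs <- names(sim$rip$files)[!sim$rip$is_ip]
  calls <- list()
  for (i in seq_along(sim$rip$files))
    calls[[names(sim$rip$files)[i]]] <-
      call_peaks(rip_reads[[i]], model, n_sim = n_sim, seed = seed + i)
  retained <- list()
  for (r in seq_along(ip_libs))
    retained[[ip_libs[r]]] <- subtract_input(calls[[ip_libs[r]]],
                                             calls[[input_libs[r]]])
  sig <- function(p) p[p$significant]
  rep_ov <- replicate_overlap(sig(calls[[ip_libs[1L]]]),
                              sig(calls[[ip_libs[2L]]]))
  final <- retained[[1L]][overlapsAny_strand(retained[[1L]],
                                             retained[[2L]])]
  targets <- intersect(target_genes(retained[[1L]]),
                       target_genes(retained[[2L]]))

  ## ---- integration ------------------------------------------------------
  rase_genes <- unique(rases$gene_id[rases$significant])
  overlap <- overlap_with_rase(targets, rase_genes)
  feature_dist <- list(
    ip_reads = feature_distribution(rip_reads[[ip_libs[1L]]], index),
    input_reads = feature_distribution(rip_reads[[input_libs[1L]]], index),
    peaks = if (length(final)) feature_distribution(final, index) else NULL)
  kmers <- NULL
  if (length(final)) {
    bg <- peak_background(model, final)
    kmers <- kmer_enrichment(final, sim$genome, bg, k = k,
                             seed = seed + 100L)
  }

  list(model = model, counts = count_mat, totals = totals,
       fpkm = fpkm_mat, correlation = corr, degs = degs,
       junctions = pooled_j, events = events, quant = quant, rases = rases,
       peaks = list(calls = calls, retained = retained, final = final,
                    replicate_overlap = rep_ov),
       targets = targets, overlap = overlap,
       feature_dist = feature_dist, kmers = kmers)
}

#' Evaluate pipeline results against the planted truth
#'
#' Compares every stage's calls with the generator's truth tables and
#' reports recall/specificity summaries: planted DEG recall (significant
#' call with the planted direction), planted event detection (gene + type
#' match), planted regulated-event recall, planted peak recall (overlap of
#' the retained peaks in both IP replicates), shared-artifact removal, the
#' replicate peak-overlap fraction, and the rank of the planted motif in
#' the k-mer table.
#'
#' @param sim The `sim_experiment` (with truth tables).
#' @param res A result list from [run_pipeline()].
#' @return Named list of scalar summaries.
#' @export
evaluate_truth <- function(sim, res) {
  genes <- sim$genes
  ## DEG recall: significant + correct direction
  planted <- genes[genes$is_deg, ]
  deg_tab <- res$degs[match(planted$gene_id, res$degs$gene), ]
  deg_ok <- deg_tab$significant &
    sign(deg_tab$log2fc) == sign(log2(planted$true_fc))
  deg_recall <- mean(deg_ok %in% TRUE)

  ## planted event detection (gene + type) and RASE recall
  pa <- sim$planted_as
  det_key <- paste(res$events$gene_id, res$events$type)
  detect_rate <- mean(paste(pa$gene_id, pa$type) %in% det_key)
  sig <- res$rases[res$rases$significant, ]
  sig_key <- paste(sig$gene_id, sig$type)
  rase_recall <- mean(paste(pa$gene_id, pa$type) %in% sig_key)

  ## peaks: recall of planted IP-only peaks among the significant calls of
  ## every IP replicate; retention after input subtraction reported too
  tp <- sim$truth_peaks
  tp_gr <- GRanges(tp$chrom, IRanges(tp$start, tp$end), strand = tp$strand)
  ip_calls <- res$peaks$calls[grep("^ip", names(res$peaks$calls))]
  called <- Reduce(`&`, lapply(ip_calls, function(p)
    overlapsAny_strand(tp_gr, p[p$significant])))
  peak_recall <- mean(called[!tp$shared])
  r1 <- res$peaks$retained[[1L]]; r2 <- res$peaks$retained[[2L]]
  hit_ret <- overlapsAny_strand(tp_gr, r1) & overlapsAny_strand(tp_gr, r2)
  peak_recall_retained <- mean(hit_ret[!tp$shared])
  artifact_removed <- if (any(tp$shared))
    mean(!(overlapsAny_strand(tp_gr, r1) |
             overlapsAny_strand(tp_gr, r2))[tp$shared]) else NA_real_

  motif_rank <- if (!is.null(res$kmers))
    match(sim$config$motif, res$kmers$kmer) else NA_integer_

  list(deg_recall = deg_recall,
       event_detection = detect_rate,
       rase_recall = rase_recall,
       peak_recall = peak_recall,
       peak_recall_retained = peak_recall_retained,
       artifact_removed = artifact_removed,
       replicate_overlap = res$peaks$replicate_overlap$fraction,
       motif_rank = motif_rank,
       n_planted_deg = nrow(planted),
       n_planted_as = nrow(pa),
       n_planted_peaks = sum(!tp$shared),
       n_artifact_peaks = sum(tp$shared))
}
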