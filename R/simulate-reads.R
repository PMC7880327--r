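# Read simulators: stranded RNA-seq libraries with junction-spanning
# fragments, and IP/input RIP libraries with planted enriched peaks.
# Fragments are emitted pre-aligned as single-end SAM records (one record
# per fragment, MAPQ 50, NH:i:1), which is the pipeline's input boundary.

sam_header <- function(chrom, seqlen)
  c("@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", chrom, "\tLN:", format(seqlen, scientific = FALSE)),
    "@PG\tID:spliceRIP\tPN:spliceRIP")

write_sam <- function(path, chrom, seqlen, qname, flag, pos, cigar) {
  lines <- sam_header(chrom, seqlen)
  if (length(qname))
    lines <- c(lines, paste(qname, flag, chrom,
                            format(pos, scientific = FALSE, trim = TRUE),
                            50L, cigar, "*", 0L, 0L, "*", "*", "NH:i:1",
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Map read start positions in mature-transcript coordinates (left-anchored
# concatenation of exons) to genomic POS + CIGAR with N gaps.
tx_reads_to_sam <- function(ex_start, ex_end, tx_starts, read_len) {
  w <- ex_end - ex_start + 1L
  cum <- cumsum(w)
  cstart <- cum - w  # 0-based transcript offset of each exon
  s <- tx_starts
  e <- s + read_len - 1L
  i1 <- findInterval(s - 1L, cum) + 1L
  i2 <- findInterval(e - 1L, cum) + 1L
  pos <- ex_start[i1] + (s - cstart[i1] - 1L)
  cigar <- character(length(s))
  same <- i1 == i2
  cigar[same] <- paste0(read_len, "M")
  adj <- i2 == i1 + 1L
  if (any(adj)) {
    b1 <- cum[i1[adj]] - s[adj] + 1L
    gap <- ex_start[i1[adj] + 1L] - ex_end[i1[adj]] - 1L
    cigar[adj] <- paste0(b1, "M", gap, "N", read_len - b1, "M")
  }
  multi <- which(i2 > i1 + 1L)
  for (m in multi) {
    segs <- character(0)
    p <- s[m]
    for (i in i1[m]:i2[m]) {
      blk <- min(e[m], cum[i]) - p + 1L
      segs <- c(segs, paste0(blk, "M"))
      if (i < i2[m])
        segs <- c(segs, paste0(ex_start[i + 1L] - ex_end[i] - 1L, "N"))
      p <- cum[i] + 1L
    }
    cigar[m] <- paste(segs, collapse = "")
  }
  list(pos = pos, cigar = cigar)
}

#' Simulate stranded RNA-seq libraries with planted signals
#'
#' Draws per-gene fragment counts as Poisson with rate proportional to the
#' gene's baseline expression (times its planted fold change in condition B),
#' assigns each fragment to the gene's alternative isoform by a Bernoulli
#' draw on the condition's inclusion ratio, places the fragment uniformly
#' along the mature transcript, and writes one SAM record per fragment
#' (junction-spanning fragments get N-gapped CIGARs). Libraries are named
#' `A_rep1..n` and `B_rep1..n`. Deterministic given the configuration seed.
#'
#' @param sim A `sim_experiment` from [generate_genome()].
#' @param dir Output directory for the SAM files.
#' @return `sim` with `$rnaseq` added: named vector of SAM paths and the
#'   library condition labels.
#' @export
simulate_rnaseq <- function(sim, dir) {
  config <- sim$config
  set.seed(config$seed + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sim$genes
  n <- nrow(genes)
  R <- config$read_length
  chrom <- "chr1"
  seqlen <- config$genome_length

  # per-transcript exon tables, in gene order
  tx_tab <- lapply(seq_len(n), function(i) {
    txids <- sim$model$transcripts$tx_id[
      sim$model$transcripts$gene_id == genes$gene_id[i]]
    lapply(txids, function(t) {
      ex <- sim$model$exons[[t]]
      list(start = start(ex), end = end(ex), len = sum(width(ex)))
    })
  })

  libs <- c(paste0("A_rep", seq_len(config$n_replicates)),
            paste0("B_rep", seq_len(config$n_replicates)))
  cond <- rep(c("A", "B"), each = config$n_replicates)
  files <- setNames(file.path(dir, paste0("rnaseq_", libs, ".sam")), libs)

  for (li in seq_along(libs)) {
    wts <- if (cond[li] == "B") genes$base_expr * genes$true_fc
           else genes$base_expr
    lam <- config$rnaseq_depth * wts / sum(wts)
    counts <- rpois(n, lam)
    acc <- vector("list", n)
    for (i in seq_len(n)) {
      if (counts[i] == 0L) next
      txs <- tx_tab[[i]]
      if (!is.na(genes$as_type[i])) {
        ratio <- if (cond[li] == "B") config$base_ratio + config$ratio_shift
                 else config$base_ratio
        alt <- genes$alt_tx[i]
        k_alt <- rbinom(1L, counts[i], ratio)
        picks <- c(rep(setdiff(1:2, alt), counts[i] - k_alt),
                   rep(alt, k_alt))
      } else picks <- rep(1L, counts[i])
      part <- list()
      for (k in unique(picks)) {
        m <- sum(picks == k)
        tx <- txs[[k]]
        if (tx$len < R) next
        s <- sample.int(tx$len - R + 1L, m, replace = TRUE)
        mapped <- tx_reads_to_sam(tx$start, tx$end, s, R)
        part[[length(part) + 1L]] <- data.frame(
          qn = sprintf("%s:%s:%d:%d", libs[li], genes$gene_id[i], k,
                       seq_len(m)),
          fl = rep(if (config$stranded && genes$strand[i] == "-") 16L
                   else 0L, m),
          po = mapped$pos, ci = mapped$cigar, stringsAsFactors = FALSE)
      }
      if (length(part)) acc[[i]] <- do.call(rbind, part)
    }
    recs <- do.call(rbind, acc[!vapply(acc, is.null, TRUE)])
    if (is.null(recs)) recs <- data.frame(qn = character(0), fl = integer(0),
                                          po = integer(0),
                                          ci = character(0))
    write_sam(files[li], chrom, seqlen, recs$qn, recs$fl, recs$po, recs$ci)
  }
  sim$rnaseq <- list(files = files, condition = setNames(cond, libs))
  sim
}

#' Simulate IP and input RIP libraries with planted peaks
#'
#' Input-library reads are placed uniformly within expressed gene spans.
#' IP-library reads are additionally concentrated, at the configured fold
#' enrichment, inside planted peak intervals; a configured fraction of those
#' peaks has the GC-rich motif written into the genome at the peak centre
#' before read generation. Shared "artifact" peaks (expression pile-ups) are
#' enriched in both IP and input libraries and live in genes disjoint from
#' the IP-only peak genes. All reads are ungapped, strand-matched, and
#' emitted as SAM. Deterministic given the configuration seed.
#'
#' @param sim A `sim_experiment` from [generate_genome()].
#' @param dir Output directory for the SAM files.
#' @return `sim` with `$rip` (SAM paths for `ip_rep*`/`input_rep*`),
#'   `$truth_peaks` (planted peak table) and its `genome` updated with the
#'   injected motifs.
#' @export
simulate_rip <- function(sim, dir) {
  config <- sim$config
  set.seed(config$seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- sim$genes
  n <- nrow(genes)
  R <- config$read_length
  wp <- config$peak_width
  span <- genes$end - genes$start + 1L

  eligible <- which(span >= wp + 2L * R)
  n_peak <- round(config$planted_peak_fraction * n)
  n_art <- round(config$artifact_peak_fraction * n)
  if (n_peak + n_art > length(eligible))
    stop("simulate_rip: not enough genes wide enough to host planted peaks",
         call. = FALSE)
  pick <- sample(eligible, n_peak + n_art)
  peak_genes <- sort(pick[seq_len(n_peak)])
  art_genes <- sort(pick[n_peak + seq_len(n_art)])

  place_peak <- function(idx) {
    lo <- genes$start[idx]
    hi <- genes$end[idx] - wp + 1L
    s <- lo + floor(runif(length(idx)) * (hi - lo + 1L))
    data.frame(gene_id = genes$gene_id[idx], chrom = genes$chrom[idx],
               start = s, end = s + wp - 1L, strand = genes$strand[idx],
               stringsAsFactors = FALSE)
  }
  real <- place_peak(peak_genes)
  art <- place_peak(art_genes)
  n_motif <- round(config$motif_fraction * nrow(real))
  real$motif <- seq_len(nrow(real)) <= n_motif
  real$shared <- rep(FALSE, nrow(real))
  art$motif <- rep(FALSE, nrow(art))
  art$shared <- rep(TRUE, nrow(art))
  truth_peaks <- rbind(real, art)
  truth_peaks$enrichment <- rep(config$enrichment, nrow(truth_peaks))
  if (any(truth_peaks$end > genes$end[match(truth_peaks$gene_id,
                                            genes$gene_id)]))
    stop("simulate_rip: peak interval exceeds gene span", call. = FALSE)

  # write the motif into the genome at the centre of motif-bearing peaks,
  # in the transcribed orientation (reverse complement on minus-strand
  # genes): the RBP recognises the RNA sequence
  k <- nchar(config$motif)
  mot <- truth_peaks[truth_peaks$motif, , drop = FALSE]
  if (nrow(mot)) {
    centre <- floor((mot$start + mot$end) / 2) - floor(k / 2)
    ins <- DNAStringSet(rep(config$motif, nrow(mot)))
    minus <- mot$strand == "-"
    if (any(minus)) ins[minus] <- reverseComplement(ins[minus])
    sim$genome <- DNAStringSet(replaceAt(
      sim$genome[[1L]], IRanges(centre, centre + k - 1L), ins))
    names(sim$genome) <- "chr1"
  }

  libs <- c(paste0("ip_rep", seq_len(config$rip_replicates)),
            paste0("input_rep", seq_len(config$rip_replicates)))
  is_ip <- grepl("^ip", libs)
  files <- setNames(file.path(dir, paste0("rip_", libs, ".sam")), libs)

  enr_tab <- function(ip) {
    tab <- rep(NA_integer_, n)
    sel <- if (ip) c(peak_genes, art_genes) else art_genes
    ids <- genes$gene_id[sel]
    tab[sel] <- match(ids, truth_peaks$gene_id)
    tab
  }

  for (li in seq_along(libs)) {
    etab <- enr_tab(is_ip[li])
    lam <- config$rip_depth * genes$base_expr / sum(genes$base_expr)
    counts <- rpois(n, lam)
    acc <- vector("list", n)
    for (i in seq_len(n)) {
      if (counts[i] == 0L) next
      S <- span[i] - R + 1L
      n_pk <- 0L
      starts <- integer(0)
      if (!is.na(etab[i])) {
        pk <- truth_peaks[etab[i], ]
        P <- wp - R + 1L
        q <- config$enrichment * P / (S - P + config$enrichment * P)
        n_pk <- rbinom(1L, counts[i], q)
        if (n_pk > 0L)
          starts <- pk$start + floor(runif(n_pk) * P)
      }
      n_bg <- counts[i] - n_pk
      if (n_bg > 0L)
        starts <- c(starts, genes$start[i] + floor(runif(n_bg) * S))
      acc[[i]] <- data.frame(
        qn = sprintf("%s:%s:%d", libs[li], genes$gene_id[i],
                     seq_along(starts)),
        fl = rep(if (config$stranded && genes$strand[i] == "-") 16L
                 else 0L, length(starts)),
        po = as.integer(starts), ci = rep(paste0(R, "M"), length(starts)),
        stringsAsFactors = FALSE)
    }
    recs <- do.call(rbind, acc[!vapply(acc, is.null, TRUE)])
    if (is.null(recs)) recs <- data.frame(qn = character(0), fl = integer(0),
                                          po = integer(0),
                                          ci = character(0))
    write_sam(files[li], "chr1", config$genome_length, recs$qn, recs$fl,
              recs$po, recs$ci)
  }
  sim$rip <- list(files = files, is_ip = setNames(is_ip, libs))
  sim$truth_peaks <- truth_peaks
  sim
}

#' Run the full synthetic-data generator
#'
#' Convenience orchestrator: [generate_genome()], [simulate_rip()] (which
#' injects motifs into the genome), [simulate_rnaseq()], then writes the
#' genome FASTA, the annotation GTF, all SAM libraries and the truth tables
#' (TSV) under `dir`. Rerunning with the same configuration produces
#' byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return The complete `sim_experiment` object (invisibly contains all
#'   paths under `$files`).
#' @export
simulate_experiment <- function(config, dir) {
  sim <- generate_genome(config)
  sim <- simulate_rip(sim, dir)
  sim <- simulate_rnaseq(sim, dir)
  gfiles <- write_genome_files(sim, dir)
  truths <- c(genes = file.path(dir, "truth_genes.tsv"),
              as = file.path(dir, "truth_as.tsv"),
              peaks = file.path(dir, "truth_peaks.tsv"))
  utils::write.table(sim$genes, truths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$planted_as, truths["as"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth_peaks, truths["peaks"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sim_config(config, file.path(dir, "config.yaml"))
  sim$files <- c(gfiles, sim$rnaseq$files, sim$rip$files, truths,
                 config = file.path(dir, "config.yaml"))
  sim
}
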