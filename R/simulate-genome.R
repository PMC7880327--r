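#' @importFrom Biostrings DNAStringSet DNAString writeXStringSet
#'   reverseComplement oligonucleotideFrequency replaceAt
#' @importFrom stats rpois rbinom rlnorm runif setNames
NULL

AS_TYPES <- c("ES", "A5SS", "A3SS", "IR", "MXE", "5pMXE", "3pMXE", "CE",
              "A3SS&ES", "A5SS&ES")

# local-coordinate exon chain: widths of exons and introns -> (start, end)
chain_coords <- function(exon_w, intron_w) {
  starts <- cumsum(c(1L, head(exon_w, -1L) + intron_w))
  data.frame(start = starts, end = starts + exon_w - 1L)
}

rint <- function(n, lo, hi) sample(seq.int(lo, hi), n, replace = TRUE)

# Two-isoform gene templates in local (genomic-left-anchored) coordinates.
# Each returns list(tx = list of exon data.frames, alt_tx = index of the
# isoform the event grammar labels "alternative").
# The template realising a given event type depends on gene strand because
# 5'/3' naming follows the transcription direction.
build_template <- function(template) {
  ew <- rint(4L, 150L, 300L)
  iw <- rint(3L, 200L, 500L)
  delta <- rint(1L, 30L, 60L)
  switch(template,
    es = {
      ex <- chain_coords(ew[1:3], iw[1:2])
      list(tx = list(ex, ex[c(1L, 3L), ]), alt_tx = 2L)
    },
    ce = {
      ex <- chain_coords(ew, iw)
      list(tx = list(ex, ex[c(1L, 4L), ]), alt_tx = 2L)
    },
    left_shift = {  # alternative donor end of the left exon (+: A5SS)
      ex <- chain_coords(ew[1:2], iw[1])
      ex2 <- ex; ex2$end[1L] <- ex2$end[1L] + delta
      list(tx = list(ex, ex2), alt_tx = 1L)  # alt = longer intron
    },
    right_shift = { # alternative acceptor start of the right exon (+: A3SS)
      ex <- chain_coords(ew[1:2], iw[1])
      ex2 <- ex; ex2$start[2L] <- ex2$start[2L] - delta
      list(tx = list(ex, ex2), alt_tx = 1L)
    },
    skip_left_shift = {  # skip + shifted left-flank end (+: A5SS&ES)
      ex <- chain_coords(ew[1:3], iw[1:2])
      ex2 <- ex[c(1L, 3L), ]; ex2$end[1L] <- ex2$end[1L] + delta
      list(tx = list(ex, ex2), alt_tx = 2L)
    },
    skip_right_shift = { # skip + shifted right-flank start (+: A3SS&ES)
      ex <- chain_coords(ew[1:3], iw[1:2])
      ex2 <- ex[c(1L, 3L), ]; ex2$start[2L] <- ex2$start[2L] - delta
      list(tx = list(ex, ex2), alt_tx = 2L)
    },
    mxe = {
      ex <- chain_coords(ew, iw)
      list(tx = list(ex[c(1L, 2L, 4L), ], ex[c(1L, 3L, 4L), ]), alt_tx = 2L)
    },
    alt_first = {  # two alternative leftmost exons (+: 5pMXE)
      ex <- chain_coords(ew[1:3], iw[1:2])
      list(tx = list(ex[c(1L, 3L), ], ex[c(2L, 3L), ]), alt_tx = 2L)
    },
    alt_last = {   # two alternative rightmost exons (+: 3pMXE)
      ex <- chain_coords(ew[1:3], iw[1:2])
      list(tx = list(ex[c(1L, 2L), ], ex[c(1L, 3L), ]), alt_tx = 2L)
    },
    ir = {
      ex <- chain_coords(ew[1:2], iw[1])
      list(tx = list(ex, data.frame(start = ex$start[1L], end = ex$end[2L])),
           alt_tx = 2L)
    },
    stop("unknown template: ", template, call. = FALSE)
  )
}

# template realising an event type on a gene of the given strand
template_for_type <- function(type, strand) {
  plus <- strand == "+"
  switch(type,
    "ES" = "es", "CE" = "ce", "MXE" = "mxe", "IR" = "ir",
    "A5SS" = if (plus) "left_shift" else "right_shift",
    "A3SS" = if (plus) "right_shift" else "left_shift",
    "A5SS&ES" = if (plus) "skip_left_shift" else "skip_right_shift",
    "A3SS&ES" = if (plus) "skip_right_shift" else "skip_left_shift",
    "5pMXE" = if (plus) "alt_first" else "alt_last",
    "3pMXE" = if (plus) "alt_last" else "alt_first",
    stop("unknown AS type: ", type, call. = FALSE))
}

#' Generate a toy genome and annotation with planted splicing events
#'
#' Places non-overlapping multi-exon genes on both strands of a single
#' random-sequence chromosome. Genes selected for a planted
#' alternative-splicing event carry two transcript isoforms realising one of
#' the ten event types (exon skipping, cassette exon, alternative 5'/3'
#' splice sites, their composites with skipping, mutually exclusive internal
#' / first / last exons, intron retention); other genes carry one isoform and
#' are coding (5'UTR/CDS/3'UTR) or noncoding. Also draws the per-gene
#' baseline expression rates and the planted fold-change assignment shared by
#' the downstream read simulators. Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A `sim_experiment` list: `genome` (a `DNAStringSet`), `model`
#'   (a `gene_model`), `genes` (per-gene truth data.frame), `planted_as`
#'   (planted event table) and `config`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  n_as <- round(config$planted_as_fraction * n)
  as_idx <- sort(sample.int(n, n_as))
  as_type <- rep(NA_character_, n)
  as_type[as_idx] <- rep(AS_TYPES, length.out = n_as)

  coding <- runif(n) >= config$noncoding_fraction
  coding[as_idx] <- FALSE  # planted-event genes are written without CDS

  # build structures, then place sequentially with random intergenic gaps
  structures <- vector("list", n)
  for (i in seq_len(n)) {
    structures[[i]] <- if (is.na(as_type[i])) {
      n_ex <- rint(1L, 3L, 6L)
      ex <- chain_coords(rint(n_ex, 150L, 300L), rint(max(n_ex - 1L, 1L),
                                                      200L, 500L))
      list(tx = list(ex), alt_tx = NA_integer_)
    } else {
      build_template(template_for_type(as_type[i], strand[i]))
    }
  }
  gaps <- rint(n, 300L, 800L)
  span_w <- vapply(structures, function(s)
    max(vapply(s$tx, function(e) max(e$end), 1L)), 1L)
  offsets <- gaps[1L] + c(0L, cumsum(head(span_w, -1L) + gaps[-1L]))
  gene_start <- offsets
  gene_end <- offsets + span_w - 1L
  if (max(gene_end) + 200 > config$genome_length)
    stop("generate_genome: genome_length too small to place ", n,
         " genes without overlap (need >= ", max(gene_end) + 200, " bp)",
         call. = FALSE)

  # assemble the gene model
  exons <- list(); cds <- list()
  tx_id <- character(0); tx_gene <- character(0)
  for (i in seq_len(n)) {
    st <- structures[[i]]
    for (k in seq_along(st$tx)) {
      txid <- paste0(gene_id[i], ".t", k)
      ex <- st$tx[[k]]
      gr <- GRanges("chr1", IRanges(ex$start + gene_start[i] - 1L,
                                    ex$end + gene_start[i] - 1L),
                    strand = strand[i])
      exons[[txid]] <- gr
      tx_id <- c(tx_id, txid); tx_gene <- c(tx_gene, gene_id[i])
      if (coding[i] && k == 1L) {
        # CDS span from mid-first-exon to mid-last-exon of the exon chain
        cs <- start(gr)[1L] + floor(width(gr)[1L] / 2)
        ce <- end(gr)[length(gr)] - floor(width(gr)[length(gr)] / 2)
        ls <- pmax(start(gr), cs); le <- pmin(end(gr), ce)
        keep <- ls <= le
        cds[[txid]] <- GRanges("chr1", IRanges(ls[keep], le[keep]),
                               strand = strand[i])
      }
    }
  }
  genes <- GRanges("chr1", IRanges(gene_start, gene_end), strand = strand)
  names(genes) <- gene_id
  mcols(genes)$gene_id <- gene_id
  mcols(genes)$coding <- coding
  model <- new_gene_model(genes,
                          data.frame(tx_id = tx_id, gene_id = tx_gene,
                                     stringsAsFactors = FALSE),
                          exons, cds)

  # expression and planted fold changes
  base_expr <- rlnorm(n, meanlog = 0, sdlog = config$expr_sdlog)
  n_deg <- round(config$planted_deg_fraction * n)
  deg_idx <- sort(sample.int(n, n_deg))
  true_fc <- rep(1, n)
  if (n_deg > 0) {
    up <- deg_idx[seq_len(ceiling(n_deg / 2))]
    down <- setdiff(deg_idx, up)
    true_fc[up] <- config$fold_change
    true_fc[down] <- 1 / config$fold_change
  }

  genes_df <- data.frame(
    gene_id = gene_id, chrom = "chr1", start = gene_start, end = gene_end,
    strand = strand, coding = coding, base_expr = base_expr,
    is_deg = seq_len(n) %in% deg_idx, true_fc = true_fc,
    as_type = as_type,
    alt_tx = vapply(structures, function(s) s$alt_tx, 1L),
    stringsAsFactors = FALSE)

  planted_as <- data.frame(
    gene_id = gene_id[as_idx], type = as_type[as_idx],
    strand = strand[as_idx],
    ratio_A = rep(config$base_ratio, length(as_idx)),
    ratio_B = rep(config$base_ratio + config$ratio_shift, length(as_idx)),
    stringsAsFactors = FALSE)

  base_p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
              G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  genome <- DNAStringSet(paste(
    sample(names(base_p), config$genome_length, replace = TRUE,
           prob = base_p),
    collapse = ""))
  names(genome) <- "chr1"

  structure(list(config = config, genome = genome, model = model,
                 genes = genes_df, planted_as = planted_as),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment: ", nrow(x$genes), " genes on ",
      format(x$config$genome_length, big.mark = ","), " bp; ",
      sum(x$genes$is_deg), " planted DEGs, ", nrow(x$planted_as),
      " planted AS events", sep = "")
  if (!is.null(x$truth_peaks))
    cat(", ", sum(!x$truth_peaks$shared), " planted peaks (+",
        sum(x$truth_peaks$shared), " shared artifacts)", sep = "")
  cat("\n")
  invisible(x)
}

#' Write the simulated genome and annotation to disk
#'
#' @param sim A `sim_experiment` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths (`genome`, `gtf`).
#' @export
write_genome_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  writeXStringSet(sim$genome, fa)
  write_gtf(sim$model, gtf)
  c(genome = fa, gtf = gtf)
}
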