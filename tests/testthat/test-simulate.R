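# Synthetic-data generator: determinism, annotation grammar, and truth-table
# fidelity checked by independent recounts of the emitted SAM text.

test_that("the same seed reproduces byte-identical outputs", {
  cfg <- small_config(seed = 21)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_experiment(cfg, d1)
  simulate_experiment(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  # a different seed changes the read libraries
  simulate_experiment(small_config(seed = 22), d2)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "rnaseq_A_rep1.sam"))),
    unname(tools::md5sum(file.path(d2, "rnaseq_A_rep1.sam")))))
})

test_that("generated genes are non-overlapping and sized to the genome", {
  sim <- generate_genome(simulation_config(seed = 2, n_genes = 200,
                                           genome_length = 2e6))
  g <- sim$genes
  expect_equal(nrow(g), 200L)
  o <- order(g$start)
  expect_true(all(g$start[o][-1] > g$end[o][-200]))  # pairwise disjoint
  expect_error(generate_genome(simulation_config(seed = 2, n_genes = 200,
                                                 genome_length = 2e5)),
               "too small")
})

test_that("an exon-skipping gene carries two isoforms differing by one exon", {
  sim <- generate_genome(small_config(seed = 4, planted_as_fraction = 0.5))
  es_genes <- sim$planted_as$gene_id[sim$planted_as$type == "ES"]
  expect_gt(length(es_genes), 0L)
  gid <- es_genes[1L]
  txs <- sim$model$transcripts$tx_id[sim$model$transcripts$gene_id == gid]
  expect_length(txs, 2L)
  e1 <- sim$model$exons[[txs[1]]]; e2 <- sim$model$exons[[txs[2]]]
  expect_equal(length(e1), length(e2) + 1L)
  missing <- GenomicRanges::setdiff(e1, e2)
  expect_length(missing, 1L)                       # exactly one exon
  expect_true(start(missing) > min(start(e2)) &&
                end(missing) < max(end(e2)))       # internal
})

test_that("emitted GTF and FASTA parse and agree with the model", {
  cfg <- small_config(seed = 6)
  dir <- file.path(tempdir(), "parsecheck")
  sim <- simulate_experiment(cfg, dir)
  model <- parse_gtf(file.path(dir, "annotation.gtf"))
  expect_equal(sort(names(model$genes)), sort(sim$genes$gene_id))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(unname(Biostrings::width(fa)), cfg$genome_length)
  # motif sits at the centre of a motif-bearing plus-strand peak
  tp <- sim$truth_peaks
  plus <- tp[tp$motif & tp$strand == "+", ]
  if (nrow(plus)) {
    centre <- floor((plus$start[1] + plus$end[1]) / 2) -
      floor(nchar(cfg$motif) / 2)
    seqstr <- as.character(Biostrings::subseq(
      fa[[1]], centre, centre + nchar(cfg$motif) - 1L))
    expect_equal(seqstr, cfg$motif)
  }
})

test_that("zero depth yields a valid header-only SAM", {
  cfg <- small_config(seed = 8, rnaseq_depth = 0, rip_depth = 0)
  dir <- file.path(tempdir(), "zerodepth")
  sim <- simulate_experiment(cfg, dir)
  lines <- readLines(sim$rnaseq$files[[1]])
  expect_true(all(startsWith(lines, "@")))
  expect_length(read_alignments(sim$rnaseq$files[[1]]), 0L)
})

test_that("planted fold changes survive an independent SAM recount", {
  cfg <- simulation_config(seed = 31, n_genes = 100, genome_length = 1.2e6,
                           rnaseq_depth = 5e4, rip_depth = 1e4,
                           planted_deg_fraction = 0.02,
                           planted_as_fraction = 0)
  dir <- file.path(tempdir(), "fccheck")
  sim <- simulate_rnaseq(generate_genome(cfg), dir)
  g <- sim$genes
  count_lib <- function(path) {
    sam <- read_sam_text(path)
    idx <- findInterval(sam$pos, sort(g$start))
    ord <- order(g$start)
    tabulate(match(g$gene_id[ord][idx], g$gene_id), nbins = nrow(g))
  }
  counts <- vapply(sim$rnaseq$files, count_lib, numeric(nrow(g)))
  up <- which(g$true_fc > 1)
  for (i in up) {
    ratio <- mean(counts[i, 4:6]) / mean(counts[i, 1:3])
    expect_gt(ratio, 4 * 0.75); expect_lt(ratio, 4 * 1.3)
  }
  # unplanted genes stay near ratio 1
  flat <- which(!g$is_deg)[1:20]
  ratios <- rowMeans(counts[flat, 4:6]) / rowMeans(counts[flat, 1:3])
  expect_lt(max(abs(log2(ratios))), 0.6)
})

test_that("planted inclusion ratios survive an independent junction walk", {
  cfg <- simulation_config(seed = 32, n_genes = 40, genome_length = 5e5,
                           rnaseq_depth = 1e5, rip_depth = 1e4,
                           planted_as_fraction = 0.25, base_ratio = 0.5,
                           ratio_shift = 0)
  dir <- file.path(tempdir(), "ratiocheck")
  sim <- simulate_rnaseq(generate_genome(cfg), dir)
  es <- sim$planted_as[sim$planted_as$type == "ES", ][1, ]
  gtx <- sim$model$transcripts
  txs <- gtx$tx_id[gtx$gene_id == es$gene_id]
  ex1 <- sim$model$exons[[txs[1]]]   # inclusion isoform (3 exons)
  skip_intron <- c(end(ex1)[1] + 1L, start(ex1)[3] - 1L)
  # independent CIGAR walk over one library
  sam <- read_sam_text(sim$rnaseq$files[["A_rep1"]])
  juncs <- lapply(seq_len(nrow(sam)), function(i) {
    b <- cigar_blocks(sam$pos[i], sam$cigar[i])
    if (nrow(b) < 2) return(NULL)
    cbind(b[-nrow(b), 2] + 1L, b[-1, 1] - 1L)
  })
  jm <- do.call(rbind, juncs)
  n_skip <- sum(jm[, 1] == skip_intron[1] & jm[, 2] == skip_intron[2])
  n_in1 <- sum(jm[, 1] == end(ex1)[1] + 1L & jm[, 2] == start(ex1)[2] - 1L)
  n_in2 <- sum(jm[, 1] == end(ex1)[2] + 1L & jm[, 2] == start(ex1)[3] - 1L)
  n_model <- (n_in1 + n_in2) / 2
  ratio <- n_skip / (n_skip + n_model)
  n <- n_skip + n_model
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(ratio - 0.5), 4 * se)
})

test_that("planted peaks are enriched ~10x over matched control windows", {
  cfg <- simulation_config(seed = 33, n_genes = 60, genome_length = 7e5,
                           rnaseq_depth = 1e4, rip_depth = 6e4,
                           enrichment = 10)
  dir <- file.path(tempdir(), "enrcheck")
  sim <- simulate_rip(generate_genome(cfg), dir)
  tp <- sim$truth_peaks[!sim$truth_peaks$shared, ]
  sam <- read_sam_text(sim$rip$files[["ip_rep1"]])
  g <- sim$genes[match(tp$gene_id, sim$genes$gene_id), ]
  ratios <- numeric(0)
  for (i in seq_len(nrow(tp))) {
    w <- tp$end[i] - tp$start[i] + 1L
    in_peak <- sum(sam$pos >= tp$start[i] & sam$pos <= tp$end[i] - 49L)
    # control: same-width window at the other end of the gene span
    ctrl_start <- if (tp$start[i] - g$start[i] > g$end[i] - tp$end[i])
      g$start[i] else g$end[i] - w + 1L
    in_ctrl <- sum(sam$pos >= ctrl_start & sam$pos <= ctrl_start + w - 50L)
    ratios <- c(ratios, (in_peak + 1) / (in_ctrl + 1))
  }
  expect_gt(median(ratios), 5)
  expect_lt(median(ratios), 20)
})
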