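# Feature distributions, gene-set overlap and k-mer enrichment.

feat_model <- function() {
  toy_model(list(
    gcod = list(strand = "+",
                txs = list(t1 = matrix(c(1001, 1300, 1601, 1900),
                                       ncol = 2, byrow = TRUE)),
                cds = list(t1 = matrix(c(1101, 1300, 1601, 1700),
                                       ncol = 2, byrow = TRUE))),
    gnc = list(strand = "+",
               txs = list(t2 = matrix(c(5001, 5400), ncol = 2)),
               cds = list())))
}

test_that("items take the class of their majority overlap", {
  idx <- derive_features(feat_model(), genome_length = 10000)
  items <- GRanges("chr1", IRanges(
    c(1350, 1181, 1201, 5100, 8000), c(1449, 1360, 1400, 5199, 8099)),
    strand = "+")
  fd <- feature_distribution(items, idx)
  expect_equal(sum(fd$fraction), 1)
  counts <- setNames(fd$count, as.character(fd$feature))
  expect_equal(unname(counts["intron"]), 1L)    # wholly intronic
  expect_equal(unname(counts["CDS"]), 2L)       # 120/60 majority + tie
  expect_equal(unname(counts["NC_exon"]), 1L)
  expect_equal(unname(counts["intergenic"]), 1L)
})

test_that("majority overlap decides; ties fall to label precedence", {
  idx <- derive_features(feat_model(), genome_length = 10000)
  # [1181,1360]: 120 bp CDS vs 60 bp intron -> CDS by majority
  fd <- feature_distribution(GRanges("chr1", IRanges(1181, 1360),
                                     strand = "+"), idx)
  expect_equal(as.character(fd$feature[fd$count == 1L]), "CDS")
  # [1241,1420]: 60 bp CDS vs 120 bp intron -> intron by majority
  fd2 <- feature_distribution(GRanges("chr1", IRanges(1241, 1420),
                                      strand = "+"), idx)
  expect_equal(as.character(fd2$feature[fd2$count == 1L]), "intron")
  # [1201,1400]: exact 100/100 tie -> CDS by precedence
  fd3 <- feature_distribution(GRanges("chr1", IRanges(1201, 1400),
                                      strand = "+"), idx)
  expect_equal(as.character(fd3$feature[fd3$count == 1L]), "CDS")
})

test_that("reads confined to noncoding exons are all NC_exon", {
  idx <- derive_features(feat_model(), genome_length = 10000)
  starts <- seq(5001, 5341, by = 20)
  reads <- GRanges("chr1", IRanges(starts, starts + 59L), strand = "+")
  fd <- feature_distribution(reads, idx)
  expect_equal(fd$fraction[fd$feature == "NC_exon"], 1)
})

test_that("target genes and set overlap follow set semantics", {
  expect_identical(target_genes(GRanges()), character(0))
  pk <- GRanges("chr1", IRanges(c(1, 100, 900), width = 50), strand = "+")
  pk$gene_id <- c("gA", "gA", "gB")
  expect_equal(target_genes(pk), c("gA", "gB"))
  ov <- overlap_with_rase(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$n_overlap, 2L)
  expect_setequal(ov$intersection, c("b", "c"))
  # symmetric and idempotent
  ov2 <- overlap_with_rase(c("b", "c", "d"), c("a", "b", "c"))
  expect_setequal(ov2$intersection, ov$intersection)
  ov3 <- overlap_with_rase(ov$intersection, ov$intersection)
  expect_equal(ov3$n_overlap, 2L)
  expect_equal(overlap_with_rase("x", "y")$n_overlap, 0L)
  expect_equal(overlap_with_rase(c("x", "y"), c("y", "x"))$n_overlap, 2L)
})

test_that("k-mer frequencies sum to one and self-background gives z ~ 0", {
  set.seed(3)
  genome <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = ""))
  names(genome) <- "chr1"
  peaks <- GRanges("chr1", IRanges(seq(101, 9101, by = 1000), width = 200),
                   strand = "+")
  km <- kmer_enrichment(peaks, genome, background = peaks, k = 3,
                        n_bg = 20, seed = 5)
  expect_equal(sum(km$f_obs), 1)
  # background windows are resampled from the peaks themselves: no k-mer
  # should look enriched beyond resampling noise
  expect_lt(max(abs(km$z)), 4)
  expect_lt(abs(mean(km$z)), 0.5)
  expect_error(kmer_enrichment(GRanges("chr1", IRanges(1, 4),
                                       strand = "+"),
                               genome, peaks, k = 5), "k exceeds")
})

test_that("a planted GC-rich 5-mer is recovered, also from minus strands", {
  for (strand in c("+", "-")) {
    set.seed(17)
    motif <- "GCGCG"
    bases <- sample(c("A", "C", "G", "T"), 60000, replace = TRUE,
                    prob = c(.35, .15, .15, .35))
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- "chr1"
    starts <- seq(501, 54501, by = 2000)
    peaks <- GRanges("chr1", IRanges(starts, width = 200), strand = strand)
    ins <- if (strand == "+") motif else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    genome <- Biostrings::DNAStringSet(Biostrings::replaceAt(
      genome[[1]], IRanges(starts + 100L, width = 5L),
      Biostrings::DNAStringSet(rep(ins, length(starts)))))
    names(genome) <- "chr1"
    bg <- GenomicRanges::setdiff(
      GRanges("chr1", IRanges(1, 60000), strand = strand), peaks)
    km <- kmer_enrichment(peaks, genome, bg, k = 5, seed = 9)
    expect_equal(km$kmer[1], motif, info = strand)
  }
})
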