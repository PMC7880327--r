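# Read clustering, permutation null and peak calling.

gr_reads <- function(starts, ends, strand = "+") {
  if (length(starts) == 0L) return(GRanges())
  GRanges("chr1", IRanges(starts, ends), strand = strand)
}

test_that("1 bp overlap merges reads; bookended reads stay apart", {
  pk <- cluster_reads(gr_reads(c(100, 149, 300), c(149, 200, 350)))
  expect_equal(start(pk), c(100, 300))
  expect_equal(end(pk), c(200, 350))
  expect_equal(pk$height, c(2L, 1L))
  expect_equal(pk$n_reads, c(2L, 1L))
  # adjacent but non-overlapping reads form separate peaks
  pk2 <- cluster_reads(gr_reads(c(100, 151), c(150, 200)))
  expect_length(pk2, 2L)
  expect_true(all(pk2$height == 1L))
  # strands never merge
  pk3 <- cluster_reads(GRanges("chr1", IRanges(c(100, 120), width = 50),
                               strand = c("+", "-")))
  expect_length(pk3, 2L)
})

test_that("clustering matches the brute-force oracle on random fixtures", {
  set.seed(7)
  for (trial in 1:20) {
    n <- sample(5:200, 1)
    starts <- sample.int(2000L, n, replace = TRUE)
    widths <- sample(20:60, n, replace = TRUE)
    pk <- cluster_reads(gr_reads(starts, starts + widths - 1L))
    want <- cluster_oracle(starts, starts + widths - 1L)
    expect_equal(start(pk), want$start)
    expect_equal(end(pk), want$end)
    expect_equal(pk$height, want$height)
  }
})

test_that("permutation null is deterministic and handles degeneracy", {
  set.seed(5); a <- permutation_null(10, 50, 1000, 200)
  set.seed(5); b <- permutation_null(10, 50, 1000, 200)
  expect_identical(a, b)
  # gene length equal to read length: every read stacks
  set.seed(1)
  expect_true(all(permutation_null(7, 50, 50, 100) == 7L))
  expect_warning(nul <- permutation_null(3, 80, 50, 10), "clamped")
  expect_true(all(nul == 3L))
  expect_identical(permutation_null(0, 50, 1000, 25), integer(25))
})

test_that("two 50 bp reads in a 100 bp gene overlap as enumerated", {
  # exhaustive enumeration over the 51 x 51 equally likely start pairs:
  # the reads fail to overlap only for the two extreme pairs, so
  # P(max height >= 2) = 2599/2601
  p_exact <- 2599 / 2601
  set.seed(1234)
  nul <- permutation_null(2, 50, 100, 500)
  se <- sqrt(p_exact * (1 - p_exact) / 500)
  expect_lt(abs(mean(nul >= 2) - p_exact), 3 * se + 1e-12)
})

test_that("empirical p-values follow the add-one bound", {
  model <- toy_model(list(g = list(strand = "+", txs = list(
    t1 = matrix(c(1001, 3000), ncol = 2)), cds = list())))
  # 30 reads stacked on one base: observed height far above any null max
  stack <- gr_reads(rep(1500, 30), rep(1549, 30))
  pk <- call_peaks(stack, model, n_sim = 500, seed = 9)
  expect_equal(pk$pvalue, 1 / 501, tolerance = 1e-12)
  expect_true(pk$significant)
  # spread reads: a height-1 peak can never beat the null
  spread <- gr_reads(seq(1001, 2901, by = 100), seq(1050, 2950, by = 100))
  pk2 <- call_peaks(spread, model, n_sim = 500, seed = 9)
  expect_true(all(pk2$pvalue > 0.9))
  expect_false(any(pk2$significant))
})

test_that("adding stacked reads never increases the empirical p", {
  model <- toy_model(list(g = list(strand = "+", txs = list(
    t1 = matrix(c(1, 2000), ncol = 2)), cds = list())))
  base <- gr_reads(seq(1, 1941, by = 50), seq(50, 1990, by = 50))
  prev_p <- Inf
  for (extra in c(0, 5, 10, 20)) {
    reads <- c(base, gr_reads(rep(900, extra), rep(949, extra)))
    pk <- call_peaks(reads, model, n_sim = 300, seed = 11)
    top <- min(pk$pvalue)
    expect_lte(top, prev_p)
    prev_p <- top
  }
})

test_that("call_peaks is deterministic given (seed, inputs)", {
  model <- toy_model(list(g = list(strand = "+", txs = list(
    t1 = matrix(c(1, 5000), ncol = 2)), cds = list())))
  set.seed(77)
  starts <- sample(1:4950, 300, replace = TRUE)
  reads <- gr_reads(starts, starts + 49L)
  p1 <- call_peaks(reads, model, seed = 4)
  p2 <- call_peaks(reads, model, seed = 4)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("input subtraction removes overlapping peaks only", {
  mk <- function(s, e, sig = TRUE) {
    g <- if (length(s)) GRanges("chr1", IRanges(s, e), strand = "+")
         else GRanges()
    g$significant <- rep_len(sig, length(g))
    g$gene_id <- rep_len("g", length(g))
    g
  }
  ip <- mk(c(100, 500), c(200, 600))
  expect_length(subtract_input(ip, mk(199, 250)), 1L)   # 1 bp overlap rule
  expect_length(subtract_input(ip, mk(201, 250)), 2L)   # bookended: kept
  expect_length(subtract_input(ip, mk(integer(0), integer(0))), 2L)
  # non-significant input peaks do not subtract
  expect_length(subtract_input(ip, mk(199, 250, sig = FALSE)), 2L)
})

test_that("peaks export to BED with heights as scores", {
  model <- toy_model(list(g = list(strand = "+", txs = list(
    t1 = matrix(c(1001, 3000), ncol = 2)), cds = list())))
  pk <- call_peaks(gr_reads(rep(1500, 5), rep(1549, 5)), model,
                   n_sim = 100, seed = 2)
  path <- tempfile(fileext = ".bed")
  write_peak_bed(pk, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, start(pk) - 1L)   # BED is 0-based half-open
  expect_equal(bed$V3, end(pk))
  expect_equal(bed$V5, pk$height)
  tsv <- read.table(sub("\\.bed$", ".tsv", path), header = TRUE)
  expect_equal(tsv$pvalue, pk$pvalue)
})

test_that("replicate overlap summarises shared and exclusive peaks", {
  a <- GRanges("chr1", IRanges(c(100, 300, 500), width = 50),
               strand = "+")
  same <- replicate_overlap(a, a)
  expect_equal(same$fraction, 1)
  expect_equal(same$n1_overlap, 3L)
  disjoint <- replicate_overlap(a, GenomicRanges::shift(a, 1000))
  expect_equal(disjoint$fraction, 0)
  expect_equal(disjoint$rep1_only, 3L)
})
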