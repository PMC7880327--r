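# Event grammar, quantification and regulated-event calling.

ALL_TYPES <- c("ES", "A5SS", "A3SS", "IR", "MXE", "5pMXE", "3pMXE", "CE",
               "A3SS&ES", "A5SS&ES")

test_that("each hand-built gene model yields exactly its intended event", {
  for (type in ALL_TYPES) {
    fx <- event_fixture(type, strand = "+")
    ev <- detect_events(fx$junctions, fx$model, alignments = fx$ungapped)
    expect_equal(nrow(ev), 1L, info = type)
    expect_equal(ev$type, type, info = type)
    expect_equal(ev$gene_id, "gX", info = type)
    expect_true(all(ev$known), info = type)
  }
})

test_that("5'-side event names flip on the minus strand", {
  for (type in c("A5SS", "A3SS", "A5SS&ES", "A3SS&ES", "5pMXE", "3pMXE",
                 "ES", "MXE", "IR", "CE")) {
    fx <- event_fixture(type, strand = "-")
    ev <- detect_events(fx$junctions, fx$model, alignments = fx$ungapped)
    expect_equal(nrow(ev), 1L, info = type)
    expect_equal(ev$type, expected_label(type, "-"), info = type)
  }
})

test_that("textbook ES case: three junctions on a 3-exon gene", {
  fx <- event_fixture("ES")
  ev <- detect_events(fx$junctions, fx$model)
  expect_equal(ev$type, "ES")
  # skipped exon is the middle one: alternative form is the long junction
  expect_equal(ev$alt_junctions, "1201-1800")
  expect_equal(ev$model_junctions, "1201-1400;1601-1800")
})

test_that("novel junctions mark events novel; intergenic ones are dropped", {
  fx <- event_fixture("ES")
  # remove the skip isoform from the annotation: the skip junction is novel
  model <- toy_model(list(gX = list(strand = "+", txs = list(
    t1 = matrix(c(1001, 1200, 1401, 1600, 1801, 2000), ncol = 2,
                byrow = TRUE)), cds = list())))
  ev <- detect_events(fx$junctions, model)
  expect_equal(ev$type, "ES")
  expect_false(ev$known)
  # a junction outside all genes is excluded and counted
  far <- c(fx$junctions, jgr(list(c(50000, 50100))))
  ev2 <- detect_events(far, fx$model)
  expect_equal(attr(ev2, "intergenic"), 1L)
  expect_equal(nrow(ev2), 1L)
})

test_that("intron retention requires both boundaries crossed", {
  fx <- event_fixture("IR")
  ev <- detect_events(fx$junctions, fx$model, alignments = fx$ungapped)
  expect_equal(ev$type, "IR")
  # one-sided evidence is not retention
  one_sided <- fx$ungapped[1]
  ev2 <- detect_events(fx$junctions, fx$model, alignments = one_sided)
  expect_equal(nrow(ev2), 0L)
  # without alignments IR is undetectable
  ev3 <- detect_events(fx$junctions, fx$model)
  expect_equal(nrow(ev3), 0L)
})

make_quant <- function(model_n, alt_n, type = "ES", min_support = 10L) {
  # synthetic evidence for the ES fixture with given per-sample counts
  fx <- event_fixture(type)
  ev <- detect_events(fx$junctions, fx$model, alignments = fx$ungapped)
  samples <- lapply(seq_along(model_n), function(i) {
    j <- fx$junctions
    j$count <- ifelse(paste0(start(j), "-", end(j)) %in%
                        strsplit(ev$model_junctions, ";")[[1L]],
                      model_n[i], alt_n[i])
    list(junctions = j, ungapped = GRanges())
  })
  names(samples) <- paste0("s", seq_along(samples))
  quantify_events(ev, samples, min_support = min_support)
}

test_that("AS ratio is alt/(alt+model) with a support gate", {
  q <- make_quant(model_n = 8L, alt_n = 2L)
  expect_equal(unname(q$ratio[1, 1]), 0.2)
  q0 <- make_quant(model_n = 10L, alt_n = 0L)
  expect_equal(unname(q0$ratio[1, 1]), 0)
  # below min_support the ratio is NA
  qlow <- make_quant(model_n = 3L, alt_n = 2L)
  expect_true(is.na(qlow$ratio[1, 1]))
  qlow2 <- make_quant(model_n = 3L, alt_n = 2L, min_support = 5L)
  expect_equal(unname(qlow2$ratio[1, 1]), 0.4)
})

test_that("regulated events reproduce the hand-computed t-test", {
  # ratios A = (0.2, 0.25, 0.3), B = (0.6, 0.65, 0.7):
  # pooled sd = 0.05, t = 0.4 / (0.05 * sqrt(2/3)) = 9.798, df = 4
  q <- make_quant(model_n = rep(100L, 6),
                  alt_n = as.integer(round(100 * c(.2, .25, .3, .6, .65,
                                                   .7) /
                                             (1 - c(.2, .25, .3, .6, .65,
                                                    .7)))))
  # set ratios directly to the stated values for the arithmetic check
  q$ratio[1, ] <- c(0.2, 0.25, 0.3, 0.6, 0.65, 0.7)
  res <- detect_rases(q, rep(c("A", "B"), each = 3))
  expect_equal(res$delta, 0.4)
  expect_equal(round(res$t, 2), 9.80)
  expect_lt(res$pvalue, 0.001)
  expect_true(res$significant)
})

test_that("identical ratios and sub-threshold deltas are not significant", {
  q <- make_quant(model_n = rep(50L, 6), alt_n = rep(20L, 6))
  q$ratio[1, ] <- c(0.4, 0.5, 0.6, 0.4, 0.5, 0.6)
  res <- detect_rases(q, rep(c("A", "B"), each = 3))
  expect_equal(res$delta, 0)
  expect_false(res$significant)
  q$ratio[1, ] <- c(0.4, 0.5, 0.6, 0.45, 0.55, 0.65)
  res2 <- detect_rases(q, rep(c("A", "B"), each = 3))
  expect_equal(res2$delta, 0.05)
  expect_false(res2$significant)   # delta gate regardless of p
})

test_that("ratio symmetry: swapping model and alternative maps r to 1-r", {
  fx <- event_fixture("ES")
  ev <- detect_events(fx$junctions, fx$model)
  swapped <- ev
  swapped$model_junctions <- ev$alt_junctions
  swapped$alt_junctions <- ev$model_junctions
  mk <- function(events, alt) {
    samples <- lapply(seq_along(alt), function(i) {
      j <- fx$junctions
      j$count <- ifelse(paste0(start(j), "-", end(j)) == "1201-1800",
                        alt[i], 60L)
      list(junctions = j, ungapped = GRanges())
    })
    names(samples) <- paste0("s", seq_along(samples))
    quantify_events(events, samples)
  }
  alt <- c(12L, 18L, 24L, 40L, 52L, 66L)
  qa <- mk(ev, alt); qb <- mk(swapped, alt)
  expect_equal(unname(qa$ratio[1, ]), 1 - unname(qb$ratio[1, ]))
  cond <- rep(c("A", "B"), each = 3)
  ra <- detect_rases(qa, cond); rb <- detect_rases(qb, cond)
  expect_equal(ra$delta, rb$delta)
  expect_equal(ra$pvalue, rb$pvalue)
})

test_that("events with too few defined ratios are reported untestable", {
  q <- make_quant(model_n = c(50L, 2L, 2L, 50L, 50L, 50L),
                  alt_n = c(20L, 1L, 1L, 20L, 20L, 20L))
  expect_message(res <- detect_rases(q, rep(c("A", "B"), each = 3)),
                 "not testable")
  expect_false(res$testable)
  expect_false(res$significant)
})
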