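# Shared fixtures: hand-built gene models and event configurations,
# brute-force oracles, and independent SAM text parsers.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Build a gene_model from a compact description:
# genes = list(gene_id = list(strand =, txs = list(tx_id = exon matrix
# [start, end]), cds = list(tx_id = matrix))).
toy_model <- function(genes, chrom = "chr1") {
  gr <- GRanges(); gnames <- character(0)
  transcripts <- data.frame(tx_id = character(0), gene_id = character(0))
  exons <- list(); cds <- list()
  for (gid in names(genes)) {
    g <- genes[[gid]]
    exon_all <- do.call(rbind, unname(g$txs))
    gr <- c(gr, GRanges(chrom, IRanges(min(exon_all[, 1]),
                                       max(exon_all[, 2])),
                        strand = g$strand))
    gnames <- c(gnames, gid)
    for (txid in names(g$txs)) {
      m <- g$txs[[txid]]
      m <- m[order(m[, 1]), , drop = FALSE]
      exons[[txid]] <- GRanges(chrom, IRanges(m[, 1], m[, 2]),
                               strand = g$strand)
      transcripts <- rbind(transcripts,
                           data.frame(tx_id = txid, gene_id = gid))
      if (!is.null(g$cds[[txid]])) {
        cm <- g$cds[[txid]]
        cds[[txid]] <- GRanges(chrom, IRanges(cm[, 1], cm[, 2]),
                               strand = g$strand)
      }
    }
  }
  names(gr) <- gnames
  mcols(gr)$gene_id <- gnames
  mcols(gr)$coding <- vapply(gnames, function(gid)
    length(genes[[gid]]$cds) > 0, TRUE)
  spliceRIP:::new_gene_model(gr, transcripts, exons, cds)
}

jgr <- function(coords, strand = "+", count = 10L, chrom = "chr1") {
  m <- do.call(rbind, coords)
  out <- GRanges(chrom, IRanges(m[, 1], m[, 2]), strand = strand)
  out$count <- rep_len(count, length(out))
  out
}

# The ten hand-built one-event gene models with their junction evidence.
# Each fixture: a gene with the two isoforms realising exactly one event,
# the observed junction list, and (for IR) ungapped boundary reads.
event_fixture <- function(type, strand = "+") {
  ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  ug <- NULL
  if (type == "ES") {
    txs <- list(t1 = ex(1001, 1200, 1401, 1600, 1801, 2000),
                t2 = ex(1001, 1200, 1801, 2000))
    j <- list(c(1201, 1400), c(1601, 1800), c(1201, 1800))
  } else if (type == "CE") {
    txs <- list(t1 = ex(1001, 1200, 1401, 1600, 1801, 2000, 2201, 2400),
                t2 = ex(1001, 1200, 2201, 2400))
    j <- list(c(1201, 1400), c(1601, 1800), c(2001, 2200), c(1201, 2200))
  } else if (type == "A5SS") {
    # genomic left-donor shift; label depends on strand
    txs <- list(t1 = ex(1001, 1200, 1401, 1600),
                t2 = ex(1001, 1260, 1401, 1600))
    j <- list(c(1201, 1400), c(1261, 1400))
  } else if (type == "A3SS") {
    txs <- list(t1 = ex(1001, 1200, 1401, 1600),
                t2 = ex(1001, 1200, 1341, 1600))
    j <- list(c(1201, 1400), c(1201, 1340))
  } else if (type == "A5SS&ES") {
    txs <- list(t1 = ex(1001, 1200, 1401, 1600, 1801, 2000),
                t2 = ex(1001, 1260, 1801, 2000))
    j <- list(c(1201, 1400), c(1601, 1800), c(1261, 1800))
  } else if (type == "A3SS&ES") {
    txs <- list(t1 = ex(1001, 1200, 1401, 1600, 1801, 2000),
                t2 = ex(1001, 1200, 1741, 2000))
    j <- list(c(1201, 1400), c(1601, 1800), c(1201, 1740))
  } else if (type == "MXE") {
    txs <- list(t1 = ex(1001, 1200, 1401, 1600, 2201, 2400),
                t2 = ex(1001, 1200, 1801, 2000, 2201, 2400))
    j <- list(c(1201, 1400), c(1601, 2200), c(1201, 1800), c(2001, 2200))
  } else if (type == "5pMXE") {
    txs <- list(t1 = ex(1001, 1200, 1801, 2000),
                t2 = ex(1401, 1600, 1801, 2000))
    j <- list(c(1201, 1800), c(1601, 1800))
  } else if (type == "3pMXE") {
    txs <- list(t1 = ex(1001, 1200, 1401, 1600),
                t2 = ex(1001, 1200, 1801, 2000))
    j <- list(c(1201, 1400), c(1201, 1800))
  } else if (type == "IR") {
    txs <- list(t1 = ex(1001, 1200, 1401, 1600),
                t2 = ex(1001, 1600))
    j <- list(c(1201, 1400))
    ug <- GRanges("chr1", IRanges(c(1190, 1360), c(1240, 1410)),
                  strand = strand)
  } else stop("unknown fixture type ", type)
  model <- toy_model(list(gX = list(strand = strand, txs = txs,
                                    cds = list())))
  list(model = model, junctions = jgr(j, strand = strand), ungapped = ug)
}

# the label the grammar should emit for a genomic fixture built as "type"
# on the given strand (5'-side patterns swap names on the minus strand)
expected_label <- function(type, strand) {
  if (strand == "+") return(type)
  swap <- c("A5SS" = "A3SS", "A3SS" = "A5SS",
            "A5SS&ES" = "A3SS&ES", "A3SS&ES" = "A5SS&ES",
            "5pMXE" = "3pMXE", "3pMXE" = "5pMXE")
  if (type %in% names(swap)) unname(swap[type]) else type
}

# brute-force per-base coverage oracle over [lo, hi]
coverage_oracle <- function(starts, ends, lo, hi) {
  depth <- integer(hi - lo + 1L)
  for (i in seq_along(starts)) {
    a <- max(starts[i], lo); b <- min(ends[i], hi)
    if (a <= b) {
      idx <- (a - lo + 1L):(b - lo + 1L)
      depth[idx] <- depth[idx] + 1L
    }
  }
  depth
}

# brute-force >=1 bp overlap clustering oracle: returns merged intervals
# with max depth per cluster
cluster_oracle <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  cs <- ce <- integer(0)
  for (i in seq_along(starts)) {
    if (length(cs) && starts[i] <= ce[length(ce)]) {
      ce[length(ce)] <- max(ce[length(ce)], ends[i])
    } else {
      cs <- c(cs, starts[i]); ce <- c(ce, ends[i])
    }
  }
  height <- vapply(seq_along(cs), function(k)
    max(coverage_oracle(starts, ends, cs[k], ce[k])), 1L)
  data.frame(start = cs, end = ce, height = height)
}

# independent SAM text parsing (no package code): returns data.frame of
# qname, flag, pos, cigar for body records
read_sam_text <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (!length(body))
    return(data.frame(qname = character(0), flag = integer(0),
                      pos = integer(0), cigar = character(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  data.frame(qname = vapply(f, `[[`, "", 1L),
             flag = as.integer(vapply(f, `[[`, "", 2L)),
             pos = as.integer(vapply(f, `[[`, "", 4L)),
             cigar = vapply(f, `[[`, "", 6L),
             stringsAsFactors = FALSE)
}

# independent CIGAR walk: genomic blocks of one record
cigar_blocks <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNS]", cigar))[[1L]]
  len <- as.integer(sub("[MIDNS]", "", ops))
  op <- sub("[0-9]+", "", ops)
  blocks <- NULL; cur <- pos; bstart <- NA_integer_
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "D")) {
      if (is.na(bstart)) bstart <- cur
      cur <- cur + len[i]
    } else if (op[i] == "N") {
      blocks <- rbind(blocks, c(bstart, cur - 1L)); bstart <- NA_integer_
      cur <- cur + len[i]
    }
  }
  rbind(blocks, c(bstart, cur - 1L))
}

small_config <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_genes = 24L, genome_length = 2.5e5,
               rnaseq_depth = 12000, rip_depth = 8000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}
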