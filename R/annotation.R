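#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end
#'   width findOverlaps countOverlaps reduce setdiff gaps mcols mcols<-
#'   granges resize shift
#' @importFrom IRanges IRanges ranges Views viewMaxs subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits Rle runValue elementNROWS
#'   DataFrame
NULL

# Internal constructor for the hierarchical gene model:
#   genes       GRanges (names = gene_id; mcols: gene_id, coding)
#   transcripts data.frame(tx_id, gene_id)
#   exons       GRangesList by tx_id, exons sorted by start, disjoint
#   cds         GRangesList by tx_id for coding transcripts
new_gene_model <- function(genes, transcripts, exons, cds) {
  model <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons, cds = cds),
    class = "gene_model")
  validate_gene_model(model)
  model
}

validate_gene_model <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  genes <- model$genes
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stop("gene model: genes must be uniquely named by gene_id", call. = FALSE)
  tx <- model$transcripts
  if (!all(tx$gene_id %in% names(genes)))
    stop("gene model: transcript with missing parent gene id", call. = FALSE)
  if (!all(names(model$exons) %in% tx$tx_id))
    stop("gene model: exons with missing parent transcript id", call. = FALSE)
  for (i in seq_len(nrow(tx))) {
    txid <- tx$tx_id[i]
    g <- genes[tx$gene_id[i]]
    ex <- model$exons[[txid]]
    if (is.null(ex) || length(ex) == 0L)
      stop("gene model: transcript ", txid, " has no exons", call. = FALSE)
    if (!all(as.character(strand(ex)) == as.character(strand(g))))
      stop("gene model: strand of ", txid, " inconsistent with its gene",
           call. = FALSE)
    if (any(start(ex) < start(g)) || any(end(ex) > end(g)))
      stop("gene model: exon of ", txid, " outside gene span of ",
           tx$gene_id[i], call. = FALSE)
    if (is.unsorted(start(ex)) ||
        (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)])))
      stop("gene model: exons of ", txid, " not sorted/disjoint",
           call. = FALSE)
    cd <- model$cds[[txid]]
    if (!is.null(cd) && length(cd)) {
      ov <- sum(vapply(seq_along(cd), function(k)
        sum(pmax(0L, pmin(end(ex), end(cd)[k]) -
                   pmax(start(ex), start(cd)[k]) + 1L)), 1L))
      if (ov != sum(width(cd)))
        stop("gene model: CDS of ", txid, " not contained in its exons",
             call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model: ", length(x$genes), " genes, ", nrow(x$transcripts),
      " transcripts, ", sum(elementNROWS(x$exons)), " exons (",
      sum(vapply(x$cds, length, 1L) > 0L), " coding transcripts)\n", sep = "")
  invisible(x)
}

#' Parse a GTF file into a hierarchical gene model
#'
#' Reads gene/transcript/exon (and optional CDS) records carrying quoted
#' `gene_id`/`transcript_id` attributes and assembles a validated gene model:
#' genes as a named `GRanges`, transcripts as a gene-keyed table and exons/CDS
#' as per-transcript `GRangesList`s with exons sorted and disjoint. Feature
#' lines of unknown type are ignored with a warning. Files whose exon records
#' lack a parent `transcript_id`, or whose exons fall outside their gene span,
#' are rejected.
#'
#' @param path Path to a GTF file.
#' @return A `gene_model` object.
#' @seealso [write_gtf()], [annotated_junctions()], [derive_features()]
#' @export
parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  known_types <- c("gene", "transcript", "exon", "CDS")
  unknown <- setdiff(unique(as.character(gr$type)), known_types)
  if (length(unknown)) {
    warning("parse_gtf: ignoring feature types: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    gr <- gr[as.character(gr$type) %in% known_types]
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("parse_gtf: records without a gene_id attribute", call. = FALSE)

  gtab <- gr[gr$type == "gene"]
  etab <- gr[gr$type == "exon"]
  ctab <- gr[gr$type == "CDS"]
  if (length(etab) == 0L)
    stop("parse_gtf: no exon records", call. = FALSE)
  if (is.null(etab$transcript_id) || anyNA(etab$transcript_id))
    stop("parse_gtf: exon records without a transcript_id attribute",
         call. = FALSE)

  # derive gene spans when explicit gene lines are absent
  if (length(gtab) == 0L) {
    sp <- split(granges(etab), etab$gene_id)
    gtab <- unlist(range(sp))
    gtab$gene_id <- names(gtab)
  } else {
    names(gtab) <- gtab$gene_id
  }
  genes <- granges(gtab)
  names(genes) <- gtab$gene_id
  mcols(genes)$gene_id <- gtab$gene_id

  ord <- order(etab$transcript_id, start(etab))
  etab <- etab[ord]
  exons <- GenomicRanges::split(granges(etab), etab$transcript_id)
  tx_of <- vapply(split(etab$gene_id, etab$transcript_id),
                  function(g) g[[1L]], "")
  transcripts <- data.frame(tx_id = names(exons),
                            gene_id = unname(tx_of[names(exons)]),
                            stringsAsFactors = FALSE)
  cds <- GRangesList()
  if (length(ctab)) {
    if (is.null(ctab$transcript_id) || anyNA(ctab$transcript_id))
      stop("parse_gtf: CDS records without a transcript_id attribute",
           call. = FALSE)
    ctab <- ctab[order(ctab$transcript_id, start(ctab))]
    cds <- GenomicRanges::split(granges(ctab), ctab$transcript_id)
  }
  coding_tx <- names(cds)[elementNROWS(cds) > 0L]
  coding_gene <- unique(transcripts$gene_id[transcripts$tx_id %in% coding_tx])
  mcols(genes)$coding <- names(genes) %in% coding_gene

  new_gene_model(genes, transcripts, as.list(exons), as.list(cds))
}

#' Write a gene model to GTF
#'
#' Emits gene, transcript, exon and CDS records (1-based inclusive
#' coordinates, quoted `gene_id`/`transcript_id` attributes). CDS frames are
#' computed in transcription order. The writer and [parse_gtf()] round-trip.
#'
#' @param model A `gene_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(model, path) {
  lines <- character(0)
  fmt <- function(chrom, feat, s, e, strand, frame, attr)
    paste(chrom, "sim", feat, s, e, ".", strand, frame, attr, sep = "\t")
  genes <- model$genes
  for (gid in names(genes)) {
    g <- genes[gid]
    chrom <- as.character(seqnames(g))
    gstrand <- as.character(strand(g))
    gattr <- sprintf("gene_id \"%s\";", gid)
    lines <- c(lines, fmt(chrom, "gene", start(g), end(g), gstrand, ".",
                          gattr))
    txids <- model$transcripts$tx_id[model$transcripts$gene_id == gid]
    for (txid in txids) {
      ex <- model$exons[[txid]]
      tattr <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", gid, txid)
      lines <- c(lines, fmt(chrom, "transcript", min(start(ex)), max(end(ex)),
                            gstrand, ".", tattr))
      lines <- c(lines, fmt(chrom, "exon", start(ex), end(ex), gstrand, ".",
                            tattr))
      cd <- model$cds[[txid]]
      if (!is.null(cd) && length(cd)) {
        # frame: number of bases to skip to reach the next codon start,
        # accumulated along the transcript (5' to 3')
        cd_tx <- if (gstrand == "-") rev(cd) else cd
        prior <- c(0, cumsum(width(cd_tx)))[seq_along(cd_tx)]
        frame <- as.character((3L - (prior %% 3L)) %% 3L)
        ord <- if (gstrand == "-") rev(seq_along(cd_tx)) else
          seq_along(cd_tx)
        lines <- c(lines, fmt(chrom, "CDS", start(cd_tx)[ord],
                              end(cd_tx)[ord], gstrand, frame[ord], tattr))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

junction_key <- function(gr)
  paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr), ":",
         as.character(strand(gr)))

#' Annotated splice junctions of a gene model
#'
#' The union, over consecutive exon pairs of every transcript, of intron
#' intervals (first to last intronic base, 1-based), deduplicated across
#' transcripts. Single-exon transcripts contribute nothing.
#'
#' @param model A `gene_model`.
#' @return A `GRanges` of unique introns with a `gene_id` metadata column;
#'   the donor-side exon ends at `start - 1` and the acceptor-side exon
#'   starts at `end + 1` (genomic orientation).
#' @export
annotated_junctions <- function(model) {
  out <- GRanges()
  for (i in seq_len(nrow(model$transcripts))) {
    txid <- model$transcripts$tx_id[i]
    ex <- model$exons[[txid]]
    if (length(ex) < 2L) next
    j <- GRanges(seqnames(ex)[-1L],
                 IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1L] - 1L),
                 strand = strand(ex)[-1L])
    mcols(j)$gene_id <- model$transcripts$gene_id[i]
    out <- c(out, j)
  }
  if (length(out) == 0L) {
    mcols(out)$gene_id <- character(0)
    return(out)
  }
  if (any(width(out) < 1L))
    stop("annotated_junctions: intron of width < 1 bp", call. = FALSE)
  out[!duplicated(junction_key(out))]
}

# exon-union ranges per gene (GRangesList, reduced)
exon_union <- function(model) {
  all_ex <- unlist(GRangesList(model$exons), use.names = FALSE)
  gid <- rep(model$transcripts$gene_id[
    match(names(model$exons), model$transcripts$tx_id)],
    elementNROWS(GRangesList(model$exons)))
  reduce(GenomicRanges::split(all_ex, factor(gid, levels = names(model$genes))))
}

#' Exon-union gene lengths
#'
#' Length of the exon-union model of each gene in bp, the length used for
#' FPKM normalization.
#'
#' @param model A `gene_model`.
#' @return Named integer vector (bp) over genes.
#' @export
gene_lengths <- function(model) {
  vapply(exon_union(model), function(gr) sum(width(gr)), 1L)
}

FEATURE_LEVELS <- c("CDS", "UTR5", "UTR3", "NC_exon", "intron", "intergenic")

#' Derive labeled genomic feature intervals
#'
#' Splits every gene span into 5'UTR / CDS / 3'UTR (coding transcripts, by
#' CDS span and strand), noncoding exons (transcripts without a CDS) and
#' introns (gaps between exons), and labels everything outside gene spans
#' intergenic. When transcripts give a base conflicting labels the precedence
#' is CDS > 5'UTR > 3'UTR > NC exon > intron, so translated sequence wins.
#' Labels tile each gene span with no gaps or double labels.
#'
#' @param model A `gene_model`.
#' @param genome_length Optional chromosome length(s), used to close the
#'   final intergenic interval; defaults to the largest annotated end.
#' @return A `feature_index`: a list with `features` (a `GRanges` with a
#'   `feature` factor column) ready for majority-overlap queries.
#' @export
derive_features <- function(model, genome_length = NULL) {
  genes <- model$genes
  chroms <- unique(as.character(seqnames(genes)))
  if (is.null(genome_length))
    genome_length <- stats::setNames(rep(max(end(genes)), length(chroms)),
                                     chroms)
  if (is.null(names(genome_length)))
    names(genome_length) <- chroms

  u5 <- GRanges(); u3 <- GRanges(); cds_all <- GRanges(); nc <- GRanges()
  for (i in seq_len(nrow(model$transcripts))) {
    txid <- model$transcripts$tx_id[i]
    ex <- model$exons[[txid]]
    cd <- model$cds[[txid]]
    if (is.null(cd) || length(cd) == 0L) {
      nc <- c(nc, granges(ex))
      next
    }
    cds_all <- c(cds_all, granges(cd))
    cspan <- range(cd)
    left <- ex[end(ex) < start(cspan)]
    lcut <- ex[start(ex) < start(cspan) & end(ex) >= start(cspan)]
    if (length(lcut))
      left <- c(left, GRanges(seqnames(lcut),
                              IRanges(start(lcut), start(cspan) - 1L),
                              strand = strand(lcut)))
    right <- ex[start(ex) > end(cspan)]
    rcut <- ex[end(ex) > end(cspan) & start(ex) <= end(cspan)]
    if (length(rcut))
      right <- c(right, GRanges(seqnames(rcut),
                                IRanges(end(cspan) + 1L, end(rcut)),
                                strand = strand(rcut)))
    if (as.character(strand(ex))[1L] == "+") {
      u5 <- c(u5, granges(left)); u3 <- c(u3, granges(right))
    } else {
      u5 <- c(u5, granges(right)); u3 <- c(u3, granges(left))
    }
  }
  cds_all <- reduce(cds_all)
  u5 <- GenomicRanges::setdiff(reduce(u5), cds_all)
  u3 <- GenomicRanges::setdiff(reduce(u3), c(cds_all, u5))
  nc <- GenomicRanges::setdiff(reduce(nc), c(cds_all, u5, u3))
  exonic <- reduce(c(cds_all, u5, u3, nc))
  introns <- GenomicRanges::setdiff(granges(genes), exonic)

  labeled <- c(cds_all, u5, u3, nc, introns)
  lab <- rep(c("CDS", "UTR5", "UTR3", "NC_exon", "intron"),
             c(length(cds_all), length(u5), length(u3), length(nc),
               length(introns)))
  # intergenic: complement of gene spans, strand-agnostic
  span_by_chrom <- reduce(GRanges(seqnames(genes), ranges(genes),
                                  strand = "*"))
  inter <- GenomicRanges::setdiff(
    GRanges(names(genome_length),
            IRanges(1L, as.integer(genome_length)), strand = "*"),
    span_by_chrom)
  labeled <- c(labeled, inter)
  lab <- c(lab, rep("intergenic", length(inter)))
  mcols(labeled)$feature <- factor(lab, levels = FEATURE_LEVELS)
  structure(list(features = labeled, genome_length = genome_length),
            class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  tot <- tapply(width(x$features), x$features$feature, sum)
  tot[is.na(tot)] <- 0
  cat("feature_index over", length(x$features), "intervals (bp per class):\n")
  print(tot)
  invisible(x)
}

#' Export a feature index to BED
#'
#' One BED record per labeled interval; the BED name column carries the
#' feature class.
#'
#' @param index A `feature_index` from [derive_features()].
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_feature_bed <- function(index, path) {
  gr <- index$features
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = as.character(gr$feature), score = 0L,
                   strand = sub("\\*", ".", as.character(strand(gr))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
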