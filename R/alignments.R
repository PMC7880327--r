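#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments GAlignments cigar njunc
#'   qwidth
NULL

#' Read spliced alignments from SAM/BAM
#'
#' Streams a SAM (or BAM) file into a `GAlignments` object, keeping only
#' usable records: mapped, primary (not secondary or supplementary), and
#' uniquely mapped. "Uniquely mapped" means mapping quality at or above
#' `min_mapq`, or an explicit `NH:i:1` tag. Records with malformed CIGAR
#' strings are skipped with a warning. Exclusion tallies are attached as the
#' `"excluded"` attribute.
#'
#' @param path Path to a SAM or BAM file.
#' @param min_mapq Minimum mapping quality accepted as unique (default 20).
#' @param validate If `TRUE` (default) pre-validate SAM CIGAR fields and
#'   drop malformed records instead of failing.
#' @return A `GAlignments` object; blocks of each alignment are recovered
#'   from its M/D/N CIGAR runs. Attribute `"excluded"` holds counts of
#'   records dropped per filter.
#' @export
read_alignments <- function(path, min_mapq = 20L, validate = TRUE) {
  if (!file.exists(path)) stop("no such alignment file: ", path,
                               call. = FALSE)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  n_malformed <- 0L
  if (is_sam && validate) {
    lines <- readLines(path)
    body <- !startsWith(lines, "@")
    if (any(body)) {
      cig <- sub("^(?:[^\t]*\t){5}([^\t]*).*", "\\1", lines[body],
                 perl = TRUE)
      ok <- grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", cig)
      n_malformed <- sum(!ok)
      if (n_malformed > 0L) {
        warning("read_alignments: skipped ", n_malformed,
                " record(s) with malformed CIGAR", call. = FALSE)
        tmp <- tempfile(fileext = ".sam")
        writeLines(c(lines[!body], lines[body][ok]), tmp)
        path <- tmp
      }
    }
  }
  bam <- if (is_sam) {
    dest <- tempfile()
    asBam(path, destination = dest, overwrite = TRUE,
          indexDestination = FALSE)
  } else path
  param <- ScanBamParam(
    what = c("mapq", "flag"), tag = "NH",
    flag = scanBamFlag(isUnmappedQuery = NA, isSecondaryAlignment = NA,
                       isSupplementaryAlignment = NA))
  gal <- readGAlignments(bam, param = param)
  # unmapped records never materialise as alignments; count them from the
  # record total
  n_records <- Rsamtools::countBam(bam)$records
  md <- mcols(gal)
  secondary <- bitwAnd(md$flag, 256L) != 0L
  supplementary <- bitwAnd(md$flag, 2048L) != 0L
  nh <- md$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(gal))
  unique_ok <- (!is.na(md$mapq) & md$mapq >= min_mapq) |
    (!is.na(nh) & nh == 1L)
  keep <- !secondary & !supplementary & unique_ok
  excluded <- c(unmapped = n_records - length(gal),
                secondary = sum(secondary),
                supplementary = sum(supplementary & !secondary),
                not_unique = sum(!unique_ok & !secondary & !supplementary),
                malformed_cigar = n_malformed)
  out <- gal[keep]
  mcols(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Extract observed splice junctions with read support
#'
#' Every N gap of every alignment contributes one supporting read to its
#' junction (a read with k gaps supports k junctions). Junction identity is
#' exact: same chromosome, strand, donor and acceptor coordinates.
#'
#' @param gal A `GAlignments` from [read_alignments()].
#' @param annotated Optional `GRanges` of annotated introns (from
#'   [annotated_junctions()]); observed junctions are flagged `known` iff
#'   present there.
#' @return A `GRanges` of intron intervals with metadata columns `count`
#'   (supporting reads) and, when `annotated` is given, `known`.
#' @export
extract_junctions <- function(gal, annotated = NULL) {
  j <- unlist(GenomicAlignments::junctions(gal), use.names = FALSE)
  if (length(j) == 0L) {
    out <- GRanges()
    mcols(out)$count <- integer(0)
    if (!is.null(annotated)) mcols(out)$known <- logical(0)
    return(out)
  }
  key <- junction_key(j)
  tab <- table(key)
  out <- j[!duplicated(key)]
  mcols(out) <- NULL
  mcols(out)$count <- as.integer(tab[junction_key(out)])
  out <- out[order(as.character(seqnames(out)), start(out), end(out))]
  if (!is.null(annotated))
    mcols(out)$known <- junction_key(out) %in% junction_key(annotated)
  out
}

#' Write junction counts to TSV
#'
#' Columns: chrom, strand, donor_end (last exonic base of the donor side),
#' acceptor_start (first exonic base of the acceptor side), count, and
#' known when present.
#'
#' @param junctions Junction `GRanges` from [extract_junctions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junction_tsv <- function(junctions, path) {
  df <- data.frame(chrom = as.character(seqnames(junctions)),
                   strand = as.character(strand(junctions)),
                   donor_end = start(junctions) - 1L,
                   acceptor_start = end(junctions) + 1L,
                   count = junctions$count)
  if (!is.null(junctions$known)) df$known <- junctions$known
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Strand-aware per-base coverage over a region
#'
#' Depth at base i is the number of alignment blocks (CIGAR M/D runs between
#' N gaps) covering i on the requested strand.
#'
#' @param gal A `GAlignments`.
#' @param chrom Chromosome name.
#' @param start,end Region bounds (1-based, inclusive).
#' @param strand `"+"`, `"-"` or `NULL` for both strands.
#' @return Integer vector of length `end - start + 1`.
#' @export
alignment_coverage <- function(gal, chrom, start, end, strand = NULL) {
  if (!chrom %in% GenomeInfoDb::seqlevels(gal))
    stop("alignment_coverage: unknown chromosome ", chrom, call. = FALSE)
  sl <- GenomeInfoDb::seqlengths(gal)[chrom]
  if (!is.na(sl) && (start < 1L || end > sl))
    stop("alignment_coverage: region outside chromosome bounds",
         call. = FALSE)
  if (start < 1L || end < start)
    stop("alignment_coverage: invalid region", call. = FALSE)
  if (!is.null(strand))
    gal <- gal[as.character(GenomicAlignments::strand(gal)) == strand]
  blocks <- unlist(GenomicAlignments::grglist(gal, drop.D.ranges = FALSE),
                   use.names = FALSE)
  blocks <- blocks[as.character(seqnames(blocks)) == chrom]
  cov <- IRanges::coverage(ranges(blocks), width = max(end,
    if (length(blocks)) max(end(blocks)) else end))
  as.integer(cov[start:end])
}
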