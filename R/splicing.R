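# Alternative-splicing event detection from junction evidence.
#
# The grammar classifies local junction configurations of one gene into ten
# event types. Working in genomic coordinates with introns as [s, e]
# (1-based, first..last intronic base):
#   ES        skip junction vs an inclusion chain over exactly one annotated
#             exon, sharing both outer anchors
#   CE        same with >= 2 consecutive skipped exons (cassette)
#   A5SS&ES / one-exon skip whose outer anchor on one side is shifted to an
#   A3SS&ES   alternative boundary of the same flanking exon
#   A5SS/A3SS two junctions sharing one anchor whose alternative boundaries
#             belong to overlapping annotated exons (an alternative end of
#             the same exon); 5'/3' naming follows the strand
#   MXE       two disjoint internal exons, each supported by junctions from
#             a common upstream anchor and to a common downstream anchor,
#             never joined to each other
#   5pMXE/    the same mutual-exclusion pattern at the first/last exon
#   3pMXE     position (no junctions on the outer side), strand-aware
#   IR        a junction whose intron has ungapped reads crossing both
#             exon-intron boundaries (retention competing with splicing)
#
# Patterns are mutually exclusive: skip-chain events require exact/shifted
# anchor matches over annotated exons, mutual-exclusion events require
# disjoint exons, and alternative-boundary events require overlapping exons.

EVENT_TYPES <- AS_TYPES

jkey2 <- function(s, e) paste0(s, "-", e)

# overlapping annotated exons realising alternative boundaries
.overlapping_exons <- function(E, end_at = NULL, start_at = NULL) {
  if (!is.null(end_at)) {
    x <- E[E$ee == end_at[1L], , drop = FALSE]
    y <- E[E$ee == end_at[2L], , drop = FALSE]
  } else {
    x <- E[E$es == start_at[1L], , drop = FALSE]
    y <- E[E$es == start_at[2L], , drop = FALSE]
  }
  if (nrow(x) == 0L || nrow(y) == 0L) return(FALSE)
  any(outer(x$es, y$ee, "<=") & outer(x$ee, y$es, ">="))
}

.gene_events <- function(gid, chrom, gstrand, J, E, ann_keys, ungapped,
                         anchor) {
  plus <- gstrand == "+"
  ev <- list()
  add <- function(type, model_j, alt_j, alt_is_intron = FALSE) {
    model <- paste(vapply(model_j, function(p) jkey2(p[1L], p[2L]), ""),
                   collapse = ";")
    alt <- paste(vapply(alt_j, function(p) jkey2(p[1L], p[2L]), ""),
                 collapse = ";")
    jk <- c(vapply(model_j, function(p) jkey2(p[1L], p[2L]), ""),
            if (!alt_is_intron) vapply(alt_j, function(p)
              jkey2(p[1L], p[2L]), ""))
    ev[[length(ev) + 1L]] <<- data.frame(
      gene_id = gid, chrom = chrom, strand = gstrand, type = type,
      model_junctions = model, alt_junctions = alt,
      alt_is_intron = alt_is_intron, known = all(jk %in% ann_keys),
      stringsAsFactors = FALSE)
  }
  has_j <- function(s, e) any(J$s == s & J$e == e)
  has_link <- function(s, e) has_j(s, e) || jkey2(s, e) %in% ann_keys

  ## --- skip-chain events: ES / CE / composites ---------------------------
  for (ti in seq_len(nrow(J))) {
    ts <- J$s[ti]; te <- J$e[ti]
    inside <- E[E$es >= ts & E$ee <= te, , drop = FALSE]
    inside <- inside[!duplicated(inside[c("es", "ee")]), , drop = FALSE]
    inside <- inside[order(inside$es), , drop = FALSE]
    m <- nrow(inside)
    if (m == 0L) next
    for (i in seq_len(m)) for (j in i:m) {
      run <- inside[i:j, , drop = FALSE]
      if (nrow(run) > 1L) {
        inner_ok <- all(vapply(seq_len(nrow(run) - 1L), function(q)
          has_j(run$ee[q] + 1L, run$es[q + 1L] - 1L), TRUE))
        if (!inner_ok) next
      }
      lefts <- unique(J$s[J$e == run$es[1L] - 1L])
      rights <- unique(J$e[J$s == run$ee[nrow(run)] + 1L])
      for (l0 in lefts) for (r0 in rights) {
        chain <- c(list(c(l0, run$es[1L] - 1L)),
                   if (nrow(run) > 1L)
                     lapply(seq_len(nrow(run) - 1L), function(q)
                       c(run$ee[q] + 1L, run$es[q + 1L] - 1L)),
                   list(c(run$ee[nrow(run)] + 1L, r0)))
        if (l0 == ts && r0 == te) {
          add(if (nrow(run) == 1L) "ES" else "CE", chain, list(c(ts, te)))
        } else if (r0 == te && l0 != ts && nrow(run) == 1L &&
                   .overlapping_exons(E, end_at = c(l0 - 1L, ts - 1L))) {
          add(if (plus) "A5SS&ES" else "A3SS&ES", chain, list(c(ts, te)))
        } else if (l0 == ts && r0 != te && nrow(run) == 1L &&
                   .overlapping_exons(E, start_at = c(r0 + 1L, te + 1L))) {
          add(if (plus) "A3SS&ES" else "A5SS&ES", chain, list(c(ts, te)))
        }
      }
    }
  }

  ## --- mutual-exclusion events: MXE / 5pMXE / 3pMXE ----------------------
  Eu <- E[!duplicated(E[c("es", "ee")]), , drop = FALSE]
  Eu <- Eu[order(Eu$es), , drop = FALSE]
  nE <- nrow(Eu)
  if (nE >= 2L) for (xi in seq_len(nE - 1L)) for (yi in (xi + 1L):nE) {
    X <- Eu[xi, ]; Y <- Eu[yi, ]
    if (X$ee >= Y$es) next                      # must be disjoint, ordered
    if (has_link(X$ee + 1L, Y$es - 1L)) next    # never joined to each other
    in_x <- J$s[J$e == X$es - 1L]; in_y <- J$s[J$e == Y$es - 1L]
    out_x <- J$e[J$s == X$ee + 1L]; out_y <- J$e[J$s == Y$ee + 1L]
    uu <- intersect(in_x, in_y); dd <- intersect(out_x, out_y)
    ann_into <- function(Z) any(grepl(paste0("-", Z$es - 1L, "$"), ann_keys))
    ann_from <- function(Z) any(grepl(paste0("^", Z$ee + 1L, "-"), ann_keys))
    if (length(uu) && length(dd)) {
      u <- max(uu); d <- min(dd)
      add("MXE", list(c(u, X$es - 1L), c(X$ee + 1L, d)),
          list(c(u, Y$es - 1L), c(Y$ee + 1L, d)))
    } else if (length(dd) && !length(in_x) && !length(in_y) &&
               !ann_into(X) && !ann_into(Y) &&
               any(E$es == X$es & E$first) && any(E$es == Y$es & E$first)) {
      d <- min(dd)
      add(if (plus) "5pMXE" else "3pMXE",
          list(c(X$ee + 1L, d)), list(c(Y$ee + 1L, d)))
    } else if (length(uu) && !length(out_x) && !length(out_y) &&
               !ann_from(X) && !ann_from(Y) &&
               any(E$ee == X$ee & E$last) && any(E$ee == Y$ee & E$last)) {
      u <- max(uu)
      add(if (plus) "3pMXE" else "5pMXE",
          list(c(u, X$es - 1L)), list(c(u, Y$es - 1L)))
    }
  }

  ## --- alternative boundary events: A5SS / A3SS --------------------------
  for (s0 in unique(J$s)) {
    es <- sort(unique(J$e[J$s == s0]))
    if (length(es) >= 2L)
      for (i in seq_len(length(es) - 1L)) for (j in (i + 1L):length(es)) {
        if (!.overlapping_exons(E, start_at = c(es[i] + 1L, es[j] + 1L)))
          next
        # shared genomic-left anchor: two acceptors on +, two donors on -
        add(if (plus) "A3SS" else "A5SS",
            list(c(s0, es[i])), list(c(s0, es[j])))
      }
  }
  for (e0 in unique(J$e)) {
    ss <- sort(unique(J$s[J$e == e0]))
    if (length(ss) >= 2L)
      for (i in seq_len(length(ss) - 1L)) for (j in (i + 1L):length(ss)) {
        if (!.overlapping_exons(E, end_at = c(ss[i] - 1L, ss[j] - 1L)))
          next
        add(if (plus) "A5SS" else "A3SS",
            list(c(ss[j], e0)), list(c(ss[i], e0)))
      }
  }

  ## --- intron retention --------------------------------------------------
  if (!is.null(ungapped) && length(ungapped)) {
    us <- start(ungapped); ue <- end(ungapped)
    for (ti in seq_len(nrow(J))) {
      b1 <- J$s[ti]; b2 <- J$e[ti]
      cross1 <- any(us <= b1 - anchor & ue >= b1 + anchor - 1L)
      cross2 <- any(us <= b2 - anchor + 1L & ue >= b2 + anchor)
      if (cross1 && cross2)
        add("IR", list(c(J$s[ti], J$e[ti])), list(c(J$s[ti], J$e[ti])),
            alt_is_intron = TRUE)
    }
  }

  if (!length(ev)) return(NULL)
  out <- do.call(rbind, ev)
  out[!duplicated(out[c("type", "model_junctions", "alt_junctions")]), ,
      drop = FALSE]
}

#' Detect and classify alternative splicing events
#'
#' Applies the ten-type event grammar (see the package vignette) to the
#' observed splice junctions of each gene, anchored to the gene's annotated
#' exon boundaries. Intron-retention events additionally require ungapped
#' reads crossing both exon-intron boundaries, so they are only detected
#' when `alignments` is supplied. Junctions not attributable to any gene
#' (wrong strand or outside all gene spans) are excluded and tallied in the
#' `"intergenic"` attribute.
#'
#' @param junctions `GRanges` of observed introns with a `count` column,
#'   pooled over samples (see [extract_junctions()]).
#' @param model A `gene_model`.
#' @param alignments Optional pooled `GAlignments` used for
#'   intron-retention evidence.
#' @param anchor Minimum bases an ungapped read must extend on each side of
#'   an exon-intron boundary to count as retention evidence (default 5).
#' @param min_count Minimum supporting reads for a junction to enter the
#'   grammar (default 1).
#' @return `data.frame` of events: `event_id`, `gene_id`, `chrom`, `strand`,
#'   `type` (one of `r paste(EVENT_TYPES, collapse = ", ")`),
#'   `model_junctions` / `alt_junctions` (semicolon-joined `start-end`
#'   intron intervals), `alt_is_intron` (`TRUE` for IR) and `known` (all
#'   junctions annotated).
#' @export
detect_events <- function(junctions, model, alignments = NULL, anchor = 5L,
                          min_count = 1L) {
  junctions <- junctions[junctions$count >= min_count]
  ov <- findOverlaps(junctions, model$genes, type = "within")
  intergenic <- length(junctions) - length(unique(queryHits(ov)))

  ann <- annotated_junctions(model)
  ann_by_gene <- split(paste0(start(ann), "-", end(ann)), ann$gene_id)

  # annotated exon tables per gene with first/last (genomic-left/right) flags
  ex_by_gene <- list()
  for (i in seq_len(nrow(model$transcripts))) {
    gid <- model$transcripts$gene_id[i]
    ex <- model$exons[[model$transcripts$tx_id[i]]]
    df <- data.frame(es = start(ex), ee = end(ex),
                     first = seq_along(ex) == 1L,
                     last = seq_along(ex) == length(ex))
    ex_by_gene[[gid]] <- rbind(ex_by_gene[[gid]], df)
  }

  ungapped <- NULL; ug_by_gene <- NULL
  if (!is.null(alignments)) {
    ungapped <- if (inherits(alignments, "GAlignments"))
      granges(alignments[njunc(alignments) == 0L])
    else granges(alignments)  # already ungapped read footprints
    ovu <- findOverlaps(ungapped, model$genes, type = "within")
    ug_by_gene <- split(queryHits(ovu), subjectHits(ovu))
  }

  j_by_gene <- split(queryHits(ov), subjectHits(ov))
  res <- list()
  hit_genes <- unique(subjectHits(ov))
  for (gi in sort(hit_genes)) {
    gid <- names(model$genes)[gi]
    jn <- junctions[j_by_gene[[as.character(gi)]]]
    J <- data.frame(s = start(jn), e = end(jn), count = jn$count)
    E <- ex_by_gene[[gid]]
    ug_g <- NULL
    if (!is.null(ungapped))
      ug_g <- ungapped[ug_by_gene[[as.character(gi)]]]
    res[[length(res) + 1L]] <- .gene_events(
      gid, as.character(seqnames(model$genes[gi])),
      as.character(strand(model$genes[gi])), J, E,
      ann_by_gene[[gid]] %||% character(0), ug_g, anchor)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), type = character(0),
                      model_junctions = character(0),
                      alt_junctions = character(0),
                      alt_is_intron = logical(0), known = logical(0))
  out$event_id <- paste(out$gene_id, out$type, out$alt_junctions, sep = "|")
  rownames(out) <- NULL
  out <- out[c("event_id", "gene_id", "chrom", "strand", "type",
               "model_junctions", "alt_junctions", "alt_is_intron",
               "known")]
  attr(out, "intergenic") <- intergenic
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample evidence bundle for event quantification
#'
#' @param gal A `GAlignments` for one sample.
#' @param annotated Optional annotated junctions for known/novel flags.
#' @return List with `junctions` (counted) and `ungapped` (footprints of
#'   gapless reads, for intron-retention evidence).
#' @export
sample_evidence <- function(gal, annotated = NULL) {
  list(junctions = extract_junctions(gal, annotated),
       ungapped = granges(gal[njunc(gal) == 0L]))
}

#' Quantify alternative splicing events per sample
#'
#' For each event and sample, the model (alternative) count is the mean
#' supporting-read count over the event's model (alternative) junctions; for
#' intron retention the alternative count is the mean number of ungapped
#' reads crossing the two exon-intron boundaries by at least `anchor` bp.
#' The AS ratio is `alt / (alt + model)`, reported only when the summed raw
#' read support in that sample reaches `min_support`.
#'
#' @param events Event table from [detect_events()].
#' @param samples Named list of [sample_evidence()] bundles.
#' @param min_support Minimum summed model+alt read support per sample for a
#'   defined ratio (default 10).
#' @param anchor Boundary anchor in bp for retention reads (default 5).
#' @return An `as_quant` list: `events`, and events x samples matrices
#'   `model_count`, `alt_count`, `support`, `ratio` (ratio `NA` below
#'   `min_support`).
#' @export
quantify_events <- function(events, samples, min_support = 10L,
                            anchor = 5L) {
  ne <- nrow(events)
  ns <- length(samples)
  model_count <- alt_count <- support <- ratio <-
    matrix(NA_real_, ne, ns, dimnames = list(events$event_id,
                                             names(samples)))
  parse_j <- function(s) {
    if (s == "") return(matrix(numeric(0), ncol = 2))
    do.call(rbind, lapply(strsplit(s, ";")[[1L]], function(p)
      as.numeric(strsplit(p, "-")[[1L]])))
  }
  mj <- lapply(events$model_junctions, parse_j)
  aj <- lapply(events$alt_junctions, parse_j)

  # boundary-crossing windows for intron-retention events, built once
  ir_idx <- which(events$alt_is_intron)
  if (length(ir_idx)) {
    b1 <- vapply(aj[ir_idx], function(m) m[1L, 1L], 1.0)
    b2 <- vapply(aj[ir_idx], function(m) m[1L, 2L], 1.0)
    w1 <- GRanges(events$chrom[ir_idx],
                  IRanges(b1 - anchor, b1 + anchor - 1L),
                  strand = events$strand[ir_idx])
    w2 <- GRanges(events$chrom[ir_idx],
                  IRanges(b2 - anchor + 1L, b2 + anchor),
                  strand = events$strand[ir_idx])
  }

  for (si in seq_len(ns)) {
    sm <- samples[[si]]
    jc <- setNames(sm$junctions$count,
                   paste0(as.character(seqnames(sm$junctions)), ":",
                          start(sm$junctions), "-", end(sm$junctions), ":",
                          as.character(strand(sm$junctions))))
    lookup <- function(chrom, strandc, m) {
      if (nrow(m) == 0L) return(numeric(0))
      v <- jc[paste0(chrom, ":", m[, 1L], "-", m[, 2L], ":", strandc)]
      v[is.na(v)] <- 0
      v
    }
    if (length(ir_idx)) {
      ir_c1 <- countOverlaps(w1, sm$ungapped, type = "within")
      ir_c2 <- countOverlaps(w2, sm$ungapped, type = "within")
      names(ir_c1) <- names(ir_c2) <- as.character(ir_idx)
    }
    for (ei in seq_len(ne)) {
      chrom <- events$chrom[ei]; strandc <- events$strand[ei]
      mv <- lookup(chrom, strandc, mj[[ei]])
      if (events$alt_is_intron[ei]) {
        c1 <- ir_c1[[as.character(ei)]]
        c2 <- ir_c2[[as.character(ei)]]
        av <- mean(c(c1, c2))
        araw <- c1 + c2
      } else {
        av0 <- lookup(chrom, strandc, aj[[ei]])
        av <- mean(av0)
        araw <- sum(av0)
      }
      mc <- if (length(mv)) mean(mv) else 0
      model_count[ei, si] <- mc
      alt_count[ei, si] <- av
      support[ei, si] <- sum(mv) + araw
      ratio[ei, si] <- if (support[ei, si] >= min_support &&
                           (mc + av) > 0) av / (av + mc) else NA_real_
    }
  }
  structure(list(events = events, model_count = model_count,
                 alt_count = alt_count, support = support, ratio = ratio),
            class = "as_quant")
}

#' @export
print.as_quant <- function(x, ...) {
  cat("as_quant: ", nrow(x$events), " events x ", ncol(x$ratio),
      " samples; ", sum(!is.na(x$ratio)), " defined ratios\n", sep = "")
  invisible(x)
}

#' Call regulated alternative splicing events
#'
#' Two-sample Student's t-test (pooled variance, two-sided) on the
#' per-replicate AS ratios of each event between two conditions. An event is
#' flagged significant when the raw p-value is at most `p_cutoff` and the
#' absolute difference of condition mean ratios is at least `delta_cutoff`.
#' A Benjamini-Hochberg adjusted p-value column is also reported.
#'
#' @param quant An `as_quant` from [quantify_events()].
#' @param condition Factor/character over the samples (two levels; second
#'   level is the treatment "B").
#' @param p_cutoff,delta_cutoff Significance gates (defaults 0.05 and 0.2).
#' @return `data.frame`: per event, condition mean ratios, `delta`
#'   (absolute ratio change), `t`, `pvalue`, `padj`, `testable` and
#'   `significant`. Events with fewer than two defined ratios in either
#'   condition are untestable.
#' @export
detect_rases <- function(quant, condition, p_cutoff = 0.05,
                         delta_cutoff = 0.2) {
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2L,
            length(condition) == ncol(quant$ratio))
  a <- condition == levels(condition)[1L]
  ev <- quant$events
  n <- nrow(ev)
  mean_a <- mean_b <- delta <- tstat <- pval <- rep(NA_real_, n)
  testable <- logical(n)
  for (i in seq_len(n)) {
    ra <- quant$ratio[i, a]; rb <- quant$ratio[i, !a]
    ra <- ra[!is.na(ra)]; rb <- rb[!is.na(rb)]
    if (length(ra) < 2L || length(rb) < 2L) next
    testable[i] <- TRUE
    mean_a[i] <- mean(ra); mean_b[i] <- mean(rb)
    delta[i] <- abs(mean_b[i] - mean_a[i])
    if (stats::sd(c(ra - mean(ra), rb - mean(rb))) == 0) {
      # degenerate: no within-group variance
      pval[i] <- if (delta[i] == 0) 1 else 0
      tstat[i] <- if (delta[i] == 0) 0 else Inf
    } else {
      tt <- t.test(rb, ra, var.equal = TRUE)
      tstat[i] <- unname(tt$statistic)
      pval[i] <- tt$p.value
    }
  }
  out <- data.frame(event_id = ev$event_id, gene_id = ev$gene_id,
                    type = ev$type, mean_ratio_A = mean_a,
                    mean_ratio_B = mean_b, delta = delta, t = tstat,
                    pvalue = pval, stringsAsFactors = FALSE)
  out$padj <- NA_real_
  out$padj[testable] <- p.adjust(out$pvalue[testable], method = "BH")
  out$testable <- testable
  out$significant <- testable & !is.na(pval) & pval <= p_cutoff &
    delta >= delta_cutoff
  if (any(!testable))
    message("detect_rases: ", sum(!testable),
            " event(s) without enough defined ratios were not testable")
  rownames(out) <- NULL
  out
}
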