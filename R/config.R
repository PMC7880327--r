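#' Simulation configuration
#'
#' Builds and validates the configuration object that fully determines a
#' synthetic experiment: a toy genome with multi-exon genes on both strands,
#' two-condition replicated RNA-seq libraries with planted fold-change genes
#' and planted splicing-ratio shifts, and IP/input RIP libraries with planted
#' enriched peaks (optionally carrying a GC-rich motif) plus shared IP/input
#' artifact peaks. All randomness downstream is a deterministic function of
#' `seed`.
#'
#' Defaults describe the study-scale synthetic conditions used throughout the
#' package's tests: 200 genes in a 2 Mb genome, 3 replicates per condition at
#' 3e5 fragments each, 2 IP + 2 input RIP libraries at 1e5 fragments each,
#' 4-fold planted expression changes, 0.4 planted inclusion-ratio shifts and
#' 10-fold planted peak enrichment.
#'
#' @param seed Integer seed; fully determines all generated outputs.
#' @param n_genes Number of genes to place on the genome.
#' @param genome_length Genome length in bp (single chromosome `chr1`).
#' @param n_replicates RNA-seq replicates per condition.
#' @param rip_replicates IP (and input) RIP library replicates.
#' @param rnaseq_depth Expected fragments per RNA-seq library.
#' @param rip_depth Expected fragments per IP/input library.
#' @param planted_deg_fraction Fraction of genes with a planted expression
#'   fold change (half up, half down).
#' @param fold_change Planted fold change (condition B over A) for up genes;
#'   down genes use its reciprocal.
#' @param planted_as_fraction Fraction of genes carrying a planted
#'   alternative-splicing event (cycled over the ten event types).
#' @param ratio_shift Planted difference in the alternative-form inclusion
#'   ratio between conditions (condition B = `base_ratio + ratio_shift`).
#' @param base_ratio Alternative-form inclusion ratio in condition A.
#' @param planted_peak_fraction Fraction of genes with a planted IP-enriched
#'   peak.
#' @param artifact_peak_fraction Fraction of genes with a planted shared
#'   IP/input artifact peak (disjoint from the IP-only peak genes).
#' @param enrichment Fold enrichment of read density inside planted peaks.
#' @param motif Nucleotide string written into the genome at the centre of
#'   motif-bearing peaks (default a GC-rich 5-mer).
#' @param motif_fraction Fraction of planted IP-only peaks that carry the
#'   motif.
#' @param read_length Read (fragment) length in bp; the simulator emits one
#'   single-end SAM record per fragment.
#' @param peak_width Width of planted peak intervals in bp (must be >=
#'   `read_length`).
#' @param noncoding_fraction Fraction of constitutive genes written without a
#'   CDS (their exons are noncoding exons).
#' @param gc_content Genome G+C fraction (default 0.3, an AT-rich background
#'   emulating transcribed mammalian sequence, against which a GC-rich
#'   motif is distinctive).
#' @param expr_sdlog Log-normal sdlog of per-gene baseline expression rates.
#' @param stranded Logical; if `TRUE` reads carry the transcript strand
#'   (stranded protocol).
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- simulation_config(seed = 1, n_genes = 20, genome_length = 2e5,
#'                          rnaseq_depth = 5000, rip_depth = 5000)
#' cfg$n_genes
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 200L,
                              genome_length = 2e6,
                              n_replicates = 3L,
                              rip_replicates = 2L,
                              rnaseq_depth = 3e5,
                              rip_depth = 1e5,
                              planted_deg_fraction = 0.1,
                              fold_change = 4,
                              planted_as_fraction = 0.25,
                              ratio_shift = 0.4,
                              base_ratio = 0.3,
                              planted_peak_fraction = 0.15,
                              artifact_peak_fraction = 0.05,
                              enrichment = 10,
                              motif = "GCGCG",
                              motif_fraction = 1,
                              read_length = 50L,
                              peak_width = 100L,
                              noncoding_fraction = 0.2,
                              gc_content = 0.3,
                              expr_sdlog = 0.8,
                              stranded = TRUE) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    genome_length = as.numeric(genome_length),
    n_replicates = as.integer(n_replicates),
    rip_replicates = as.integer(rip_replicates),
    rnaseq_depth = as.numeric(rnaseq_depth),
    rip_depth = as.numeric(rip_depth),
    planted_deg_fraction = planted_deg_fraction,
    fold_change = fold_change,
    planted_as_fraction = planted_as_fraction,
    ratio_shift = ratio_shift,
    base_ratio = base_ratio,
    planted_peak_fraction = planted_peak_fraction,
    artifact_peak_fraction = artifact_peak_fraction,
    enrichment = enrichment,
    motif = toupper(as.character(motif)),
    motif_fraction = motif_fraction,
    read_length = as.integer(read_length),
    peak_width = as.integer(peak_width),
    noncoding_fraction = noncoding_fraction,
    gc_content = gc_content,
    expr_sdlog = expr_sdlog,
    stranded = isTRUE(stranded)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  frac_fields <- c("planted_deg_fraction", "planted_as_fraction",
                   "planted_peak_fraction", "artifact_peak_fraction",
                   "noncoding_fraction", "motif_fraction")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("sim_config: '", f, "' must be a single number in [0, 1]",
           call. = FALSE)
  }
  if (cfg$base_ratio < 0 || cfg$base_ratio > 1)
    stop("sim_config: 'base_ratio' must lie in [0, 1]", call. = FALSE)
  shifted <- cfg$base_ratio + cfg$ratio_shift
  if (shifted < 0 || shifted > 1)
    stop("sim_config: 'base_ratio + ratio_shift' must lie in [0, 1]; got ",
         shifted, call. = FALSE)
  if (cfg$planted_peak_fraction + cfg$artifact_peak_fraction > 1)
    stop("sim_config: peak fractions sum above 1", call. = FALSE)
  if (cfg$n_genes < 1L) stop("sim_config: need at least one gene",
                             call. = FALSE)
  if (cfg$fold_change <= 0) stop("sim_config: 'fold_change' must be > 0",
                                 call. = FALSE)
  if (cfg$enrichment < 1) stop("sim_config: 'enrichment' must be >= 1",
                               call. = FALSE)
  if (cfg$read_length < 20L)
    stop("sim_config: 'read_length' must be >= 20 bp", call. = FALSE)
  if (cfg$peak_width < cfg$read_length)
    stop("sim_config: 'peak_width' must be >= 'read_length'", call. = FALSE)
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1)
    stop("sim_config: 'gc_content' must lie in (0, 1)", call. = FALSE)
  if (!grepl("^[ACGT]+$", cfg$motif))
    stop("sim_config: 'motif' must be a non-empty ACGT string", call. = FALSE)
  invisible(cfg)
}

#' Read/write a simulation configuration as YAML
#'
#' @param path Path to a YAML file holding `simulation_config()` fields.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` writes `cfg` and invisibly returns `path`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown sim_config fields in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(simulation_config, vals)
}

#' @rdname read_sim_config
#' @param cfg A `sim_config` object.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  out <- unclass(cfg)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic experiment configuration (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", x$n_genes, " genes / ", format(x$genome_length,
      big.mark = ","), " bp\n", sep = "")
  cat("  RNA-seq: 2 x ", x$n_replicates, " libraries, ", x$rnaseq_depth,
      " fragments each\n", sep = "")
  cat("  RIP: ", x$rip_replicates, " IP + ", x$rip_replicates,
      " input libraries, ", x$rip_depth, " fragments each\n", sep = "")
  cat("  planted: ", round(100 * x$planted_deg_fraction), "% DEGs (x",
      x$fold_change, "), ", round(100 * x$planted_as_fraction),
      "% AS events (shift ", x$ratio_shift, "), ",
      round(100 * x$planted_peak_fraction), "% peaks (x", x$enrichment,
      "), motif ", x$motif, "\n", sep = "")
  invisible(x)
}
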