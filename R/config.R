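#' Pipeline configuration
#'
#' Collects every threshold the screens, the guilt-by-association stage and
#' the reannotation rules use, with the defaults of the published analysis:
#' fold-change gates 1.5 / 0.67 at FDR < 0.05, hazard-ratio gates 1.5 / 0.67
#' at p <= 0.05 with a proportional-hazards check at 0.01, GSEA with 1000
#' gene-set permutations (set sizes 15--500) gated at FWER < 0.05 in both
#' data halves, Enrichment Metascore permutation null of 10,000 random
#' groups, overlap-distance tree cut at 0.5, 80% probe coverage, 95%
#' duplicate-transcript sharing, 58 bp strand-specific Agilent overlap with
#' 5 bp exon padding, promoter window -2 kb/+1 kb around the TSS, and the
#' differential-methylation delta-beta gate of 0.2.
#'
#' @param fc_up,fc_down Linear fold-change gates for up/down calls.
#' @param fdr FDR (BH q-value) threshold for the differential screens.
#' @param hr_up,hr_down Hazard-ratio gates for survival calls.
#' @param p_surv Cox p-value threshold (both uni- and multivariate).
#' @param ph_alpha Proportional-hazards (Schoenfeld) rejection threshold.
#' @param fwer FWER threshold applied per half in the consensus gate.
#' @param gsea_nperm,gsea_min,gsea_max Gene-set permutation count and the
#'   size window for tested sets.
#' @param em_nperm Number of random lncRNA groups for the metascore null.
#' @param overlap_cut Tree-cut height on the overlap distance.
#' @param coverage Minimum aligned fraction of a probe (Affymetrix rule).
#' @param dup_share Minimum shared fraction of the shorter transcript for
#'   two transcripts to count as duplicates.
#' @param agilent_min_overlap Minimum strand-specific overlap in bp.
#' @param exon_pad Padding in bp added to both sides of each exon.
#' @param promoter_up,promoter_down Promoter window around the TSS in bp
#'   (upstream, downstream in transcription orientation).
#' @param delta_beta Minimum absolute difference of group median beta-values.
#' @param test_method Two-group test: `"wilcoxon"` (default), `"ttest"`, or
#'   `"auto"` (Shapiro + Bartlett gates choose between them).
#' @param seed Integer global seed; all stochastic stages derive child seeds
#'   from it via [derive_seed()].
#' @return A validated list of class `"lnchet_config"`.
#' @export
#' @examples
#' cfg <- lnchet_config(seed = 7L)
#' cfg$fc_up
lnchet_config <- function(fc_up = 1.5, fc_down = 0.67, fdr = 0.05,
                          hr_up = 1.5, hr_down = 0.67, p_surv = 0.05,
                          ph_alpha = 0.01, fwer = 0.05,
                          gsea_nperm = 1000L, gsea_min = 15L, gsea_max = 500L,
                          em_nperm = 10000L, overlap_cut = 0.5,
                          coverage = 0.80, dup_share = 0.95,
                          agilent_min_overlap = 58L, exon_pad = 5L,
                          promoter_up = 2000L, promoter_down = 1000L,
                          delta_beta = 0.2,
                          test_method = c("wilcoxon", "ttest", "auto"),
                          seed = 1L) {
  test_method <- match.arg(test_method)
  cfg <- list(
    fc_up = fc_up, fc_down = fc_down, fdr = fdr,
    hr_up = hr_up, hr_down = hr_down, p_surv = p_surv,
    ph_alpha = ph_alpha, fwer = fwer,
    gsea_nperm = as.integer(gsea_nperm), gsea_min = as.integer(gsea_min),
    gsea_max = as.integer(gsea_max), em_nperm = as.integer(em_nperm),
    overlap_cut = overlap_cut, coverage = coverage, dup_share = dup_share,
    agilent_min_overlap = as.integer(agilent_min_overlap),
    exon_pad = as.integer(exon_pad),
    promoter_up = as.integer(promoter_up),
    promoter_down = as.integer(promoter_down),
    delta_beta = delta_beta, test_method = test_method,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "lnchet_config"
  cfg
}

validate_config <- function(cfg) {
  if (!(cfg$fc_down < 1 && 1 < cfg$fc_up))
    .fail("fold-change gates must satisfy fc_down < 1 < fc_up")
  if (!(cfg$hr_down < 1 && 1 < cfg$hr_up))
    .fail("hazard-ratio gates must satisfy hr_down < 1 < hr_up")
  for (nm in c("fdr", "p_surv", "ph_alpha", "fwer", "overlap_cut",
               "coverage", "dup_share", "delta_beta"))
    .check_frac(cfg[[nm]], nm)
  for (nm in c("gsea_nperm", "em_nperm", "gsea_min", "gsea_max",
               "agilent_min_overlap", "promoter_up", "promoter_down"))
    if (cfg[[nm]] < 1L) .fail(sprintf("'%s' must be >= 1", nm))
  if (cfg$exon_pad < 0L) .fail("'exon_pad' must be >= 0")
  if (cfg$gsea_min > cfg$gsea_max) .fail("gsea_min must be <= gsea_max")
  if (is.na(cfg$seed)) .fail("'seed' must be a fixed integer")
  invisible(cfg)
}

#' @export
print.lnchet_config <- function(x, ...) {
  cat("lnchet pipeline configuration\n")
  cat(sprintf("  FC gates %.2f/%.2f at FDR < %.2f; test = %s\n",
              x$fc_up, x$fc_down, x$fdr, x$test_method))
  cat(sprintf("  HR gates %.2f/%.2f at p <= %.2f; PH alpha %.2f\n",
              x$hr_up, x$hr_down, x$p_surv, x$ph_alpha))
  cat(sprintf("  GSEA: %d gene-set permutations, sizes [%d, %d], FWER < %.2f\n",
              x$gsea_nperm, x$gsea_min, x$gsea_max, x$fwer))
  cat(sprintf("  Metascore: %d random groups; overlap cut %.2f\n",
              x$em_nperm, x$overlap_cut))
  cat(sprintf("  Reannotation: coverage %.2f, dup share %.2f, overlap %d bp (pad %d)\n",
              x$coverage, x$dup_share, x$agilent_min_overlap, x$exon_pad))
  cat(sprintf("  Methylation: |delta-beta| > %.2f; promoter -%d/+%d bp\n",
              x$delta_beta, x$promoter_up, x$promoter_down))
  cat(sprintf("  Seed: %d\n", x$seed))
  invisible(x)
}
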