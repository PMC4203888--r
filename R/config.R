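#' Analysis configuration with study defaults
#'
#' Bundles every tunable threshold of the pipeline with its default.
#' Defaults are the values the dendritic-transcriptome study design
#' uses: BLAST e-value cutoff 1e-5 for reciprocal best hits, FDR level
#' 0.1% for differential expression, top 5% expression sets, rankmap
#' rank range 31--500 with a Bonferroni factor of 500 on the binomial
#' confidence bands, a minimum of 100 aligned amino acids for rate
#' estimation, and the 5--40 micrometre dendrite quantification window.
#'
#' @param evalue_max Maximum BLAST e-value for a hit to count.
#' @param fdr_q Benjamini-Hochberg FDR level for divergence calls.
#' @param top_fraction Fraction defining the highly expressed set.
#' @param k_min,k_max Rank range of the concordance (rankmap) curve.
#' @param bonferroni_factor Bonferroni correction factor for the
#'   rankmap confidence bands.
#' @param conf_level Unadjusted confidence level of those bands.
#' @param min_aa Minimum aligned amino-acid length for Ka/Ks rows.
#' @param ds_window Distance window (micrometres) for the per-dendrite
#'   median D/S summary.
#' @param bin_width Distance bin width (micrometres) for D/S profiles.
#' @param seed Root seed for simulators.
#' @return A named list of class `dendrodiv_config`.
#' @export
run_config <- function(evalue_max = 1e-5, fdr_q = 0.001,
                       top_fraction = 0.05, k_min = 31L, k_max = 500L,
                       bonferroni_factor = 500L, conf_level = 0.95,
                       min_aa = 100L, ds_window = c(5, 40),
                       bin_width = 1, seed = 1L) {
  stopifnot(evalue_max > 0, fdr_q > 0, fdr_q < 1,
            top_fraction > 0, top_fraction < 1,
            k_min >= 1, k_max >= k_min, bonferroni_factor >= 1,
            conf_level > 0, conf_level < 1, min_aa >= 1,
            length(ds_window) == 2L, ds_window[1] >= 0,
            ds_window[2] > ds_window[1], bin_width > 0)
  structure(list(evalue_max = evalue_max, fdr_q = fdr_q,
                 top_fraction = top_fraction, k_min = as.integer(k_min),
                 k_max = as.integer(k_max),
                 bonferroni_factor = as.integer(bonferroni_factor),
                 conf_level = conf_level, min_aa = as.integer(min_aa),
                 ds_window = ds_window, bin_width = bin_width,
                 seed = as.integer(seed)),
            class = "dendrodiv_config")
}

# Deterministic sub-seed derivation so one root seed drives every
# simulator component independently. Kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
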