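# Dendrite/soma (D/S) fluorescence quantification from traced
# transects: distance-binned intensity-ratio profiles over 0-40 um,
# per-dendrite median summaries over the 5-40 um window (proximal
# pixels excluded to minimize soma bleed-through), and the log-scale
# species comparison.

#' Distance-binned dendrite/soma intensity ratio profile
#'
#' Bins the transect samples by distance from the dendrite path origin
#' and divides each bin's mean dendrite intensity by the mean soma
#' intensity. Bins without samples are reported as missing (`NA`), not
#' zero.
#'
#' @param distance Numeric vector of sample distances (micrometres,
#'   non-negative).
#' @param intensity Background-subtracted dendrite intensities
#'   (same length).
#' @param soma Soma reference pixel intensities (non-empty; mean must
#'   be > 0).
#' @param bin_width Bin width in micrometres (default 1).
#' @param range Profile distance range (default `c(0, 40)`).
#' @return data.frame with `bin_mid`, `n_samples`, `ds_ratio`.
#' @export
ds_ratio_profile <- function(distance, intensity, soma, bin_width = 1,
                             range = c(0, 40)) {
  stopifnot(length(distance) == length(intensity), bin_width > 0,
            length(range) == 2L, range[2] > range[1])
  if (any(distance < 0)) stop("distances must be non-negative")
  if (any(intensity < 0) || any(soma < 0))
    stop("intensities must be non-negative after background subtraction")
  if (length(soma) == 0L) stop("soma sample set is empty")
  s_mean <- mean(soma)
  if (s_mean <= 0) stop("soma mean intensity is zero; D/S undefined")
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  keep <- distance >= range[1] & distance <= range[2]
  bin <- cut(distance[keep], breaks, include.lowest = TRUE, right = FALSE)
  means <- tapply(intensity[keep], bin, mean)
  n <- tapply(intensity[keep], bin, length)
  n[is.na(n)] <- 0L
  data.frame(bin_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             n_samples = as.integer(n),
             ds_ratio = as.numeric(means) / s_mean)
}

#' Per-dendrite median D/S summary over a distance window
#'
#' Median dendrite intensity within the window (default 5-40 um,
#' excluding proximal pixels to minimize soma effects) divided by the
#' median soma pixel intensity.
#'
#' @inheritParams ds_ratio_profile
#' @param window Distance window `c(lo, hi)` in micrometres
#'   (default `c(5, 40)`).
#' @param min_samples Minimum in-window samples; dendrites with fewer
#'   are excluded (`NA` with a warning naming the reason).
#' @return Scalar D/S ratio, or `NA` if the dendrite is excluded.
#' @export
dendrite_median_ds <- function(distance, intensity, soma,
                               window = c(5, 40), min_samples = 3L) {
  stopifnot(length(distance) == length(intensity), length(window) == 2L,
            window[2] > window[1])
  if (length(soma) == 0L) stop("soma sample set is empty")
  s_med <- stats::median(soma)
  if (s_med <= 0) stop("soma median intensity is zero; D/S undefined")
  inwin <- distance >= window[1] & distance <= window[2]
  if (sum(inwin) < min_samples) {
    warning("dendrite excluded: only ", sum(inwin),
            " sample(s) in the ", window[1], "-", window[2],
            " um window (need >= ", min_samples, ")")
    return(NA_real_)
  }
  stats::median(intensity[inwin]) / s_med
}

#' Summarize all dendrites of a transect table
#'
#' Applies [dendrite_median_ds()] to every (cell, dendrite) group of a
#' transect table read by [read_transects_tsv()], using each cell's
#' soma samples as reference.
#'
#' @param transects data.frame with columns `cell_id`, `dendrite_id`,
#'   `distance_um`, `intensity`.
#' @param soma data.frame with columns `cell_id`, `intensity`.
#' @inheritParams dendrite_median_ds
#' @return data.frame with `cell_id`, `dendrite_id`, `ds_ratio`
#'   (excluded dendrites carry `NA`).
#' @export
summarize_transects <- function(transects, soma, window = c(5, 40),
                                min_samples = 3L) {
  groups <- unique(transects[, c("cell_id", "dendrite_id")])
  groups <- groups[order(groups$cell_id, groups$dendrite_id), ,
                   drop = FALSE]
  ds <- vapply(seq_len(nrow(groups)), function(i) {
    sel <- transects$cell_id == groups$cell_id[i] &
           transects$dendrite_id == groups$dendrite_id[i]
    sref <- soma$intensity[soma$cell_id == groups$cell_id[i]]
    if (length(sref) == 0L)
      stop("no soma samples for cell '", groups$cell_id[i], "'")
    dendrite_median_ds(transects$distance_um[sel],
                       transects$intensity[sel], sref,
                       window = window, min_samples = min_samples)
  }, numeric(1))
  data.frame(cell_id = groups$cell_id, dendrite_id = groups$dendrite_id,
             ds_ratio = ds, row.names = NULL)
}

#' Species comparison of D/S ratios on the log scale
#'
#' Two-sided Welch t test of the natural-log D/S ratios between two
#' species; the untransformed group means are reported alongside.
#'
#' @param ratios_A,ratios_B Positive D/S ratios (>= 2 per group; `NA`s
#'   from excluded dendrites are dropped).
#' @return List with `t_stat`, `df`, `p_value`, `mean_A`, `mean_B`.
#' @export
species_ds_test <- function(ratios_A, ratios_B) {
  ratios_A <- ratios_A[!is.na(ratios_A)]
  ratios_B <- ratios_B[!is.na(ratios_B)]
  if (length(ratios_A) < 2L || length(ratios_B) < 2L)
    stop("each species needs >= 2 dendrite ratios")
  if (any(ratios_A <= 0) || any(ratios_B <= 0))
    stop("D/S ratios must be positive (log transform undefined)")
  la <- log(ratios_A); lb <- log(ratios_B)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    eq <- abs(mean(la) - mean(lb)) < .Machine$double.eps^0.5
    return(list(t_stat = if (eq) 0 else sign(mean(la) - mean(lb)) * Inf,
                df = length(la) + length(lb) - 2L,
                p_value = if (eq) 1 else 0,
                mean_A = mean(ratios_A), mean_B = mean(ratios_B)))
  }
  tt <- stats::t.test(la, lb)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_A = mean(ratios_A), mean_B = mean(ratios_B))
}
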