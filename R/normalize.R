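# Array-scale normalization: upper-decile summarization of probes into
# probe-set values, then per-array median centering and interdecile
# range scaling. Percentiles use linear interpolation between order
# statistics (quantile type 7) throughout.

#' Summarize probe-level values with the upper-decile statistic
#'
#' Collapses a probe-level matrix to probe-set values by taking, per
#' array, the 90th percentile of each probe set's member probes.
#'
#' @param probe_expr Numeric matrix of probe-level values (probes x
#'   arrays) with probe ids as rownames.
#' @param probeset_of Named character vector or factor mapping probe id
#'   to probe-set id; every row of `probe_expr` must be covered.
#' @return Matrix of probe-set values (probe sets x arrays).
#' @export
upper_decile_summarize <- function(probe_expr, probeset_of) {
  stopifnot(is.matrix(probe_expr), !is.null(rownames(probe_expr)))
  ps <- probeset_of[rownames(probe_expr)]
  if (anyNA(ps))
    stop("probe(s) without a probe-set assignment: ",
         paste(utils::head(rownames(probe_expr)[is.na(ps)], 3L),
               collapse = ", "))
  groups <- split(seq_len(nrow(probe_expr)), as.character(ps))
  if (any(lengths(groups) == 0L)) stop("empty probe set")
  ids <- sort(names(groups))
  out <- matrix(NA_real_, length(ids), ncol(probe_expr),
                dimnames = list(ids, colnames(probe_expr)))
  for (id in ids)
    out[id, ] <- apply(probe_expr[groups[[id]], , drop = FALSE], 2L,
                       stats::quantile, probs = 0.9, names = FALSE,
                       type = 7L)
  out
}

#' Median-center and interdecile-scale each array
#'
#' Per column: subtract the column median and divide by the range
#' between the 10th and 90th percentile of that column. Output columns
#' have median 0 and interdecile range 1, and the transform is
#' invariant to positive affine rescaling of the input column.
#'
#' @param x Numeric matrix (rows = probe sets or metagenes, columns =
#'   arrays).
#' @return Matrix of the same shape on the common scale.
#' @export
median_center_scale <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 1L)
  if (any(!is.finite(x))) stop("non-finite values in expression matrix")
  out <- x
  for (j in seq_len(ncol(x))) {
    q <- stats::quantile(x[, j], c(0.1, 0.5, 0.9), names = FALSE, type = 7L)
    scale <- q[3L] - q[1L]
    if (scale <= 0)
      stop("array '", colnames(x)[j],
           "': 10th and 90th percentiles coincide; scale undefined")
    out[, j] <- (x[, j] - q[2L]) / scale
  }
  out
}
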