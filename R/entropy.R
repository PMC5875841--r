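# Minimum-Shannon-entropy channel selection.
#
# Among simultaneously recorded PPG channels, the one least corrupted by
# noise or poor skin contact concentrates its amplitude histogram into
# fewer bins, so histogram Shannon entropy acts as an inverse proxy for
# signal quality. Selection is per recording (one channel feeds the whole
# downstream pipeline).

#' Histogram Shannon entropy of a signal
#'
#' The signal is normalized to `[0, 1]` over a quantile range and binned
#' into `n_bins` equal-width bins; the entropy is `-sum(p * log2(p))` over
#' bin occupancies (with `0 * log2(0) = 0`). Normalization by an amplitude
#' range makes the value invariant to affine rescaling of the signal. A
#' constant signal has all mass in one bin and entropy 0.
#'
#' The default range is the 1st-99th percentile with outliers clamped into
#' the end bins: under a pure min-max range, rare extreme samples (exactly
#' what additive noise produces) stretch the range, concentrate the bulk of
#' the histogram and can *lower* the entropy of a noisier channel, which
#' would defeat minimum-entropy selection. `clip_quantiles = c(0, 1)`
#' recovers plain min-max normalization.
#'
#' @param x numeric sample vector, length >= 2, all finite.
#' @param n_bins number of histogram bins (default 50).
#' @param clip_quantiles lower/upper quantiles defining the normalization
#'   range (default `c(0.01, 0.99)`); samples outside are clamped.
#' @return Entropy in bits, in `[0, log2(n_bins)]`.
#' @export
shannon_entropy <- function(x, n_bins = 50, clip_quantiles = c(0.01, 0.99)) {
  if (length(x) < 2) stopf("signal must have length >= 2")
  if (anyNA(x) || any(!is.finite(x))) stopf("signal contains non-finite values")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stopf("n_bins must be >= 2")
  rng <- stats::quantile(x, clip_quantiles, names = FALSE)
  if (rng[1] == rng[2]) return(0)
  u <- pmin(pmax((x - rng[1]) / (rng[2] - rng[1]), 0), 1)
  bins <- pmin(floor(u * n_bins) + 1L, n_bins)
  p <- tabulate(bins, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Select the best PPG channel by minimum Shannon entropy
#'
#' Returns the index of the channel with the smallest histogram entropy;
#' ties are broken by the lowest channel index. All per-channel entropies
#' are reported for audit.
#'
#' @param record a [ppg_record()].
#' @param n_bins histogram bins passed to [shannon_entropy()].
#' @param clip_quantiles normalization range, see [shannon_entropy()].
#' @return A list with `index` (selected channel), `channel_id`, and
#'   `entropies` (named numeric vector, bits).
#' @export
select_channel <- function(record, n_bins = 50,
                           clip_quantiles = c(0.01, 0.99)) {
  stopifnot(inherits(record, "ppg_record"))
  ent <- apply(record$samples, 2, shannon_entropy, n_bins = n_bins,
               clip_quantiles = clip_quantiles)
  names(ent) <- record$channel_ids
  idx <- which.min(ent)  # which.min takes the first minimum: tie-break
  list(index = unname(idx), channel_id = record$channel_ids[idx],
       entropies = ent)
}
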