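#' Threshold-based-representation encoder configuration
#'
#' The TBR encoder emits a positive spike when the one-step increase of the
#' signal exceeds a threshold, a negative spike when the decrease exceeds it,
#' and nothing otherwise. Threshold resolution:
#' \describe{
#'   \item{`sd_scaled_global` (default)}{`alpha * sd` of the first
#'     differences pooled across all channels of the sample. Whole-recording
#'     gain (amplifier scaling) cancels, but relative amplitude differences
#'     between channels -- the scalp topography -- are preserved in the
#'     spike counts.}
#'   \item{`sd_scaled`}{`alpha * sd(diff(signal))` per channel; invariant to
#'     per-channel scaling, so topographic amplitude information is
#'     discarded and only each channel's temporal structure remains.}
#'   \item{`absolute`}{A fixed threshold in signal units.}
#' }
#'
#' @param threshold_mode `"sd_scaled_global"`, `"sd_scaled"` or
#'   `"absolute"`.
#' @param tbr_thr Positive threshold: the absolute value, or the multiplier
#'   `alpha` on the SD of first differences under the sd-scaled modes. The
#'   default 2 produces sparse trains marking statistically salient signal
#'   changes; 0.5 (a common convention) yields dense trains that also relay
#'   most background fluctuation.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(threshold_mode = c("sd_scaled_global", "sd_scaled",
                                              "absolute"),
                           tbr_thr = 2) {
  threshold_mode <- match.arg(threshold_mode)
  if (!is_num1(tbr_thr) || tbr_thr <= 0) {
    stop_snnerp("tbr_thr must be a positive number", "snnerp_config_error")
  }
  structure(list(threshold_mode = threshold_mode, tbr_thr = tbr_thr),
            class = "encoder_config")
}

#' Encode a single-channel signal as a ternary spike train
#'
#' @param signal Numeric vector, length >= 2, finite.
#' @param config An [encoder_config()].
#' @return Integer vector over `{-1, 0, +1}` of the same length; the first
#'   element is always 0 (no predecessor sample). Spikes mark strictly
#'   super-threshold first differences.
#' @examples
#' encode_tbr(c(0, 1, 0.4, 0.45), encoder_config("absolute", 0.5))
#' @export
encode_tbr <- function(signal, config = encoder_config()) {
  if (length(signal) < 2) {
    stop_snnerp("signal must have length >= 2", "snnerp_input_error")
  }
  if (!all(is.finite(signal))) {
    stop_snnerp("signal must be finite", "snnerp_input_error")
  }
  d <- diff(signal)
  thr <- switch(config$threshold_mode,
                absolute = config$tbr_thr,
                sd_scaled = config$tbr_thr * stats::sd(d),
                sd_scaled_global = stop_snnerp(
                  "sd_scaled_global needs the full sample; use encode_sample()",
                  "snnerp_input_error"))
  if (!is.finite(thr) || thr <= 0) {
    stop_snnerp(
      "sd-scaled threshold resolved to 0 (constant signal); use an absolute threshold",
      "snnerp_encoding_error")
  }
  c(0L, (d > thr) - (d < -thr))
}

#' Encode a multichannel ERP sample as a spike-train set
#'
#' Applies [encode_tbr()] channel-wise; under `sd_scaled` the threshold is
#' resolved independently for every channel.
#'
#' @param sample An `erp_sample` (or any channel x time numeric matrix with
#'   row names as channel labels).
#' @param config An [encoder_config()].
#' @return An object of class `spike_trains`: list with `spikes` (channel x
#'   time integer matrix over `{-1, 0, +1}`) and `source_len`.
#' @export
encode_sample <- function(sample, config = encoder_config()) {
  dat <- if (inherits(sample, "erp_sample")) sample$data else sample
  stopifnot(is.matrix(dat), !is.null(rownames(dat)))
  if (config$threshold_mode == "sd_scaled_global") {
    pooled_sd <- stats::sd(as.numeric(dat[, -1, drop = FALSE] -
                                        dat[, -ncol(dat), drop = FALSE]))
    if (!is.finite(pooled_sd) || pooled_sd == 0) {
      stop_snnerp(
        "sd-scaled threshold resolved to 0 (constant sample); use an absolute threshold",
        "snnerp_encoding_error")
    }
    config <- encoder_config("absolute", config$tbr_thr * pooled_sd)
  }
  spk <- matrix(0L, nrow(dat), ncol(dat), dimnames = dimnames(dat))
  for (ch in seq_len(nrow(dat))) {
    spk[ch, ] <- tryCatch(encode_tbr(dat[ch, ], config), error = function(e) {
      stop_snnerp(sprintf("channel %s: %s", rownames(dat)[ch],
                          conditionMessage(e)),
                  class(e)[1])
    })
  }
  structure(list(spikes = spk, source_len = ncol(dat)),
            class = "spike_trains")
}

#' Write spike trains as delimited text
#'
#' @param st A `spike_trains` object.
#' @param path Output file; rows = channels, columns = time, values -1/0/+1.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(st, path) {
  stopifnot(inherits(st, "spike_trains"))
  utils::write.table(st$spikes, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  invisible(path)
}
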