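## Superfusion release arithmetic: first-order washout simulator and the
## fractional-release / uptake / basal-outflow / evoked-efflux calculations
## used for tritiated-transmitter experiments.

#' Construct a superfusion release series
#'
#' Holds the per-sample released radioactivity and the tissue content left
#' after the last sample, which is the only measurable anchor; the tissue
#' content at the start of any sample is reconstructed backward from it.
#'
#' @param released numeric vector, Bq released per collected sample
#' @param tissue_after Bq remaining in the tissue after the last sample
#' @param tissue_mass tissue wet mass, g (needed for [uptake()])
#' @param stim_sample_index 1-based index of the stimulation sample, or NA
#' @param sample_duration sample collection period, s (default 180 = 3 min)
#' @return list of class `release_series`
#' @export
release_series <- function(released, tissue_after, tissue_mass = NA_real_,
                           stim_sample_index = NA_integer_,
                           sample_duration = 180) {
  if (any(released < 0)) stop("released amounts must be >= 0")
  if (tissue_after < 0) stop("tissue_after must be >= 0")
  if (!is.na(stim_sample_index) &&
      (stim_sample_index < 1L || stim_sample_index > length(released)))
    stop("stim_sample_index outside the series")
  structure(list(released = as.numeric(released),
                 tissue_after = as.numeric(tissue_after),
                 tissue_mass = tissue_mass,
                 stim_sample_index = stim_sample_index,
                 sample_duration = sample_duration),
            class = "release_series")
}

#' Simulate a first-order washout release series with a stimulated bump
#'
#' Each sample releases a constant fraction (`basal_fraction` %) of the pool
#' remaining at the start of that sample; at the stimulation sample the
#' fraction is multiplied by `stim_gain`. Radioactivity is conserved exactly:
#' released amounts plus the final tissue content reproduce `tissue_initial`.
#'
#' @param basal_fraction basal fractional release per sample, percent
#'   (0 < basal_fraction < 100)
#' @param stim_gain multiplicative gain applied at the stimulation sample
#' @param n_samples number of collected samples
#' @param stim_sample_index 1-based stimulation sample index
#' @param tissue_initial loaded radioactivity, Bq
#' @param tissue_mass tissue wet mass, g
#' @return a [release_series()]
#' @export
generate_release_series <- function(basal_fraction = 1, stim_gain = 3,
                                    n_samples = 15, stim_sample_index = 7,
                                    tissue_initial = 1e5,
                                    tissue_mass = 0.005) {
  if (basal_fraction <= 0 || basal_fraction >= 100)
    stop("basal_fraction must lie strictly between 0 and 100")
  if (!is.na(stim_sample_index) &&
      (stim_sample_index < 1 || stim_sample_index > n_samples))
    stop("stim index outside series")
  h <- basal_fraction / 100
  frac <- rep(h, n_samples)
  if (!is.na(stim_sample_index)) frac[stim_sample_index] <- h * stim_gain
  if (any(frac >= 1) || any(frac < 0))
    stop("parameters imply a negative tissue pool")
  released <- numeric(n_samples)
  pool <- tissue_initial
  for (k in seq_len(n_samples)) {
    released[k] <- pool * frac[k]
    pool <- pool - released[k]
  }
  release_series(released, pool, tissue_mass, stim_sample_index)
}

## tissue content at the start of every sample, reconstructed backward
tissue_at_start <- function(series) {
  series$tissue_after + rev(cumsum(rev(series$released)))
}

#' Fractional release per sample
#'
#' Released radioactivity in each sample expressed as a percentage of the
#' radioactivity present in the tissue at the start of that sample.
#'
#' @param series a [release_series()]
#' @return numeric vector, percent per sample
#' @export
fractional_release <- function(series) {
  tis <- tissue_at_start(series)
  if (any(tis <= 0)) stop("zero tissue content at a sample; fractional release undefined")
  100 * series$released / tis
}

#' Tissue uptake
#'
#' Sum of all released radioactivity plus the tissue content after the
#' experiment, per gram of tissue.
#'
#' @param series a [release_series()]
#' @return Bq/g
#' @export
uptake <- function(series) {
  if (is.na(series$tissue_mass) || series$tissue_mass <= 0)
    stop("tissue mass missing or non-positive")
  (sum(series$released) + series$tissue_after) / series$tissue_mass
}

#' Basal outflow
#'
#' Mean fractional release over the consecutive drug-free samples immediately
#' preceding the stimulation.
#'
#' @param series a [release_series()] with a stimulation index
#' @param pre_stim_samples number of pre-stimulus samples to average
#'   (default 2)
#' @return percent
#' @export
basal_outflow <- function(series, pre_stim_samples = 2) {
  k <- series$stim_sample_index
  if (is.na(k)) stop("series has no stimulation sample")
  if (k <= pre_stim_samples)
    stop("stimulus too early: not enough drug-free samples before it")
  fr <- fractional_release(series)
  mean(fr[(k - pre_stim_samples):(k - 1L)])
}

#' Stimulus-evoked net release
#'
#' Mean fractional release over the response window (the stimulation sample
#' plus the following `window - 1` samples by default) minus the basal
#' outflow.
#'
#' @param series a [release_series()] with a stimulation index
#' @param window response window length in samples (default 3: the
#'   stimulation sample and the two that follow)
#' @param pre_stim_samples passed to [basal_outflow()]
#' @return net percent
#' @export
evoked_release <- function(series, window = 3, pre_stim_samples = 2) {
  k <- series$stim_sample_index
  if (is.na(k)) stop("series has no stimulation sample")
  if (k > length(series$released))
    stop("no post-stimulus samples")
  idx <- k:min(length(series$released), k + window - 1L)
  fr <- fractional_release(series)
  mean(fr[idx]) - basal_outflow(series, pre_stim_samples)
}

#' Write a release series as CSV with metadata rows
#' @param series a [release_series()]
#' @param path output path
#' @export
write_release_series <- function(series, path) {
  write_table_with_provenance(
    data.frame(sample_index = seq_along(series$released),
               released_bq = series$released),
    path,
    provenance = list(tissue_after_bq = series$tissue_after,
                      mass_g = series$tissue_mass,
                      stim_index = series$stim_sample_index,
                      sample_duration_s = series$sample_duration))
}

#' Read a release series written by [write_release_series()]
#' @param path input path
#' @return a [release_series()]
#' @export
read_release_series <- function(path) {
  df <- read_table_with_provenance(path)
  prov <- attr(df, "provenance")
  release_series(df$released_bq,
                 tissue_after = as.numeric(prov[["tissue_after_bq"]]),
                 tissue_mass = as.numeric(prov[["mass_g"]]),
                 stim_sample_index = as.integer(prov[["stim_index"]]),
                 sample_duration = as.numeric(prov[["sample_duration_s"]]))
}
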