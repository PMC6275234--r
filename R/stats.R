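#' Parallel spike-train container
#'
#' Per-neuron sorted spike-time lists with duration metadata. Times are in
#' ms within `[0, duration)`; grid-based simulations produce integer times
#' at 1 ms resolution.
#'
#' @param trains list of numeric vectors of spike times (ms), one per
#'   neuron, each strictly increasing.
#' @param duration recording duration (ms).
#' @param resolution time grid resolution (ms).
#' @return An object of class `spike_data`.
#' @export
spike_data <- function(trains, duration, resolution = 1) {
  stopifnot(is.list(trains), duration > 0)
  for (tr in trains) {
    if (length(tr)) {
      if (any(diff(tr) <= 0)) stop("spike times must be strictly increasing")
      if (tr[1] < 0 || tr[length(tr)] >= duration)
        stop("spike times must lie in [0, duration)")
    }
  }
  structure(list(trains = trains, n_neurons = length(trains),
                 duration = as.numeric(duration), resolution = resolution),
            class = "spike_data")
}

# assemble a spike_data from parallel (time, id) event vectors
spikes_to_data <- function(times, ids, n_neurons, duration_ms) {
  trains <- split(as.numeric(times), factor(ids, levels = seq_len(n_neurons)))
  names(trains) <- NULL
  spike_data(trains, duration_ms)
}

#' @export
print.spike_data <- function(x, ...) {
  nsp <- sum(lengths(x$trains))
  cat(sprintf(
    "spike_data: %d neurons, %g ms, %d spikes (population rate %.3g Hz)\n",
    x$n_neurons, x$duration, nsp, nsp / x$n_neurons / (x$duration / 1000)))
  invisible(x)
}

new_measure <- function(measure, values, excluded) {
  structure(list(measure = measure, values = values,
                 excluded = as.integer(excluded)),
            class = "measure_distribution")
}

#' @export
print.measure_distribution <- function(x, ...) {
  cat(sprintf("%s distribution: %d values (mean %.4g, sd %.4g), %d excluded\n",
              x$measure, length(x$values), mean(x$values),
              stats::sd(x$values), x$excluded))
  invisible(x)
}

#' Per-neuron firing rates
#'
#' `rate = spike count / duration`, reported in Hz.
#'
#' @param s a [spike_data()].
#' @return A `measure_distribution` with one value per neuron.
#' @export
firing_rates <- function(s) {
  stopifnot(inherits(s, "spike_data"))
  new_measure("FR", lengths(s$trains) / (s$duration / 1000), 0L)
}

#' Local coefficient of variation (LV)
#'
#' The spike-time regularity measure of Shinomoto et al. (2003), built from
#' ratios of adjacent inter-spike intervals:
#' \deqn{LV = \frac{3}{m-1} \sum_{k=1}^{m-1}
#'   \left(\frac{ISI_k - ISI_{k+1}}{ISI_k + ISI_{k+1}}\right)^2}
#' with \eqn{m} the number of ISIs. LV is 0 for a perfectly regular train
#' and 1 in expectation for a Poisson train. Neurons with fewer than
#' `min_spikes` spikes (fewer than two ISIs) are excluded and counted.
#'
#' @param s a [spike_data()].
#' @param min_spikes minimum spikes for inclusion (default 3).
#' @return A `measure_distribution`; warns (not fails) when every neuron is
#'   excluded.
#' @export
local_variation <- function(s, min_spikes = 3L) {
  stopifnot(inherits(s, "spike_data"))
  lv1 <- function(tr) {
    isi <- diff(tr)
    m <- length(isi)
    r <- (isi[-m] - isi[-1]) / (isi[-m] + isi[-1])
    3 / (m - 1) * sum(r^2)
  }
  keep <- lengths(s$trains) >= min_spikes
  if (!any(keep)) {
    warning("all neurons excluded from LV (too few spikes)")
    return(new_measure("LV", numeric(0), sum(!keep)))
  }
  new_measure("LV", vapply(s$trains[keep], lv1, numeric(1)), sum(!keep))
}

#' Pairwise correlation coefficients of binned spike trains
#'
#' Bins every train at `bin_ms` (a final partial bin is dropped) and
#' computes the Pearson correlation of the binned counts for every
#' unordered neuron pair. Pairs involving a zero-variance binned train are
#' excluded and counted.
#'
#' @param s a [spike_data()].
#' @param bin_ms bin width in ms (default 2).
#' @return A `measure_distribution` with one value per included pair.
#' @export
pairwise_correlation <- function(s, bin_ms = 2) {
  stopifnot(inherits(s, "spike_data"))
  n_bins <- floor(s$duration / bin_ms)
  counts <- vapply(s$trains, function(tr)
    tabulate(pmin(floor(tr / bin_ms) + 1L, n_bins + 1L), n_bins + 1L)[
      seq_len(n_bins)],
    numeric(n_bins))
  mu <- colMeans(counts)
  vars <- (colSums(counts^2) - n_bins * mu^2) / (n_bins - 1)
  keep <- vars > 1e-9   # integer counts: true variances are 0 or >= ~1/n_bins
  n <- s$n_neurons
  n_pairs_total <- n * (n - 1) / 2
  if (sum(keep) < 2) {
    warning("fewer than two trains with binned variance > 0")
    return(new_measure("CC", numeric(0), n_pairs_total))
  }
  cc <- stats::cor(counts[, keep, drop = FALSE])
  vals <- cc[upper.tri(cc)]
  m <- sum(keep)
  new_measure("CC", vals, n_pairs_total - m * (m - 1) / 2)
}

#' Cohen's d effect size
#'
#' The normalized difference between the means of two samples,
#' \eqn{d = (\bar x - \bar y)/s_p}, with the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_x-1)s_x^2 + (n_y-1)s_y^2)/(n_x+n_y-2)}}.
#' Antisymmetric: `cohens_d(x, y) == -cohens_d(y, x)`. With zero pooled
#' variance, the result is 0 for equal means and signed `Inf` otherwise.
#'
#' @param x,y numeric samples of size >= 2.
#' @return The signed effect size.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("both samples must have size >= 2")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (dm == 0) return(0)
    return(sign(dm) * Inf)
  }
  dm / sqrt(sp2)
}

shared_histogram <- function(x, y, bins = 70L) {
  rng <- range(c(x, y), finite = TRUE)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  hx <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  hy <- graphics::hist(y, breaks = breaks, plot = FALSE)$counts
  list(breaks = breaks, counts_a = hx, counts_b = hy)
}

#' Compare two spike recordings (substantiation assessment)
#'
#' Computes the three characteristic measures -- firing rate (FR), local
#' coefficient of variation (LV) and pairwise correlation (CC) -- for both
#' recordings through one shared code path, builds shared-range histograms
#' (70 bins by default) and quantifies the difference per measure with
#' Cohen's d. Identical inputs give d = 0 for all measures. Note the three
#' measures probe different aspects of the dynamics (counts, serial
#' regularity, coordination across neurons) and need not agree: matched
#' rates do not imply matched regularity.
#'
#' @param a,b [spike_data()] objects with equal `n_neurons` and `duration`.
#' @param bin_ms CC bin width (ms).
#' @param bins histogram bin count.
#' @param min_spikes LV inclusion threshold.
#' @return An object of class `spike_comparison`: per measure, both
#'   distributions, the shared histogram, the effect size `d`, and the
#'   exclusion counts.
#' @export
compare_spike_data <- function(a, b, bin_ms = 2, bins = 70L,
                               min_spikes = 3L) {
  stopifnot(inherits(a, "spike_data"), inherits(b, "spike_data"))
  if (a$n_neurons != b$n_neurons || a$duration != b$duration)
    stop("spike_data objects differ in n_neurons or duration")
  one <- function(measure) {
    f <- switch(measure,
                FR = firing_rates,
                LV = function(s) local_variation(s, min_spikes),
                CC = function(s) pairwise_correlation(s, bin_ms))
    da <- f(a); db <- f(b)
    list(measure = measure, a = da, b = db,
         histogram = shared_histogram(da$values, db$values, bins),
         d = cohens_d(da$values, db$values),
         excluded = c(a = da$excluded, b = db$excluded))
  }
  out <- lapply(c("FR", "LV", "CC"), one)
  names(out) <- c("FR", "LV", "CC")
  structure(list(measures = out,
                 d = vapply(out, function(m) m$d, numeric(1)),
                 n_neurons = a$n_neurons, duration = a$duration),
            class = "spike_comparison")
}

#' @export
print.spike_comparison <- function(x, ...) {
  cat(sprintf("spike_comparison: %d neurons, %g ms\n",
              x$n_neurons, x$duration))
  for (m in x$measures)
    cat(sprintf(
      "  %s: mean %.4g vs %.4g, d = %.4g (excluded: %d / %d)\n",
      m$measure, mean(m$a$values), mean(m$b$values), m$d,
      m$excluded["a"], m$excluded["b"]))
  invisible(x)
}

#' Summarize effect sizes across network states
#'
#' Aggregates the per-measure Cohen's d of several [compare_spike_data()]
#' reports (one per replayed network state) into mean and standard
#' deviation per measure.
#'
#' @param reports list of `spike_comparison` objects.
#' @return A data frame with columns `measure`, `mean_d`, `sd_d`,
#'   `mean_abs_d`.
#' @export
summarize_states <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "spike_comparison")))
  d <- t(vapply(reports, function(r) r$d, numeric(3)))
  data.frame(measure = colnames(d),
             mean_d = colMeans(d),
             sd_d = apply(d, 2, stats::sd),
             mean_abs_d = colMeans(abs(d)),
             row.names = NULL)
}
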