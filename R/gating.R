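#' Positivity gates for comparative cytometry
#'
#' A `gate_set` records a per-channel positivity threshold, the method that
#' produced it, the control it was derived from, and the percent of events
#' it calls positive on the sample it was applied to. Events strictly above
#' the threshold are positive; an event exactly at the threshold is
#' negative, so a constant control yields 0% positive.
#'
#' @param channel channel name.
#' @param threshold numeric threshold (intensity units).
#' @param method one of `"fmo-3pct"`, `"overton"`, `"max-difference"`.
#' @param control_sample_id id of the control sample the gate came from.
#' @param percent_positive percent of events called positive, in \[0, 100\].
#' @param degenerate flag set when the two distributions were
#'   indistinguishable (maximum CDF difference 0).
#' @return An object of class `gate_set`.
#' @export
gate_set <- function(channel, threshold,
                     method = c("fmo-3pct", "overton", "max-difference"),
                     control_sample_id = NA_character_,
                     percent_positive = NA_real_,
                     degenerate = FALSE) {
  method <- match.arg(method)
  if (!is.na(percent_positive) &&
      (percent_positive < 0 || percent_positive > 100))
    stop("gate_set: percent_positive must lie in [0, 100]")
  structure(
    list(channel = channel, threshold = threshold, method = method,
         control_sample_id = control_sample_id,
         percent_positive = percent_positive, degenerate = degenerate),
    class = "gate_set"
  )
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf("<gate_set> %s @ %.4g (%s%s)%s\n", x$channel, x$threshold,
              x$method,
              if (is.na(x$percent_positive)) ""
              else sprintf(", %.2f%% positive", x$percent_positive),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' FMO 3% background gate
#'
#' Places the positivity threshold at the empirical `1 - background`
#' quantile of a fluorescence-minus-one control, so that `background` of
#' the control's events sit at or above it (the classic "3% background"
#' rule). Events strictly above the threshold are positive.
#'
#' @param control an [event_table] with `role = "FMO-control"`.
#' @param channel the channel omitted from the FMO stain.
#' @param background fraction of control events allowed above background;
#'   default 0.03.
#' @return A [gate_set] with `method = "fmo-3pct"`; its `percent_positive`
#'   is the percent of *control* events strictly above the threshold
#'   (at most `100 * background`).
#' @examples
#' ctl <- event_table(data.frame(Ki67 = 1:1000), "fmo", role = "FMO-control")
#' fmo_background_gate(ctl, "Ki67")$threshold  # 970
#' @export
fmo_background_gate <- function(control, channel, background = 0.03) {
  stopifnot(inherits(control, "event_table"))
  if (!identical(control$role, "FMO-control"))
    stop("fmo_background_gate: control must have role 'FMO-control'")
  if (background <= 0 || background >= 1)
    stop("fmo_background_gate: background must lie in (0, 1)")
  x <- channel_values(control, channel)
  n <- length(x)
  if (n < 1L) stop("fmo_background_gate: empty channel")
  if (n < 1 / background)
    warning("fmo_background_gate: fewer than 1/background events; ",
            "the background quantile is unstable")
  xs <- sort(x)
  # order statistic at the (1 - background) quantile: 'background' of the
  # control sits at or above it, and strictly fewer than 'background' above
  threshold <- xs[max(1L, ceiling((1 - background) * n))]
  gate_set(channel, threshold, "fmo-3pct",
           control_sample_id = control$sample_id,
           percent_positive = 100 * mean(x > threshold))
}

shared_breaks <- function(xs, xc, bins) {
  rng <- range(c(xs, xc))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = bins + 1L)
}

#' Overton percentile-by-percentile histogram subtraction
#'
#' Estimates the percent of marker-positive events in a sample by
#' subtracting a biological control's normalized histogram channel by
#' channel. Both histograms are binned on a shared equal-width grid, the
#' per-bin difference (sample minus control) is accumulated, and the
#' percent positive is the sum of positive differences above the channel
#' where the cumulative difference is minimal (the point of maximal
#' control excess). The result is clamped to \[0, 100\].
#'
#' @param sample,control [event_table]s sharing `channel`.
#' @param channel channel name.
#' @param bins number of equal-width histogram bins over the pooled range
#'   (default 256, the classic cytometer channel count), or a numeric
#'   vector of explicit break points covering both samples.
#' @return A list with `percent_positive` and `gate` (a [gate_set] whose
#'   threshold is the upper edge of the minimal-cumulative-difference bin).
#' @examples
#' s <- event_table(data.frame(GFP = c(rlnorm(500), rlnorm(500, 3))), "s")
#' c0 <- event_table(data.frame(GFP = rlnorm(500)), "c",
#'                   role = "biological-control")
#' overton_subtraction(s, c0, "GFP")$percent_positive  # about 50
#' @export
overton_subtraction <- function(sample, control, channel, bins = 256L) {
  xs <- channel_values(sample, channel)
  xc <- channel_values(control, channel)
  if (length(xs) < 1L || length(xc) < 1L)
    stop("overton_subtraction: empty channel")
  breaks <- if (length(bins) > 1L) sort(as.numeric(bins))
            else shared_breaks(xs, xc, bins)
  if (min(breaks) > min(xs, xc) || max(breaks) < max(xs, xc))
    stop("overton_subtraction: breaks must cover both samples")
  bin_rel_freq <- function(x) {
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = length(breaks) - 1L) / length(x)
  }
  hs <- bin_rel_freq(xs)
  hc <- bin_rel_freq(xc)
  if (sum(hs > 0 | hc > 0) < 2L)
    stop("overton_subtraction: fewer than 2 occupied bins; ",
         "increase 'bins' or check the data")
  d <- hs - hc
  cum <- cumsum(d)
  jmin <- which.min(cum)
  pos <- if (jmin < length(d)) sum(pmax(d[(jmin + 1L):length(d)], 0)) else 0
  pct <- min(max(100 * pos, 0), 100)
  gate <- gate_set(channel, breaks[jmin + 1L], "overton",
                   control_sample_id = control$sample_id,
                   percent_positive = pct)
  list(percent_positive = pct, gate = gate)
}

#' Maximum difference gate
#'
#' Places the threshold at the intensity where the control's empirical CDF
#' exceeds the sample's by the most (the Kolmogorov-Smirnov location), and
#' reports percent positive as the sample's exceedance above the threshold
#' minus the control's, clamped to \[0, 100\]. Used when the sample's
#' cumulative curve is not a uniform rightward shift of the control's.
#'
#' @inheritParams overton_subtraction
#' @return A [gate_set] with `method = "max-difference"`. When the two
#'   distributions are indistinguishable (maximum difference 0) the gate is
#'   flagged `degenerate` with 0% positive.
#' @export
max_difference_gate <- function(sample, control, channel) {
  xs <- channel_values(sample, channel)
  xc <- channel_values(control, channel)
  if (length(xs) < 1L || length(xc) < 1L)
    stop("max_difference_gate: empty channel")
  grid <- sort(unique(c(xs, xc)))
  Fs <- stats::ecdf(xs)(grid)
  Fc <- stats::ecdf(xc)(grid)
  dd <- Fc - Fs
  imax <- which.max(dd)
  threshold <- grid[imax]
  degenerate <- dd[imax] <= 0
  pct <- if (degenerate) 0 else
    min(max(100 * (mean(xs > threshold) - mean(xc > threshold)), 0), 100)
  gate_set(channel, threshold, "max-difference",
           control_sample_id = control$sample_id,
           percent_positive = pct, degenerate = degenerate)
}

#' Test for a uniform rightward shift of the cumulative curve
#'
#' `TRUE` when the sample's empirical CDF lies at or below the control's
#' (plus a tolerance) at every pooled event value, i.e. the sample
#' stochastically dominates the control. This is the dispatch condition
#' for choosing Overton subtraction over the maximum difference method.
#'
#' @inheritParams overton_subtraction
#' @param tolerance allowed CDF excess; default twice the two-sample
#'   Kolmogorov-Smirnov critical value at alpha = 0.05,
#'   `2 * 1.358 * sqrt((n1 + n2) / (n1 * n2))`.
#' @return logical scalar.
#' @export
uniform_shift_test <- function(sample, control, channel, tolerance = NULL) {
  xs <- channel_values(sample, channel)
  xc <- channel_values(control, channel)
  if (length(xs) < 1L || length(xc) < 1L)
    stop("uniform_shift_test: empty channel")
  n1 <- as.numeric(length(xs)); n2 <- as.numeric(length(xc))
  if (is.null(tolerance))
    tolerance <- 2 * 1.358 * sqrt((n1 + n2) / (n1 * n2))
  grid <- sort(unique(c(xs, xc)))
  all(stats::ecdf(xs)(grid) <= stats::ecdf(xc)(grid) + tolerance)
}

#' Dispatch rule for gate derivation
#'
#' FMO controls get the 3% background gate. Against a biological control,
#' Overton subtraction is used when the sample's cumulative curve is
#' uniformly shifted to higher fluorescence ([uniform_shift_test]);
#' otherwise the maximum difference method is used.
#'
#' @inheritParams overton_subtraction
#' @param background background rate passed to [fmo_background_gate].
#' @param tolerance passed to [uniform_shift_test].
#' @return A [gate_set]; its `method` records the choice made.
#' @export
select_gating_method <- function(sample, control, channel,
                                 background = 0.03, bins = 256L,
                                 tolerance = NULL) {
  if (is.null(control) || !inherits(control, "event_table"))
    stop("select_gating_method: no control sample available for channel '",
         channel, "'")
  if (identical(control$role, "FMO-control"))
    return(fmo_background_gate(control, channel, background))
  if (!identical(control$role, "biological-control"))
    stop("select_gating_method: control role must be 'FMO-control' or ",
         "'biological-control'")
  if (uniform_shift_test(sample, control, channel, tolerance))
    overton_subtraction(sample, control, channel, bins)$gate
  else
    max_difference_gate(sample, control, channel)
}

#' Quadrant gating in two dimensions
#'
#' Applies two independent 1D gates on distinct channels and labels every
#' event with its quadrant. Positivity is strictly-above on each axis.
#'
#' @param events an [event_table] containing both gated channels.
#' @param gate_x,gate_y [gate_set]s on distinct channels of `events`.
#' @return A factor of length `n_events(events)` with levels
#'   `"-/-"`, `"+/-"`, `"-/+"`, `"+/+"` (x sign first).
#' @export
apply_gates_2d <- function(events, gate_x, gate_y) {
  stopifnot(inherits(gate_x, "gate_set"), inherits(gate_y, "gate_set"))
  if (identical(gate_x$channel, gate_y$channel))
    stop("apply_gates_2d: gates must be on distinct channels")
  x <- channel_values(events, gate_x$channel)
  y <- channel_values(events, gate_y$channel)
  px <- x > gate_x$threshold
  py <- y > gate_y$threshold
  lab <- ifelse(px & py, "+/+",
         ifelse(px & !py, "+/-",
         ifelse(!px & py, "-/+", "-/-")))
  factor(lab, levels = c("-/-", "+/-", "-/+", "+/+"))
}
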