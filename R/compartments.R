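#' Compartment labels
#'
#' The four operational differentiation compartments by Ki67 x aCasp3
#' quadrant: quiescent stem-like (both negative), proliferating stem-like
#' (Ki67+ only), transient-amplifying-like (both positive), terminally
#' differentiated / apoptotic-like (aCasp3+ only).
#' @keywords internal
compartment_levels <- c("qSC", "pSC", "TA", "TD")

#' Classify GFP+ events into differentiation compartments
#'
#' Maps each GFP+ event to one of the four compartments by its Ki67 and
#' aCasp3 positivity (strictly above the gate threshold): Ki67+ aCasp3- is
#' proliferating stem-like (pSC), Ki67+ aCasp3+ transient-amplifying-like
#' (TA), Ki67- aCasp3+ terminally differentiated / apoptotic-like (TD),
#' and Ki67- aCasp3- quiescent stem-like (qSC). The caller applies the GFP
#' gate first; compartment fractions are percentages of GFP+ events.
#'
#' @param gfp_events an [event_table] restricted to GFP+ events (may have
#'   zero rows only via the `gfp_load` path: a table with no events is
#'   expressed by `gfp_load = 0` and `NULL` events).
#' @param ki67_gate,acasp3_gate [gate_set]s on the Ki67 and aCasp3
#'   channels.
#' @param gfp_load percent of all acquired events that were GFP+, when
#'   known (carried into the profile).
#' @param mass tissue mass in mg; when available the profile also reports
#'   `gfp_mass = gfp_load/100 * mass`.
#' @return list with `labels` (factor over qSC/pSC/TA/TD per event) and
#'   `profile`, a one-row data frame (`sample_id`, `gfp_load`, `qSC`,
#'   `pSC`, `TA`, `TD` in percent of GFP+ events, `gfp_mass`). With zero
#'   GFP+ events the fractions are `NA` (missing, not 0) and the load is
#'   reported as passed (0 by default).
#' @export
classify_compartments <- function(gfp_events, ki67_gate, acasp3_gate,
                                  gfp_load = NA_real_, mass = NA_real_) {
  sample_id <- if (is.null(gfp_events)) NA_character_ else gfp_events$sample_id
  if (!is.na(mass) || is.null(gfp_events)) m <- mass
  else m <- gfp_events$mass
  if (is.null(gfp_events) || n_events(gfp_events) == 0L) {
    load <- if (is.na(gfp_load)) 0 else gfp_load
    return(list(
      labels = factor(character(0), levels = compartment_levels),
      profile = data.frame(sample_id = sample_id, gfp_load = load,
                           qSC = NA_real_, pSC = NA_real_, TA = NA_real_,
                           TD = NA_real_,
                           gfp_mass = if (is.na(m)) NA_real_
                                      else load / 100 * m)))
  }
  ki <- channel_values(gfp_events, ki67_gate$channel) > ki67_gate$threshold
  ac <- channel_values(gfp_events, acasp3_gate$channel) > acasp3_gate$threshold
  lab <- ifelse(ki & !ac, "pSC",
         ifelse(ki & ac, "TA",
         ifelse(!ki & ac, "TD", "qSC")))
  labels <- factor(lab, levels = compartment_levels)
  frac <- 100 * as.numeric(table(labels)) / length(labels)
  profile <- data.frame(sample_id = sample_id, gfp_load = gfp_load,
                        qSC = frac[1], pSC = frac[2], TA = frac[3],
                        TD = frac[4],
                        gfp_mass = if (is.na(m) || is.na(gfp_load))
                          NA_real_ else gfp_load / 100 * m)
  list(labels = labels, profile = profile)
}

#' Metastatic load: percent GFP+ events
#'
#' @param events an [event_table].
#' @param gfp_gate a [gate_set] on the GFP channel.
#' @return percent of events strictly above the gate, in \[0, 100\].
#' @export
metastatic_load <- function(events, gfp_gate) {
  stopifnot(inherits(gfp_gate, "gate_set"))
  x <- channel_values(events, gfp_gate$channel)
  if (length(x) == 0L) stop("metastatic_load: empty event table")
  100 * mean(x > gfp_gate$threshold)
}

#' Relative differences against a reference group
#'
#' Group effects are reported as relative differences in percent with the
#' control (reference) group value in the denominator:
#' `100 * (x - ref) / ref`.
#'
#' @param group_means numeric vector of group means.
#' @param reference index of the reference (control) group; default 1.
#' @return numeric vector, same length; the reference entry is 0.
#' @examples
#' relative_difference(c(0.33, 0.22))  # 0, -33.33
#' @export
relative_difference <- function(group_means, reference = 1L) {
  ref <- group_means[reference]
  if (is.na(ref) || ref == 0)
    stop("relative_difference: reference mean must be nonzero")
  100 * (group_means - ref) / ref
}

#' Power-law relationship between two mass variables
#'
#' Fits `y = b * x^a` by least squares on the log-log scale (equivalently,
#' a Gaussian fit of `log y` on `log x`), reports `a` (with its SE), `b`,
#' an R-squared on the original scale, and the comparison against the
#' horizontal-line null (constant `log y`) by AIC difference, evidence
#' ratio and extra-sum-of-squares F test. Used for the relationship
#' between the GFP+ cell mass infiltrating an implant and the GFP+ mass in
#' the lungs.
#'
#' @param x_masses,y_masses positive masses (mg), `n >= 3`.
#' @return An object of class `power_law_relation`: `a`, `se_a`, `b`,
#'   `R2` (original scale), `comparison` (a `model_comparison` vs the
#'   constant null on the log scale), and the log-scale `trend_fit`.
#' @examples
#' x <- c(1, 2, 4, 8, 16)
#' fit_power_relation(x, 2 * x^-0.5)
#' @export
fit_power_relation <- function(x_masses, y_masses) {
  x <- as.numeric(x_masses); y <- as.numeric(y_masses)
  if (length(x) != length(y)) stop("fit_power_relation: length mismatch")
  if (length(x) < 3L) stop("fit_power_relation: need at least 3 points")
  if (any(x <= 0) || any(y <= 0))
    stop("fit_power_relation: masses must be positive (log undefined)")
  lx <- log(x); ly <- log(y)
  alt <- fit_trend(lx, ly, "linear")
  null <- fit_trend(lx, ly, "constant")
  a <- unname(alt$coefficients["g"])
  b <- exp(unname(alt$coefficients["(Intercept)"]))
  # classical SE of the slope (n - 2 denominator)
  n <- length(x)
  se_a <- if (n > 2) sqrt(sum(alt$residuals^2) / (n - 2) /
                            sum((lx - mean(lx))^2)) else NA_real_
  yhat <- b * x^a
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - yhat)^2) / tss else 0
  structure(
    list(a = a, se_a = se_a, b = b, R2 = r2,
         comparison = compare_models(alt, null), fit_log = alt),
    class = "power_law_relation"
  )
}

#' @export
print.power_law_relation <- function(x, ...) {
  cat(sprintf(
    "<power_law_relation> y = %.4g * x^%.4g (SE a %.3g) | R2=%.3f dAIC=%.4g ER=%.4g p=%.4g\n",
    x$b, x$a, x$se_a, x$R2, x$comparison$delta_aic, x$comparison$er,
    x$comparison$p))
  invisible(x)
}

#' Ternary (compositional) coordinates of a compartment profile
#'
#' Merges the four compartments to three parts (default: qSC and pSC
#' pooled as SC), renormalizes to sum 1, and returns both the 3-part
#' composition and its 2-simplex plotting coordinates
#' (`x = c2 + c3/2`, `y = c3 * sqrt(3)/2` for composition `(c1, c2, c3)`).
#'
#' @param fractions named numeric vector with entries `qSC`, `pSC`, `TA`,
#'   `TD` (percent or proportions; only ratios matter).
#' @param merge named character vector mapping each compartment to its
#'   merged part; default pools the stem compartments.
#' @return list with `composition` (named, sums to 1) and `xy`.
#' @export
ternary_coordinates <- function(fractions,
                                merge = c(qSC = "SC", pSC = "SC",
                                          TA = "TA", TD = "TD")) {
  stopifnot(all(compartment_levels %in% names(fractions)),
            all(compartment_levels %in% names(merge)))
  f <- as.numeric(fractions[compartment_levels])
  if (any(is.na(f))) stop("ternary_coordinates: missing fractions")
  parts <- tapply(f, merge[compartment_levels], sum)
  parts <- stats::setNames(as.numeric(parts), names(parts))
  total <- sum(parts)
  if (total <= 0) stop("ternary_coordinates: all-zero composition")
  comp <- parts / total
  # keep the merged parts in first-appearance order of the merge rule
  ord <- unique(unname(merge[compartment_levels]))
  comp <- comp[ord]
  xy <- c(x = unname(comp[2] + comp[3] / 2),
          y = unname(comp[3] * sqrt(3) / 2))
  list(composition = comp, xy = xy)
}
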