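#' Specification of a synthetic flow-cytometry cohort
#'
#' Describes the study design the flow generator emulates: four treatment
#' groups of mice (control surgery, plain scaffold implant, VEGF-enriched
#' implant, tumor-free VEGF implant), each with a per-mouse GFP+ load
#' distribution, a compartment mixture over (qSC, pSC, TA, TD) for the
#' GFP+ events, per-channel log-normal intensity models for
#' marker-positive and marker-negative events, and a tissue-mass range.
#'
#' Defaults follow the study conditions: group sizes 5/5/7/3; lung loads
#' Gaussian(0.33, 0.09)% for the control group, Gaussian(0.22, 0.13)% for
#' the plain implant group, exponential(scale 0.7)% for the VEGF implant
#' group, and a point mass at 0 for the tumor-free group; lung metastases
#' essentially pure TA in the surgery-only and plain-implant groups and
#' TA-dominant with a small quiescent admixture under VEGF enrichment.
#'
#' @param groups named integer vector: mice per group, in treatment order.
#' @param load_model named list per group: `list(family =, ...)` with
#'   family `"normal"` (`mu`, `sigma`, percent, truncated at 0),
#'   `"exponential"` (`beta`, percent) or `"point"` (`value`).
#' @param compartment_mix named list per group: probability vector over
#'   (qSC, pSC, TA, TD) summing to 1, or `NULL` for groups without GFP+
#'   cells.
#' @param events_per_sample events acquired per sample; default 1e6 (the
#'   acquisition depth is not part of the study record; this default is a
#'   configuration guess, scale it down for quick runs).
#' @param channel_model per-channel list with `neg = c(meanlog, sdlog)`
#'   and `pos = c(meanlog, sdlog)` log-normal components.
#' @param mass_range uniform tissue-mass range in mg.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c(control = 5L, pcl = 5L, `pcl-vegf` = 7L,
                                   `vegf-only` = 3L),
                        load_model = NULL,
                        compartment_mix = NULL,
                        events_per_sample = 1e6,
                        channel_model = NULL,
                        mass_range = c(100, 250),
                        seed = 20230413L) {
  if (is.null(load_model))
    load_model <- list(
      control = list(family = "normal", mu = 0.33, sigma = 0.09),
      pcl = list(family = "normal", mu = 0.22, sigma = 0.13),
      `pcl-vegf` = list(family = "exponential", beta = 0.7),
      `vegf-only` = list(family = "point", value = 0)
    )[names(groups)]
  if (is.null(compartment_mix))
    compartment_mix <- list(
      control = c(qSC = 0, pSC = 0, TA = 1, TD = 0),
      pcl = c(qSC = 0, pSC = 0, TA = 1, TD = 0),
      `pcl-vegf` = c(qSC = 0.06, pSC = 0.02, TA = 0.9126, TD = 0.0074) /
        sum(c(0.06, 0.02, 0.9126, 0.0074)),
      `vegf-only` = NULL
    )[names(groups)]
  if (is.null(channel_model))
    channel_model <- list(
      GFP = list(neg = c(log(100), 0.5), pos = c(log(2000), 0.5)),
      Ki67 = list(neg = c(log(100), 0.5), pos = c(log(2000), 0.5)),
      aCasp3 = list(neg = c(log(100), 0.5), pos = c(log(2000), 0.5))
    )
  stopifnot(all(groups >= 1L), length(load_model) == length(groups),
            events_per_sample >= 1)
  for (g in names(groups)) {
    lm <- load_model[[g]]
    if (is.null(lm) || is.null(lm$family))
      stop("cohort_spec: load_model missing for group '", g, "'")
    pars <- unlist(lm[names(lm) != "family"])
    if (any(pars < 0))
      stop("cohort_spec: load parameters must be nonnegative ('", g, "')")
    mix <- compartment_mix[[g]]
    if (!is.null(mix)) {
      if (length(mix) != 4L || abs(sum(mix) - 1) > 1e-8 || any(mix < 0))
        stop("cohort_spec: compartment_mix for '", g,
             "' must be 4 nonnegative probabilities summing to 1")
    }
  }
  structure(
    list(groups = groups, load_model = load_model,
         compartment_mix = compartment_mix,
         events_per_sample = events_per_sample,
         channel_model = channel_model, mass_range = mass_range,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

draw_load_pct <- function(model, n) {
  switch(model$family,
    normal = pmax(stats::rnorm(n, model$mu, model$sigma), 0),
    exponential = stats::rexp(n, rate = 1 / model$beta),
    point = rep(model$value, n),
    stop("unknown load family '", model$family, "'")
  )
}

draw_channel <- function(cm, positive) {
  n <- length(positive)
  out <- numeric(n)
  npos <- sum(positive)
  if (npos > 0)
    out[positive] <- stats::rlnorm(npos, cm$pos[1], cm$pos[2])
  if (npos < n)
    out[!positive] <- stats::rlnorm(n - npos, cm$neg[1], cm$neg[2])
  out
}

#' Generate a synthetic flow-cytometry cohort
#'
#' Simulates one lung sample per mouse plus matched controls. Each mouse's
#' true GFP+ fraction is drawn from its group's load model; each GFP+
#' event gets a compartment drawn from the group mixture, and its Ki67 /
#' aCasp3 intensities come from the positive or negative log-normal
#' component dictated by the compartment (pSC and TA are Ki67+, TA and TD
#' are aCasp3+). GFP- events are marker negative. Controls: one FMO
#' control per marker channel (that channel unstained, i.e. background
#' only) and one biological control (healthy tissue, all channels
#' background). Truth (true load, realized GFP+ count, compartment counts)
#' is retained in a sidecar table. Generation is reproducible under the
#' spec seed.
#'
#' @param spec a [cohort_spec].
#' @param control_events events per control sample; defaults to
#'   `spec$events_per_sample`.
#' @return list with `samples` (list of [event_table]), `controls`
#'   (named list: `fmo_Ki67`, `fmo_aCasp3`, `fmo_GFP`, `biological`), and
#'   `truth` (data frame: sample_id, group, mouse, tissue, mass,
#'   true_load_pct, n_events, n_gfp, and per-compartment true event
#'   counts).
#' @export
generate_flow_cohort <- function(spec, control_events = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(control_events)) control_events <- spec$events_per_sample
  set.seed(spec$seed)
  ne <- spec$events_per_sample

  # refuse designs whose positive loads are unresolvable at this depth
  for (g in names(spec$groups)) {
    lm <- spec$load_model[[g]]
    mean_load <- switch(lm$family, normal = lm$mu, exponential = lm$beta,
                        point = lm$value)
    expected_gfp <- ne * mean_load / 100
    if (mean_load > 0 && expected_gfp < 10)
      stop("generate_flow_cohort: group '", g, "' expects ~",
           round(expected_gfp, 2), " GFP+ events per sample at ",
           format(ne, scientific = TRUE), " events; increase ",
           "events_per_sample (need >= ", ceiling(1000 / mean_load),
           ") or the load")
  }

  cm <- spec$channel_model
  samples <- list()
  truth <- list()
  for (g in names(spec$groups)) {
    n_mice <- spec$groups[[g]]
    loads <- draw_load_pct(spec$load_model[[g]], n_mice)
    mix <- spec$compartment_mix[[g]]
    for (i in seq_len(n_mice)) {
      sid <- sprintf("%s_m%02d_lung", g, i)
      mass <- stats::runif(1, spec$mass_range[1], spec$mass_range[2])
      n_gfp <- stats::rbinom(1, ne, loads[i] / 100)
      gfp_pos <- c(rep(TRUE, n_gfp), rep(FALSE, ne - n_gfp))
      comp_counts <- c(qSC = 0L, pSC = 0L, TA = 0L, TD = 0L)
      ki_pos <- ac_pos <- rep(FALSE, ne)
      if (n_gfp > 0) {
        if (is.null(mix))
          stop("generate_flow_cohort: group '", g, "' generated GFP+ ",
               "events but has no compartment_mix")
        comp <- sample(compartment_levels, n_gfp, replace = TRUE,
                       prob = mix)
        comp_counts <- vapply(compartment_levels,
                              function(l) sum(comp == l), integer(1))
        ki_pos[seq_len(n_gfp)] <- comp %in% c("pSC", "TA")
        ac_pos[seq_len(n_gfp)] <- comp %in% c("TA", "TD")
      }
      channels <- data.frame(
        GFP = draw_channel(cm$GFP, gfp_pos),
        Ki67 = draw_channel(cm$Ki67, ki_pos),
        aCasp3 = draw_channel(cm$aCasp3, ac_pos)
      )
      samples[[sid]] <- event_table(channels, sid, tissue = "lung",
                                    group = g, mass = mass)
      truth[[sid]] <- data.frame(
        sample_id = sid, group = g, mouse = i, tissue = "lung",
        mass = mass, true_load_pct = loads[i], n_events = ne,
        n_gfp = n_gfp, qSC = comp_counts[["qSC"]],
        pSC = comp_counts[["pSC"]], TA = comp_counts[["TA"]],
        TD = comp_counts[["TD"]])
    }
  }

  all_neg <- function(n) rep(FALSE, n)
  make_control <- function(sid, omit, role) {
    chans <- data.frame(
      GFP = draw_channel(cm$GFP, if (omit %in% c("GFP", "all"))
        all_neg(control_events) else stats::runif(control_events) < 0.003),
      Ki67 = draw_channel(cm$Ki67, if (omit %in% c("Ki67", "all"))
        all_neg(control_events) else stats::runif(control_events) < 0.2),
      aCasp3 = draw_channel(cm$aCasp3, if (omit %in% c("aCasp3", "all"))
        all_neg(control_events) else stats::runif(control_events) < 0.2)
    )
    event_table(chans, sid, tissue = "control", group = "control-sample",
                role = role)
  }
  controls <- list(
    fmo_GFP = make_control("fmo_GFP", "GFP", "FMO-control"),
    fmo_Ki67 = make_control("fmo_Ki67", "Ki67", "FMO-control"),
    fmo_aCasp3 = make_control("fmo_aCasp3", "aCasp3", "FMO-control"),
    biological = make_control("bio_control", "all", "biological-control")
  )
  list(samples = samples, controls = controls,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
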