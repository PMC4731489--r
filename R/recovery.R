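#' Closed-form expected value of a built-in contrast
#'
#' Analytic expectation of the window-mean contrast amplitude a noiseless
#' pipeline would measure on the default simulation: for every template
#' locked to the same events as the contrast, the injected
#' condition-amplitude difference times its weight at the measurement
#' channel times the window mean of its Gaussian envelope (components
#' locked to the same event overlap each other, e.g. the N1 and P2 of the
#' corollary-discharge complex, and both terms are included). Topographies
#' are zero-sum so average referencing adds nothing. Serves as the
#' independent oracle for the recovery tests; it never touches simulated
#' data.
#'
#' @param name contrast name from [builtin_contrasts()].
#' @param templates template list (default [default_templates()]); only
#'   latencies/widths are read, amplitude differences are the documented
#'   injected values.
#' @param level game level the contrast is evaluated in (scales N170).
#' @param cd_attenuation,level_scale must match the values the templates
#'   were built with.
#' @return expected window-mean amplitude in microvolts.
#' @export
expected_contrast_value <- function(name, templates = default_templates(),
                                    level = "Who", cd_attenuation = 0.5,
                                    level_scale = c(Learn = 0.7, Who = 0.85, Discern = 1)) {
  spec <- builtin_contrasts()[[name]]
  abort_if(is.null(spec), "unknown contrast: %s", name)
  # injected A-minus-B amplitude difference per same-lock template, with
  # the template's weight at the contrast's measurement channel
  contrib <- switch(name,
    C1 = list(C1 = c(-2, 1)),
    P50 = list(P50 = c(1, 0.8)),
    MMN = list(MMN = c(-2.5, 0.8)),
    N1 = list(N1 = c(-4 * (1 - cd_attenuation), 1),
              P2 = c(3 * (1 - cd_attenuation), 1)),
    P2 = list(P2 = c(3 * (1 - cd_attenuation), 1),
              N1 = c(-4 * (1 - cd_attenuation), 1)),
    N170 = list(N170 = c(-3 * level_scale[[level]], 1)),
    N2pc = list(N2pc = c(-1.5, 1)),
    LRP = list(LRP = c(-2, 1)),
    P300 = list(P300 = c(4, 1)),
    ERN = list(ERN = c(-3, 1)))
  sum(vapply(names(contrib), function(tn) {
    injected_contrast_value(templates[[tn]], contrib[[tn]][1], contrib[[tn]][2],
                            mean_weight = 0, window_ms = spec$window_ms)
  }, numeric(1)))
}

#' End-to-end recovery experiment for all built-in contrasts
#'
#' Simulates `n_runs` independent runs of all three game levels, pushes
#' each recording through the full chain (band-pass filter, average
#' reference, epoch, baseline correction, threshold rejection), pools
#' epochs over runs, and measures every registered contrast at the level
#' the condition-average figures use: Who for C1, the corollary-discharge
#' N1/P2, N2pc, LRP and P300; Discern for N170 and ERN; all levels
#' collapsed for the auditory P50 and MMN. Measured window-mean amplitudes
#' are compared with the closed-form injected expectation
#' ([expected_contrast_value()]).
#'
#' @param seed integer seed; run r of level l uses sub-seed
#'   `seed*1000 + 10*r + l`.
#' @param n_runs number of simulated three-level runs (3 by default, which
#'   gives every visual/response condition cell at least 40 epochs).
#' @param tone_runs number of Learn+Discern runs pooled for the paired-tone
#'   contrasts (P50/MMN). Deviant tones are rare by design (8 per level),
#'   so these cells are the variance bottleneck: 12 runs give 192 deviant
#'   epochs, enough for the window-mean estimator's standard error to sit
#'   well inside the 20% recovery band.
#' @param profile,templates,config simulation configuration.
#' @param srate sampling rate (Hz).
#' @return data frame: contrast `name`, `levels` used, epochs per cell
#'   (`n_A`, `n_B`), `measured`, `expected`, `rel_error`.
#' @export
recovery_experiment <- function(seed = 1, n_runs = 3, tone_runs = 12,
                                profile = default_profile(),
                                templates = default_templates(),
                                config = paradigm_config(), srate = 250) {
  specs <- builtin_contrasts()
  # P50/MMN are collapsed over the two levels without response-triggered
  # tones: the Who corollary-discharge tones overlap the paired-tone
  # epochs at the same fronto-central channels and would bias the
  # recovered amplitudes
  plan <- list(C1 = "Who", P50 = c("Learn", "Discern"),
               MMN = c("Learn", "Discern"), N1 = "Who",
               P2 = "Who", N170 = "Discern", N2pc = "Who", LRP = "Who",
               P300 = "Who", ERN = "Discern")
  tone_contrasts <- c("P50", "MMN")
  # per contrast: list of pooled epochs, gathered level by level
  pooled <- stats::setNames(vector("list", length(specs)), names(specs))
  for (r in seq_len(max(n_runs, tone_runs))) {
    for (li in seq_along(GAME_LEVELS)) {
      lv <- GAME_LEVELS[li]
      full_run <- r <= n_runs
      tone_run <- r <= tone_runs && lv %in% c("Learn", "Discern")
      if (!full_run && !tone_run) next
      wanted <- names(specs)[vapply(names(specs), function(nm) {
        lv %in% plan[[nm]] &&
          ((nm %in% tone_contrasts && tone_run) ||
           (!nm %in% tone_contrasts && full_run))
      }, logical(1))]
      if (length(wanted) == 0) next
      sub_seed <- seed * 1000 + 10 * r + li
      sch <- generate_level(lv, config, seed = sub_seed)
      rec <- simulate_recording(sch, profile = profile, templates = templates,
                                seed = sub_seed + 1, srate = srate)
      rec <- average_reference(filter_band(rec))
      for (nm in wanted) {
        spec <- specs[[nm]]
        ev <- rec$events[rec$events$event_type %in% spec$event_type, ]
        if (nrow(ev) == 0) next
        ep <- epoch(rec, ev, lock = spec$lock, window_ms = spec$epoch_window_ms,
                    channels = spec$channels)
        ep <- baseline_correct(ep, spec$baseline_ms)
        pooled[[nm]] <- c(pooled[[nm]], list(ep))
      }
      rm(rec)
    }
  }
  rows <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    ep <- pool_epochs(pooled[[nm]])
    ep <- reject_epochs(ep, 100)
    res <- contrast_from_epochs(ep, spec)
    lv_for_exp <- if (length(plan[[nm]]) > 1) "Discern" else plan[[nm]]
    expd <- expected_contrast_value(nm, templates, level = lv_for_exp)
    ns <- cell_counts(ep, spec)
    data.frame(name = nm, levels = paste(plan[[nm]], collapse = "+"),
               n_A = ns[1], n_B = ns[2], measured = res$amplitude,
               expected = expd,
               rel_error = abs(res$amplitude - expd) / abs(expd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

cell_counts <- function(ep, spec) {
  if (spec$arithmetic == "factor") {
    f <- spec$factor_fun(ep$labels)
    range(table(f))
  } else {
    c(sum(resolve_predicate(spec$cond_A, ep$labels)),
      sum(resolve_predicate(spec$cond_B, ep$labels)))
  }
}
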