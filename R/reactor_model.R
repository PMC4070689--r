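# SBR mass-balance layer: HRT/SRT arithmetic, the no-growth washout curve,
# the selective-recession detector, and the substrate-share estimator.

#' Sequencing batch reactor configuration
#'
#' Defaults describe a 10 L laboratory SBR fed 5 L of synthetic wastewater
#' per cycle through a 5/55/120/45/15 min feed/anaerobic/aerobic/settle/
#' decant sequence (4 h cycles, nominal HRT 8 h) at a nominal solids
#' retention time of 10 d, with excess sludge withdrawn once per cycle
#' during the aerobic phase.
#'
#' @param working_volume reactor working volume, liters.
#' @param feed_volume feed volume per cycle, liters (must not exceed the
#'   working volume).
#' @param phases named numeric vector of phase durations in minutes:
#'   `feed`, `anaerobic`, `aerobic`, `settle`, `decant`.
#' @param srt nominal solids retention time, days.
#' @return object of class `reactor_config`.
#' @export
reactor_config <- function(working_volume = 10, feed_volume = 5,
                           phases = c(feed = 5, anaerobic = 55, aerobic = 120,
                                      settle = 45, decant = 15),
                           srt = 10) {
  fail_if(any(c(working_volume, feed_volume, phases, srt) <= 0),
          "all reactor parameters must be positive")
  fail_if(feed_volume > working_volume, "feed volume cannot exceed working volume")
  structure(list(working_volume = working_volume, feed_volume = feed_volume,
                 phases = phases, srt = srt),
            class = "reactor_config")
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("SBR config:", x$working_volume, "L, feed", x$feed_volume,
      "L/cycle, cycle", sum(x$phases), "min, SRT", x$srt, "d\n")
  invisible(x)
}

#' Cycle length in days
#' @param config a [reactor_config()].
#' @return cycle length in days.
#' @export
cycle_length_days <- function(config) {
  stopifnot(inherits(config, "reactor_config"))
  sum(config$phases) / (24 * 60)
}

#' Nominal hydraulic retention time
#'
#' HRT = working volume / volumetric feed rate, where the feed rate is the
#' feed volume per cycle divided by the cycle length.
#'
#' @param config a [reactor_config()].
#' @return nominal HRT in hours.
#' @examples
#' nominal_hrt(reactor_config())  # 8 h
#' @export
nominal_hrt <- function(config) {
  stopifnot(inherits(config, "reactor_config"))
  fail_if(config$feed_volume <= 0, "feed volume must be positive")
  cycle_h <- sum(config$phases) / 60
  config$working_volume / (config$feed_volume / cycle_h)
}

#' Per-cycle biomass wastage fraction implied by the SRT
#'
#' With excess sludge withdrawn once per cycle, the fraction `w` of biomass
#' wasted per cycle of length \eqn{\Delta t} follows from the SRT. The
#' default `"exact"` form \eqn{w = 1 - e^{-\Delta t / \mathrm{SRT}}} makes
#' the discrete per-cycle decay coincide with continuous first-order washout
#' \eqn{e^{-t/\mathrm{SRT}}} on the cycle grid; the `"nominal"` small-
#' fraction form \eqn{w = \Delta t / \mathrm{SRT}} differs from it at order
#' \eqn{w^2} per cycle.
#'
#' @param config a [reactor_config()].
#' @param mode `"exact"` (default) or `"nominal"`.
#' @return wastage fraction per cycle, in (0, 1).
#' @export
wastage_fraction_per_cycle <- function(config, mode = c("exact", "nominal")) {
  stopifnot(inherits(config, "reactor_config"))
  mode <- match.arg(mode)
  dt <- cycle_length_days(config)
  fail_if(config$srt <= 0, "SRT must be positive")
  switch(mode,
         exact = 1 - exp(-dt / config$srt),
         nominal = dt / config$srt)
}

#' Expected no-growth washout curve
#'
#' The expected fraction of an OTU under the null hypothesis that its growth
#' stopped entirely at day `t0` while the rest of the community holds total
#' biomass at steady state, so the OTU is diluted out solely by excess-sludge
#' withdrawal: `continuous` mode gives
#' \eqn{f(t) = f_0 e^{-(t - t_0)/\mathrm{SRT}}}; `per_cycle` mode multiplies
#' \eqn{f_0} by \eqn{(1 - w)} for each completed cycle.
#'
#' @param f0 anchoring fraction (percent, > 0) observed at `t0`.
#' @param t0 anchor day (user-chosen; typically the last observation before
#'   the suspected decline — never auto-detected).
#' @param days evaluation days (all >= `t0`).
#' @param config a [reactor_config()].
#' @param mode `"continuous"` (default) or `"per_cycle"`.
#' @param wastage wastage form for `per_cycle` mode, see
#'   [wastage_fraction_per_cycle()].
#' @return object of class `washout_curve`: data.frame with columns `day`,
#'   `expected` (percent), with `f0`, `t0`, `mode` attributes.
#' @export
expected_no_growth_curve <- function(f0, t0, days, config,
                                     mode = c("continuous", "per_cycle"),
                                     wastage = c("exact", "nominal")) {
  mode <- match.arg(mode)
  wastage <- match.arg(wastage)
  fail_if(f0 <= 0, "anchor fraction must be positive")
  fail_if(any(days < t0 - 1e-9), "evaluation days must not precede t0")
  expected <- switch(mode,
    continuous = f0 * exp(-(days - t0) / config$srt),
    per_cycle = {
      dt <- cycle_length_days(config)
      w <- wastage_fraction_per_cycle(config, wastage)
      n <- floor((days - t0) / dt + 1e-9)
      f0 * (1 - w)^n
    })
  out <- data.frame(day = days, expected = expected)
  attr(out, "f0") <- f0; attr(out, "t0") <- t0; attr(out, "mode") <- mode
  class(out) <- c("washout_curve", "data.frame")
  out
}

#' Detect an OTU receding faster than SRT washout
#'
#' Anchors the no-growth washout curve at the observed fraction of `otu` on
#' day `t0` and compares subsequent observations against it. The verdict is
#' `faster_than_washout` when at least `min_consecutive` consecutive sampled
#' points after `t0` have their confidence-interval upper bound strictly
#' below the expected curve (the population is vanishing faster than sludge
#' wastage alone can explain — e.g. selective lysis); `not_receding` when at
#' least `min_consecutive` consecutive points sit with their lower bound
#' above the curve; otherwise `consistent_with_washout`. With fewer than
#' `min_consecutive` points after `t0` the verdict is `insufficient_data`.
#'
#' @param series a `fraction_series` with confidence intervals.
#' @param otu OTU id present in `series`.
#' @param t0 anchor day (must be a sampled day with positive fraction).
#' @param config a [reactor_config()].
#' @param min_consecutive run length required for a verdict (default 2).
#' @param window_days restrict evaluation to `(t0, t0 + window_days]`
#'   (default `Inf`).
#' @param mode washout-curve mode, see [expected_no_growth_curve()].
#' @return object of class `recession_call`: list with `otu`, `t0`,
#'   `verdict`, `evidence` (data.frame: day, observed, lower, upper,
#'   expected).
#' @export
detect_selective_recession <- function(series, otu, t0, config,
                                       min_consecutive = 2L, window_days = Inf,
                                       mode = c("continuous", "per_cycle")) {
  stopifnot(inherits(series, "fraction_series"))
  mode <- match.arg(mode)
  fail_if(!otu %in% colnames(series$fractions), paste0("OTU not in series: ", otu))
  fail_if(is.null(series$day), "series must carry sampling days")
  fail_if(is.null(series$upper), "series must carry confidence intervals")
  i0 <- which(abs(series$day - t0) < 1e-9)
  fail_if(length(i0) != 1, "t0 must be a (unique) sampled day")
  f0 <- series$fractions[i0, otu]
  fail_if(f0 <= 0, "fraction at t0 must be positive")
  sel <- which(series$day > t0 + 1e-9 & series$day <= t0 + window_days)
  sel <- sel[order(series$day[sel])]
  if (length(sel) < min_consecutive) {
    out <- list(otu = otu, t0 = t0, verdict = "insufficient_data",
                reason = "fewer sampled points after t0 than min_consecutive",
                evidence = NULL)
    class(out) <- "recession_call"
    return(out)
  }
  curve <- expected_no_growth_curve(f0, t0, series$day[sel], config, mode = mode)
  evidence <- data.frame(
    day = series$day[sel],
    observed = series$fractions[sel, otu],
    lower = series$lower[sel, otu],
    upper = series$upper[sel, otu],
    expected = curve$expected
  )
  runlen <- function(flag) {
    if (!any(flag)) return(0L)
    r <- rle(flag)
    max(r$lengths[r$values])
  }
  below <- evidence$upper < evidence$expected
  above <- evidence$lower > evidence$expected
  verdict <- if (runlen(below) >= min_consecutive) {
    "faster_than_washout"
  } else if (runlen(above) >= min_consecutive) {
    "not_receding"
  } else {
    "consistent_with_washout"
  }
  structure(list(otu = otu, t0 = t0, verdict = verdict, evidence = evidence),
            class = "recession_call")
}

#' @export
print.recession_call <- function(x, ...) {
  cat("Recession call for", x$otu, "anchored at day", x$t0, ":", x$verdict, "\n")
  if (!is.null(x$evidence)) {
    print(format(x$evidence, digits = 3), row.names = FALSE)
  } else if (!is.null(x$reason)) cat("  (", x$reason, ")\n")
  invisible(x)
}

#' Share of total biomass production implied by a fraction change
#'
#' With total biomass at steady state, the community produces
#' \eqn{\Delta t/\mathrm{SRT}} new biomass per unit standing biomass over
#' \eqn{\Delta t} days (production balances wastage). An OTU moving from
#' fraction `f1` to `f2` must have produced its net gain plus what wastage
#' removed from it, approximated trapezoidally:
#' \deqn{\mathrm{focal} = (f_2 - f_1)/100 + \frac{f_1 + f_2}{200}
#'   \frac{\Delta t}{\mathrm{SRT}},}
#' and its share of total production is focal divided by
#' \eqn{\Delta t/\mathrm{SRT}}. Shares above 1 (growth exceeding the total
#' substrate supply — the steady-state assumption is violated) or below 0
#' (decline faster than washout) are flagged.
#'
#' @param f1,f2 fractions in percent at the start and end of the interval,
#'   both in (0, 100).
#' @param dt interval length, days (> 0).
#' @param config a [reactor_config()].
#' @return the share (numeric scalar) with attribute `flag` equal to
#'   `"ok"`, `"exceeds_supply"` or `"negative"`.
#' @examples
#' substrate_share(1.9, 29.9, dt = 5, config = reactor_config())
#' @export
substrate_share <- function(f1, f2, dt, config) {
  stopifnot(inherits(config, "reactor_config"))
  fail_if(dt <= 0, "dt must be positive")
  fail_if(f1 <= 0 || f1 >= 100 || f2 <= 0 || f2 >= 100,
          "fractions must be in (0, 100)")
  total <- dt / config$srt
  focal <- (f2 - f1) / 100 + ((f1 + f2) / 200) * total
  share <- focal / total
  attr(share, "flag") <- if (share > 1) "exceeds_supply" else
    if (share < 0) "negative" else "ok"
  share
}

#' Read / write a reactor configuration as plain-text key-value pairs
#'
#' Keys: `working_volume`, `feed_volume`, `phase_feed`, `phase_anaerobic`,
#' `phase_aerobic`, `phase_settle`, `phase_decant`, `srt`.
#'
#' @param config a [reactor_config()].
#' @param path file path.
#' @return `path` (write) or a `reactor_config` (read).
#' @export
write_reactor_config <- function(config, path) {
  stopifnot(inherits(config, "reactor_config"))
  lines <- c(
    paste0("working_volume=", config$working_volume),
    paste0("feed_volume=", config$feed_volume),
    paste0("phase_", names(config$phases), "=", config$phases),
    paste0("srt=", config$srt)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reactor_config
#' @export
read_reactor_config <- function(path) {
  kv <- read_key_values(path)
  phases <- c(feed = as.numeric(kv[["phase_feed"]]),
              anaerobic = as.numeric(kv[["phase_anaerobic"]]),
              aerobic = as.numeric(kv[["phase_aerobic"]]),
              settle = as.numeric(kv[["phase_settle"]]),
              decant = as.numeric(kv[["phase_decant"]]))
  reactor_config(working_volume = as.numeric(kv[["working_volume"]]),
                 feed_volume = as.numeric(kv[["feed_volume"]]),
                 phases = phases, srt = as.numeric(kv[["srt"]]))
}

# plain key=value reader (comments with '#', blank lines ignored)
read_key_values <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) < 2
  fail_if(any(bad), paste0("malformed key=value line in ", path))
  setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
           vapply(kv, `[`, character(1), 1L))
}

#' Benchmark the recession detector on planted lysis events
#'
#' Simulates `n_runs` independent reactor communities, each with one planted
#' lysis event (survival drawn in `[0.02, 0.1]`) in a community of `n_taxa`
#' taxa undergoing propagation/recession episodes (all growth rates
#' non-negative, so no taxon other than the lysed one can recede faster than
#' washout). Read counts are drawn multinomially at `depth` reads per sample
#' on a 2-day sampling grid, and [detect_selective_recession()] is run for
#' every taxon with the anchor placed at the last sample before the event.
#'
#' @param n_runs number of simulated communities (default 20).
#' @param n_taxa taxa per community (default 22).
#' @param depth reads per sample (default 2,000).
#' @param seed base seed; run `r` uses `seed + r`.
#' @param window_days detector window after the anchor (default 12).
#' @return data.frame with one row per run: `run`, `focal`, `survival`,
#'   `detected` (planted taxon flagged), `false_positives` (other taxa
#'   flagged).
#' @export
lysis_recovery_benchmark <- function(n_runs = 20L, n_taxa = 22L, depth = 2000L,
                                     seed = 1L, window_days = 12) {
  config <- reactor_config()
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r
    taxa_ids <- sprintf("taxon%02d", seq_len(n_taxa))
    res <- withr::with_seed(run_seed, {
      base <- 1 / config$srt
      horizon <- 60
      growth <- constant_growth(taxa_ids, base, horizon)
      focal <- sample(taxa_ids, 1L)
      survival <- runif(1, 0.02, 0.1)
      # focal propagates before the event so it is abundant when lysed
      growth <- overlay_episode(growth, focal, 32, 40, 0.45)
      # other taxa: episodes with non-negative rates
      for (tx in sample(setdiff(taxa_ids, focal), 5L)) {
        s <- runif(1, 20, 45)
        growth <- overlay_episode(growth, tx, s, s + 8, runif(1, 0.0, 0.3))
      }
      init <- setNames(rlnorm(n_taxa, 0, 0.4), taxa_ids)
      lysis <- data.frame(taxon_id = focal, day = 40.5, survival = survival)
      dyn <- dynamics_spec(init, growth, lysis)
      truth <- simulate_dynamics(dyn, config, horizon,
                                 sampling_days = seq(20, 60, by = 2))
      tab <- sample_counts(truth, depth, seed = run_seed * 13L)
      list(focal = focal, survival = survival, tab = tab)
    })
    series <- compute_fractions(res$tab)
    calls <- lapply(colnames(series$fractions), function(tx) {
      if (series$fractions[which(abs(series$day - 40) < 1e-6), tx] <= 0) {
        return("no_anchor")
      }
      detect_selective_recession(series, tx, t0 = 40, config,
                                 window_days = window_days)$verdict
    })
    names(calls) <- colnames(series$fractions)
    flagged <- names(calls)[vapply(calls, identical, TRUE, "faster_than_washout")]
    out[[r]] <- data.frame(
      run = r, focal = res$focal, survival = res$survival,
      detected = res$focal %in% flagged,
      false_positives = length(setdiff(flagged, res$focal))
    )
  }
  do.call(rbind, out)
}
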