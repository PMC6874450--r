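## Coupling-control respirometry: oxygen-trace flux derivation, state
## extraction (ROUTINE / LEAK / ETS / ROX), the Bioenergetic Health Index and
## the covariate-adjusted young/old comparison.

AGENTS <- c("oligomycin", "fccp_step", "rotenone", "antimycin_a")

#' Construct an event-annotated oxygraph trace
#'
#' @param time Numeric vector of seconds, strictly increasing.
#' @param o2 Oxygen concentration (nmol/mL) at each time point.
#' @param events `data.frame` with columns `time_s` and `agent`; agents must
#'   appear in protocol order oligomycin -> fccp_step (one or more) ->
#'   rotenone -> antimycin_a.
#' @param chamber_volume Chamber volume in mL (default 2).
#' @param cell_count Cells in the chamber (default 5e6).
#' @return Object of class `oxygraph_trace`.
#' @export
oxygraph_trace <- function(time, o2, events, chamber_volume = 2,
                           cell_count = 5e6) {
  if (length(time) != length(o2) || any(diff(time) <= 0))
    iflux_input_error("time must be strictly increasing and match o2")
  if (any(!is.finite(o2))) iflux_input_error("o2 must be finite")
  if (!all(c("time_s", "agent") %in% names(events)))
    iflux_input_error("events needs columns time_s and agent")
  events <- events[order(events$time_s), ]
  if (!all(events$agent %in% AGENTS))
    iflux_input_error("unknown titration agent")
  seq_agents <- events$agent[events$agent != "fccp_step"]
  if (!identical(seq_agents, c("oligomycin", "rotenone", "antimycin_a")))
    iflux_input_error("protocol requires oligomycin, rotenone, antimycin_a once each, in order")
  t_fccp <- events$time_s[events$agent == "fccp_step"]
  if (!length(t_fccp)) iflux_input_error("at least one fccp_step is required")
  t_oli <- events$time_s[events$agent == "oligomycin"]
  t_rot <- events$time_s[events$agent == "rotenone"]
  if (min(t_fccp) < t_oli || max(t_fccp) > t_rot)
    iflux_input_error("fccp_step events must lie between oligomycin and rotenone")
  structure(list(time = time, o2 = o2, events = events,
                 chamber_volume = chamber_volume, cell_count = cell_count),
            class = "oxygraph_trace")
}

#' Sliding-window oxygen flux from a trace
#'
#' For each sample point, the least-squares slope of concentration over the
#' centered window is converted to a per-cell flux:
#' `flux = -slope * chamber_volume * 1000 / (cell_count / 1e6)`, in
#' pmol O2 / s / 1e6 cells.
#'
#' @param trace An [oxygraph_trace()].
#' @param window_s Window width in seconds (default 120).
#' @return `data.frame` with `time` and `flux` at every point whose centered
#'   window is fully inside the record.
#' @export
compute_flux_trace <- function(trace, window_s = 120) {
  t <- trace$time; y <- trace$o2
  n <- length(t)
  if (t[n] - t[1] < 2 * window_s)
    iflux_input_error("trace shorter than twice the flux window")
  half <- window_s / 2
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  ## cumulative sums for O(n) windowed least-squares slopes
  ct <- c(0, cumsum(t)); ct2 <- c(0, cumsum(t^2))
  cy <- c(0, cumsum(y)); cty <- c(0, cumsum(t * y))
  m <- hi - lo + 1L
  st <- ct[hi + 1L] - ct[lo]
  st2 <- ct2[hi + 1L] - ct2[lo]
  sy <- cy[hi + 1L] - cy[lo]
  sty <- cty[hi + 1L] - cty[lo]
  denom <- st2 - st^2 / m
  slope <- (sty - st * sy / m) / denom
  keep <- (t - t[1]) >= half & (t[n] - t) >= half & m >= 3 & denom > 0
  scale <- trace$chamber_volume * 1000 / (trace$cell_count / 1e6)
  data.frame(time = t[keep], flux = -slope[keep] * scale)
}

## Outlier-trimmed least-squares slope of the O2 concentration over the
## settle-trimmed state region: fit, drop points with residuals beyond
## 3 x MAD, refit. Near-LS efficiency on clean plateaus, robust to residual
## injection artifacts.
state_window <- function(trace, start, end, window_s, settle_s, state) {
  lo <- start + settle_s
  idx <- which(trace$time >= lo & trace$time < end)
  if (end - lo < window_s || length(idx) < 3)
    iflux_input_error(sprintf("window for state %s is shorter than the flux window", state))
  t <- trace$time[idx]; y <- trace$o2[idx]
  fit <- stats::lm.fit(cbind(1, t), y)
  r <- fit$residuals
  s <- mad(r)
  if (s > 0 && any(abs(r) > 3 * s)) {
    keep <- abs(r) <= 3 * s
    fit <- stats::lm.fit(cbind(1, t[keep]), y[keep])
  }
  scale <- trace$chamber_volume * 1000 / (trace$cell_count / 1e6)
  list(value = unname(-fit$coefficients[2]) * scale, span = end - lo,
       resid_sd = sd(fit$residuals))
}

#' Extract coupling-control state fluxes
#'
#' ROUTINE is estimated before oligomycin, LEAK between oligomycin and the
#' first FCCP step, ETS as the maximum over per-FCCP-step plateau estimates,
#' and ROX after antimycin A. Each state window is trimmed by `settle_s`
#' after the triggering injection so injection transients are excluded; the
#' state flux is the outlier-trimmed least-squares slope of the oxygen
#' concentration over the remaining window (3 x MAD residual trim), converted
#' to pmol O2 / s / 1e6 cells.
#'
#' @param trace An [oxygraph_trace()].
#' @param settle_s Seconds discarded after each injection (default 60).
#' @param window_s Minimum usable state-window span in seconds (default 120);
#'   a shorter state raises an error naming the state.
#' @return Object of class `state_fluxes`: `routine`, `leak`, `ets`, `rox`
#'   (pmol O2 / s / 1e6 cells), per-state diagnostics (window span, residual
#'   sd), and `flags` noting any violation of the expected ordering
#'   `ets >= routine >= leak >= rox`.
#' @export
extract_state_fluxes <- function(trace, settle_s = 60, window_s = 120) {
  flux <- trace
  ev <- trace$events
  t_oli <- ev$time_s[ev$agent == "oligomycin"]
  t_fccp <- sort(ev$time_s[ev$agent == "fccp_step"])
  t_rot <- ev$time_s[ev$agent == "rotenone"]
  t_ant <- ev$time_s[ev$agent == "antimycin_a"]
  t0 <- trace$time[1]; tend <- trace$time[length(trace$time)]

  routine <- state_window(flux, t0, t_oli, window_s, settle_s, "ROUTINE")
  leak <- state_window(flux, t_oli, t_fccp[1], window_s, settle_s, "LEAK")
  bounds <- c(t_fccp, t_rot)
  steps <- lapply(seq_along(t_fccp), function(i)
    state_window(flux, t_fccp[i], bounds[i + 1], window_s, settle_s,
                 sprintf("ETS step %d", i)))
  step_vals <- vapply(steps, `[[`, numeric(1), "value")
  ets <- steps[[which.max(step_vals)]]
  rox <- state_window(flux, t_ant, tend, window_s, settle_s, "ROX")

  vals <- c(routine = routine$value, leak = leak$value, ets = ets$value,
            rox = rox$value)
  flags <- character(0)
  if (vals["ets"] < vals["routine"]) flags <- c(flags, "ets < routine")
  if (vals["routine"] < vals["leak"]) flags <- c(flags, "routine < leak")
  if (vals["leak"] < vals["rox"]) flags <- c(flags, "leak < rox")
  if (any(vals < 0)) flags <- c(flags, "negative state flux")

  structure(list(routine = unname(vals["routine"]), leak = unname(vals["leak"]),
                 ets = unname(vals["ets"]), rox = unname(vals["rox"]),
                 ets_steps = step_vals,
                 diagnostics = data.frame(
                   state = c("routine", "leak", "ets", "rox"),
                   span = c(routine$span, leak$span, ets$span, rox$span),
                   resid_sd = c(routine$resid_sd, leak$resid_sd, ets$resid_sd,
                                rox$resid_sd)),
                 flags = flags),
            class = "state_fluxes")
}

#' Derive the bioenergetic profile and Bioenergetic Health Index
#'
#' Components: ATP-linked = ROUTINE - LEAK; proton leak = LEAK - ROX; reserve
#' capacity = ETS - ROUTINE; non-mitochondrial = ROX. The BHI is the log of
#' the ratio of the beneficial components to the deleterious ones:
#' `BHI = log10((reserve * atp_linked) / (non_mitochondrial * proton_leak))`.
#' If any component is not strictly positive the BHI is undefined (`NA`) and
#' the profile is flagged.
#'
#' @param states A `state_fluxes` object or list with `routine`, `leak`,
#'   `ets`, `rox`.
#' @param log_base Base of the logarithm (default 10).
#' @return Object of class `bioenergetic_profile` with the four components,
#'   `bhi` and `flags`.
#' @export
derive_profile <- function(states, log_base = 10) {
  s <- states[c("routine", "leak", "ets", "rox")]
  if (any(!is.finite(unlist(s)))) iflux_input_error("state fluxes must be finite")
  atp <- s$routine - s$leak
  pl <- s$leak - s$rox
  res <- s$ets - s$routine
  nm <- s$rox
  comp <- c(atp_linked = atp, proton_leak = pl, reserve_capacity = res,
            non_mitochondrial = nm)
  flags <- character(0)
  bhi <- NA_real_
  if (any(comp <= 0)) {
    flags <- sprintf("non-positive component(s): %s",
                     paste(names(comp)[comp <= 0], collapse = ", "))
  } else {
    bhi <- log((res * atp) / (nm * pl), base = log_base)
  }
  structure(list(atp_linked = atp, proton_leak = pl, reserve_capacity = res,
                 non_mitochondrial = nm, bhi = bhi, log_base = log_base,
                 flags = flags),
            class = "bioenergetic_profile")
}

#' @export
print.bioenergetic_profile <- function(x, ...) {
  cat(sprintf("ATP-linked %.3f | proton leak %.3f | reserve %.3f | non-mito %.3f\n",
              x$atp_linked, x$proton_leak, x$reserve_capacity,
              x$non_mitochondrial))
  cat(sprintf("BHI (log%g) = %s%s\n", x$log_base,
              if (is.na(x$bhi)) "undefined" else sprintf("%.4f", x$bhi),
              if (length(x$flags)) paste0("  [", x$flags, "]") else ""))
  invisible(x)
}

flag_memory_outliers <- function(samples, k = 1.5) {
  flag <- rep(FALSE, nrow(samples))
  for (g in unique(samples$age_group)) {
    i <- samples$age_group == g
    qs <- quantile(samples$memory_pct[i], c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    flag[i] <- samples$memory_pct[i] < qs[1] - k * iqr |
      samples$memory_pct[i] > qs[2] + k * iqr
  }
  flag
}

adjusted_fit <- function(samples) {
  d <- samples
  d$group_old <- as.numeric(d$age_group == "old")
  fit <- lm(bhi ~ group_old + memory_pct, data = d)
  cf <- coef(summary(fit))
  mbar <- mean(d$memory_pct)
  list(fit = fit,
       adjusted_means = c(
         young = unname(coef(fit)[1] + coef(fit)["memory_pct"] * mbar),
         old = unname(coef(fit)[1] + coef(fit)["group_old"] +
                        coef(fit)["memory_pct"] * mbar)),
       p_group = cf["group_old", "Pr(>|t|)"],
       coefficients = coef(fit),
       se = cf[, "Std. Error"])
}

#' Memory-fraction-adjusted BHI comparison
#'
#' Fits the linear covariate model `bhi = b0 + b1 * old + b2 * memory_pct` by
#' least squares and evaluates group means at the grand-mean memory
#' percentage; the group effect p-value is the t-test on `b1`. Samples whose
#' memory percentage lies outside `k` x IQR of their group's quartiles are
#' flagged, and the analysis is reported both with and without them. If the
#' memory covariate is constant the function falls back to an unadjusted Welch
#' comparison with a warning.
#'
#' @param samples `data.frame` with columns `donor`, `age_group`, `bhi`,
#'   `memory_pct` (percent of CD4+ cells that are memory, in \[0, 100\]).
#' @param outlier_k IQR multiplier for the outlier fence (default 1.5).
#' @return List with `samples` (plus `outlier_flag`), `all` and
#'   `without_outliers` fit summaries (adjusted means, group p, coefficients),
#'   and `outliers` (flagged donor ids).
#' @export
adjust_bhi_for_memory <- function(samples, outlier_k = 1.5) {
  req <- c("donor", "age_group", "bhi", "memory_pct")
  if (!all(req %in% names(samples)))
    iflux_input_error("samples needs donor, age_group, bhi, memory_pct")
  if (any(samples$memory_pct < 0 | samples$memory_pct > 100))
    iflux_input_error("memory_pct must lie in [0, 100]")
  tab <- table(samples$age_group)
  if (length(tab) != 2 || any(tab < 3))
    iflux_input_error("need >= 3 samples per age group")

  samples$outlier_flag <- flag_memory_outliers(samples, outlier_k)

  if (var(samples$memory_pct) == 0) {
    warning("memory_pct is constant; falling back to unadjusted Welch comparison")
    y <- samples$bhi[samples$age_group == "young"]
    o <- samples$bhi[samples$age_group == "old"]
    wt <- tryCatch(welch_ttest(y, o),
                   immunoflux_degenerate_input = function(e)
                     list(p_value = 1))
    return(list(samples = samples,
                all = list(adjusted_means = c(young = mean(y), old = mean(o)),
                           p_group = wt$p_value, coefficients = NULL),
                without_outliers = NULL,
                outliers = samples$donor[samples$outlier_flag],
                fallback = "welch_unadjusted"))
  }

  all_fit <- adjusted_fit(samples)
  wo <- NULL
  kept <- samples[!samples$outlier_flag, ]
  if (any(samples$outlier_flag) && all(table(kept$age_group) >= 3))
    wo <- adjusted_fit(kept)
  list(samples = samples, all = all_fit, without_outliers = wo,
       outliers = samples$donor[samples$outlier_flag])
}

#' Young/old comparison of respirometry metrics
#'
#' Welch two-tailed tests of BHI, non-mitochondrial respiration and reserve
#' capacity between age groups.
#'
#' @param samples `data.frame` with `age_group` and the metric columns.
#' @param metrics Metric column names (default the three headline metrics).
#' @return `data.frame` with one row per metric: group means, t, df, p and the
#'   direction sign (`sign(mean_young - mean_old)`).
#' @export
compare_respiration <- function(samples,
                                metrics = c("bhi", "non_mitochondrial",
                                            "reserve_capacity")) {
  missing_m <- setdiff(metrics, names(samples))
  if (length(missing_m))
    iflux_input_error(sprintf("missing metric columns: %s",
                              paste(missing_m, collapse = ", ")))
  yi <- samples$age_group == "young"; oi <- samples$age_group == "old"
  if (sum(yi) < 2 || sum(oi) < 2)
    iflux_input_error("need >= 2 donors per age group")
  rows <- lapply(metrics, function(m) {
    y <- samples[[m]][yi]; o <- samples[[m]][oi]
    y <- y[is.finite(y)]; o <- o[is.finite(o)]
    if (length(y) < 2 || length(o) < 2)
      iflux_input_error(sprintf("metric %s has < 2 finite values in a group", m))
    tt <- tryCatch(welch_ttest(y, o),
                   immunoflux_degenerate_input = function(e) NULL)
    data.frame(metric = m, mean_young = mean(y), mean_old = mean(o),
               statistic = if (is.null(tt)) 0 else tt$statistic,
               df = if (is.null(tt)) NA_real_ else tt$df,
               p_value = if (is.null(tt)) 1 else tt$p_value,
               direction = sign(mean(y) - mean(o)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an oxygraph trace from CSV files
#'
#' Trace CSV columns: `time_s`, `o2_nmol_per_ml`; events CSV columns:
#' `time_s`, `agent`.
#'
#' @param trace_path,events_path CSV paths.
#' @param chamber_volume,cell_count Chamber parameters; see
#'   [oxygraph_trace()].
#' @return An [oxygraph_trace()].
#' @export
read_oxygraph_csv <- function(trace_path, events_path, chamber_volume = 2,
                              cell_count = 5e6) {
  tr <- utils::read.csv(trace_path)
  ev <- utils::read.csv(events_path)
  oxygraph_trace(tr$time_s, tr$o2_nmol_per_ml, ev, chamber_volume, cell_count)
}
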