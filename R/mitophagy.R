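## Mitophagy-dye flow cytometry: low/intermediate/high intensity gating and
## age/condition contrasts of the bin fractions.

FLOW_CONDITIONS <- c("unstained", "dye_only", "cccp", "bafilomycin")

#' Construct a per-sample flow event table
#'
#' @param sample_id,donor Identifiers.
#' @param age_group `"young"` or `"old"`.
#' @param condition One of `"unstained"`, `"dye_only"`, `"cccp"`,
#'   `"bafilomycin"`.
#' @param intensities Non-negative per-event fluorescence intensities
#'   (arbitrary units). Stained samples should carry at least `min_events`
#'   events.
#' @param min_events Minimum events for stained samples (default 1000; the
#'   reference acquisition depth is 20,000).
#' @return Object of class `flow_event_table`.
#' @export
flow_event_table <- function(sample_id, donor, age_group, condition,
                             intensities, min_events = 1000) {
  if (!condition %in% FLOW_CONDITIONS)
    iflux_input_error("unknown flow condition")
  if (!age_group %in% c("young", "old")) iflux_input_error("bad age_group")
  if (any(intensities < 0) || any(!is.finite(intensities)))
    iflux_input_error("intensities must be finite and >= 0")
  if (condition != "unstained" && length(intensities) < min_events)
    iflux_input_error(sprintf("stained sample %s has < %d events", sample_id,
                              min_events))
  structure(list(sample_id = sample_id, donor = donor, age_group = age_group,
                 condition = condition, intensities = intensities),
            class = "flow_event_table")
}

#' Derive shared lo/int/hi intensity gates from reference samples
#'
#' One gate pair is used for the whole experiment: the lo/int boundary is a
#' high quantile of the unstained distribution (autofluorescence ceiling) and
#' the int/hi boundary a quantile of the pooled young dye-only distribution.
#' Both can be overridden with explicit values.
#'
#' @param unstained Numeric vector of pooled unstained intensities.
#' @param dye_only_young Numeric vector of pooled young dye-only intensities.
#' @param q_lo Quantile of the unstained distribution for the lo/int boundary
#'   (default 0.99).
#' @param q_hi Quantile of the young dye-only distribution for the int/hi
#'   boundary (default 0.90).
#' @param boundaries Optional explicit `c(lo_int, int_hi)` override.
#' @return Object of class `intensity_gates` with `lo_int_boundary` and
#'   `int_hi_boundary` (strictly ordered) and the derivation metadata.
#' @export
derive_gates <- function(unstained = NULL, dye_only_young = NULL, q_lo = 0.99,
                         q_hi = 0.90, boundaries = NULL) {
  if (!is.null(boundaries)) {
    lo <- boundaries[1]; hi <- boundaries[2]
    meta <- "explicit"
  } else {
    if (is.null(unstained) || is.null(dye_only_young) ||
        !length(unstained) || !length(dye_only_young))
      iflux_input_error("unstained and dye_only references are required to derive gates")
    lo <- quantile(unstained, q_lo, names = FALSE)
    hi <- quantile(dye_only_young, q_hi, names = FALSE)
    meta <- sprintf("q%.2f(unstained), q%.2f(young dye_only)", q_lo, q_hi)
  }
  if (!(lo < hi))
    iflux_input_error("gate boundaries out of order (lo_int must be < int_hi)")
  structure(list(lo_int_boundary = lo, int_hi_boundary = hi,
                 derivation = meta),
            class = "intensity_gates")
}

#' Fraction of events in the lo/int/hi intensity bins
#'
#' Half-open convention: lo is `x < lo_int`, int is `lo_int <= x < int_hi`,
#' hi is `x >= int_hi`. Percentages sum to 100 exactly.
#'
#' @param intensities Numeric vector of per-event intensities (or a
#'   `flow_event_table`).
#' @param gates An [derive_gates()] object.
#' @return Named numeric vector `c(pct_lo, pct_int, pct_hi)`.
#' @export
bin_fractions <- function(intensities, gates) {
  if (inherits(intensities, "flow_event_table"))
    intensities <- intensities$intensities
  if (!length(intensities)) iflux_input_error("no events to bin")
  n <- length(intensities)
  lo <- sum(intensities < gates$lo_int_boundary)
  hi <- sum(intensities >= gates$int_hi_boundary)
  c(pct_lo = 100 * lo / n, pct_int = 100 * (n - lo - hi) / n,
    pct_hi = 100 * hi / n)
}

#' Bin fractions for every sample of an experiment
#'
#' @param tables List of [flow_event_table()] objects.
#' @param gates An [derive_gates()] object shared by all samples.
#' @return `data.frame` with one row per sample: identifiers, condition and
#'   `pct_lo`, `pct_int`, `pct_hi`.
#' @export
experiment_bin_fractions <- function(tables, gates) {
  rows <- lapply(tables, function(ft) {
    fr <- bin_fractions(ft, gates)
    data.frame(sample_id = ft$sample_id, donor = ft$donor,
               age_group = ft$age_group, condition = ft$condition,
               pct_lo = fr["pct_lo"], pct_int = fr["pct_int"],
               pct_hi = fr["pct_hi"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age and condition contrasts of bin fractions
#'
#' Young vs old two-tailed Student t-tests for every bin under every stained
#' condition, plus within-age paired contrasts (paired by donor) of dye-only
#' vs CCCP and dye-only vs bafilomycin.
#'
#' @param fractions `data.frame` from [experiment_bin_fractions()].
#' @return List with `age_contrasts` and `condition_contrasts` data frames.
#' @export
condition_contrast <- function(fractions) {
  bins <- c("pct_lo", "pct_int", "pct_hi")
  stained <- setdiff(unique(fractions$condition), "unstained")

  age_rows <- list()
  for (cond in stained) for (b in bins) {
    d <- fractions[fractions$condition == cond, ]
    y <- d[[b]][d$age_group == "young"]; o <- d[[b]][d$age_group == "old"]
    if (length(y) < 2 || length(o) < 2)
      iflux_input_error("need >= 2 donors per age group per condition")
    tt <- tryCatch(student_ttest(o, y),
                   immunoflux_degenerate_input = function(e) NULL)
    age_rows[[length(age_rows) + 1L]] <-
      data.frame(condition = cond, bin = b, mean_young = mean(y),
                 mean_old = mean(o),
                 statistic = if (is.null(tt)) 0 else tt$statistic,
                 p_value = if (is.null(tt)) 1 else tt$p_value)
  }

  cond_rows <- list()
  for (cond in intersect(c("cccp", "bafilomycin"), stained)) {
    for (age in c("young", "old")) for (b in bins) {
      base <- fractions[fractions$condition == "dye_only" &
                          fractions$age_group == age, ]
      trt <- fractions[fractions$condition == cond &
                         fractions$age_group == age, ]
      common <- intersect(base$donor, trt$donor)
      if (length(common) < 2) next
      x <- trt[[b]][match(common, trt$donor)]
      y <- base[[b]][match(common, base$donor)]
      diffs <- x - y
      ht <- if (sd(diffs) == 0) NULL else t.test(x, y, paired = TRUE)
      cond_rows[[length(cond_rows) + 1L]] <-
        data.frame(condition = cond, age_group = age, bin = b,
                   mean_dye_only = mean(y), mean_treated = mean(x),
                   mean_paired_diff = mean(diffs),
                   statistic = if (is.null(ht)) 0 else unname(ht$statistic),
                   p_value = if (is.null(ht)) 1 else ht$p.value,
                   n_pairs = length(common))
    }
  }
  list(age_contrasts = do.call(rbind, age_rows),
       condition_contrasts = do.call(rbind, cond_rows))
}

#' Read per-event flow intensities from CSV
#'
#' Columns: `sample, donor, age_group, condition, intensity`.
#'
#' @param path CSV path.
#' @return List of [flow_event_table()] objects, one per sample.
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$sample), function(d)
    flow_event_table(d$sample[1], d$donor[1], d$age_group[1], d$condition[1],
                     d$intensity, min_events = 1))
}
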