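## TEM morphometry: rule-based autophagosome (AP) / autolysosome (AL)
## classification, per-cell summaries and stratified group comparisons.

LUMINAL_LEVELS <- c("lower_than_cytosol", "similar_to_cytosol", "dense_amorphous")

#' Construct a vesicle feature record
#'
#' @param vesicle_id Identifier.
#' @param diameter_um Diameter in micrometres (> 0).
#' @param double_membrane_fraction Fraction of the perimeter showing a double
#'   membrane, in \[0, 1\].
#' @param ribosomes_attached Logical: ribosomes on the cytosolic face.
#' @param luminal_density One of `"lower_than_cytosol"`,
#'   `"similar_to_cytosol"`, `"dense_amorphous"`.
#' @param contains_identifiable_organelle Logical.
#' @param multiple_inner_single_membrane_vesicles Logical.
#' @param area_au Vesicle area in arbitrary units (> 0).
#' @return A one-row `data.frame` of validated features.
#' @export
vesicle_features <- function(vesicle_id, diameter_um, double_membrane_fraction,
                             ribosomes_attached, luminal_density,
                             contains_identifiable_organelle,
                             multiple_inner_single_membrane_vesicles,
                             area_au) {
  if (diameter_um <= 0 || area_au <= 0)
    iflux_input_error("diameter and area must be positive")
  if (double_membrane_fraction < 0 || double_membrane_fraction > 1)
    iflux_input_error("double_membrane_fraction must lie in [0, 1]")
  if (!luminal_density %in% LUMINAL_LEVELS)
    iflux_input_error("unknown luminal_density level")
  data.frame(vesicle_id = vesicle_id, diameter_um = diameter_um,
             double_membrane_fraction = double_membrane_fraction,
             ribosomes_attached = isTRUE(ribosomes_attached),
             luminal_density = luminal_density,
             contains_identifiable_organelle =
               isTRUE(contains_identifiable_organelle),
             multiple_inner_single_membrane_vesicles =
               isTRUE(multiple_inner_single_membrane_vesicles),
             area_au = area_au)
}

#' Classify a vesicle as autophagosome, autolysosome or unclassified
#'
#' A vesicle of at least `size_min_um` diameter is an AP when it meets two or
#' more of: a (complete or partial) double membrane, absence of attached
#' ribosomes, luminal density similar to cytosol, identifiable organelles in
#' the lumen. Otherwise it is an AL when less than 40% of the membrane is
#' double AND its lumen is lower-density than cytosol, or it contains multiple
#' inner single-membrane vesicles with light or dense amorphous content.
#' Everything else is unclassified (a valid outcome, excluded from AV counts).
#'
#' @param v One vesicle: a one-row `data.frame` (or list) with the
#'   [vesicle_features()] fields.
#' @param size_min_um Minimum diameter considered (default 0.5 um); smaller
#'   vesicles are unclassified.
#' @return `"AP"`, `"AL"` or `"unclassified"`.
#' @export
classify_vesicle <- function(v, size_min_um = 0.5) {
  if (v$diameter_um < size_min_um) return("unclassified")
  ap_criteria <- c(double_membrane = v$double_membrane_fraction > 0,
                   no_ribosomes = !v$ribosomes_attached,
                   density_like_cytosol =
                     v$luminal_density == "similar_to_cytosol",
                   organelle = v$contains_identifiable_organelle)
  if (sum(ap_criteria) >= 2) return("AP")
  if (v$double_membrane_fraction < 0.4 &&
      (v$luminal_density == "lower_than_cytosol" ||
       (v$multiple_inner_single_membrane_vesicles &&
        v$luminal_density %in% c("lower_than_cytosol", "dense_amorphous"))))
    return("AL")
  "unclassified"
}

#' Construct a TEM cell annotation
#'
#' @param cell_id,donor Identifiers.
#' @param age_group `"young"` or `"old"`.
#' @param subset `"naive"` or `"memory"`.
#' @param cytosol_area_au Cytosol area, arbitrary units (> 0).
#' @param mitochondria Numeric vector of mitochondrion areas (A.U., may be
#'   empty).
#' @param vesicles `data.frame` of vesicle features (rows as in
#'   [vesicle_features()]; may have zero rows).
#' @return Object of class `cell_annotation`.
#' @export
cell_annotation <- function(cell_id, donor, age_group, subset, cytosol_area_au,
                            mitochondria, vesicles) {
  if (!age_group %in% c("young", "old")) iflux_input_error("bad age_group")
  if (!subset %in% c("naive", "memory")) iflux_input_error("bad subset")
  if (cytosol_area_au <= 0) iflux_input_error("cytosol area must be positive")
  if (length(mitochondria) && any(mitochondria <= 0))
    iflux_input_error("mitochondrion areas must be positive")
  structure(list(cell_id = cell_id, donor = donor, age_group = age_group,
                 subset = subset, cytosol_area_au = cytosol_area_au,
                 mitochondria = mitochondria, vesicles = vesicles),
            class = "cell_annotation")
}

#' Per-cell morphometric summary
#'
#' Counts AP, AL and AV (= AP + AL), the AV maturation percentage
#' (100 * AL / AV, undefined when AV = 0), mitochondrion count and mean area,
#' total AP area and AP area as percent of cytosol area.
#'
#' @param cell A [cell_annotation()].
#' @param size_min_um Passed to [classify_vesicle()].
#' @return One-row `data.frame` with the summary fields plus identifiers.
#' @export
summarize_cell <- function(cell, size_min_um = 0.5) {
  v <- cell$vesicles
  if (is.null(v) || !nrow(v)) {
    cls <- character(0)
  } else {
    cls <- vapply(seq_len(nrow(v)), function(i)
      classify_vesicle(v[i, ], size_min_um), character(1))
  }
  ap <- sum(cls == "AP"); al <- sum(cls == "AL"); av <- ap + al
  ap_area <- if (ap) sum(v$area_au[cls == "AP"]) else 0
  data.frame(cell_id = cell$cell_id, donor = cell$donor,
             age_group = cell$age_group, subset = cell$subset,
             ap_count = ap, al_count = al, av_count = av,
             maturation_pct = if (av > 0) 100 * al / av else NA_real_,
             unclassified_count = sum(cls == "unclassified"),
             mito_count = length(cell$mitochondria),
             mean_mito_area_au = if (length(cell$mitochondria))
               mean(cell$mitochondria) else NA_real_,
             ap_area_au = ap_area,
             ap_area_pct_cytosol = 100 * ap_area / cell$cytosol_area_au)
}

#' Summarize a list of annotated cells
#'
#' @param cells List of [cell_annotation()] objects.
#' @param size_min_um Passed to [classify_vesicle()].
#' @return `data.frame`, one row per cell (see [summarize_cell()]).
#' @export
summarize_cells <- function(cells, size_min_um = 0.5) {
  out <- do.call(rbind, lapply(cells, summarize_cell, size_min_um = size_min_um))
  rownames(out) <- NULL
  out
}

morpho_strata_test <- function(summ, metric, strat_a, strat_b, label) {
  pick <- function(s) {
    x <- summ[[metric]][summ$age_group == s$age_group & summ$subset == s$subset]
    x[is.finite(x)]
  }
  a <- pick(strat_a); b <- pick(strat_b)
  if (length(a) < 2 || length(b) < 2)
    iflux_input_error(sprintf("stratum with < 2 cells for %s (%s)", metric, label))
  tt <- tryCatch(student_ttest(a, b), immunoflux_degenerate_input = function(e) NULL)
  data.frame(metric = metric, contrast = label,
             mean_a = mean(a), sem_a = sd(a) / sqrt(length(a)), n_a = length(a),
             mean_b = mean(b), sem_b = sd(b) / sqrt(length(b)), n_b = length(b),
             statistic = if (is.null(tt)) 0 else tt$statistic,
             p_value = if (is.null(tt)) 1 else tt$p_value)
}

#' Stratified morphometry comparisons
#'
#' Two-tailed Student t-tests per metric, with cells as the replication unit:
#' naive vs memory within each age group and young vs old within each subset,
#' for mitochondrion counts and areas, AP/AL/AV counts, maturation percentage
#' and AP areas. Means and SEM are reported alongside for plotting parity.
#'
#' @param summaries `data.frame` from [summarize_cells()].
#' @param metrics Metric columns to test.
#' @return `data.frame` of per-metric, per-contrast test results.
#' @export
compare_morphometry <- function(summaries,
                                metrics = c("mito_count", "mean_mito_area_au",
                                            "ap_count", "al_count", "av_count",
                                            "maturation_pct", "ap_area_au",
                                            "ap_area_pct_cytosol")) {
  contrasts <- list(
    list(a = list(age_group = "young", subset = "memory"),
         b = list(age_group = "young", subset = "naive"),
         label = "memory_vs_naive_young"),
    list(a = list(age_group = "old", subset = "memory"),
         b = list(age_group = "old", subset = "naive"),
         label = "memory_vs_naive_old"),
    list(a = list(age_group = "old", subset = "naive"),
         b = list(age_group = "young", subset = "naive"),
         label = "old_vs_young_naive"),
    list(a = list(age_group = "old", subset = "memory"),
         b = list(age_group = "young", subset = "memory"),
         label = "old_vs_young_memory"))
  rows <- list()
  for (m in metrics) for (ct in contrasts)
    rows[[length(rows) + 1L]] <- morpho_strata_test(summaries, m, ct$a, ct$b,
                                                    ct$label)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read TEM annotation tables into cell annotations
#'
#' @param vesicles_path TSV with columns `cell_id, vesicle_id, diameter_um,
#'   double_membrane_fraction, ribosomes_attached, luminal_density,
#'   contains_organelle, multiple_inner_vesicles, area_au`.
#' @param mito_path TSV with columns `cell_id, mito_id, area_au`.
#' @param cells_path TSV with columns `cell_id, donor, age_group, subset,
#'   cytosol_area_au`.
#' @return List of [cell_annotation()] objects.
#' @export
read_morphometry_tsv <- function(vesicles_path, mito_path, cells_path) {
  ves <- read.delim(vesicles_path)
  mito <- read.delim(mito_path)
  cells <- read.delim(cells_path)
  lapply(seq_len(nrow(cells)), function(i) {
    ci <- cells[i, ]
    vv <- ves[ves$cell_id == ci$cell_id, ]
    v <- if (nrow(vv)) data.frame(
      vesicle_id = vv$vesicle_id, diameter_um = vv$diameter_um,
      double_membrane_fraction = vv$double_membrane_fraction,
      ribosomes_attached = as.logical(vv$ribosomes_attached),
      luminal_density = vv$luminal_density,
      contains_identifiable_organelle = as.logical(vv$contains_organelle),
      multiple_inner_single_membrane_vesicles =
        as.logical(vv$multiple_inner_vesicles),
      area_au = vv$area_au) else
        data.frame(vesicle_id = character(0))
    cell_annotation(ci$cell_id, ci$donor, ci$age_group, ci$subset,
                    ci$cytosol_area_au,
                    mito$area_au[mito$cell_id == ci$cell_id], v)
  })
}
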