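## Expression-array arm: detection filtering, array-wise Z-transformation,
## per-gene Z-ratio statistics, parametric gene-set enrichment (PAGE) and the
## young-vs-old pathway contrast.

#' Construct an expression matrix with detection p-values
#'
#' @param log_signal Numeric gene x sample matrix of log signal values
#'   (rownames = genes, colnames = samples).
#' @param detection_p Matrix of detection p-values, same dimensions.
#' @param samples `data.frame` with columns `sample`, `age_group`
#'   (`"young"`/`"old"`) and optionally `sex`.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(log_signal, detection_p, samples) {
  if (!is.matrix(log_signal) || !is.matrix(detection_p) ||
      !identical(dim(log_signal), dim(detection_p)))
    iflux_input_error("log_signal and detection_p must be matrices of equal dimension")
  if (any(detection_p < 0 | detection_p > 1))
    iflux_input_error("detection p-values must lie in [0, 1]")
  if (!all(c("sample", "age_group") %in% names(samples)))
    iflux_input_error("samples needs columns sample and age_group")
  samples <- samples[match(colnames(log_signal), samples$sample), ]
  if (anyNA(samples$sample))
    iflux_input_error("samples sheet must describe every expression column")
  structure(list(log_signal = log_signal, detection_p = detection_p,
                 samples = samples),
            class = "expression_matrix")
}

#' Filter genes by detection p-value
#'
#' Retains genes detected (`detection_p <= p_cut`) in at least `min_fraction`
#' of samples. Defaults follow common BeadArray practice.
#'
#' @param em An [expression_matrix()].
#' @param p_cut Detection p-value threshold (default 0.02).
#' @param min_fraction Minimum fraction of samples detected (default 0.5).
#' @return A filtered `expression_matrix`.
#' @export
detection_filter <- function(em, p_cut = 0.02, min_fraction = 0.5) {
  keep <- rowMeans(em$detection_p <= p_cut) >= min_fraction
  if (!any(keep))
    iflux_input_error("no genes pass the detection filter; relax p_cut/min_fraction")
  expression_matrix(em$log_signal[keep, , drop = FALSE],
                    em$detection_p[keep, , drop = FALSE], em$samples)
}

#' Array-wise Z-transformation of log signal values
#'
#' Each sample (column) is standardized across genes:
#' `z = (x - mean(x)) / sd(x)`, with the sample standard deviation by default.
#'
#' @param mat Gene x sample numeric matrix (or `expression_matrix`).
#' @param sd_type `"sample"` (default, n-1 denominator) or `"population"`.
#' @return Matrix of Z scores; every column has mean 0 and sd 1.
#' @export
z_transform <- function(mat, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (inherits(mat, "expression_matrix")) mat <- mat$log_signal
  if (nrow(mat) < 2) iflux_input_error("need >= 2 genes per sample")
  mu <- colMeans(mat)
  s <- apply(mat, 2, sd)
  if (sd_type == "population") s <- s * sqrt((nrow(mat) - 1) / nrow(mat))
  if (any(s == 0)) iflux_input_error("a sample has zero spread across genes")
  sweep(sweep(mat, 2, mu, "-"), 2, s, "/")
}

#' Per-gene Z-ratio differential statistics
#'
#' For every gene the difference of group-mean Z scores (old minus young) is
#' scaled by the standard deviation of those differences across all genes; the
#' resulting Z-ratios therefore have unit spread by construction. Per-gene
#' p-values come from a two-sample Student t-test on the Z scores and q-values
#' from Benjamini-Hochberg.
#'
#' @param zmatrix Gene x sample matrix of Z scores (from [z_transform()]).
#' @param groups Character vector (`"young"`/`"old"`) aligned with columns.
#' @param z_cut,alpha,fdr_cut Significance cutoffs: a gene is `significant`
#'   when `|z_ratio| >= z_cut`, `p <= alpha` and `q <= fdr_cut`
#'   (defaults 1.5, 0.05, 0.3).
#' @return `data.frame` with `gene`, `mean_z_young`, `mean_z_old`, `z_ratio`,
#'   `p_value`, `q_value`, `significant`.
#' @export
z_ratio <- function(zmatrix, groups, z_cut = 1.5, alpha = 0.05, fdr_cut = 0.3) {
  if (length(groups) != ncol(zmatrix))
    iflux_input_error("groups must match zmatrix columns")
  yi <- groups == "young"; oi <- groups == "old"
  if (sum(yi) < 2 || sum(oi) < 2)
    iflux_input_error("need >= 2 samples per group")
  my <- rowMeans(zmatrix[, yi, drop = FALSE])
  mo <- rowMeans(zmatrix[, oi, drop = FALSE])
  d <- mo - my
  s <- sd(d)
  if (all(d == 0)) {
    zr <- d  # identical group profiles: no differential signal anywhere
  } else {
    if (!is.finite(s) || s == 0)
      iflux_degenerate_error("zero spread of group-mean differences across genes")
    zr <- d / s
  }

  ## per-gene two-sample t on the Z values; constant genes get p = 1
  ny <- sum(yi); no <- sum(oi)
  vy <- apply(zmatrix[, yi, drop = FALSE], 1, var)
  vo <- apply(zmatrix[, oi, drop = FALSE], 1, var)
  sp2 <- ((ny - 1) * vy + (no - 1) * vo) / (ny + no - 2)
  se <- sqrt(sp2 * (1 / ny + 1 / no))
  tstat <- ifelse(se > 0, d / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df = ny + no - 2), 1)
  q <- bh_fdr(p)
  data.frame(gene = rownames(zmatrix), mean_z_young = my, mean_z_old = mo,
             z_ratio = zr, p_value = p, q_value = q,
             significant = abs(zr) >= z_cut & p <= alpha & q <= fdr_cut,
             row.names = NULL)
}

#' Read a gene-set collection in GMT format
#'
#' Sets are mapped against a gene universe; unknown genes are dropped and sets
#' left empty after mapping are removed (both logged via `attr(, "log")`).
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector of gene identifiers to map onto.
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, universe)
}

#' Build a gene-set collection from a named list
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param universe Optional gene universe for mapping (genes outside it are
#'   dropped, empty sets removed, with a log attribute).
#' @return Named list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    iflux_input_error("gene sets must be named")
  log <- character(0)
  if (!is.null(universe)) {
    mapped <- lapply(sets, intersect, universe)
    lost <- sum(lengths(sets)) - sum(lengths(mapped))
    if (lost > 0) log <- c(log, sprintf("%d member genes outside universe dropped", lost))
    empty <- names(mapped)[lengths(mapped) == 0]
    if (length(empty))
      log <- c(log, sprintf("empty after mapping, removed: %s",
                            paste(empty, collapse = ", ")))
    sets <- mapped[lengths(mapped) > 0]
  }
  if (any(lengths(sets) == 0)) iflux_input_error("gene sets must be non-empty")
  structure(sets, class = c("gene_set_collection", "list"), log = log)
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of gene sets.
#' @param path Output path.
#' @param description Description field written in column 2.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parametric Analysis of Gene set Enrichment (PAGE)
#'
#' Each set of m genes is scored by `z = (S_m - mu) * sqrt(m) / delta`, where
#' `S_m` is the mean score of the set members and `mu`, `delta` are the mean
#' and standard deviation of all gene scores. Two-sided p-values come from the
#' standard normal, q-values from Benjamini-Hochberg. The normal approximation
#' is reliable for sets of at least `min_size` genes; smaller sets are scored
#' but flagged.
#'
#' @param scores Named numeric vector of per-gene scores (the universe).
#' @param sets A [gene_set_collection()] or named list of gene sets.
#' @param min_size Sets smaller than this (after mapping) are flagged
#'   (`small_set = TRUE`); default 10.
#' @param alpha,fdr_cut Selection gates: `selected` when `p <= alpha` and
#'   `q <= fdr_cut` (defaults 0.05, 0.3).
#' @return `data.frame` with `set_name`, `m`, `s_m`, `mu`, `delta`, `z`,
#'   `p_value`, `q_value`, `small_set`, `selected`. Sets with no mapped gene
#'   are dropped (logged in `attr(, "dropped")`).
#' @export
page <- function(scores, sets, min_size = 10, alpha = 0.05, fdr_cut = 0.3) {
  if (any(!is.finite(scores))) iflux_input_error("gene scores must be finite")
  if (is.null(names(scores))) iflux_input_error("scores must be named by gene")
  mu <- mean(scores)
  delta <- sd(scores)
  if (delta == 0) iflux_degenerate_error("gene scores have zero spread")
  mapped <- lapply(sets, intersect, names(scores))
  dropped <- names(mapped)[lengths(mapped) == 0]
  mapped <- mapped[lengths(mapped) > 0]
  if (!length(mapped)) iflux_input_error("no gene set overlaps the score universe")
  m <- lengths(mapped)
  s_m <- vapply(mapped, function(g) mean(scores[g]), numeric(1))
  z <- (s_m - mu) * sqrt(m) / delta
  p <- normal_ztest_p(z)
  q <- bh_fdr(p)
  out <- data.frame(set_name = names(mapped), m = m, s_m = s_m, mu = mu,
                    delta = delta, z = z, p_value = p, q_value = q,
                    small_set = m < min_size,
                    selected = p <= alpha & q <= fdr_cut,
                    row.names = NULL)
  attr(out, "dropped") <- dropped
  out
}

#' Young-vs-old pathway contrast
#'
#' Pathway scores are computed per donor (PAGE on each donor's Z-transformed
#' expression) and averaged within age group; the contrast axis is
#' `mean_z_young - mean_z_old`. Sets passing the significance gates of a
#' set-level PAGE run on the gene-level Z-ratios are ranked by the absolute
#' contrast, and the top `k` in each direction are selected.
#'
#' @param set_by_donor Set x donor matrix of per-donor PAGE z-scores.
#' @param groups Character vector (`"young"`/`"old"`) aligned with columns.
#' @param set_stats `data.frame` from [page()] on the gene-level contrast
#'   scores, carrying per-set `p_value`/`q_value` gates (matched by
#'   `set_name`); if `NULL`, all sets pass the gates.
#' @param k Number of top pathways selected per direction (default 50).
#' @param alpha,fdr_cut Gates applied to `set_stats` (defaults 0.05, 0.3).
#' @return `data.frame` with `set_name`, `mean_z_young`, `mean_z_old`,
#'   `z_difference` (young minus old), `passes_gate`, `rank` (by
#'   `|z_difference|` among gate-passing sets) and `selected`.
#' @export
pathway_contrast <- function(set_by_donor, groups, set_stats = NULL, k = 50,
                             alpha = 0.05, fdr_cut = 0.3) {
  if (length(groups) != ncol(set_by_donor))
    iflux_input_error("groups must match set_by_donor columns")
  yi <- groups == "young"; oi <- groups == "old"
  my <- rowMeans(set_by_donor[, yi, drop = FALSE])
  mo <- rowMeans(set_by_donor[, oi, drop = FALSE])
  zd <- my - mo
  gate <- rep(TRUE, nrow(set_by_donor))
  if (!is.null(set_stats)) {
    idx <- match(rownames(set_by_donor), set_stats$set_name)
    gate <- !is.na(idx) & set_stats$p_value[idx] <= alpha &
      set_stats$q_value[idx] <= fdr_cut
  }
  out <- data.frame(set_name = rownames(set_by_donor), mean_z_young = my,
                    mean_z_old = mo, z_difference = zd, passes_gate = gate,
                    row.names = NULL)
  out$rank <- NA_integer_
  out$rank[gate] <- rank(-abs(out$z_difference[gate]), ties.method = "first")
  up <- out$passes_gate & out$z_difference > 0
  down <- out$passes_gate & out$z_difference < 0
  sel_up <- out$set_name[up][order(-out$z_difference[up])][seq_len(min(k, sum(up)))]
  sel_down <- out$set_name[down][order(out$z_difference[down])][seq_len(min(k, sum(down)))]
  out$selected <- out$set_name %in% c(sel_up, sel_down)
  out[order(-out$z_difference), ]
}

#' Full expression-arm pipeline
#'
#' Detection filter, Z-transformation, gene-level Z-ratios, set-level PAGE on
#' the Z-ratio scores, per-donor PAGE and the young/old pathway contrast.
#'
#' @param em An [expression_matrix()].
#' @param sets Gene-set collection.
#' @param p_cut,min_fraction Detection-filter settings.
#' @param k Top pathways per direction for the contrast.
#' @return List with `genes` (Z-ratio table), `sets` (PAGE on Z-ratios),
#'   `contrast` (pathway contrast table) and `zmatrix`.
#' @export
enrichment_pipeline <- function(em, sets, p_cut = 0.02, min_fraction = 0.5,
                                k = 50) {
  emf <- detection_filter(em, p_cut, min_fraction)
  z <- z_transform(emf)
  groups <- emf$samples$age_group
  genes <- z_ratio(z, groups)
  scores <- setNames(genes$z_ratio, genes$gene)
  set_stats <- page(scores, sets)
  per_donor <- vapply(seq_len(ncol(z)), function(j) {
    pg <- page(setNames(z[, j], rownames(z)), sets, alpha = 1, fdr_cut = 1)
    setNames(pg$z, pg$set_name)[set_stats$set_name]
  }, numeric(nrow(set_stats)))
  rownames(per_donor) <- set_stats$set_name
  colnames(per_donor) <- colnames(z)
  contrast <- pathway_contrast(per_donor, groups, set_stats, k = k)
  list(genes = genes, sets = set_stats, contrast = contrast, zmatrix = z)
}
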