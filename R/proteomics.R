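## Multi-plex isobaric-tag (iTRAQ 8plex) protein quantification:
## reference-channel normalization, old/young ratio statistics and the
## three-stage significance/evidence filter cascade.

#' Construct a per-plex protein quantification table
#'
#' One object per iTRAQ 8plex run: a protein x channel intensity matrix plus
#' the channel-to-sample design. Exactly one channel per plex must carry the
#' common reference (control) sample used to place runs on a shared scale.
#'
#' @param plex_id Plex identifier (scalar character).
#' @param intensities Numeric matrix, proteins in rows (rownames = accessions),
#'   channels in columns (colnames = tag labels). Finite and non-negative.
#' @param sample_map `data.frame` with columns `channel`, `donor`, `age_group`
#'   (`"young"`/`"old"`), `role` (`"biological"`, `"reference"`,
#'   `"technical_duplicate"`); one row per channel.
#' @return An object of class `protein_quant_table`.
#' @export
protein_quant_table <- function(plex_id, intensities, sample_map) {
  if (!is.matrix(intensities) || is.null(rownames(intensities)) ||
      is.null(colnames(intensities)))
    iflux_input_error("intensities must be a matrix with protein rownames and channel colnames")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    iflux_input_error("intensities must be finite and >= 0")
  if (any(rowSums(intensities > 0) == 0))
    iflux_input_error("every protein row needs at least one positive intensity")
  req <- c("channel", "donor", "age_group", "role")
  if (!all(req %in% names(sample_map)))
    iflux_input_error(sprintf("sample_map needs columns: %s",
                              paste(req, collapse = ", ")))
  sample_map <- sample_map[match(colnames(intensities), sample_map$channel), ]
  if (anyNA(sample_map$channel))
    iflux_input_error("sample_map must describe every intensity channel")
  if (sum(sample_map$role == "reference") != 1)
    iflux_input_error(sprintf("plex %s must have exactly one reference channel",
                              plex_id))
  if (!all(sample_map$role %in% c("biological", "reference", "technical_duplicate")))
    iflux_input_error("unknown sample role in sample_map")
  if (!all(sample_map$age_group %in% c("young", "old")))
    iflux_input_error("age_group must be 'young' or 'old'")
  structure(list(plex_id = as.character(plex_id), intensities = intensities,
                 sample_map = sample_map),
            class = "protein_quant_table")
}

#' Normalize multi-plex intensities to the common reference channel
#'
#' Within each plex, every protein's channel intensities are divided by that
#' protein's intensity in the plex's reference channel, so the reference sample
#' is exactly 1 everywhere and channels from different runs become
#' commensurate. Proteins are intersected across plexes; proteins whose
#' reference intensity is zero in any plex are dropped with a logged reason.
#'
#' @param tables List of [protein_quant_table()] objects (one per plex).
#' @return A list with elements
#'   \describe{
#'     \item{abundance}{protein x column matrix of normalized abundances;
#'       columns are `<plex>:<channel>`, reference channels included (all 1).}
#'     \item{columns}{`data.frame` describing each column (`plex`, `channel`,
#'       `donor`, `age_group`, `role`).}
#'     \item{dropped}{`data.frame` of dropped proteins and reasons.}
#'   }
#' @export
normalize_to_reference <- function(tables) {
  if (!length(tables)) iflux_input_error("no plex tables supplied")
  if (!all(vapply(tables, inherits, logical(1), "protein_quant_table")))
    iflux_input_error("tables must be protein_quant_table objects")

  shared <- Reduce(intersect, lapply(tables, function(t) rownames(t$intensities)))
  all_ids <- unique(unlist(lapply(tables, function(t) rownames(t$intensities))))
  dropped <- data.frame(protein = setdiff(all_ids, shared),
                        reason = if (length(setdiff(all_ids, shared)))
                          "absent from at least one plex" else character(0))

  if (!length(shared)) iflux_input_error("no proteins shared across all plexes")

  zero_ref <- character(0)
  for (t in tables) {
    ref_ch <- t$sample_map$channel[t$sample_map$role == "reference"]
    ref <- t$intensities[shared, ref_ch]
    zero_ref <- union(zero_ref, shared[ref == 0])
  }
  if (length(zero_ref))
    dropped <- rbind(dropped, data.frame(protein = zero_ref,
                                         reason = "zero reference intensity"))
  keep <- setdiff(shared, zero_ref)
  if (!length(keep)) iflux_input_error("all shared proteins have a zero reference intensity")

  mats <- list(); cols <- list()
  for (t in tables) {
    ref_ch <- t$sample_map$channel[t$sample_map$role == "reference"]
    ref <- t$intensities[keep, ref_ch]
    norm <- t$intensities[keep, , drop = FALSE] / ref
    colnames(norm) <- paste(t$plex_id, colnames(norm), sep = ":")
    mats[[t$plex_id]] <- norm
    cols[[t$plex_id]] <- data.frame(column = colnames(norm),
                                    plex = t$plex_id,
                                    channel = t$sample_map$channel,
                                    donor = t$sample_map$donor,
                                    age_group = t$sample_map$age_group,
                                    role = t$sample_map$role)
  }
  abundance <- do.call(cbind, mats)
  columns <- do.call(rbind, cols)
  rownames(columns) <- NULL
  list(abundance = abundance, columns = columns, dropped = dropped)
}

#' Old/young ratio statistics per protein
#'
#' Technical duplicates are first collapsed to their donor mean, then each
#' protein is compared between old and young donors with a two-tailed Student
#' t-test on the reference-normalized abundances. The reported ratio is
#' mean(old) / mean(young), the presentation used for the differential table.
#'
#' @param normalized Result of [normalize_to_reference()], or a compatible
#'   list with `abundance` and `columns`.
#' @return `data.frame` with one row per protein: `protein`, `avg_young`,
#'   `avg_old`, `ratio`, `p_value`, `n_young`, `n_old`.
#' @export
group_ratio_test <- function(normalized) {
  ab <- normalized$abundance
  cols <- normalized$columns
  bio <- cols[cols$role %in% c("biological", "technical_duplicate"), ]
  if (!nrow(bio)) iflux_input_error("no biological channels present")

  ## collapse technical duplicates: one column per donor
  donors <- unique(bio[, c("donor", "age_group")])
  donor_mat <- vapply(seq_len(nrow(donors)), function(i) {
    cc <- bio$column[bio$donor == donors$donor[i]]
    rowMeans(ab[, cc, drop = FALSE])
  }, numeric(nrow(ab)))
  if (is.null(dim(donor_mat))) donor_mat <- matrix(donor_mat, nrow = nrow(ab))
  colnames(donor_mat) <- donors$donor
  rownames(donor_mat) <- rownames(ab)

  yi <- donors$age_group == "young"
  oi <- donors$age_group == "old"
  if (sum(yi) < 2 || sum(oi) < 2)
    iflux_input_error("need >= 2 young and >= 2 old donors")

  res <- lapply(rownames(donor_mat), function(p) {
    y <- donor_mat[p, yi]; o <- donor_mat[p, oi]
    if (anyNA(y) || anyNA(o)) return(NULL)  # protein missing in one group
    tt <- tryCatch(student_ttest(o, y), immunoflux_degenerate_input = function(e) NULL)
    data.frame(protein = p,
               avg_young = mean(y), avg_old = mean(o),
               ratio = mean(o) / mean(y),
               p_value = if (is.null(tt)) 1 else tt$p_value,
               n_young = sum(yi), n_old = sum(oi))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Default thresholds of the differential-protein filter cascade
#'
#' Fold-change bounds 1.3 / 0.7, alpha 0.05, >= 2 unique peptides, high
#' peptide confidence, ion score > 30.
#'
#' @param up,down Ratio bounds: stage 1 keeps `ratio > up` or `ratio < down`.
#' @param alpha Stage-2 p-value threshold (`p < alpha`).
#' @param min_unique Minimum unique peptides (stage 3, `>=`).
#' @param min_conf Required peptide confidence level (stage 3).
#' @param min_ion Ion-score threshold (stage 3, strictly `>`).
#' @return Named list of thresholds.
#' @export
cascade_config <- function(up = 1.3, down = 0.7, alpha = 0.05,
                           min_unique = 2, min_conf = "high", min_ion = 30) {
  list(up = up, down = down, alpha = alpha, min_unique = min_unique,
       min_conf = min_conf, min_ion = min_ion)
}

#' Three-stage significance/evidence filter cascade
#'
#' Stage 1 keeps proteins with ratio above `up` or below `down`; stage 2 keeps
#' `p < alpha`; stage 3 keeps proteins with sufficient peptide evidence
#' (`unique_peptides >= min_unique`, confidence equal to `min_conf`,
#' `max_ion_score > min_ion`). Proteins without an evidence record fail stage 3
#' with a logged reason.
#'
#' @param records `data.frame` from [group_ratio_test()].
#' @param evidence `data.frame` with columns `protein`, `unique_peptides`,
#'   `confidence` (`"high"`/`"medium"`/`"low"`), `max_ion_score`.
#' @param config Thresholds from [cascade_config()].
#' @return An object of class `filter_cascade_report`: per-stage counts
#'   (`n_input`, `n_pass_ratio`, `n_pass_pvalue`, `n_pass_evidence`), the
#'   `selected` accessions split into `up` and `down` subsets, the selected
#'   records, and per-stage rejection reasons.
#' @export
filter_cascade <- function(records, evidence, config = cascade_config()) {
  if (is.null(records) || !nrow(records)) {
    return(structure(list(n_input = 0L, n_pass_ratio = 0L, n_pass_pvalue = 0L,
                          n_pass_evidence = 0L, selected = character(0),
                          up = character(0), down = character(0),
                          records = records, rejections = data.frame(
                            protein = character(0), stage = character(0),
                            reason = character(0)),
                          config = config),
                     class = "filter_cascade_report"))
  }
  rej_df <- function(proteins, stage, reason)
    data.frame(protein = proteins, stage = rep(stage, length(proteins)),
               reason = reason)
  rej <- list()
  s1 <- records$ratio > config$up | records$ratio < config$down
  rej[[1]] <- rej_df(records$protein[!s1], "ratio",
                     sprintf("ratio %.4f within [%g, %g]",
                             records$ratio[!s1], config$down, config$up))
  r1 <- records[s1, ]
  s2 <- r1$p_value < config$alpha
  rej[[2]] <- rej_df(r1$protein[!s2], "p_value",
                     sprintf("p %.4g >= %g", r1$p_value[!s2], config$alpha))
  r2 <- r1[s2, ]
  ev <- evidence[match(r2$protein, evidence$protein), ]
  has_ev <- !is.na(ev$protein)
  s3 <- has_ev & ev$unique_peptides >= config$min_unique &
    ev$confidence == config$min_conf & ev$max_ion_score > config$min_ion
  why <- ifelse(!has_ev, "no evidence record",
         ifelse(ev$unique_peptides < config$min_unique, "too few unique peptides",
         ifelse(ev$confidence != config$min_conf, "insufficient confidence",
                "ion score too low")))
  rej[[3]] <- rej_df(r2$protein[!s3], "evidence", why[!s3])
  r3 <- r2[s3, ]

  structure(list(n_input = nrow(records),
                 n_pass_ratio = nrow(r1),
                 n_pass_pvalue = nrow(r2),
                 n_pass_evidence = nrow(r3),
                 selected = r3$protein,
                 up = r3$protein[r3$ratio > config$up],
                 down = r3$protein[r3$ratio < config$down],
                 records = r3,
                 rejections = do.call(rbind, rej),
                 config = config),
            class = "filter_cascade_report")
}

#' @export
print.filter_cascade_report <- function(x, ...) {
  cat("Filter cascade:", x$n_input, "->", x$n_pass_ratio, "(ratio) ->",
      x$n_pass_pvalue, "(p) ->", x$n_pass_evidence, "(evidence)\n")
  cat("  up:", length(x$up), " down:", length(x$down), "\n")
  invisible(x)
}

#' Format a differential table in the presentation used for reporting
#'
#' Ratios and group averages rounded to 4 decimals, ranked by p-value.
#'
#' @param records `data.frame` from [group_ratio_test()].
#' @return `data.frame` sorted by `p_value` with rounded display columns.
#' @export
format_differential_table <- function(records) {
  out <- records[order(records$p_value), ]
  out$avg_young <- round(out$avg_young, 4)
  out$avg_old <- round(out$avg_old, 4)
  out$ratio <- round(out$ratio, 4)
  out$p_value <- round(out$p_value, 4)
  rownames(out) <- NULL
  out
}

## -- plain-text readers -------------------------------------------------------

#' Read one plex intensity TSV plus its design rows
#'
#' The TSV has a `protein_id` column followed by one column per channel named
#' `<plex>:<tag>`. The design table maps `plex, tag, donor, age_group, role`.
#'
#' @param path Path to the plex TSV.
#' @param plex_id Plex identifier matching the design table.
#' @param design `data.frame` with columns `plex`, `tag`, `donor`,
#'   `age_group`, `role`.
#' @return A [protein_quant_table()].
#' @export
read_plex_tsv <- function(path, plex_id, design) {
  df <- read.delim(path, check.names = FALSE)
  if (!"protein_id" %in% names(df))
    iflux_input_error("plex TSV must have a protein_id column")
  m <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  rownames(m) <- df$protein_id
  colnames(m) <- sub("^.*:", "", colnames(m))
  d <- design[design$plex == plex_id, ]
  protein_quant_table(plex_id, m,
                      data.frame(channel = d$tag, donor = d$donor,
                                 age_group = d$age_group, role = d$role))
}

#' Read a protein evidence TSV
#'
#' Columns: `protein_id`, `unique_peptides`, `confidence`, `max_ion_score`.
#'
#' @param path Path to the evidence TSV.
#' @return `data.frame` with the column names used by [filter_cascade()].
#' @export
read_evidence_tsv <- function(path) {
  df <- read.delim(path)
  data.frame(protein = df$protein_id, unique_peptides = df$unique_peptides,
             confidence = df$confidence, max_ion_score = df$max_ion_score)
}
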