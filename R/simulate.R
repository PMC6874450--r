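## Seeded synthetic-data generators. Each generator is a pure function of
## (config, seed): it emulates the statistical structure of one assay arm of
## the study design (sample sizes, planted effect directions) and returns a
## ground-truth sidecar sufficient to score recovery of every planted effect.

#' Study-wide synthetic-data configuration
#'
#' Defaults mirror the study design: 4 young vs 18 old donors across four
#' 8plex runs sharing one reference channel for proteomics; 8 young vs 25 old
#' expression arrays; 7 vs 7 respirometry donors; 5 young vs 4 old TEM donors
#' imaged 15/12 times per subset; 12 vs 12 flow donors at 20,000 events.
#' Planted effects follow the reported directions: a 1.5-fold mitochondrial
#' protein up-shift in old, a -0.5 Z down-shift of OXPHOS gene sets in old,
#' lower reserve capacity and higher non-mitochondrial respiration in old,
#' inflated autophagosome counts in old, and a larger intermediate-intensity
#' mitophagy-dye mass in old.
#'
#' @param seed Integer seed recorded in every generator output.
#' @param ... Named overrides of top-level sections (`proteomics`,
#'   `expression`, `respirometry`, `morphometry`, `flow`), each a list merged
#'   over the defaults.
#' @return Nested configuration list of class `study_config`.
#' @export
study_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    proteomics = list(
      n_young = 4, n_old = 18, n_proteins = 3510, n_mito_up = 30,
      up_fold = 1.5, intensity_cv = 0.10, n_plexes = 4,
      n_technical_duplicates = 6, evidence_fail = 0.05,
      base_meanlog = log(1e6), base_sdlog = 0.5, batch_sdlog = 0.2),
    expression = list(
      n_genes = 2000, n_young = 8, n_old = 25,
      young_sex = c(rep("M", 5), rep("F", 3)),
      old_sex = c(rep("M", 19), rep("F", 6)),
      baseline_mean = 8, baseline_sd = 1.5, noise_sd = 0.35,
      n_random_sets = 45, set_size_range = c(15, 40),
      n_planted_sets = 5, planted_prefix = "OXPHOS",
      planted_z_shift = -0.5, dropout_frac = 0.05),
    respirometry = list(
      n_young = 7, n_old = 7,
      young_means = c(routine = 50, leak = 12, ets = 130, rox = 5),
      old_means = c(routine = 45, leak = 14, ets = 90, rox = 9),
      between_donor_cv = 0.10, noise_sd = 0.05, o2_start = 350,
      dt = 1, t_oligomycin = 480, segment_leak = 480, fccp_steps = 3,
      segment_fccp = 240, fccp_fractions = c(0.85, 1, 0.95),
      segment_rotenone = 240, segment_antimycin = 600,
      rotenone_rox_factor = 1.5, artifact_size = 2, artifact_tau = 10,
      memory_young = c(26, 40), memory_old = c(41, 48),
      include_memory_outlier = TRUE, memory_outlier_pct = 59),
    morphometry = list(
      n_young_donors = 5, n_old_donors = 4,
      cells = c(young_naive = 15, old_naive = 12, young_memory = 15,
                old_memory = 12),
      ap_mean = c(young_naive = 2, old_naive = 6, young_memory = 4,
                  old_memory = 7),
      al_mean = c(young_naive = 2, old_naive = 2, young_memory = 2,
                  old_memory = 2),
      mito_mean = c(young_naive = 8, old_naive = 8, young_memory = 13,
                    old_memory = 13),
      mito_area_meanlog = c(naive = log(1.0), memory = log(1.5)),
      mito_area_sdlog = 0.35, cytosol_meanlog = log(120),
      cytosol_sdlog = 0.15, vesicle_area_meanlog = log(0.8),
      vesicle_area_sdlog = 0.4),
    flow = list(
      n_young = 12, n_old = 12, n_events = 20000,
      component_meanlog = c(lo = log(5), int = log(80), hi = log(800)),
      component_sdlog = c(lo = 0.5, int = 0.4, hi = 0.35),
      unstained_meanlog = log(4), unstained_sdlog = 0.5,
      weights = list(
        dye_only = list(young = c(0.75, 0.20, 0.05),
                        old = c(0.60, 0.35, 0.05)),
        cccp = list(young = c(0.30, 0.20, 0.50),
                    old = c(0.25, 0.30, 0.45)),
        bafilomycin = list(young = c(0.50, 0.45, 0.05),
                           old = c(0.35, 0.60, 0.05))),
      donor_int_jitter_sd = 0.06,
      conditions = c("unstained", "dye_only", "cccp", "bafilomycin")))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) iflux_input_error(sprintf("unknown config section '%s'", nm))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  }
  structure(cfg, class = c("study_config", "list"))
}

lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

## -- proteomics ---------------------------------------------------------------

proteomics_design <- function(p) {
  donors <- c(paste0("y", seq_len(p$n_young)), paste0("o", seq_len(p$n_old)))
  ages <- c(rep("young", p$n_young), rep("old", p$n_old))
  n_bio <- length(donors)
  slots_per_plex <- 8L - 1L  # one reference channel per plex
  total_slots <- p$n_plexes * slots_per_plex
  if (n_bio + p$n_technical_duplicates != total_slots)
    iflux_input_error("donors + duplicates must fill the non-reference channels")
  dup_donors <- donors[rep_len(seq_len(n_bio), p$n_technical_duplicates)]
  all_donor <- c(donors, dup_donors)
  all_age <- c(ages, ages[rep_len(seq_len(n_bio), p$n_technical_duplicates)])
  all_role <- c(rep("biological", n_bio),
                rep("technical_duplicate", p$n_technical_duplicates))
  tags <- c("113", "114", "115", "116", "117", "118", "119", "121")
  design <- list()
  k <- 1L
  for (px in seq_len(p$n_plexes)) {
    rows <- data.frame(plex = paste0("plex", px), tag = tags,
                       donor = NA_character_, age_group = NA_character_,
                       role = NA_character_)
    rows$donor[1] <- "reference"; rows$age_group[1] <- "young"
    rows$role[1] <- "reference"
    for (j in 2:8) {
      rows$donor[j] <- all_donor[k]; rows$age_group[j] <- all_age[k]
      rows$role[j] <- all_role[k]; k <- k + 1L
    }
    design[[px]] <- rows
  }
  do.call(rbind, design)
}

#' Simulate multi-plex iTRAQ protein quantification data
#'
#' Log-normal reporter intensities over `n_plexes` 8plex runs sharing one
#' common reference channel (drawn once per protein, rescaled by a plex-level
#' batch factor), with `n_mito_up` planted proteins multiplied by `up_fold`
#' in old donors' channels. Evidence fields are drawn so a small configured
#' fraction of proteins fails each stage of the filter cascade.
#'
#' @param config A [study_config()].
#' @return List with `tables` (list of [protein_quant_table()]), `evidence`
#'   (`data.frame`), `design` and `truth` (planted accessions, fold, seed).
#' @export
simulate_proteomics <- function(config = study_config()) {
  p <- config$proteomics
  with_preserved_seed(config$seed + 101L, {
    n <- p$n_proteins
    planted <- sprintf("MTUP%04d", seq_len(p$n_mito_up))
    nulls <- sprintf("PROT%04d", seq_len(n - p$n_mito_up))
    prots <- c(planted, nulls)
    design <- proteomics_design(p)

    sdlog <- lnorm_sdlog(p$intensity_cv)
    base <- rlnorm(n, p$base_meanlog, p$base_sdlog)
    ref0 <- base * rlnorm(n, 0, sdlog)  # reference drawn once, reused
    names(base) <- names(ref0) <- prots

    tables <- lapply(unique(design$plex), function(px) {
      d <- design[design$plex == px, ]
      batch <- rlnorm(1, 0, p$batch_sdlog)
      m <- matrix(NA_real_, n, nrow(d), dimnames = list(prots, d$tag))
      for (j in seq_len(nrow(d))) {
        if (d$role[j] == "reference") {
          m[, j] <- ref0 * batch
        } else {
          fold <- ifelse(prots %in% planted & d$age_group[j] == "old",
                         p$up_fold, 1)
          m[, j] <- base * fold * rlnorm(n, 0, sdlog) * batch
        }
      }
      protein_quant_table(px, m, data.frame(channel = d$tag, donor = d$donor,
                                            age_group = d$age_group,
                                            role = d$role))
    })

    evidence <- data.frame(
      protein = prots,
      unique_peptides = ifelse(runif(n) < p$evidence_fail, 1L,
                               2L + rpois(n, 3)),
      confidence = ifelse(runif(n) < p$evidence_fail, "medium", "high"),
      max_ion_score = ifelse(runif(n) < p$evidence_fail, runif(n, 5, 30),
                             runif(n, 31, 120)))

    list(tables = tables, evidence = evidence, design = design,
         truth = list(planted_up = planted, up_fold = p$up_fold,
                      seed = config$seed))
  })
}

## -- expression ---------------------------------------------------------------

#' Simulate a gene expression study with planted pathway shifts
#'
#' Gaussian log-signals per gene; `n_planted_sets` gene sets (named with
#' `planted_prefix`) are shifted in old samples by `planted_z_shift` units of
#' the between-gene Z scale. Detection p-values are near zero for expressed
#' genes and high for a `dropout_frac` fraction of undetected genes. Random
#' null sets are drawn from the non-planted genes.
#'
#' @param config A [study_config()].
#' @return List with `expression` (an [expression_matrix()]), `sets`
#'   (a [gene_set_collection()]) and `truth` (planted set names and genes,
#'   shift, seed).
#' @export
simulate_expression <- function(config = study_config()) {
  e <- config$expression
  with_preserved_seed(config$seed + 202L, {
    genes <- sprintf("GENE%05d", seq_len(e$n_genes))
    samples <- data.frame(
      sample = c(paste0("Y", seq_len(e$n_young)), paste0("O", seq_len(e$n_old))),
      age_group = c(rep("young", e$n_young), rep("old", e$n_old)),
      sex = c(e$young_sex, e$old_sex))
    n_s <- nrow(samples)

    baseline <- rnorm(e$n_genes, e$baseline_mean, e$baseline_sd)
    sig <- baseline + matrix(rnorm(e$n_genes * n_s, 0, e$noise_sd),
                             e$n_genes, n_s)
    dimnames(sig) <- list(genes, samples$sample)

    ## planted sets drawn from a reserved pool so null sets stay null
    sizes <- sample(seq(e$set_size_range[1], e$set_size_range[2]),
                    e$n_planted_sets + e$n_random_sets, replace = TRUE)
    pool_size <- sum(sizes[seq_len(e$n_planted_sets)])
    pool <- sample(genes, pool_size)
    planted_sets <- list(); used <- 0
    for (i in seq_len(e$n_planted_sets)) {
      planted_sets[[sprintf("%s_SET%d", e$planted_prefix, i)]] <-
        pool[(used + 1):(used + sizes[i])]
      used <- used + sizes[i]
    }
    null_genes <- setdiff(genes, pool)
    random_sets <- list()
    for (i in seq_len(e$n_random_sets)) {
      random_sets[[sprintf("RANDOM_SET%d", i)]] <-
        sample(null_genes, sizes[e$n_planted_sets + i])
    }

    total_sd <- sqrt(e$baseline_sd^2 + e$noise_sd^2)
    shift <- e$planted_z_shift * total_sd
    old_cols <- samples$age_group == "old"
    planted_genes <- unlist(planted_sets, use.names = FALSE)
    sig[planted_genes, old_cols] <- sig[planted_genes, old_cols] + shift

    det <- matrix(runif(e$n_genes * n_s, 0, 0.01), e$n_genes, n_s,
                  dimnames = dimnames(sig))
    drop_idx <- sample(seq_len(e$n_genes), round(e$dropout_frac * e$n_genes))
    det[drop_idx, ] <- runif(length(drop_idx) * n_s, 0.1, 1)

    em <- expression_matrix(sig, det, samples)
    sets <- gene_set_collection(c(planted_sets, random_sets))
    list(expression = em, sets = sets,
         truth = list(planted_sets = names(planted_sets),
                      planted_genes = planted_genes,
                      z_shift = e$planted_z_shift,
                      dropped_genes = genes[drop_idx], seed = config$seed))
  })
}

## -- respirometry -------------------------------------------------------------

build_trace <- function(states, r, dt = r$dt) {
  ## piecewise-constant true flux encoded as a piecewise-linear O2 decline
  t_oli <- r$t_oligomycin
  t_fccp <- t_oli + r$segment_leak + (seq_len(r$fccp_steps) - 1) * r$segment_fccp
  t_rot <- t_fccp[r$fccp_steps] + r$segment_fccp
  t_ant <- t_rot + r$segment_rotenone
  t_end <- t_ant + r$segment_antimycin
  ev <- data.frame(
    time_s = c(t_oli, t_fccp, t_rot, t_ant),
    agent = c("oligomycin", rep("fccp_step", r$fccp_steps), "rotenone",
              "antimycin_a"))
  tt <- seq(0, t_end, by = dt)
  flux <- numeric(length(tt))
  flux[tt < t_oli] <- states["routine"]
  flux[tt >= t_oli & tt < t_fccp[1]] <- states["leak"]
  for (i in seq_len(r$fccp_steps)) {
    hi <- if (i < r$fccp_steps) t_fccp[i + 1] else t_rot
    flux[tt >= t_fccp[i] & tt < hi] <- states["ets"] * r$fccp_fractions[i]
  }
  flux[tt >= t_rot & tt < t_ant] <- states["rox"] * r$rotenone_rox_factor
  flux[tt >= t_ant] <- states["rox"]
  ## pmol/s/1e6 cells -> nmol/mL/s for the default 2 mL / 5e6 cell chamber
  dcdt <- flux * (5e6 / 1e6) / (2 * 1000)
  conc <- r$o2_start - cumsum(c(0, dcdt[-length(dcdt)] * dt))
  ## injection transients, decayed well inside the settle window
  for (te in ev$time_s)
    conc <- conc + ifelse(tt >= te, r$artifact_size * exp(-(tt - te) / r$artifact_tau), 0)
  conc <- conc + rnorm(length(tt), 0, r$noise_sd)
  oxygraph_trace(tt, conc, ev)
}

#' Simulate a respirometry cohort of event-annotated oxygen traces
#'
#' Per-donor true state fluxes are drawn around group means (young: higher
#' ETS/reserve, lower ROX; old: the reverse) and encoded as piecewise-linear
#' oxygen declines with injection transients and white measurement noise.
#' Memory-cell percentages are drawn per group, optionally with one planted
#' high-memory old donor emulating the flow-phenotype outlier.
#'
#' @param config A [study_config()].
#' @return List with `traces` (named list of [oxygraph_trace()]), `cohort`
#'   (`data.frame`: donor, age_group, memory_pct) and `truth` (per-donor true
#'   state fluxes and BHI, seed).
#' @export
simulate_oxygraph <- function(config = study_config()) {
  r <- config$respirometry
  with_preserved_seed(config$seed + 303L, {
    donors <- c(paste0("ry", seq_len(r$n_young)), paste0("ro", seq_len(r$n_old)))
    ages <- c(rep("young", r$n_young), rep("old", r$n_old))
    sdlog <- lnorm_sdlog(r$between_donor_cv)
    true_states <- lapply(seq_along(donors), function(i) {
      mu <- if (ages[i] == "young") r$young_means else r$old_means
      mu * rlnorm(4, 0, sdlog)
    })
    names(true_states) <- donors
    traces <- lapply(true_states, build_trace, r = r)

    mem <- ifelse(ages == "young",
                  runif(length(donors), r$memory_young[1], r$memory_young[2]),
                  runif(length(donors), r$memory_old[1], r$memory_old[2]))
    if (r$include_memory_outlier && r$n_old >= 1)
      mem[length(mem)] <- r$memory_outlier_pct

    true_bhi <- vapply(true_states, function(s)
      log10(((s["ets"] - s["routine"]) * (s["routine"] - s["leak"])) /
              (s["rox"] * (s["leak"] - s["rox"]))), numeric(1))

    list(traces = traces,
         cohort = data.frame(donor = donors, age_group = ages,
                             memory_pct = mem),
         truth = list(states = true_states, bhi = true_bhi,
                      seed = config$seed))
  })
}

## -- morphometry --------------------------------------------------------------

draw_vesicle <- function(id, class, m) {
  if (class == "AP") {
    dm <- runif(1, 0.4, 1)
    rib <- runif(1) < 0.10
    dens <- if (runif(1) < 0.7) "similar_to_cytosol" else "dense_amorphous"
    org <- runif(1) < 0.5
    multi <- FALSE
    diam <- runif(1, 0.5, 1.5)
  } else {
    dm <- if (runif(1) < 0.8) 0 else runif(1, 0.05, 0.35)
    rib <- if (dm > 0) TRUE else runif(1) < 0.5
    dens <- if (runif(1) < 0.8) "lower_than_cytosol" else "dense_amorphous"
    org <- FALSE
    multi <- runif(1) < 0.9
    diam <- runif(1, 0.5, 1.2)
  }
  vesicle_features(id, diam, dm, rib, dens, org, multi,
                   area_au = rlnorm(1, log(0.8), 0.4))
}

#' Simulate TEM cell annotations with planted count differences
#'
#' Per-stratum Poisson counts for autophagosomes, autolysosomes and
#' mitochondria (old naive cells carry the planted AP inflation); vesicle
#' features are drawn consistent with the intended class so the rule-based
#' classifier recovers the planted label with high fidelity; areas are
#' log-normal.
#'
#' @param config A [study_config()].
#' @return List with `cells` (list of [cell_annotation()]), `truth` (planted
#'   per-vesicle labels and stratum means, seed).
#' @export
simulate_morphometry <- function(config = study_config()) {
  m <- config$morphometry
  with_preserved_seed(config$seed + 404L, {
    cells <- list(); labels <- list()
    for (stratum in names(m$cells)) {
      parts <- strsplit(stratum, "_")[[1]]
      age <- parts[1]; subset <- parts[2]
      nd <- if (age == "young") m$n_young_donors else m$n_old_donors
      donors <- paste0(substr(age, 1, 1), "d", seq_len(nd))
      for (i in seq_len(m$cells[[stratum]])) {
        cid <- sprintf("%s_cell%02d", stratum, i)
        n_ap <- rpois(1, m$ap_mean[[stratum]])
        n_al <- rpois(1, m$al_mean[[stratum]])
        cls <- c(rep("AP", n_ap), rep("AL", n_al))
        ves <- if (length(cls)) do.call(rbind, lapply(seq_along(cls), function(k)
          draw_vesicle(sprintf("%s_v%d", cid, k), cls[k], m)))
          else data.frame(vesicle_id = character(0))
        n_mito <- rpois(1, m$mito_mean[[stratum]])
        mito <- if (n_mito) rlnorm(n_mito, m$mito_area_meanlog[[subset]],
                                   m$mito_area_sdlog) else numeric(0)
        cells[[cid]] <- cell_annotation(
          cid, donors[((i - 1) %% nd) + 1], age, subset,
          rlnorm(1, m$cytosol_meanlog, m$cytosol_sdlog), mito, ves)
        labels[[cid]] <- cls
      }
    }
    list(cells = cells,
         truth = list(labels = labels, ap_mean = m$ap_mean,
                      al_mean = m$al_mean, mito_mean = m$mito_mean,
                      seed = config$seed))
  })
}

## -- flow ---------------------------------------------------------------------

draw_mixture <- function(n, w, f) {
  comp <- sample.int(3, n, replace = TRUE, prob = w)
  rlnorm(n, f$component_meanlog[comp], f$component_sdlog[comp])
}

#' Simulate mitophagy-dye flow cytometry event tables
#'
#' Per-event intensities are three-component log-normal mixtures (lo / int /
#' hi compartments). Condition effects move mass between components (CCCP
#' toward hi, bafilomycin toward int); old dye-only samples carry more
#' intermediate mass than young. A shared per-donor jitter on the intermediate
#' weight creates realistic between-donor variability while preserving paired
#' within-donor condition effects.
#'
#' @param config A [study_config()].
#' @return List with `tables` (list of [flow_event_table()]) and `truth`
#'   (per-sample mixture weights, seed).
#' @export
simulate_flow <- function(config = study_config()) {
  f <- config$flow
  with_preserved_seed(config$seed + 505L, {
    donors <- c(paste0("fy", seq_len(f$n_young)), paste0("fo", seq_len(f$n_old)))
    ages <- c(rep("young", f$n_young), rep("old", f$n_old))
    jit <- rnorm(length(donors), 0, f$donor_int_jitter_sd)
    tables <- list(); weights <- list()
    for (i in seq_along(donors)) {
      for (cond in f$conditions) {
        sid <- paste(donors[i], cond, sep = "_")
        if (cond == "unstained") {
          x <- rlnorm(f$n_events, f$unstained_meanlog, f$unstained_sdlog)
          weights[[sid]] <- c(NA, NA, NA)
        } else {
          w <- f$weights[[cond]][[ages[i]]]
          w[2] <- max(0, min(0.97, w[2] + jit[i]))
          w[1] <- max(0, w[1] - jit[i])
          w <- w / sum(w)
          x <- draw_mixture(f$n_events, w, f)
          weights[[sid]] <- w
        }
        tables[[sid]] <- flow_event_table(sid, donors[i], ages[i], cond, x)
      }
    }
    list(tables = tables,
         truth = list(weights = weights, donor_int_jitter = setNames(jit, donors),
                      seed = config$seed))
  })
}
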