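# Small in-code fixtures shared across test files.

# One plex with a reference channel and two biological donors per group.
toy_plex <- function(plex_id = "plex1", intensities = NULL) {
  prots <- c("P1", "P2", "P3")
  if (is.null(intensities)) {
    intensities <- rbind(P1 = c(100, 200, 100, 150, 120),
                         P2 = c(50, 50, 50, 50, 50),
                         P3 = c(10, 40, 20, 30, 10))
  }
  colnames(intensities) <- c("113", "114", "115", "116", "117")
  protein_quant_table(
    plex_id, intensities,
    data.frame(channel = c("113", "114", "115", "116", "117"),
               donor = c("reference", "y1", "y2", "o1", "o2"),
               age_group = c("young", "young", "young", "old", "old"),
               role = c("reference", rep("biological", 4))))
}

# A normalized-structure object with explicit donor columns, bypassing plexes.
toy_normalized <- function(mat, donors, ages, roles = NULL) {
  if (is.null(roles)) roles <- rep("biological", length(donors))
  colnames(mat) <- paste0("plex1:", seq_along(donors))
  list(abundance = mat,
       columns = data.frame(column = colnames(mat), plex = "plex1",
                            channel = as.character(seq_along(donors)),
                            donor = donors, age_group = ages, role = roles),
       dropped = data.frame(protein = character(0), reason = character(0)))
}

# Noise-free oxygraph trace with chosen plateau fluxes (pmol/s/1e6 cells).
toy_trace <- function(routine = 50, leak = 12, ets = 130, rox = 6,
                      fccp_fractions = c(0.85, 1, 0.95), noise_sd = 0,
                      artifact_size = 0, seed = 1) {
  cfg <- study_config(seed = seed,
                      respirometry = list(noise_sd = noise_sd,
                                          artifact_size = artifact_size,
                                          between_donor_cv = 0,
                                          fccp_fractions = fccp_fractions,
                                          n_young = 1, n_old = 1,
                                          young_means = c(
                                            routine = as.numeric(routine),
                                            leak = as.numeric(leak),
                                            ets = as.numeric(ets),
                                            rox = as.numeric(rox))))
  simulate_oxygraph(cfg)$traces[[1]]
}

# A vesicle row from discretized feature levels.
make_vesicle <- function(dm, rib, dens, org, multi, diameter = 1, area = 1) {
  vesicle_features("v", diameter, dm, rib, dens, org, multi, area)
}

# Independent restatement of the published AP/AL identification rules,
# written as literal prose-order conditionals (the truth-table oracle).
oracle_classify <- function(dm, rib, dens, org, multi, diameter = 1,
                            size_min = 0.5) {
  if (diameter < size_min) return("unclassified")
  n_criteria <- 0
  if (dm > 0) n_criteria <- n_criteria + 1                  # double membrane
  if (!rib) n_criteria <- n_criteria + 1                    # no ribosomes
  if (dens == "similar_to_cytosol") n_criteria <- n_criteria + 1
  if (org) n_criteria <- n_criteria + 1                     # organelle inside
  if (n_criteria >= 2) return("AP")
  if (dm < 0.4) {
    if (dens == "lower_than_cytosol") return("AL")
    if (multi && dens %in% c("lower_than_cytosol", "dense_amorphous"))
      return("AL")
  }
  "unclassified"
}
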