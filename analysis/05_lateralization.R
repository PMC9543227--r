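# Lateralized-subgroup analysis. Two parts:
#   (a) on the main cohort: assign each patient a dominant motor side
#       from the UPDRS-III items 20-26 and rerun the NBS per subgroup
#       (dominant side dropped from the confounds);
#   (b) on a cohort with contralateral planting (left-affected patients
#       lose right-hemisphere connectivity and vice versa): check that
#       each subgroup's network is dominated by the hemisphere opposite
#       its symptoms, and that a subgroup's NI mask, cross-applied to
#       the other subgroup, shows no longitudinal change there.

source("analysis/00_config.R")

cohort <- read_cohort(file.path(RESULTS, "cohort"))
atlas <- cohort$atlas

sides <- cohort_side_assignments(cohort)
write.csv(sides, file.path(RESULTS, "05_side_assignments.csv"),
          row.names = FALSE)
cat("dominant-side labels (main cohort):\n"); print(table(sides$label))

run_side <- function(co, side, assignments, seed_off) {
  n_side <- sum(assignments$label == side)
  if (n_side < 5) {
    cat(sprintf("%s subgroup too small (n = %d); skipping NBS\n",
                side, n_side))
    return(NULL)
  }
  sg <- subgroup_nbs(co, side, confounds = CONFOUNDS,
                     assignments = assignments,
                     primary_threshold = NBS_THRESHOLD,
                     n_permutations = N_PERMUTATIONS,
                     seed = longconn:::derive_seed(SEED, seed_off))
  cat(sprintf("\n%s subgroup (n = %d):\n", side, sg$n))
  if (!length(sg$nbs$components)) { cat("  no components\n"); return(NULL) }
  top <- sg$nbs$components[[1]]
  ds <- dominance_summary(top, atlas)
  cat(sprintf("  top component: %d edges, corrected p = %.4g\n",
              top$n_edges, top$component_pvalue))
  cat("  hemisphere edge shares:\n"); print(round(ds$edge_shares, 3))
  entry <- list(n = sg$n, top_n_edges = top$n_edges,
                top_p = top$component_pvalue,
                edge_shares = as.list(ds$edge_shares),
                own_ni_p = longitudinal_ni_test(sg$ni$own)$p_bonferroni)
  if (!is.null(sg$ni$other)) {
    entry$other_ni_p <- longitudinal_ni_test(sg$ni$other)$p_bonferroni
    cat("  NI cross-applied to the other subgroup, corrected p:\n   ")
    cat(sprintf(" %.3g", entry$other_ni_p), "\n")
  }
  entry
}

out <- list(side_counts = as.list(table(sides$label)))
for (side in c("LPD", "RPD")) {
  out[[paste0("main_", side)]] <- run_side(cohort, side, sides,
                                           50 + nchar(side))
}

cat("\n-- contralateral-planting cohort --\n")
peR <- planted_effect(default_planted_subnetwork(atlas, hemisphere = "R",
                                                 seed = 71))
peL <- planted_effect(default_planted_subnetwork(atlas, hemisphere = "L",
                                                 seed = 72))
lat_cohort <- simulate_longitudinal_cohort(
  atlas, n_pd = 35, n_hc = 10, planted = list(L = peR, R = peL),
  seed = longconn:::derive_seed(SEED, 60))
lat_sides <- cohort_side_assignments(lat_cohort)
print(table(lat_sides$label))
for (side in c("LPD", "RPD")) {
  out[[paste0("lateralized_", side)]] <-
    run_side(lat_cohort, side, lat_sides, 70 + nchar(side))
}

write_results(out, RESULTS, name = "05_lateralization", config = CFG)
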