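#' Simulation studies: calibration, recovery, and the demo pipeline
#'
#' Reusable study drivers at the package's reference conditions: cohort
#' sizes and the planted-network shape mirror the longitudinal design the
#' pipeline targets (35 patients, three visits, a 125-edge / 72-region
#' right-dominant subnetwork), with effect sizes chosen for testability.
#'
#' @name simulation_studies
NULL

#' Planted-subnetwork recovery study
#'
#' Repeatedly simulates a cohort with a planted 125-edge decrement of
#' `3 x` the edge noise SD at the follow-up, runs the NBS, and measures
#' the Jaccard overlap between the top significant component and the
#' planted edge set.
#'
#' The primary threshold defaults to 4 here: the planted effect puts the
#' per-edge t far above any usual threshold, so threshold choice only
#' governs how many null edges slip in and attach to the detected
#' component; at ~22k candidate edges a lenient threshold dilutes the
#' recovered edge set with supra-threshold noise, which is measurement
#' artifact, not detection failure.
#'
#' @param n_reps number of replicate cohorts.
#' @param n_pd patients per cohort.
#' @param decrement follow-up mean decrement (default `3 x` the 0.02 edge
#'   noise SD).
#' @param primary_threshold NBS primary threshold.
#' @param n_permutations permutations per replicate.
#' @param seed top-level seed.
#' @return List with `jaccard` (per-rep values, NA when no significant
#'   component) and `hit_rate` (fraction of reps with overlap >= 0.8).
#' @export
recovery_study <- function(n_reps = 20, n_pd = 35, decrement = 0.06,
                           primary_threshold = 4, n_permutations = 200,
                           seed = 1) {
  atlas <- default_atlas()
  planted <- default_planted_subnetwork(atlas)
  jac <- vapply(seq_len(n_reps), function(r) {
    pe <- planted_effect(planted, decrement = c(BL = 0, "5YFU" = decrement))
    co <- simulate_longitudinal_cohort(atlas, n_pd = n_pd, n_hc = 0,
                                       timepoints = c("BL", "5YFU"),
                                       planted = pe,
                                       seed = derive_seed(seed, r))
    res <- nbs(co, "BL", "5YFU",
               confounds = c("age", "sex", "education", "ledd",
                             "dominant_side"),
               primary_threshold = primary_threshold,
               n_permutations = n_permutations,
               seed = derive_seed(seed, 5000 + r))
    sig <- Filter(function(co.) isTRUE(co.$significant), res$components)
    if (!length(sig)) return(NA_real_)
    edge_jaccard(sig[[1]]$edges, planted)
  }, numeric(1))
  list(jaccard = jac, hit_rate = mean(!is.na(jac) & jac >= 0.8))
}

#' NI longitudinal power and false-positive study
#'
#' Power: cohorts with the default progressive decrement (0.05 / 0.10 on
#' the planted network); the NI over the planted mask is tested BL vs
#' 5YFU with Bonferroni correction over the three visit pairs. False
#' positives: no-decrement cohorts, same mask, uncorrected BL vs 5YFU
#' test at the 0.05 level.
#'
#' @param n_reps replicates per arm.
#' @param n_pd patients per cohort.
#' @param seed top-level seed.
#' @return List with `power`, `fpr`, and the per-rep p-value vectors.
#' @export
ni_power_study <- function(n_reps = 100, n_pd = 35, seed = 1) {
  atlas <- default_atlas()
  planted <- default_planted_subnetwork(atlas)
  run_arm <- function(decremented, offset) {
    vapply(seq_len(n_reps), function(r) {
      pe <- if (decremented) planted_effect(planted) else NULL
      co <- simulate_longitudinal_cohort(atlas, n_pd = n_pd, n_hc = 0,
                                         planted = pe,
                                         seed = derive_seed(seed, offset + r))
      traj <- ni_trajectories(co, planted)
      out <- longitudinal_ni_test(traj)
      row <- out[out$tp_a == "BL" & out$tp_b == "5YFU", ]
      if (decremented) row$p_bonferroni else row$p
    }, numeric(1))
  }
  p_alt <- run_arm(TRUE, 0)
  p_null <- run_arm(FALSE, 20000)
  list(power = mean(p_alt < 0.05), fpr = mean(p_null < 0.05),
       p_alt = p_alt, p_null = p_null)
}

#' NI-score correlation recovery study
#'
#' Simulates a large cohort whose MoCA change is coupled to the realized
#' planted-edge loss with score noise set for a target correlation
#' `rho`, then measures the sample correlation between the NI change and
#' the MoCA change; also returns the NI-change vs UPDRS-III-change
#' correlation (negative by construction: motor scores worsen as
#' connectivity drops).
#'
#' @param n number of patients.
#' @param rho target NI-change / MoCA-change correlation.
#' @param seed seed.
#' @return List with `r_moca`, `r_updrs`, `n`.
#' @export
correlation_recovery_study <- function(n = 200, rho = 0.6, seed = 1) {
  atlas <- small_atlas(20)
  planted_edges <- all_edges(20)[seq(1, 190, by = 10), ]
  dec <- 0.10
  subject_sd <- 0.25
  edge_sd <- 0.02
  loss_sd <- sqrt((subject_sd * dec)^2 +
                    2 * edge_sd^2 / nrow(planted_edges))
  pe <- planted_effect(planted_edges,
                       decrement = c(BL = 0, "3YFU" = 0.05, "5YFU" = dec),
                       score_coupling = -20,
                       edge_noise_sd = edge_sd, subject_sd = subject_sd,
                       score_noise_sd = score_noise_for_rho(20, loss_sd, rho))
  co <- simulate_longitudinal_cohort(atlas, n_pd = n, n_hc = 0,
                                     planted = pe, seed = seed)
  traj <- ni_trajectories(co, planted_edges)
  r_moca <- correlate_ni_score(co, traj, "moca", "change-vs-change",
                               interval = c("BL", "5YFU"))
  r_updrs <- correlate_ni_score(co, traj, "updrs3", "change-vs-change",
                                interval = c("BL", "5YFU"))
  list(r_moca = r_moca$r, r_updrs = r_updrs$r, n = r_moca$n)
}

#' Contralateral-dominance recovery study
#'
#' Cohorts with side-specific planting - left-affected patients lose
#' right-hemisphere connectivity and vice versa - analyzed per subgroup;
#' a replicate counts as recovered when the left-affected subgroup's top
#' component is right-dominant (intra-R edge share > 0.5).
#'
#' @param n_reps replicates.
#' @param n_pd patients per cohort.
#' @param seed top-level seed.
#' @return List with `recovered` (logical per rep) and `rate`.
#' @export
lateralization_recovery_study <- function(n_reps = 10, n_pd = 35, seed = 1) {
  atlas <- default_atlas()
  peR <- planted_effect(default_planted_subnetwork(atlas, hemisphere = "R",
                                                   seed = 71))
  peL <- planted_effect(default_planted_subnetwork(atlas, hemisphere = "L",
                                                   seed = 72))
  recovered <- vapply(seq_len(n_reps), function(r) {
    co <- simulate_longitudinal_cohort(atlas, n_pd = n_pd, n_hc = 0,
                                       planted = list(L = peR, R = peL),
                                       seed = derive_seed(seed, 300 + r))
    sg <- withCallingHandlers(
      subgroup_nbs(co, "LPD",
                   confounds = c("age", "sex", "education", "ledd"),
                   primary_threshold = 3.2, n_permutations = 200,
                   seed = derive_seed(seed, 400 + r)),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!length(sg$nbs$components)) return(FALSE)
    ds <- dominance_summary(sg$nbs$components[[1]], atlas)
    ds$edge_shares[["intra-R"]] > 0.5
  }, logical(1))
  list(recovered = recovered, rate = mean(recovered))
}

#' Demo pipeline: simulate, analyze, and write results
#'
#' End-to-end run at demonstration scale: simulate a cohort with a
#' planted right-dominant decrement, run the NBS contrast BL vs 5YFU,
#' compute NI trajectories and longitudinal tests, correlate NI change
#' with MoCA change, summarize subnetwork dominance, and write all
#' results (JSON + subnetwork exports) under `out_dir`. Fully
#' deterministic in `seed`.
#'
#' @param out_dir output directory.
#' @param seed single seed for every stage.
#' @param n_regions atlas size (default 40: demonstration scale).
#' @param n_pd,n_hc group sizes.
#' @param n_permutations NBS permutations.
#' @return Invisibly, a list with the main result objects.
#' @export
demo_pipeline <- function(out_dir, seed = 1, n_regions = 40, n_pd = 20,
                          n_hc = 10, n_permutations = 300) {
  atlas <- small_atlas(n_regions)
  planted <- default_planted_subnetwork(atlas, n_edges = 30, n_regions = 16,
                                        hemisphere = "R",
                                        seed = derive_seed(seed, 1))
  pe <- planted_effect(planted)
  cohort <- simulate_longitudinal_cohort(atlas, n_pd = n_pd, n_hc = n_hc,
                                         planted = pe,
                                         seed = derive_seed(seed, 2))
  cfg <- run_config(seed = seed, n_regions = n_regions, n_pd = n_pd,
                    n_hc = n_hc, nbs_threshold = 3,
                    n_permutations = n_permutations)
  res <- nbs(cohort, "BL", "5YFU",
             confounds = c("age", "sex", "education", "ledd"),
             primary_threshold = 3, n_permutations = n_permutations,
             seed = derive_seed(seed, 3))
  sig <- Filter(function(x) isTRUE(x$significant), res$components)
  out <- list(n_components = length(res$components),
              n_significant = length(sig))
  if (length(sig)) {
    top <- sig[[1]]
    write_subnetwork(top, atlas, out_dir, name = "top_subnetwork",
                     meta = list(contrast = "BL>5YFU"))
    traj <- ni_trajectories(cohort, top, group = c("PD"))
    tests <- longitudinal_ni_test(traj)
    hc_traj <- ni_trajectories(cohort, top, group = "HC")
    hc_tests <- longitudinal_ni_test(hc_traj)
    corr <- correlate_ni_score(cohort, traj, "moca", "change-vs-change",
                               interval = c("BL", "5YFU"))
    ds <- dominance_summary(top, atlas)
    out <- c(out, list(
      top_n_edges = top$n_edges, top_n_regions = top$n_regions,
      top_pvalue = top$component_pvalue,
      jaccard_vs_planted = edge_jaccard(top$edges, planted),
      ni_tests = tests, hc_ni_tests = hc_tests,
      r_change_moca = corr$r, p_change_moca = corr$p,
      intra_r_share = ds$edge_shares[["intra-R"]]))
  }
  write_results(out, out_dir, name = "pipeline", config = cfg)
  invisible(out)
}
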