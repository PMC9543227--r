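# Network index over the discovered subnetwork: per-patient trajectories
# across the three visits, paired longitudinal tests (Bonferroni over the
# three visit pairs), cross-application to controls, correlation of NI
# change with MoCA/UPDRS-III change, and the change-correlated
# sub-subnetwork.

source("analysis/00_config.R")

cohort <- read_cohort(file.path(RESULTS, "cohort"))
top_edges <- read_subnetwork_edges(file.path(RESULTS, "03_top_subnetwork.tsv"))

traj <- ni_trajectories(cohort, top_edges, group = "PD")
tests <- longitudinal_ni_test(traj)
cat("PD NI longitudinal tests (Bonferroni m = 3):\n")
print(tests, digits = 3)

hc_tests <- longitudinal_ni_test(ni_trajectories(cohort, top_edges,
                                                 group = "HC"))
cat("HC NI longitudinal tests (same edge mask, cross-applied):\n")
print(hc_tests, digits = 3)

cors <- rbind(
  correlate_ni_score(cohort, traj, "moca", "same-timepoint",
                     timepoint = "3YFU"),
  correlate_ni_score(cohort, traj, "moca", "change-vs-change",
                     interval = c("BL", "5YFU")),
  correlate_ni_score(cohort, traj, "moca", "change-vs-change",
                     interval = c("BL", "5YFU"), drop_extreme = 2),
  correlate_ni_score(cohort, traj, "updrs3", "change-vs-change",
                     interval = c("3YFU", "5YFU"))
)
cors$note <- c("", "", "excl. 2 sharpest MoCA decliners", "")
cat("NI-score correlations:\n")
print(cors, digits = 3)

ccs <- change_correlated_subnetwork(cohort, top_edges, "moca",
                                    interval = c("BL", "5YFU"),
                                    edge_alpha = 0.05)
cat(sprintf("change-correlated subnetwork: %d of %d edges retained\n",
            ccs$n_edges, nrow(top_edges)))

write.csv(traj, file.path(RESULTS, "04_ni_trajectories.csv"),
          row.names = FALSE)
write_results(list(pd_tests = tests, hc_tests = hc_tests,
                   correlations = cors,
                   change_correlated_n_edges = ccs$n_edges),
              RESULTS, name = "04_ni", config = CFG)
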