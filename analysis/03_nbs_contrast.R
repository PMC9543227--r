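# Network-based statistic on the simulated cohort: which subnetwork is
# weaker at 5YFU than at BL in patients, adjusting for age, sex,
# education, LEDD, and dominant motor side?

source("analysis/00_config.R")

cohort <- read_cohort(file.path(RESULTS, "cohort"))
atlas <- cohort$atlas
planted <- read.csv(file.path(RESULTS, "planted_edges.csv"))

res <- nbs(cohort, "BL", "5YFU", confounds = CONFOUNDS,
           primary_threshold = NBS_THRESHOLD,
           n_permutations = N_PERMUTATIONS,
           seed = longconn:::derive_seed(SEED, 31))
print(res)

sig <- Filter(function(x) isTRUE(x$significant), res$components)
stopifnot(length(sig) >= 1)
top <- sig[[1]]
cat(sprintf("top component: %d edges / %d regions, corrected p = %.4g\n",
            top$n_edges, top$n_regions, top$component_pvalue))
cat(sprintf("overlap with the planted subnetwork (Jaccard): %.3f\n",
            edge_jaccard(top$edges, planted)))

ds <- dominance_summary(top, atlas)
cat("hemisphere edge shares:\n"); print(round(ds$edge_shares, 3))
cat("top-degree regions:\n"); print(head(ds$top_regions, 5))

write_subnetwork(top, atlas, RESULTS, name = "03_top_subnetwork",
                 meta = list(contrast = "BL>5YFU",
                             threshold = NBS_THRESHOLD,
                             n_permutations = N_PERMUTATIONS))
write_results(list(n_components = length(res$components),
                   top_n_edges = top$n_edges,
                   top_n_regions = top$n_regions,
                   top_p = top$component_pvalue,
                   jaccard_vs_planted = edge_jaccard(top$edges, planted),
                   edge_shares = as.list(ds$edge_shares),
                   lobe_pair_shares = as.list(ds$lobe_pair_shares)),
              RESULTS, name = "03_nbs", config = CFG)
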