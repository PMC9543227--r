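# Shared settings for the analysis scripts. Every script derives its
# randomness from this single seed and writes under results/.

library(longconn)
options(longconn.verbose = TRUE)

SEED <- as.integer(Sys.getenv("LONGCONN_SEED", "42"))
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

CONFOUNDS <- c("age", "sex", "education", "ledd", "dominant_side")
NBS_THRESHOLD <- 3.2
N_PERMUTATIONS <- 1000

CFG <- run_config(seed = SEED, nbs_threshold = NBS_THRESHOLD,
                  n_permutations = N_PERMUTATIONS,
                  confounds = paste(CONFOUNDS, collapse = ","))
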