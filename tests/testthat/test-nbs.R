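atlas8 <- toy_atlas(8)

test_that("identical matrices at both timepoints give all-zero t", {
  m <- edgevec_to_mat(runif(28, 0.3, 0.6), 8)
  mats <- lapply(1:5, function(s) list(BL = m, "5YFU" = m))
  names(mats) <- paste0("s", 1:5)
  co <- manual_cohort(mats, atlas8)
  st <- edgewise_paired_stats(co, "BL", "5YFU")
  expect_equal(max(abs(st$t)), 0)
})

test_that("the one-edge paired t matches the textbook one-sample t", {
  diffs <- c(0.05, 0.02, 0.08, 0.04, 0.06)
  co <- diff_cohort(as.list(diffs), data.frame(i = 0, j = 1), atlas8)
  st <- edgewise_paired_stats(co, "BL", "5YFU")
  t_hand <- mean(diffs) / (sd(diffs) / sqrt(5))
  pos <- longconn:::edge_positions(data.frame(i = 0, j = 1), 8)
  expect_equal(st$t[pos], t_hand, tolerance = 1e-10)
  expect_equal(st$df, 4)
  # direction = increase flips the sign
  st2 <- edgewise_paired_stats(co, "BL", "5YFU", direction = "increase")
  expect_equal(st2$t[pos], -t_hand, tolerance = 1e-10)
})

test_that("confound adjustment matches lm() and rejects bad designs", {
  set.seed(4)
  n <- 12
  a <- toy_atlas(6)
  diffs <- lapply(1:n, function(s) rnorm(1, 0.05, 0.03))
  co <- diff_cohort(diffs, data.frame(i = 0, j = 1), a)
  co$subjects$age <- rnorm(n, 65, 5)
  co$subjects$sex <- rep_len(c("M", "F"), n)
  st <- edgewise_paired_stats(co, "BL", "5YFU", confounds = c("age", "sex"))
  pos <- longconn:::edge_positions(data.frame(i = 0, j = 1), 6)
  d <- unlist(diffs)
  fit <- lm(d ~ I(co$subjects$age - mean(co$subjects$age)) +
              I((co$subjects$sex == "M") - mean(co$subjects$sex == "M")))
  t_lm <- summary(fit)$coefficients["(Intercept)", "t value"]
  expect_equal(st$t[pos], t_lm, tolerance = 1e-8)
  expect_equal(st$df, n - 3)
  # collinear confounds named
  co$subjects$age2 <- co$subjects$age
  expect_error(edgewise_paired_stats(co, "BL", "5YFU",
                                     confounds = c("age", "age2")),
               "collinear")
  # too few subjects
  co3 <- diff_cohort(diffs[1:4], data.frame(i = 0, j = 1), a)
  co3$subjects$age <- c(60, 62, 64, 66)
  co3$subjects$sex <- c("M", "F", "M", "F")
  co3$subjects$ledd <- c(100, 410, 220, 305)
  expect_error(edgewise_paired_stats(co3, "BL", "5YFU",
                                     confounds = c("age", "sex", "ledd")),
               "need more than")
})

test_that("supra-threshold components match an independent union-find oracle", {
  # constructed: two disjoint triangles above threshold
  tvec <- numeric(28)
  tri1 <- data.frame(i = c(0, 0, 1), j = c(1, 2, 2))
  tri2 <- data.frame(i = c(4, 4, 5), j = c(5, 6, 6))
  tvec[longconn:::edge_positions(tri1, 8)] <- 3.5
  tvec[longconn:::edge_positions(tri2, 8)] <- 4.0
  comps <- supra_threshold_components(edgevec_to_mat(tvec, 8), 3)
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, 1L, "n_edges"), c(3L, 3L))
  expect_equal(vapply(comps, `[[`, 1L, "n_regions"), c(3L, 3L))
  # all-subthreshold map: empty list
  expect_length(supra_threshold_components(edgevec_to_mat(numeric(28), 8), 2),
                0)
  # random 20-node maps agree with the oracle
  set.seed(9)
  for (rep in 1:5) {
    tv <- rnorm(190)
    got <- supra_threshold_components(edgevec_to_mat(tv, 20), 1.0)
    want <- uf_components(tv, 1.0, 20)
    expect_equal(lapply(got, function(s) {
      sort(longconn:::edge_positions(s$edges, 20))
    }), lapply(want, sort))
  }
  expect_error(supra_threshold_components(edgevec_to_mat(tvec, 8), -1),
               "threshold")
})

test_that("raising the primary threshold never grows a component", {
  set.seed(10)
  tv <- rnorm(190, 1, 1)
  for (pair in list(c(1, 1.5), c(1.5, 2), c(2, 2.5))) {
    lo <- supra_threshold_components(edgevec_to_mat(tv, 20), pair[1])
    hi <- supra_threshold_components(edgevec_to_mat(tv, 20), pair[2])
    max_lo <- if (length(lo)) lo[[1]]$n_edges else 0L
    max_hi <- if (length(hi)) hi[[1]]$n_edges else 0L
    expect_lte(max_hi, max_lo)
  }
})

test_that("exact sign-flip enumeration matches the exhaustive oracle", {
  set.seed(12)
  n_sub <- 6
  # a planted component plus noise so several components appear
  edges <- data.frame(i = c(0, 0, 1, 4, 6), j = c(1, 2, 2, 5, 7))
  diffs <- lapply(1:n_sub, function(s) {
    c(0.06, 0.05, 0.07, 0.04, 0.01) + rnorm(5, 0, 0.02)
  })
  co <- diff_cohort(diffs, edges, atlas8)
  res <- nbs(co, "BL", "5YFU", primary_threshold = 2,
             n_permutations = "exact")
  st <- edgewise_paired_stats(co, "BL", "5YFU")
  oracle <- exhaustive_nbs_oracle(st$D, 2, 8)
  expect_equal(vapply(res$components, `[[`, 1L, "n_edges"),
               unname(oracle$extents))
  expect_equal(vapply(res$components, `[[`, 1, "component_pvalue"),
               unname(oracle$pvalues), tolerance = 1e-12)
})

test_that("NBS recovers a planted subnetwork and flags it significant", {
  a <- toy_atlas(30)
  planted <- default_planted_subnetwork(a, n_edges = 20, n_regions = 12,
                                        seed = 31)
  pe <- planted_effect(planted, decrement = c(BL = 0, "5YFU" = 0.08))
  co <- simulate_longitudinal_cohort(a, n_pd = 20, n_hc = 0,
                                     timepoints = c("BL", "5YFU"),
                                     planted = pe, seed = 33)
  st <- edgewise_paired_stats(co, "BL", "5YFU")
  pos <- longconn:::edge_positions(planted, 30)
  expect_gt(mean(st$t[pos]), mean(st$t[-pos]))
  res <- nbs(co, "BL", "5YFU", primary_threshold = 3,
             n_permutations = 500, seed = 35)
  expect_true(length(res$components) >= 1)
  top <- res$components[[1]]
  expect_true(top$significant)
  expect_lt(top$component_pvalue, 0.05)
  expect_gt(edge_jaccard(top$edges, planted), 0.8)
})

test_that("permutation p is invariant to region relabelling", {
  a <- toy_atlas(10)
  pe <- planted_effect(all_edges(10)[c(2, 11, 17, 25), ],
                       decrement = c(BL = 0, "5YFU" = 0.06))
  co <- simulate_longitudinal_cohort(a, n_pd = 10, n_hc = 0,
                                     timepoints = c("BL", "5YFU"),
                                     planted = pe, seed = 41)
  perm <- sample(10)
  co2 <- co
  for (id in names(co2$matrices)) {
    for (tp in co2$timepoints) {
      co2$matrices[[id]][[tp]] <- co2$matrices[[id]][[tp]][perm, perm]
    }
  }
  r1 <- nbs(co, "BL", "5YFU", primary_threshold = 2.5,
            n_permutations = 300, seed = 43)
  r2 <- nbs(co2, "BL", "5YFU", primary_threshold = 2.5,
            n_permutations = 300, seed = 43)
  expect_equal(vapply(r1$components, `[[`, 1, "component_pvalue"),
               vapply(r2$components, `[[`, 1, "component_pvalue"))
  expect_equal(vapply(r1$components, `[[`, 1L, "n_edges"),
               vapply(r2$components, `[[`, 1L, "n_edges"))
})
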