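atlas20 <- toy_atlas(20)
edges10 <- all_edges(20)[c(1, 5, 9, 20, 33, 47, 60, 81, 100, 120), ]

test_that("the generator is deterministic in its single seed", {
  pe <- planted_effect(edges10)
  a <- simulate_longitudinal_cohort(atlas20, n_pd = 5, n_hc = 3,
                                    planted = pe, seed = 7)
  b <- simulate_longitudinal_cohort(atlas20, n_pd = 5, n_hc = 3,
                                    planted = pe, seed = 7)
  expect_identical(a$matrices, b$matrices)
  expect_identical(a$scores, b$scores)
  expect_identical(a$subjects, b$subjects)
})

test_that("every emitted matrix satisfies the connectivity invariants", {
  co <- simulate_longitudinal_cohort(atlas20, n_pd = 4, n_hc = 2,
                                     planted = planted_effect(edges10),
                                     seed = 3)
  for (id in names(co$matrices)) {
    for (tp in co$timepoints) {
      expect_silent(validate_connectivity(co$matrices[[id]][[tp]]))
    }
  }
})

test_that("zero noise makes realized decrements exactly the configured ones", {
  pe <- planted_effect(edges10, decrement = c(BL = 0, "3YFU" = 0.04,
                                              "5YFU" = 0.12),
                       edge_noise_sd = 0, between_subject_sd = 0,
                       subject_sd = 0, score_noise_sd = 0)
  co <- simulate_longitudinal_cohort(atlas20, n_pd = 3, n_hc = 0,
                                     planted = pe, seed = 5)
  pos <- longconn:::edge_positions(edges10, 20)
  wb <- cohort_edge_matrix(co, "BL")[, pos]
  w3 <- cohort_edge_matrix(co, "3YFU")[, pos]
  w5 <- cohort_edge_matrix(co, "5YFU")[, pos]
  expect_equal(unname(wb - w3), matrix(0.04, 3, 10), tolerance = 1e-12)
  expect_equal(unname(wb - w5), matrix(0.12, 3, 10), tolerance = 1e-12)
  # non-planted edges untouched
  other <- setdiff(seq_len(190), pos)
  expect_equal(cohort_edge_matrix(co, "BL")[, other],
               cohort_edge_matrix(co, "5YFU")[, other], tolerance = 1e-12)
})

test_that("planted group means decrease progressively; controls drift only", {
  a <- default_atlas()
  pe <- planted_effect(default_planted_subnetwork(a))
  co <- simulate_longitudinal_cohort(a, n_pd = 35, n_hc = 10, planted = pe,
                                     seed = 11)
  pos <- longconn:::edge_positions(pe$edges, 210)
  pd_means <- vapply(co$timepoints, function(tp) {
    mean(cohort_edge_matrix(co, tp)[, pos])
  }, numeric(1))
  expect_true(all(diff(pd_means) < 0))
  hc_means <- vapply(co$timepoints, function(tp) {
    mean(cohort_edge_matrix(co, tp, group = "HC")[, pos])
  }, numeric(1))
  expect_lt(max(abs(diff(hc_means))), 0.01)
})

test_that("a null cohort yields approximately uniform edgewise p-values", {
  co <- simulate_longitudinal_cohort(toy_atlas(16), n_pd = 12, n_hc = 0,
                                     planted = NULL, seed = 13)
  st <- edgewise_paired_stats(co, "BL", "5YFU")
  p <- 2 * pt(-abs(st$t), df = st$df)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("score coupling is recovered by regression at large n", {
  pe <- planted_effect(edges10, score_coupling = -20, score_noise_sd = 0.3)
  co <- simulate_longitudinal_cohort(atlas20, n_pd = 220, n_hc = 0,
                                     planted = pe, seed = 17)
  pos <- longconn:::edge_positions(edges10, 20)
  loss <- rowMeans(cohort_edge_matrix(co, "BL")[, pos]) -
    rowMeans(cohort_edge_matrix(co, "5YFU")[, pos])
  sc <- co$scores
  dmoca <- sc$moca[sc$timepoint == "5YFU"] - sc$moca[sc$timepoint == "BL"]
  slope <- unname(coef(lm(dmoca ~ loss))[2])
  expect_equal(slope, -20, tolerance = 0.10 * 20)
})

test_that("planted-effect validation enforces monotone progression", {
  expect_error(planted_effect(edges10, decrement = c(BL = 0, "3YFU" = 0.1,
                                                     "5YFU" = 0.05)),
               "monotone")
  expect_error(simulate_longitudinal_cohort(
    atlas20, n_pd = 2, n_hc = 0,
    planted = planted_effect(data.frame(i = 0, j = 99))),
    "outside")
  expect_error(simulate_longitudinal_cohort(atlas20, n_pd = 1), "n_pd")
})

test_that("clipping to [0,1] is counted, not silent", {
  pe <- planted_effect(edges10, decrement = c(BL = 0, "3YFU" = 0.5,
                                              "5YFU" = 0.9))
  co <- simulate_longitudinal_cohort(atlas20, n_pd = 5, n_hc = 0,
                                     planted = pe, seed = 19)
  expect_gt(co$log$n_clipped, 0)
  for (id in names(co$matrices)) {
    expect_true(all(co$matrices[[id]][["5YFU"]] >= 0))
  }
})

test_that("lateralized item sums are consistent with the drawn side", {
  co <- simulate_longitudinal_cohort(atlas20, n_pd = 40, n_hc = 0, seed = 23)
  sa <- cohort_side_assignments(co)
  drawn <- co$subjects$dominant_side[match(sa$id, co$subjects$id)]
  relabel <- c(L = "LPD", R = "RPD", symmetric = "symmetric")
  expect_equal(sa$label, unname(relabel[drawn]))
})
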