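test_that("NI is the mean subnetwork weight, with hand-checked cases", {
  n <- 6
  v <- numeric(15)
  ed <- data.frame(i = c(0, 1, 2), j = c(1, 3, 4))
  pos <- longconn:::edge_positions(ed, n)
  v[pos] <- c(0.2, 0.4, 0.9)
  m <- edgevec_to_mat(v, n)
  expect_equal(compute_ni(m, ed), 0.5)
  # all-equal weights
  m2 <- edgevec_to_mat(rep(0.5, 15), n)
  expect_equal(compute_ni(m2, ed), 0.5)
  # full edge set = global mean connectivity
  set.seed(2)
  m3 <- edgevec_to_mat(runif(15), n)
  expect_equal(compute_ni(m3, all_edges(n)), mean(mat_to_edgevec(m3)))
  # linear scaling
  expect_equal(compute_ni(0.5 * m3, all_edges(n)),
               0.5 * compute_ni(m3, all_edges(n)))
  expect_error(compute_ni(m, ed[0, ]), "empty subnetwork")
})

test_that("NI is invariant under consistent region relabelling", {
  set.seed(3)
  n <- 8
  m <- edgevec_to_mat(runif(28), n)
  ed <- all_edges(n)[c(3, 9, 14, 22), ]
  perm <- sample(n) - 1L  # 0-based permutation: old index k -> perm[k+1]
  mp <- m
  mp[perm + 1, perm + 1] <- m
  edp <- data.frame(i = perm[ed$i + 1], j = perm[ed$j + 1])
  expect_equal(compute_ni(mp, edp), compute_ni(m, ed))
})

test_that("longitudinal NI tests apply Bonferroni over the visit pairs", {
  ids <- sprintf("s%02d", 1:10)
  traj <- expand.grid(id = ids, timepoint = c("BL", "3YFU", "5YFU"),
                      stringsAsFactors = FALSE)
  traj$group <- "PD"
  set.seed(4)
  base <- runif(10, 0.4, 0.5)
  traj$ni <- base[match(traj$id, ids)] -
    c(BL = 0, "3YFU" = 0.02, "5YFU" = 0.05)[traj$timepoint] +
    rnorm(nrow(traj), 0, 0.005)
  out <- longitudinal_ni_test(traj)
  expect_equal(nrow(out), 3)
  expect_equal(out$p_bonferroni, pmin(1, out$p * 3))
  # identical NI at both timepoints: t = 0, uncorrected p = 1
  traj0 <- traj[traj$timepoint %in% c("BL", "3YFU"), ]
  traj0$ni <- base[match(traj0$id, ids)]
  out0 <- longitudinal_ni_test(traj0, pairs = list(c("BL", "3YFU")))
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p, 1)
  # the wilcoxon option handles all-zero differences explicitly
  outw <- longitudinal_ni_test(traj0, pairs = list(c("BL", "3YFU")),
                               method = "wilcoxon")
  expect_equal(outw$p, 1)
})

test_that("NI-score correlation handles exact, sampled, and degenerate cases", {
  a <- toy_atlas(6)
  ids <- sprintf("s%02d", 1:20)
  set.seed(5)
  ni_vals <- runif(20, 0.3, 0.6)
  mats <- lapply(ids, function(id) list(BL = edgevec_to_mat(rep(0.5, 15), 6)))
  names(mats) <- ids
  traj <- data.frame(id = ids, group = "PD", timepoint = "BL", ni = ni_vals)
  scores <- data.frame(id = ids, timepoint = "BL", moca = 2 * ni_vals + 1,
                       updrs3 = 10, updrs_left = 5, updrs_right = 2)
  co <- manual_cohort(mats, a, scores = scores)
  co$timepoints <- "BL"
  r <- correlate_ni_score(co, traj, "moca", "same-timepoint", timepoint = "BL")
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$n, 20)
  # zero-variance score is refused
  co$scores$moca <- 26
  expect_error(correlate_ni_score(co, traj, "moca", "same-timepoint",
                                  timepoint = "BL"), "zero variance")
})

test_that("the sampled r at rho = 0.6 falls in its sampling band", {
  set.seed(6)
  n <- 500
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  ids <- sprintf("s%03d", 1:n)
  traj <- data.frame(id = ids, group = "PD", timepoint = "BL",
                     ni = 0.5 + 0.05 * x)
  scores <- data.frame(id = ids, timepoint = "BL", moca = 25 + 2 * y,
                       updrs3 = NA, updrs_left = NA, updrs_right = NA)
  co <- structure(list(atlas = toy_atlas(4), subjects = data.frame(id = ids),
                       scores = scores, matrices = list(),
                       timepoints = "BL", planted = NULL, seed = 1,
                       log = list()), class = "cohort_dataset")
  r <- correlate_ni_score(co, traj, "moca", "same-timepoint", timepoint = "BL")
  expect_gte(r$r, 0.53)
  expect_lte(r$r, 0.66)
})

test_that("change-correlated subnetworks retain planted edges, not null ones", {
  a <- toy_atlas(20)
  base_edges <- all_edges(20)[1:10, ]
  set.seed(7)
  retained_hits <- 0L
  for (rep in 1:10) {
    n_sub <- 40
    ids <- sprintf("s%02d", 1:n_sub)
    ds <- rnorm(n_sub, -2, 1.5)  # score change
    mats <- lapply(seq_len(n_sub), function(s) {
      v0 <- rep(0.5, 190)
      v1 <- v0 + rnorm(190, 0, 0.02)
      # 3 planted edges track the score change strongly
      pos <- longconn:::edge_positions(base_edges[1:3, ], 20)
      v1[pos] <- v0[pos] + 0.02 * ds[s] + rnorm(3, 0, 0.005)
      list(BL = edgevec_to_mat(pmin(pmax(v0, 0), 1), 20),
           "5YFU" = edgevec_to_mat(pmin(pmax(v1, 0), 1), 20))
    })
    names(mats) <- ids
    scores <- expand.grid(id = ids, timepoint = c("BL", "5YFU"),
                          stringsAsFactors = FALSE)
    scores$moca <- 26
    scores$moca[scores$timepoint == "5YFU"] <- 26 + ds
    scores$updrs3 <- 10; scores$updrs_left <- 5; scores$updrs_right <- 2
    co <- manual_cohort(mats, a, scores = scores)
    sub <- change_correlated_subnetwork(co, base_edges, "moca",
                                        c("BL", "5YFU"), edge_alpha = 0.05)
    keys <- paste(sub$edges$i, sub$edges$j)
    planted_keys <- paste(base_edges$i[1:3], base_edges$j[1:3])
    if (all(planted_keys %in% keys)) retained_hits <- retained_hits + 1L
  }
  expect_gte(retained_hits, 9L)
})

test_that("null edges are retained at about the screening alpha", {
  a <- toy_atlas(30)
  base_edges <- all_edges(30)[1:300, ]
  set.seed(8)
  n_sub <- 30
  ids <- sprintf("s%02d", 1:n_sub)
  ds <- rnorm(n_sub, -1, 2)
  mats <- lapply(seq_len(n_sub), function(s) {
    list(BL = edgevec_to_mat(runif(435, 0.4, 0.6), 30),
         "5YFU" = edgevec_to_mat(runif(435, 0.4, 0.6), 30))
  })
  names(mats) <- ids
  scores <- expand.grid(id = ids, timepoint = c("BL", "5YFU"),
                        stringsAsFactors = FALSE)
  scores$moca <- 26; scores$moca[scores$timepoint == "5YFU"] <- 26 + ds
  scores$updrs3 <- 10; scores$updrs_left <- 5; scores$updrs_right <- 2
  co <- manual_cohort(mats, a, scores = scores)
  sub <- change_correlated_subnetwork(co, base_edges, "moca", c("BL", "5YFU"),
                                      edge_alpha = 0.05)
  # binomial 99.5% bound around 0.05 over 300 independent edges
  expect_lte(sub$n_edges, qbinom(0.995, 300, 0.05))
})

test_that("the leave-two-out sensitivity mode drops the sharpest decliners", {
  a <- toy_atlas(6)
  ids <- sprintf("s%02d", 1:12)
  set.seed(9)
  dni <- rnorm(12, -0.05, 0.02)
  dmo <- 10 * dni + rnorm(12, 0, 0.1)
  dmo[1:2] <- c(-12, -10)  # two sharp decliners
  mats <- lapply(seq_along(ids), function(s) {
    v0 <- rep(0.5, 15)
    list(BL = edgevec_to_mat(v0, 6),
         "5YFU" = edgevec_to_mat(v0 + dni[s], 6))
  })
  names(mats) <- ids
  scores <- expand.grid(id = ids, timepoint = c("BL", "5YFU"),
                        stringsAsFactors = FALSE)
  scores$moca <- 26
  scores$moca[scores$timepoint == "5YFU"] <- 26 + dmo[match(
    scores$id[scores$timepoint == "5YFU"], ids)]
  scores$updrs3 <- 10; scores$updrs_left <- 5; scores$updrs_right <- 2
  co <- manual_cohort(mats, a, scores = scores)
  traj <- ni_trajectories(co, all_edges(6))
  full <- correlate_ni_score(co, traj, "moca", "change-vs-change",
                             interval = c("BL", "5YFU"))
  drop2 <- correlate_ni_score(co, traj, "moca", "change-vs-change",
                              interval = c("BL", "5YFU"), drop_extreme = 2)
  expect_equal(drop2$n, full$n - 2)
  expect_gt(drop2$r, 0)  # correlation survives without the outliers
})
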