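test_that("dominant-side assignment follows the all-visits rule exactly", {
  expect_equal(assign_dominant_side(c(6, 7, 8), c(2, 2, 3)), "LPD")
  expect_equal(assign_dominant_side(c(2, 2, 3), c(6, 7, 8)), "RPD")
  expect_equal(assign_dominant_side(c(4, 4, 4), c(4, 4, 4)), "symmetric")
  # equality at one visit only is not symmetric and not lateralized
  expect_equal(assign_dominant_side(c(6, 4, 8), c(2, 4, 3)), "inconsistent")
  # a flip across visits is inconsistent
  expect_equal(assign_dominant_side(c(6, 7, 2), c(2, 2, 5)), "inconsistent")
  expect_error(assign_dominant_side(c(6, NA, 8), c(2, 2, 3)), "missing visit")
  expect_error(assign_dominant_side(c(30, 7, 8), c(2, 2, 3)), "0..28")
})

test_that("assignment is antisymmetric under a left/right swap", {
  set.seed(14)
  for (rep in 1:25) {
    l <- sample(0:28, 3, replace = TRUE)
    r <- sample(0:28, 3, replace = TRUE)
    lab <- assign_dominant_side(l, r)
    swapped <- assign_dominant_side(r, l)
    expected <- c(LPD = "RPD", RPD = "LPD", symmetric = "symmetric",
                  inconsistent = "inconsistent")[lab]
    expect_equal(swapped, unname(expected))
  }
})

test_that("dominance summaries count hemispheres, lobes, and degrees", {
  a <- toy_atlas(12)  # even L, odd R; lobes cycled in pairs
  r_idx <- a$regions$index[a$regions$hemisphere == "R"]
  # star on one right-hemisphere hub plus a chain: all intra-R
  hub <- r_idx[3]
  spokes <- r_idx[c(1, 2, 4, 5)]
  ed <- data.frame(i = pmin(hub, spokes), j = pmax(hub, spokes))
  ed <- rbind(ed, data.frame(i = min(spokes[1], spokes[2]),
                             j = max(spokes[1], spokes[2])))
  sn <- structure(list(edges = ed, n_edges = nrow(ed),
                       n_regions = 5, primary_threshold = 3,
                       component_pvalue = 0.01), class = "subnetwork")
  ds <- dominance_summary(sn, a, top_k = 3)
  expect_equal(ds$edge_shares[["intra-R"]], 1)
  expect_equal(ds$edge_shares[["intra-L"]], 0)
  expect_equal(ds$region_shares[["R"]], 1)
  expect_equal(sum(ds$edge_shares), 1)
  expect_equal(sum(ds$lobe_pair_shares), 1)
  expect_equal(ds$top_regions$index[1], hub)
  expect_equal(ds$top_regions$degree[1], 4L)
  # shares invariant to edge ordering
  ds2 <- dominance_summary(structure(list(edges = ed[sample(nrow(ed)), ]),
                                     class = "subnetwork"), a, top_k = 3)
  expect_equal(ds2$edge_shares, ds$edge_shares)
  expect_error(dominance_summary(structure(list(edges = ed[0, ]),
                                           class = "subnetwork"), a),
               "empty")
})

test_that("lobe-pair shares reproduce a hand-counted mix", {
  a <- region_atlas(data.frame(
    index = 0:9, name = paste0("r", 0:9),
    hemisphere = rep("R", 10),
    lobe = c(rep("frontal", 5), rep("temporal", 3), rep("central", 2))
  ))
  ed <- rbind(
    data.frame(i = 0:2, j = 5:7),        # 3 frontal-temporal
    data.frame(i = c(0, 1, 3), j = c(6, 7, 5)),  # 3 more frontal-temporal
    data.frame(i = c(0, 1), j = c(2, 3)),        # 2 frontal-frontal
    data.frame(i = c(3, 4), j = c(8, 9))         # 2 frontal-central
  )
  ds <- dominance_summary(structure(list(edges = ed), class = "subnetwork"), a)
  expect_equal(ds$lobe_pair_shares[["frontal-temporal"]], 0.6)
  expect_equal(ds$lobe_pair_shares[["frontal-frontal"]], 0.2)
  expect_equal(ds$lobe_pair_shares[["central-frontal"]], 0.2)
})

test_that("subgroup NBS excludes the side confound and guards small groups", {
  a <- toy_atlas(20)
  peR <- planted_effect(default_planted_subnetwork(a, n_edges = 14,
                                                   n_regions = 8,
                                                   hemisphere = "R",
                                                   seed = 51),
                        decrement = c(BL = 0, "5YFU" = 0.1))
  co <- simulate_longitudinal_cohort(a, n_pd = 30, n_hc = 6,
                                     timepoints = c("BL", "5YFU"),
                                     planted = list(L = peR, R = NULL),
                                     side_probs = c(L = 25, R = 4,
                                                    symmetric = 1),
                                     seed = 53)
  sa <- cohort_side_assignments(co)
  # this draw leaves 4 RPD subjects: below the NBS floor
  expect_error(subgroup_nbs(co, "RPD", primary_threshold = 3,
                            n_permutations = 100, seed = 1),
               "too small")
  # a subgroup of 6 runs, but with a small-sample warning
  co_w <- simulate_longitudinal_cohort(a, n_pd = 30, n_hc = 0,
                                       timepoints = c("BL", "5YFU"),
                                       planted = list(L = peR, R = NULL),
                                       side_probs = c(L = 20, R = 9,
                                                      symmetric = 1),
                                       seed = 57)
  expect_warning(subgroup_nbs(co_w, "RPD", primary_threshold = 3,
                              n_permutations = 100, seed = 1),
                 "caution")
  sg <- subgroup_nbs(co, "LPD",
                     confounds = c("age", "sex", "dominant_side"),
                     primary_threshold = 3, n_permutations = 200, seed = 55)
  expect_false("dominant_side" %in% sg$confounds)
  expect_equal(sg$n, sum(sa$label == "LPD"))
  top <- sg$nbs$components[[1]]
  ds <- dominance_summary(top, a)
  expect_gt(ds$edge_shares[["intra-R"]], 0.5)
  # cross-applied NI masks exist for the other subgroup and controls
  expect_false(is.null(sg$ni$own))
  expect_false(is.null(sg$ni$hc))
  # degenerate subgroup sizes are refused
  tiny <- sa[sa$label == "LPD", ][1, ]
  co_t <- co
  co_t$subjects <- co$subjects[co$subjects$id %in% c(tiny$id), , drop = FALSE]
  expect_error(subgroup_nbs(co_t, "LPD", primary_threshold = 3), "subgroup")
})
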