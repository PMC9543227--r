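#' Synthetic longitudinal cohorts with planted dysconnectivity
#'
#' The generator emulates the statistical structure of a longitudinal
#' patient/control study: per-subject PLV-like connectivity matrices at
#' baseline (`BL`) and follow-ups (`3YFU`, `5YFU`), demographic
#' covariates, clinical scores (MoCA, UPDRS-III with lateralized item
#' sums), and a planted connected subnetwork whose weights decrease
#' progressively in patients only. Each patient's cognitive-score change
#' is stochastically coupled to their realized mean planted-edge loss, so
#' correlation analyses have a known ground truth.
#'
#' @name synthetic_cohort
NULL

TIMEPOINTS <- c("BL", "3YFU", "5YFU")

#' Describe a planted longitudinal effect
#'
#' @param edges data.frame of 0-based `i`, `j` edge endpoints: the planted
#'   subnetwork.
#' @param decrement named per-timepoint mean weight decrement, monotone
#'   non-decreasing over `BL`, `3YFU`, `5YFU`.
#' @param score_coupling MoCA points per unit realized mean planted-edge
#'   loss (negative: connectivity loss lowers cognition).
#' @param updrs_coupling UPDRS-III points per unit realized loss
#'   (positive: loss worsens motor score).
#' @param edge_noise_sd per-edge, per-visit measurement noise SD.
#' @param between_subject_sd SD of the per-subject trait offset per edge.
#' @param subject_sd SD of the per-subject progression multiplier (mean
#'   1): heterogeneity of the realized loss across patients.
#' @param score_noise_sd SD of the MoCA change noise.
#' @param updrs_noise_sd SD of the UPDRS-III change noise.
#' @return A `planted_effect` object.
#' @export
planted_effect <- function(edges,
                           decrement = c(BL = 0, "3YFU" = 0.05, "5YFU" = 0.10),
                           score_coupling = -20,
                           updrs_coupling = 30,
                           edge_noise_sd = 0.02,
                           between_subject_sd = 0.05,
                           subject_sd = 0.25,
                           score_noise_sd = 1.1,
                           updrs_noise_sd = 3) {
  edges <- as.data.frame(edges)[, c("i", "j")]
  if (is.null(names(decrement))) names(decrement) <- TIMEPOINTS[seq_along(decrement)]
  dec <- decrement[TIMEPOINTS[TIMEPOINTS %in% names(decrement)]]
  if (any(diff(dec) < 0)) {
    stop_input("decrements must be monotone non-decreasing over time")
  }
  if (any(dec < 0 | dec > 1)) stop_input("decrements must lie in [0,1]")
  structure(list(edges = edges, decrement = dec,
                 score_coupling = score_coupling,
                 updrs_coupling = updrs_coupling,
                 edge_noise_sd = edge_noise_sd,
                 between_subject_sd = between_subject_sd,
                 subject_sd = subject_sd,
                 score_noise_sd = score_noise_sd,
                 updrs_noise_sd = updrs_noise_sd),
            class = "planted_effect")
}

#' Score-noise SD achieving a target loss-score correlation
#'
#' For score change `= slope * loss + noise`, returns the noise SD giving
#' correlation `rho` between loss and score change, given the SD of the
#' realized loss across subjects.
#'
#' @param slope score points per unit loss.
#' @param loss_sd SD of realized loss across subjects.
#' @param rho target absolute correlation in (0, 1).
#' @export
score_noise_for_rho <- function(slope, loss_sd, rho) {
  stopifnot(rho > 0, rho < 1, loss_sd > 0)
  abs(slope) * loss_sd * sqrt(1 / rho^2 - 1)
}

#' A connected lateralized planted subnetwork
#'
#' Builds a connected edge set mirroring the shape of a
#' dysconnectivity network dominated by one hemisphere: `n_regions`
#' distinct endpoints (a configurable share in the dominant hemisphere),
#' a random spanning tree plus extra within-dominant-hemisphere edges up
#' to `n_edges`.
#'
#' @param atlas a [region_atlas].
#' @param n_edges total edges (default 125).
#' @param n_regions distinct endpoint regions (default 72).
#' @param hemisphere dominant hemisphere, `"R"` or `"L"`.
#' @param dominant_share share of endpoint regions in the dominant
#'   hemisphere (default 0.889).
#' @param seed integer seed.
#' @return data.frame of 0-based `i`, `j` edges (i < j), connected.
#' @export
default_planted_subnetwork <- function(atlas, n_edges = 125, n_regions = 72,
                                       hemisphere = c("R", "L"),
                                       dominant_share = 0.889, seed = 7) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(n_edges >= n_regions - 1)
  with_seed(seed, {
    dom <- atlas$regions$index[atlas$regions$hemisphere == hemisphere]
    oth <- atlas$regions$index[atlas$regions$hemisphere != hemisphere]
    n_dom <- min(round(dominant_share * n_regions), length(dom))
    nodes <- c(sample(dom, n_dom), sample(oth, n_regions - n_dom))
    ord <- sample(nodes)
    tree <- data.frame(i = ord[-length(ord)], j = ord[-1])
    dom_nodes <- intersect(nodes, dom)
    pool <- all_edges(atlas$n_regions)
    pool <- pool[pool$i %in% dom_nodes & pool$j %in% dom_nodes, ]
    key <- function(e) paste(pmin(e$i, e$j), pmax(e$i, e$j))
    pool <- pool[!key(pool) %in% key(tree), ]
    extra <- pool[sample(nrow(pool), n_edges - nrow(tree)), ]
    out <- rbind(data.frame(i = pmin(tree$i, tree$j),
                            j = pmax(tree$i, tree$j)),
                 extra)
    rownames(out) <- NULL
    out
  })
}

#' Default group-mean baseline connectivity matrix
#'
#' Smoothly varying symmetric PLV-like baseline: per-edge means drawn
#' around `mean` and clipped away from the unit-interval boundary so
#' planted decrements plus noise rarely clip.
#'
#' @param atlas a [region_atlas] (or region count).
#' @param mean,sd edge-mean distribution parameters.
#' @param seed integer seed.
#' @export
default_baseline_matrix <- function(atlas, mean = 0.45, sd = 0.08, seed = 11) {
  n <- if (inherits(atlas, "region_atlas")) atlas$n_regions else atlas
  with_seed(seed, {
    v <- pmin(pmax(rnorm(n * (n - 1) / 2, mean, sd), 0.05), 0.9)
    edgevec_to_mat(v, n)
  })
}

.trunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

# Lateralized UPDRS-III item sums (items 20-26, per body side) consistent
# with an assigned dominant side: strictly larger sums on the affected
# body side at every visit for LPD/RPD, equal sums for symmetric.
.lateral_item_sums <- function(side, n_tp) {
  base_dom <- .trunc_norm(1, 7, 2, 1, 24)
  base_oth <- .trunc_norm(1, 3, 1.5, 0, 24)
  dom <- pmin(pmax(round(base_dom + cumsum(c(0, rep(0.5, n_tp - 1))) +
                           rnorm(n_tp, 0, 1)), 0), 28)
  oth <- pmin(pmax(round(base_oth + cumsum(c(0, rep(0.3, n_tp - 1))) +
                           rnorm(n_tp, 0, 1)), 0), 28)
  if (side == "symmetric") {
    oth <- dom
  } else {
    bump <- oth >= dom
    dom[bump] <- pmin(oth[bump] + 1, 28)
  }
  if (side == "L") list(left = dom, right = oth)
  else if (side == "R") list(left = oth, right = dom)
  else list(left = dom, right = oth)
}

#' Simulate a longitudinal cohort with a planted connectivity decrement
#'
#' Patients (`PD`) carry the planted effect: at each follow-up the planted
#' edges are reduced by the configured decrement times a subject-specific
#' progression multiplier, plus noise; controls (`HC`) drift by noise
#' only. Each patient's MoCA change equals
#' `score_coupling * realized mean planted-edge loss + noise`, and
#' UPDRS-III changes couple positively to the same loss; lateralized item
#' sums are generated consistently with the drawn dominant side.
#'
#' @param atlas a [region_atlas].
#' @param n_pd,n_hc group sizes (default 35 / 32).
#' @param timepoints ordered subset of `BL`, `3YFU`, `5YFU`.
#' @param baseline group-mean baseline matrix (default
#'   [default_baseline_matrix()]).
#' @param planted a [planted_effect()], or a named list
#'   `list(L = ..., R = ...)` of side-specific effects applied to each
#'   patient according to their dominant side (contralateral planting is
#'   the caller's choice of edge sets), or `NULL` for a global-null
#'   cohort.
#' @param side_probs sampling weights for dominant side `L`, `R`,
#'   `symmetric` (default 23:10:2).
#' @param seed single integer seed driving all randomness.
#' @return A `cohort_dataset`: `atlas`, `subjects` (covariates),
#'   `scores` (one row per subject x timepoint), `matrices`
#'   (`[[id]][[timepoint]]`), `timepoints`, `planted`, and a `log` with
#'   clip/truncation counts.
#' @export
simulate_longitudinal_cohort <- function(atlas, n_pd = 35, n_hc = 32,
                                         timepoints = TIMEPOINTS,
                                         baseline = NULL, planted = NULL,
                                         side_probs = c(L = 23, R = 10,
                                                        symmetric = 2),
                                         seed = 1) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (n_pd < 2) stop_input("n_pd must be >= 2")
  if (!all(timepoints %in% TIMEPOINTS)) {
    stop_input("timepoints must be among %s", paste(TIMEPOINTS, collapse = ", "))
  }
  n <- atlas$n_regions
  n_edge <- n * (n - 1) / 2
  if (is.null(baseline)) {
    baseline <- default_baseline_matrix(atlas, seed = derive_seed(seed, 101))
  }
  validate_connectivity(baseline, what = "baseline matrix")
  base_vec <- mat_to_edgevec(baseline)

  side_specific <- !is.null(planted) && !inherits(planted, "planted_effect")
  effects <- if (is.null(planted)) list() else if (side_specific)
    Filter(Negate(is.null), planted) else list(all = planted)
  for (pe in effects) {
    stopifnot(inherits(pe, "planted_effect"))
    if (any(pe$edges$j >= n | pe$edges$i < 0)) {
      stop_input("planted edges fall outside the %d-region atlas", n)
    }
  }
  ref <- if (length(effects)) effects[[1]] else planted_effect(all_edges(2)[1, ])
  pos_for <- function(pe) edge_positions(pe$edges, n)

  with_seed(seed, {
    ids <- c(sprintf("pd%02d", seq_len(n_pd)), sprintf("hc%02d", seq_len(n_hc)))
    group <- rep(c("PD", "HC"), c(n_pd, n_hc))
    side <- c(sample(names(side_probs), n_pd, replace = TRUE,
                     prob = side_probs / sum(side_probs)),
              rep(NA_character_, n_hc))
    subjects <- data.frame(
      id = ids, group = group,
      age = round(.trunc_norm(n_pd + n_hc, 67, 8, 45, 90), 1),
      sex = sample(c("M", "F"), n_pd + n_hc, replace = TRUE, prob = c(0.65, 0.35)),
      education = round(.trunc_norm(n_pd + n_hc, 15, 3, 7, 25), 1),
      ledd = ifelse(group == "PD",
                    round(.trunc_norm(n_pd + n_hc, 555, 300, 0, 2500)), 0),
      dominant_side = side,
      stringsAsFactors = FALSE
    )
    mult <- pmax(rnorm(n_pd + n_hc, 1, ref$subject_sd), 0)

    n_clipped <- 0L
    n_trunc_scores <- 0L
    matrices <- list()
    scores <- list()
    for (s in seq_along(ids)) {
      is_pd <- group[s] == "PD"
      eff <- if (!length(effects) || !is_pd) NULL
             else if (!side_specific) effects$all
             else effects[[side[s]]]  # may be NULL (e.g. symmetric)
      trait <- base_vec + rnorm(n_edge, 0, ref$between_subject_sd)
      mats <- list()
      loss <- setNames(numeric(length(timepoints)), timepoints)
      for (tp in timepoints) {
        v <- trait + rnorm(n_edge, 0, ref$edge_noise_sd)
        if (!is.null(eff) && tp %in% names(eff$decrement)) {
          p <- pos_for(eff)
          v[p] <- v[p] - eff$decrement[[tp]] * mult[s]
        }
        clipped <- v < 0 | v > 1
        n_clipped <- n_clipped + sum(clipped)
        v <- pmin(pmax(v, 0), 1)
        mats[[tp]] <- edgevec_to_mat(v, n)
        if (!is.null(eff)) {
          p <- pos_for(eff)
          loss[[tp]] <- mean(mat_to_edgevec(mats[[timepoints[1]]])[p]) -
            mean(v[p])
        }
      }
      matrices[[ids[s]]] <- mats

      moca_bl <- .trunc_norm(1, if (is_pd) 26.2 else 26.8, 2.4, 10, 30)
      updrs_bl <- if (is_pd) .trunc_norm(1, 13.9, 8, 0, 80) else NA_real_
      items <- if (is_pd) .lateral_item_sums(side[s], length(timepoints)) else
        list(left = rep(NA_real_, length(timepoints)),
             right = rep(NA_real_, length(timepoints)))
      updrs_drift <- setNames(c(0, 3, 4)[seq_along(timepoints)], timepoints)
      for (k in seq_along(timepoints)) {
        tp <- timepoints[k]
        if (k == 1) {
          moca <- moca_bl
          updrs <- updrs_bl
        } else if (is_pd) {
          moca <- moca_bl + ref$score_coupling * loss[[tp]] +
            rnorm(1, 0, ref$score_noise_sd)
          updrs <- updrs_bl + updrs_drift[[tp]] +
            ref$updrs_coupling * loss[[tp]] + rnorm(1, 0, ref$updrs_noise_sd)
        } else {
          moca <- moca_bl + rnorm(1, 0, ref$score_noise_sd)
          updrs <- NA_real_
        }
        if (!is.na(moca) && (moca < 0 || moca > 30)) n_trunc_scores <- n_trunc_scores + 1L
        if (!is.na(updrs) && (updrs < 0 || updrs > 132)) n_trunc_scores <- n_trunc_scores + 1L
        scores[[length(scores) + 1L]] <- data.frame(
          id = ids[s], timepoint = tp,
          moca = min(max(moca, 0), 30),
          updrs3 = if (is.na(updrs)) NA_real_ else min(max(updrs, 0), 132),
          updrs_left = items$left[k], updrs_right = items$right[k],
          stringsAsFactors = FALSE
        )
      }
    }
    if (n_clipped > 0) {
      log_info("clipped %d matrix entries to [0,1]", n_clipped)
    }
    structure(list(atlas = atlas, subjects = subjects,
                   scores = do.call(rbind, scores),
                   matrices = matrices, timepoints = timepoints,
                   planted = planted, seed = seed,
                   log = list(n_clipped = n_clipped,
                              n_truncated_scores = n_trunc_scores)),
              class = "cohort_dataset")
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d PD + %d HC, timepoints %s, %d regions\n",
              sum(x$subjects$group == "PD"), sum(x$subjects$group == "HC"),
              paste(x$timepoints, collapse = "/"), x$atlas$n_regions))
  invisible(x)
}

#' Stack one timepoint's connectivity into a subjects x edges matrix
#'
#' @param cohort a `cohort_dataset`.
#' @param timepoint timepoint label.
#' @param ids subject ids (default: all of `group`).
#' @param group subject group filter when `ids` is `NULL`.
#' @return numeric matrix, one row per subject, columns in [all_edges()]
#'   order; rownames are subject ids.
#' @export
cohort_edge_matrix <- function(cohort, timepoint, ids = NULL, group = "PD") {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (!timepoint %in% cohort$timepoints) {
    stop_input("unknown timepoint '%s' (have: %s)", timepoint,
               paste(cohort$timepoints, collapse = ", "))
  }
  if (is.null(ids)) ids <- cohort$subjects$id[cohort$subjects$group %in% group]
  out <- t(vapply(ids, function(id) {
    mat_to_edgevec(cohort$matrices[[id]][[timepoint]])
  }, numeric(cohort$atlas$n_regions * (cohort$atlas$n_regions - 1) / 2)))
  rownames(out) <- ids
  out
}
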