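#' The network index and its clinical correlates
#'
#' The network index (NI) of a subject is the mean connectivity weight
#' over the edges of a significance-derived subnetwork,
#' `NI = sum_i W_i / N`, read from that subject's own matrix. Computed at
#' every visit it tracks the progression of a dysconnectivity network at
#' the individual level; its longitudinal change is compared across
#' visits (paired tests, Bonferroni over the visit pairs) and correlated
#' with clinical scores.
#'
#' @name network_index
NULL

#' Network index of one connectivity matrix over a subnetwork
#'
#' @param matrix symmetric connectivity matrix.
#' @param subnetwork a `subnetwork` or a data.frame of 0-based `i`, `j`
#'   edges.
#' @return Mean edge weight (scalar in `[0, 1]` for PLV weights).
#' @export
compute_ni <- function(matrix, subnetwork) {
  edges <- if (inherits(subnetwork, "subnetwork")) subnetwork$edges else
    as.data.frame(subnetwork)
  if (!nrow(edges)) stop_input("NI is undefined for an empty subnetwork")
  pos <- edge_positions(edges, nrow(matrix))
  mean(mat_to_edgevec(matrix)[pos])
}

#' Per-subject NI at every timepoint
#'
#' Applies a fixed subnetwork edge mask to each subject's matrix at each
#' visit - including subjects or groups the subnetwork was not derived
#' from (cross-application to controls or the other lateralized
#' subgroup).
#'
#' @param cohort a `cohort_dataset`.
#' @param subnetwork edge mask (see [compute_ni()]).
#' @param group group(s) to evaluate (default `"PD"`).
#' @param ids explicit subject ids (overrides `group`).
#' @return data.frame `id`, `group`, `timepoint`, `ni`.
#' @export
ni_trajectories <- function(cohort, subnetwork, group = "PD", ids = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.null(ids)) ids <- cohort$subjects$id[cohort$subjects$group %in% group]
  grp <- cohort$subjects$group[match(ids, cohort$subjects$id)]
  out <- do.call(rbind, lapply(seq_along(ids), function(s) {
    data.frame(id = ids[s], group = grp[s], timepoint = cohort$timepoints,
               ni = vapply(cohort$timepoints, function(tp) {
                 compute_ni(cohort$matrices[[ids[s]]][[tp]], subnetwork)
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired longitudinal tests on NI trajectories
#'
#' One paired two-sided test per timepoint pair, Bonferroni-corrected
#' over the pairs tested (the correction family is the visit pairs within
#' one band/contrast, never pooled across bands). Subjects missing either
#' timepoint of a pair are excluded listwise.
#'
#' @param traj data.frame from [ni_trajectories()].
#' @param pairs list of `c(tp_a, tp_b)` pairs; default all three pairs of
#'   `BL`, `3YFU`, `5YFU` present in `traj`.
#' @param method `"t"` (paired t-test, default) or `"wilcoxon"` (signed
#'   rank).
#' @return data.frame with one row per pair: `tp_a`, `tp_b`, `n`,
#'   `statistic`, `mean_change`, `p`, `p_bonferroni`.
#' @export
longitudinal_ni_test <- function(traj, pairs = NULL,
                                 method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  tps <- intersect(TIMEPOINTS, unique(traj$timepoint))
  if (is.null(pairs)) {
    pairs <- utils::combn(tps, 2, simplify = FALSE)
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- traj[traj$timepoint == pr[1], c("id", "ni")]
    b <- traj[traj$timepoint == pr[2], c("id", "ni")]
    mg <- merge(a, b, by = "id", suffixes = c("_a", "_b"))
    if (nrow(mg) < 3) stop_input("fewer than 3 complete subjects for %s vs %s",
                                 pr[1], pr[2])
    d <- mg$ni_a - mg$ni_b
    if (method == "t") {
      if (sd(d) == 0) {
        # constant differences: t is 0/0 (all equal) or infinite
        stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        p <- if (mean(d) == 0) 1 else 0
      } else {
        ht <- t.test(d)
        stat <- unname(ht$statistic); p <- ht$p.value
      }
    } else {
      if (all(d == 0)) {
        # all-zero differences: the signed-rank statistic is degenerate;
        # report p = 1 explicitly
        stat <- 0; p <- 1
      } else {
        ht <- suppressWarnings(wilcox.test(d))
        stat <- unname(ht$statistic); p <- ht$p.value
      }
    }
    data.frame(tp_a = pr[1], tp_b = pr[2], n = nrow(mg), statistic = stat,
               mean_change = mean(d), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  out
}

#' Pearson correlation between NI and a clinical score
#'
#' Same-timepoint correlation, or change-versus-change over a stated
#' interval (`delta = later - earlier` for both variables). An optional
#' covariate set yields partial correlations (both variables residualized
#' on the covariates before the Pearson step).
#'
#' @param cohort a `cohort_dataset`.
#' @param traj NI trajectories ([ni_trajectories()]).
#' @param score score column in `cohort$scores` (`"moca"`, `"updrs3"`).
#' @param pairing `"same-timepoint"` or `"change-vs-change"`.
#' @param timepoint visit for same-timepoint pairing.
#' @param interval `c(earlier, later)` for change-vs-change pairing.
#' @param covariates optional confound names (e.g. `"ledd"`) for a
#'   partial correlation.
#' @param drop_extreme drop this many subjects with the most extreme
#'   (lowest) score change before correlating - the leave-out
#'   sensitivity mode (change-vs-change only).
#' @return data.frame row: `r`, `p`, `n`, `variable`, `pairing`, `when`.
#' @export
correlate_ni_score <- function(cohort, traj, score = "moca",
                               pairing = c("same-timepoint", "change-vs-change"),
                               timepoint = NULL, interval = NULL,
                               covariates = NULL, drop_extreme = 0) {
  pairing <- match.arg(pairing)
  sc <- cohort$scores
  if (!score %in% names(sc)) stop_input("unknown score '%s'", score)
  if (pairing == "same-timepoint") {
    if (is.null(timepoint)) stop_input("same-timepoint pairing needs `timepoint`")
    x <- traj[traj$timepoint == timepoint, c("id", "ni")]
    y <- sc[sc$timepoint == timepoint, c("id", score)]
    mg <- merge(x, y, by = "id")
    when <- timepoint
  } else {
    if (is.null(interval) || length(interval) != 2) {
      stop_input("change-vs-change pairing needs `interval = c(earlier, later)`")
    }
    ni_w <- merge(traj[traj$timepoint == interval[1], c("id", "ni")],
                  traj[traj$timepoint == interval[2], c("id", "ni")],
                  by = "id", suffixes = c("_a", "_b"))
    sc_w <- merge(sc[sc$timepoint == interval[1], c("id", score)],
                  sc[sc$timepoint == interval[2], c("id", score)],
                  by = "id", suffixes = c("_a", "_b"))
    mg <- merge(data.frame(id = ni_w$id, ni = ni_w$ni_b - ni_w$ni_a),
                data.frame(id = sc_w$id,
                           score = sc_w[[paste0(score, "_b")]] -
                             sc_w[[paste0(score, "_a")]]),
                by = "id")
    names(mg)[names(mg) == "score"] <- score
    when <- paste(interval, collapse = "->")
  }
  names(mg) <- c("id", "ni", "score")
  drop_n <- sum(!complete.cases(mg))
  if (drop_n) log_info("excluding %d subject(s) with missing values", drop_n)
  mg <- mg[complete.cases(mg), , drop = FALSE]
  if (drop_extreme > 0) {
    if (pairing != "change-vs-change") {
      stop_input("drop_extreme applies to change-vs-change pairing only")
    }
    mg <- mg[order(mg$score), , drop = FALSE][-seq_len(drop_extreme), ,
                                              drop = FALSE]
  }
  if (nrow(mg) < 3) stop_input("need at least 3 paired observations")
  if (sd(mg$score) == 0) stop_input("score has zero variance")
  if (!is.null(covariates)) {
    cv <- cohort$subjects[match(mg$id, cohort$subjects$id), covariates,
                          drop = FALSE]
    mg$ni <- residuals(lm(mg$ni ~ ., data = cv))
    mg$score <- residuals(lm(mg$score ~ ., data = cv))
  }
  ct <- cor.test(mg$ni, mg$score)
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = nrow(mg),
             variable = score, pairing = pairing, when = when,
             stringsAsFactors = FALSE)
}

#' Subnetwork whose edge changes track a score change
#'
#' Within a base subnetwork, retains the edges whose longitudinal weight
#' change correlates with the longitudinal score change across subjects
#' at `p < edge_alpha` (uncorrected edge screening; the threshold is an
#' explicit parameter, not a fixed rule).
#'
#' @param cohort a `cohort_dataset`.
#' @param base base `subnetwork` (or edge data.frame) to screen.
#' @param score score column name.
#' @param interval `c(earlier, later)` visits defining both changes.
#' @param edge_alpha per-edge retention threshold (default 0.05).
#' @param group subject group (default `"PD"`).
#' @return A `subnetwork`-like object whose `edges` carry per-edge `r`
#'   and `p`; the retained set need not be connected.
#' @export
change_correlated_subnetwork <- function(cohort, base, score = "moca",
                                         interval = c("BL", "5YFU"),
                                         edge_alpha = 0.05, group = "PD") {
  edges <- if (inherits(base, "subnetwork")) base$edges else as.data.frame(base)
  if (!nrow(edges)) stop_input("base subnetwork is empty")
  n <- cohort$atlas$n_regions
  pos <- edge_positions(edges, n)
  wa <- cohort_edge_matrix(cohort, interval[1], group = group)[, pos, drop = FALSE]
  wb <- cohort_edge_matrix(cohort, interval[2], group = group)[, pos, drop = FALSE]
  dw <- wb - wa
  sc <- cohort$scores
  ids <- rownames(wa)
  s_a <- sc[[score]][match(paste(ids, interval[1]),
                           paste(sc$id, sc$timepoint))]
  s_b <- sc[[score]][match(paste(ids, interval[2]),
                           paste(sc$id, sc$timepoint))]
  ds <- s_b - s_a
  keep <- is.finite(ds)
  dw <- dw[keep, , drop = FALSE]; ds <- ds[keep]
  res <- apply(dw, 2, function(col) {
    if (sd(col) == 0) return(c(r = 0, p = 1))
    ct <- cor.test(col, ds)
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  out <- edges[, c("i", "j")]
  out$r <- res["r", ]
  out$p <- res["p", ]
  retained <- out[out$p < edge_alpha, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(edges = retained, n_edges = nrow(retained),
                 n_regions = length(unique(c(retained$i, retained$j))),
                 primary_threshold = NA_real_,
                 component_pvalue = NA_real_,
                 edge_alpha = edge_alpha, score = score,
                 interval = interval),
            class = "subnetwork")
}
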