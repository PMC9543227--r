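#' Network-based statistic for paired longitudinal contrasts
#'
#' Edgewise paired statistics with confound adjustment, supra-threshold
#' component extraction, and permutation-based family-wise-error control
#' over component extent. The paired design is handled by regressing each
#' subject's edge difference `d = w(tp_a) - w(tp_b)` on an intercept plus
#' confounds and testing the intercept (the adjusted mean difference);
#' the null distribution of the maximum component extent is built by
#' sign-flipping each subject's difference map, which is exact under
#' exchangeability of visit labels within subject.
#'
#' @name nbs
NULL

# Intercept t-statistics for every column of D regressed on X (first
# column of X must be the intercept). Returns a length-E vector.
# Vectorized across edges via one QR of X.
edge_intercept_t <- function(D, X) {
  n <- nrow(D)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop_input("design matrix is rank deficient")
  beta <- qr.coef(qx, D)                      # p x E
  resid <- D - X %*% beta
  rss <- colSums(resid^2)
  sigma2 <- rss / (n - p)
  xtx_inv_11 <- chol2inv(qr.R(qx))[1, 1]
  beta[1, ] / sqrt(pmax(sigma2 * xtx_inv_11, .Machine$double.xmin))
}

# Build the confound design matrix from the subjects table; categorical
# confounds are dummy-coded. Errors on constant or collinear columns.
confound_design <- function(subjects, confounds) {
  if (!length(confounds)) {
    return(matrix(1, nrow(subjects), 1, dimnames = list(NULL, "(Intercept)")))
  }
  missing <- setdiff(confounds, names(subjects))
  if (length(missing)) stop_input("confound(s) not in cohort: %s",
                                  paste(missing, collapse = ", "))
  for (cf in confounds) {
    v <- subjects[[cf]]
    if (anyNA(v)) stop_input("confound '%s' has missing values", cf)
    if (length(unique(v)) < 2) stop_input("confound '%s' is constant", cf)
  }
  fml <- stats::as.formula(paste("~", paste(confounds, collapse = " + ")))
  X <- model.matrix(fml, data = subjects)
  # center numeric confound columns so the intercept is the adjusted mean
  for (k in 2:ncol(X)) X[, k] <- X[, k] - mean(X[, k])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_input("collinear confound column(s): %s", paste(drop, collapse = ", "))
  }
  X
}

#' Edgewise paired statistics with confound adjustment
#'
#' @param cohort a `cohort_dataset`.
#' @param tp_a,tp_b timepoints to contrast (e.g. `"BL"`, `"5YFU"`).
#' @param confounds covariate names from the subjects table (dummy-coded
#'   if categorical); `character(0)` for the plain paired t.
#' @param direction `"decrease"` tests `tp_a > tp_b` (positive t =
#'   weight loss from `tp_a` to `tp_b`); `"increase"` flips the sign.
#' @param group subject group analyzed (default `"PD"`).
#' @param ids explicit subject ids (overrides `group`).
#' @return An `edge_stat_map`: `t` (edge-vector t statistics), `tmat`
#'   (symmetric matrix form), `D`, `X`, `df`, plus metadata.
#' @export
edgewise_paired_stats <- function(cohort, tp_a, tp_b,
                                  confounds = character(0),
                                  direction = c("decrease", "increase"),
                                  group = "PD", ids = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.null(ids)) ids <- cohort$subjects$id[cohort$subjects$group %in% group]
  wa <- cohort_edge_matrix(cohort, tp_a, ids = ids)
  wb <- cohort_edge_matrix(cohort, tp_b, ids = ids)
  D <- if (direction == "decrease") wa - wb else wb - wa
  subjects <- cohort$subjects[match(ids, cohort$subjects$id), , drop = FALSE]
  n <- nrow(D)
  if (n <= length(confounds) + 2) {
    stop_input("need more than %d subjects for %d confound(s); have %d",
               length(confounds) + 2, length(confounds), n)
  }
  X <- confound_design(subjects, confounds)
  tvec <- edge_intercept_t(D, X)
  structure(list(t = tvec, tmat = edgevec_to_mat(tvec, cohort$atlas$n_regions),
                 D = D, X = X, df = n - ncol(X), n = n,
                 direction = direction, confounds = confounds,
                 tp_a = tp_a, tp_b = tp_b,
                 n_regions = cohort$atlas$n_regions),
            class = "edge_stat_map")
}

# Connected components among supra-threshold edges; returns a list of
# integer edge-position vectors (into the canonical edge vector), sorted
# by decreasing extent with ties broken by smallest edge position.
components_from_tvec <- function(tvec, threshold, n_regions) {
  sel <- which(tvec >= threshold)
  if (!length(sel)) return(list())
  ed <- all_edges(n_regions)[sel, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(ed$i + 1L, ed$j + 1L), directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[ed$i + 1L]
  groups <- split(sel, comp_of_edge)
  ord <- order(-lengths(groups), vapply(groups, min, integer(1)))
  unname(groups[ord])
}

subnetwork_from_positions <- function(pos, tvec, n_regions, threshold,
                                      pvalue = NA_real_) {
  ed <- all_edges(n_regions)[pos, , drop = FALSE]
  ed$t <- tvec[pos]
  rownames(ed) <- NULL
  structure(list(edges = ed, n_edges = nrow(ed),
                 n_regions = length(unique(c(ed$i, ed$j))),
                 primary_threshold = threshold,
                 component_pvalue = pvalue),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %d edges / %d regions (threshold %g%s)\n",
              x$n_edges, x$n_regions, x$primary_threshold,
              if (is.na(x$component_pvalue)) "" else
                sprintf(", corrected p = %.4g", x$component_pvalue)))
  invisible(x)
}

#' Supra-threshold connected components of an edge statistic map
#'
#' @param stats an `edge_stat_map` (or a symmetric t matrix).
#' @param threshold primary t threshold (> 0); edges with `t >= threshold`
#'   enter the graph.
#' @return List of uncorrected `subnetwork` objects sorted by decreasing
#'   extent (edge count).
#' @export
supra_threshold_components <- function(stats, threshold) {
  if (threshold <= 0) stop_input("primary threshold must be > 0")
  if (inherits(stats, "edge_stat_map")) {
    tvec <- stats$t; nr <- stats$n_regions
  } else {
    validate_sym <- function(m) if (max(abs(m - t(m))) > 1e-8)
      stop_input("t matrix must be symmetric")
    validate_sym(stats)
    tvec <- mat_to_edgevec(stats); nr <- nrow(stats)
  }
  lapply(components_from_tvec(tvec, threshold, nr),
         subnetwork_from_positions, tvec = tvec, n_regions = nr,
         threshold = threshold)
}

# Null distribution of the max component extent under sign flipping.
# signs: n_perm x n matrix of +/-1.
null_max_extents <- function(D, X, threshold, n_regions, signs) {
  vapply(seq_len(nrow(signs)), function(b) {
    tb <- edge_intercept_t(D * signs[b, ], X)
    comps <- components_from_tvec(tb, threshold, n_regions)
    if (length(comps)) length(comps[[1]]) else 0L
  }, integer(1))
}

#' Network-based statistic with sign-flip permutation FWER control
#'
#' @inheritParams edgewise_paired_stats
#' @param primary_threshold primary t threshold defining supra-threshold
#'   edges.
#' @param n_permutations number of random sign-flip permutations
#'   (>= 100), or the string `"exact"` to enumerate all `2^n` sign
#'   patterns (n <= 20).
#' @param seed permutation seed; results are deterministic given it.
#' @param alpha significance level recorded per component (default 0.05).
#' @return List with `components` (each a `subnetwork` carrying
#'   `component_pvalue` and `significant`), `stats` (the
#'   `edge_stat_map`), `null_max_extent`, and the call parameters.
#'   Corrected p for a component of extent `k` is
#'   `(1 + #\{null max extent >= k\}) / (1 + B)` for random permutations
#'   and the exact enumeration fraction for `"exact"`.
#' @export
nbs <- function(cohort, tp_a, tp_b, confounds = character(0),
                primary_threshold, direction = c("decrease", "increase"),
                n_permutations = 1000, seed = 42, alpha = 0.05,
                group = "PD", ids = NULL) {
  direction <- match.arg(direction)
  stats <- edgewise_paired_stats(cohort, tp_a, tp_b, confounds = confounds,
                                 direction = direction, group = group,
                                 ids = ids)
  exact <- identical(n_permutations, "exact")
  if (!exact && n_permutations < 100) {
    stop_input("n_permutations must be >= 100 (or \"exact\")")
  }
  n <- stats$n
  if (exact) {
    if (n > 20) stop_input("exact enumeration limited to n <= 20 subjects")
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    signs <- grid
  } else {
    signs <- with_seed(seed, {
      matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
             nrow = n_permutations)
    })
  }
  null_ext <- null_max_extents(stats$D, stats$X, primary_threshold,
                               stats$n_regions, signs)
  comps <- components_from_tvec(stats$t, primary_threshold, stats$n_regions)
  components <- lapply(comps, function(pos) {
    k <- length(pos)
    p <- if (exact) mean(null_ext >= k) else
      (1 + sum(null_ext >= k)) / (1 + length(null_ext))
    sn <- subnetwork_from_positions(pos, stats$t, stats$n_regions,
                                    primary_threshold, pvalue = p)
    sn$significant <- p < alpha
    sn
  })
  log_info("NBS %s vs %s (%s, thresh %g, %s perms): %d component(s), min p %s",
           tp_a, tp_b, direction, primary_threshold,
           if (exact) "exact" else n_permutations, length(components),
           if (length(components))
             format(min(vapply(components, `[[`, 1, "component_pvalue")))
           else "NA")
  structure(list(components = components, stats = stats,
                 null_max_extent = null_ext,
                 primary_threshold = primary_threshold,
                 n_permutations = if (exact) nrow(signs) else n_permutations,
                 exact = exact, seed = seed, alpha = alpha),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> threshold %g, %d permutations%s\n",
              x$primary_threshold, x$n_permutations,
              if (x$exact) " (exact)" else ""))
  for (k in seq_along(x$components)) {
    co <- x$components[[k]]
    cat(sprintf("  component %d: %d edges / %d regions, corrected p = %.4g%s\n",
                k, co$n_edges, co$n_regions, co$component_pvalue,
                if (isTRUE(co$significant)) " *" else ""))
  }
  if (!length(x$components)) cat("  no supra-threshold components\n")
  invisible(x)
}

#' Empirical FWER of the NBS under the global null
#'
#' Simulates `n_datasets` null cohorts (no planted effect), runs the NBS
#' on each, and returns the fraction of datasets with any component
#' significant at `alpha` - a calibration check that the permutation
#' procedure controls the family-wise error rate.
#'
#' @param n_datasets number of simulated null cohorts.
#' @param n_subjects,n_regions cohort size per dataset.
#' @param n_permutations sign-flip permutations per dataset.
#' @param primary_threshold primary t threshold.
#' @param alpha nominal FWER level.
#' @param seed top-level seed.
#' @return List with `fwer`, `n_reject`, `n_datasets`.
#' @export
nbs_null_fwer <- function(n_datasets = 200, n_subjects = 20, n_regions = 30,
                          n_permutations = 500, primary_threshold = 2,
                          alpha = 0.05, seed = 1) {
  atlas <- small_atlas(n_regions)
  rejects <- vapply(seq_len(n_datasets), function(r) {
    co <- simulate_longitudinal_cohort(
      atlas, n_pd = n_subjects, n_hc = 0, timepoints = c("BL", "5YFU"),
      planted = NULL, seed = derive_seed(seed, r))
    res <- nbs(co, "BL", "5YFU", primary_threshold = primary_threshold,
               n_permutations = n_permutations,
               seed = derive_seed(seed, 10000 + r), alpha = alpha)
    any(vapply(res$components, function(co.) isTRUE(co.$significant), logical(1)))
  }, logical(1))
  list(fwer = mean(rejects), n_reject = sum(rejects), n_datasets = n_datasets)
}

# Minimal balanced atlas for simulation studies (n regions, alternating
# hemispheres, lobes cycled).
small_atlas <- function(n) {
  region_atlas(data.frame(
    index = 0:(n - 1),
    name = sprintf("r%03d", 0:(n - 1)),
    hemisphere = rep_len(c("L", "R"), n),
    lobe = rep_len(rep(ATLAS_LOBES, each = 2), n)
  ))
}

#' Jaccard overlap of two edge sets
#' @param a,b data.frames with 0-based `i`, `j` columns.
#' @export
edge_jaccard <- function(a, b) {
  key <- function(e) paste(pmin(e$i, e$j), pmax(e$i, e$j))
  ka <- unique(key(a)); kb <- unique(key(b))
  length(intersect(ka, kb)) / length(union(ka, kb))
}
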