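#' Motor-symptom lateralization and subnetwork dominance
#'
#' Patients are assigned a dominant motor side from the lateralized
#' UPDRS-III items (20-26): the body side with the strictly larger item
#' sum at every visit. Side-specific subgroup analyses rerun the NBS
#' within a subgroup (dominant side dropped from the confounds, since it
#' is constant there) and cross-apply the resulting NI mask to the other
#' subgroup and to controls. Dominance summaries quantify where a
#' subnetwork lives: hemisphere and lobe-pair edge shares and
#' highest-degree regions.
#'
#' @name lateralization
NULL

#' Assign dominant motor side from lateralized item sums
#'
#' @param left_sums,right_sums numeric vectors of per-visit left-body and
#'   right-body sums of UPDRS-III items 20-26 (each visit sum in 0-28).
#' @return One of `"LPD"` (left-body sums strictly larger at every
#'   visit), `"RPD"` (right strictly larger at every visit),
#'   `"symmetric"` (equal at every visit), `"inconsistent"` (the
#'   direction flips or mixes across visits). Symmetric and inconsistent
#'   patients are excluded from subgroup analyses.
#' @export
assign_dominant_side <- function(left_sums, right_sums) {
  if (length(left_sums) != length(right_sums) || !length(left_sums)) {
    stop_input("left and right sums must be non-empty and equal length")
  }
  if (anyNA(left_sums) || anyNA(right_sums)) {
    stop_input("missing visit in lateralized item sums")
  }
  if (any(left_sums < 0 | right_sums < 0 | left_sums > 28 | right_sums > 28)) {
    stop_input("item sums must lie in 0..28 (seven items scored 0-4)")
  }
  if (all(left_sums > right_sums)) return("LPD")
  if (all(right_sums > left_sums)) return("RPD")
  if (all(left_sums == right_sums)) return("symmetric")
  "inconsistent"
}

#' Side assignments for every patient in a cohort
#'
#' @param cohort a `cohort_dataset` whose scores table carries
#'   `updrs_left` / `updrs_right` sums.
#' @return data.frame `id`, per-visit sums, `label`.
#' @export
cohort_side_assignments <- function(cohort) {
  sc <- cohort$scores
  ids <- cohort$subjects$id[cohort$subjects$group == "PD"]
  rows <- lapply(ids, function(id) {
    s <- sc[sc$id == id, ]
    s <- s[match(cohort$timepoints, s$timepoint), ]
    data.frame(id = id,
               left = paste(s$updrs_left, collapse = ";"),
               right = paste(s$updrs_right, collapse = ";"),
               label = assign_dominant_side(s$updrs_left, s$updrs_right),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Side-specific NBS with NI cross-application
#'
#' Runs the NBS within one lateralized subgroup (dominant side removed
#' from the confound list - it is constant within the subgroup) and
#' evaluates the resulting top component's NI on that subgroup, the
#' opposite subgroup, and controls.
#'
#' @param cohort a `cohort_dataset`.
#' @param side `"LPD"` or `"RPD"`.
#' @param tp_a,tp_b contrasted timepoints.
#' @param confounds confound names; `"dominant_side"` is dropped
#'   automatically.
#' @param assignments optional precomputed [cohort_side_assignments()].
#' @param ... further arguments to [nbs()] (`primary_threshold`,
#'   `n_permutations`, `seed`, ...).
#' @return List with `nbs` (the subgroup `nbs_result`), `side`, `n`,
#'   `confounds`, and `ni` (trajectories of the top component's mask on
#'   own subgroup / other subgroup / HC, when a component exists).
#' @export
subgroup_nbs <- function(cohort, side = c("LPD", "RPD"), tp_a = "BL",
                         tp_b = "5YFU", confounds = character(0),
                         assignments = NULL, ...) {
  side <- match.arg(side)
  if (is.null(assignments)) assignments <- cohort_side_assignments(cohort)
  ids <- assignments$id[assignments$label == side]
  other <- assignments$id[assignments$label == setdiff(c("LPD", "RPD"), side)]
  if (length(ids) < 2) stop_input("subgroup %s has %d subject(s); need >= 2",
                                  side, length(ids))
  if (length(ids) < 5) stop_input("subgroup %s too small for NBS (n = %d < 5)",
                                  side, length(ids))
  if (length(ids) < 10) {
    warning(sprintf("subgroup %s has n = %d < 10; interpret with caution",
                    side, length(ids)), call. = FALSE)
  }
  confounds <- setdiff(confounds, "dominant_side")
  log_info("subgroup %s NBS with confounds {%s}", side,
           paste(confounds, collapse = ", "))
  res <- nbs(cohort, tp_a, tp_b, confounds = confounds, ids = ids, ...)
  ni <- NULL
  if (length(res$components)) {
    top <- res$components[[1]]
    ni <- list(
      own = ni_trajectories(cohort, top, ids = ids),
      other = if (length(other) >= 3) ni_trajectories(cohort, top, ids = other),
      hc = if (any(cohort$subjects$group == "HC"))
        ni_trajectories(cohort, top, group = "HC")
    )
  }
  list(nbs = res, side = side, n = length(ids), confounds = confounds, ni = ni)
}

#' Hemisphere and lobe dominance summary of a subnetwork
#'
#' @param subnetwork a `subnetwork` (non-empty).
#' @param atlas the [region_atlas] the edges index into.
#' @param top_k how many highest-degree regions to report (ties broken by
#'   lower region index).
#' @return List with `edge_shares` (intra-L / intra-R / inter fractions),
#'   `region_shares` (L / R fractions over distinct endpoint regions),
#'   `lobe_pair_shares` (named, sums to 1), and `top_regions`
#'   (data.frame `index`, `name`, `hemisphere`, `degree`).
#' @export
dominance_summary <- function(subnetwork, atlas, top_k = 10) {
  edges <- if (inherits(subnetwork, "subnetwork")) subnetwork$edges else
    as.data.frame(subnetwork)
  if (!nrow(edges)) stop_input("dominance summary undefined for empty subnetwork")
  cl <- classify_edges(atlas, edges)
  hclasses <- c("intra-L", "intra-R", "inter")
  edge_shares <- vapply(hclasses,
                        function(h) mean(cl$hemisphere_class == h), numeric(1))
  nodes <- unique(c(edges$i, edges$j))
  hemis <- atlas$regions$hemisphere[nodes + 1]
  region_shares <- c(L = mean(hemis == "L"), R = mean(hemis == "R"))
  lp <- table(cl$lobe_pair)
  lobe_pair_shares <- setNames(as.numeric(lp) / nrow(edges), names(lp))
  deg <- table(factor(c(edges$i, edges$j), levels = nodes))
  ord <- order(-as.integer(deg), as.integer(names(deg)))
  top <- head(ord, top_k)
  top_regions <- data.frame(
    index = as.integer(names(deg))[top],
    name = atlas$regions$name[as.integer(names(deg))[top] + 1],
    hemisphere = atlas$regions$hemisphere[as.integer(names(deg))[top] + 1],
    degree = as.integer(deg)[top],
    stringsAsFactors = FALSE
  )
  list(edge_shares = edge_shares, region_shares = region_shares,
       lobe_pair_shares = lobe_pair_shares, top_regions = top_regions)
}
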