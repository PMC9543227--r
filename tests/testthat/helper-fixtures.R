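# Shared fixtures and independent oracles for the test suite.

# Balanced toy atlas: alternating hemispheres, lobes cycled.
toy_atlas <- function(n) longconn:::small_atlas(n)

# Assemble a cohort_dataset by hand from explicit matrices, bypassing the
# generator - used to feed hand-computed oracle cases into the stats
# machinery. `mats` is list(id -> list(tp -> matrix)).
manual_cohort <- function(mats, atlas, subjects = NULL, scores = NULL) {
  ids <- names(mats)
  tps <- names(mats[[1]])
  if (is.null(subjects)) {
    subjects <- data.frame(id = ids, group = "PD",
                           age = seq(60, 70, length.out = length(ids)),
                           sex = rep_len(c("M", "F"), length(ids)),
                           education = 12, ledd = 500,
                           dominant_side = "L", stringsAsFactors = FALSE)
  }
  if (is.null(scores)) {
    scores <- expand.grid(id = ids, timepoint = tps,
                          stringsAsFactors = FALSE)
    scores$moca <- 26
    scores$updrs3 <- 14
    scores$updrs_left <- 6
    scores$updrs_right <- 2
  }
  structure(list(atlas = atlas, subjects = subjects, scores = scores,
                 matrices = mats, timepoints = tps, planted = NULL,
                 seed = NA_integer_, log = list()),
            class = "cohort_dataset")
}

# Build per-subject matrices from per-subject difference values on chosen
# edges: BL = base, 5YFU = base - diff.
diff_cohort <- function(diffs_by_subject, edges, atlas, base = 0.5) {
  n <- atlas$n_regions
  mats <- lapply(seq_along(diffs_by_subject), function(s) {
    m0 <- matrix(base, n, n); diag(m0) <- 0
    m1 <- m0
    d <- diffs_by_subject[[s]]
    for (k in seq_len(nrow(edges))) {
      i <- edges$i[k] + 1; j <- edges$j[k] + 1
      m1[i, j] <- m1[j, i] <- m0[i, j] - d[k]
    }
    list(BL = m0, "5YFU" = m1)
  })
  names(mats) <- sprintf("s%02d", seq_along(mats))
  manual_cohort(mats, atlas)
}

# Independent union-find component labelling over supra-threshold edges;
# returns list of edge-position vectors sorted by decreasing size.
uf_components <- function(tvec, threshold, n_regions) {
  sel <- which(tvec >= threshold)
  if (!length(sel)) return(list())
  ed <- all_edges(n_regions)[sel, , drop = FALSE]
  parent <- seq_len(n_regions)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(ed))) {
    ri <- find(ed$i[k] + 1L); rj <- find(ed$j[k] + 1L)
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(ed$i + 1L, find, integer(1))
  groups <- split(sel, roots)
  groups <- groups[order(-lengths(groups), vapply(groups, min, integer(1)))]
  unname(groups)
}

# Exhaustive NBS oracle for tiny paired designs (no confounds): enumerate
# every sign pattern, one-sample t per edge, union-find components, exact
# p for a component of extent k as the fraction of patterns whose maximum
# extent reaches k.
exhaustive_nbs_oracle <- function(D, threshold, n_regions) {
  n <- nrow(D)
  one_sample_t <- function(x) {
    s <- sd(x)
    if (s == 0) return(0)
    mean(x) / (s / sqrt(length(x)))
  }
  max_extent <- function(Ds) {
    tv <- apply(Ds, 2, one_sample_t)
    comps <- uf_components(tv, threshold, n_regions)
    if (length(comps)) length(comps[[1]]) else 0L
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_ext <- apply(signs, 1, function(s) max_extent(D * s))
  tv_obs <- apply(D, 2, one_sample_t)
  comps <- uf_components(tv_obs, threshold, n_regions)
  list(
    extents = lengths(comps),
    pvalues = vapply(comps, function(pos) mean(null_ext >= length(pos)),
                     numeric(1)),
    null = null_ext
  )
}
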