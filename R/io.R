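#' Cohort and result serialization
#'
#' Cohorts round-trip through a plain-text layout: `cohort.csv` (one row
#' per subject x timepoint with covariates and scores), `atlas.csv`, one
#' whitespace-delimited matrix file per subject x timepoint under
#' `matrices/`, and a JSON `manifest.json` carrying seed and generator
#' parameters. Results are written as JSON records stamped with the run
#' seed and a config hash; subnetworks are additionally exported as TSV
#' edge lists and BrainNet Viewer `.node`/`.edge` pairs.
#'
#' @name cohort_io
NULL

#' Run configuration
#'
#' Flat named list of pipeline settings; round-trips through JSON
#' identically ([write_run_config()] / [read_run_config()]). Every
#' stochastic stage derives its stream from the single `seed`.
#'
#' @param seed top-level integer seed.
#' @param ... further settings (band, epoch policy, lambda, NBS
#'   threshold, ...).
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- c(list(seed = as.integer(seed)), list(...))
  # normalize whole numbers to integer so the JSON round trip is identical
  cfg <- lapply(cfg, function(x) {
    if (is.numeric(x) && all(is.finite(x)) && all(x == round(x)) &&
        all(abs(x) < .Machine$integer.max)) as.integer(x) else x
  })
  structure(cfg[order(names(cfg))], class = "run_config")
}

#' @param config a `run_config`.
#' @param path JSON file path.
#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small rolling hash; stable across sessions, locale-independent
  h <- Reduce(function(h, ch) (h * 31 + ch) %% 2147483629,
              utf8ToInt(as.character(s)), accumulate = FALSE, init = 17)
  sprintf("%08x", as.integer(h))
}

#' Write a cohort to a directory
#'
#' @param cohort a `cohort_dataset`.
#' @param dir output directory (created).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.csv"))
  tab <- merge(cohort$scores, cohort$subjects, by = "id", sort = FALSE)
  tab$matrix_file <- file.path("matrices",
                               paste0(tab$id, "_", tab$timepoint, ".txt"))
  tab <- tab[order(match(tab$id, cohort$subjects$id),
                   match(tab$timepoint, TIMEPOINTS)), ]
  cols <- c("id", "group", "timepoint", "age", "sex", "education", "ledd",
            "dominant_side", "moca", "updrs3", "updrs_left", "updrs_right",
            "matrix_file")
  write.csv(tab[, cols], file.path(dir, "cohort.csv"), row.names = FALSE,
            quote = FALSE, na = "")
  for (r in seq_len(nrow(tab))) {
    write_matrix_txt(cohort$matrices[[tab$id[r]]][[tab$timepoint[r]]],
                     file.path(dir, tab$matrix_file[r]))
  }
  jsonlite::write_json(
    list(format_version = "1", seed = cohort$seed,
         timepoints = cohort$timepoints,
         n_regions = cohort$atlas$n_regions,
         n_subjects = nrow(cohort$subjects),
         log = cohort$log),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Validates the timepoint vocabulary, matrix symmetry (to 1e-8), and the
#' `[0,1]` weight range, naming the offending file and indices on error.
#'
#' @param dir directory written by [write_cohort()] (or hand-assembled
#'   with the same layout).
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "cohort.csv")
  if (!file.exists(path)) stop_input("cohort table not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("id", "group", "timepoint", "age", "sex", "education", "ledd",
           "dominant_side", "moca", "updrs3", "matrix_file")
  missing <- setdiff(req, names(tab))
  if (length(missing)) stop_input("cohort table lacks column(s): %s",
                                  paste(missing, collapse = ", "))
  bad_tp <- setdiff(unique(tab$timepoint), TIMEPOINTS)
  if (length(bad_tp)) {
    stop_input("unknown timepoint label '%s'; allowed: %s", bad_tp[1],
               paste(TIMEPOINTS, collapse = ", "))
  }
  atlas <- load_atlas(file.path(dir, "atlas.csv"))
  subjects <- unique(tab[, c("id", "group", "age", "sex", "education",
                             "ledd", "dominant_side")])
  rownames(subjects) <- NULL
  score_cols <- intersect(c("id", "timepoint", "moca", "updrs3",
                            "updrs_left", "updrs_right"), names(tab))
  matrices <- list()
  for (r in seq_len(nrow(tab))) {
    f <- file.path(dir, tab$matrix_file[r])
    if (!file.exists(f)) stop_input("missing matrix file: %s", f)
    m <- read_matrix_txt(f)
    if (nrow(m) != atlas$n_regions) {
      stop_input("%s: %d regions, atlas has %d", f, nrow(m), atlas$n_regions)
    }
    matrices[[tab$id[r]]][[tab$timepoint[r]]] <- m
  }
  timepoints <- TIMEPOINTS[TIMEPOINTS %in% unique(tab$timepoint)]
  for (id in subjects$id[subjects$group == "PD"]) {
    have <- names(matrices[[id]])
    if (!all(timepoints %in% have)) {
      stop_input("PD subject %s lacks matrices at: %s", id,
                 paste(setdiff(timepoints, have), collapse = ", "))
    }
  }
  manifest <- file.path(dir, "manifest.json")
  seed <- if (file.exists(manifest)) {
    jsonlite::read_json(manifest)$seed
  } else NA_integer_
  structure(list(atlas = atlas, subjects = subjects,
                 scores = tab[, score_cols], matrices = matrices,
                 timepoints = timepoints, planted = NULL, seed = seed,
                 log = list()),
            class = "cohort_dataset")
}

#' Write a subnetwork as TSV + BrainNet Viewer files + JSON metadata
#'
#' @param subnetwork a `subnetwork`.
#' @param atlas the [region_atlas].
#' @param dir output directory.
#' @param name file stem.
#' @param meta extra metadata recorded in the JSON sidecar.
#' @export
write_subnetwork <- function(subnetwork, atlas, dir, name = "subnetwork",
                             meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ed <- subnetwork$edges
  tsv <- file.path(dir, paste0(name, ".tsv"))
  extra <- setdiff(names(ed), c("i", "j"))
  lines <- c(paste(c("region_i", "region_j", extra), collapse = "\t"),
             vapply(seq_len(nrow(ed)), function(r) {
               paste(c(ed$i[r], ed$j[r],
                       fmt_num(unlist(ed[r, extra]))), collapse = "\t")
             }, character(1)))
  writeLines(lines, tsv)
  # .edge: full adjacency of edge weights (t or r), whitespace-delimited
  w <- if ("t" %in% names(ed)) ed$t else if ("r" %in% names(ed)) ed$r else
    rep(1, nrow(ed))
  adj <- matrix(0, atlas$n_regions, atlas$n_regions)
  adj[cbind(ed$i + 1, ed$j + 1)] <- w
  adj <- adj + t(adj)
  edge_path <- file.path(dir, paste0(name, ".edge"))
  con <- file(edge_path, "w")
  for (r in seq_len(nrow(adj))) {
    cat(fmt_num(adj[r, ]), sep = " ", file = con); cat("\n", file = con)
  }
  close(con)
  deg <- table(factor(c(ed$i, ed$j), levels = atlas$regions$index))
  write_brainnet_node(atlas, file.path(dir, paste0(name, ".node")),
                      size = as.integer(deg))
  jsonlite::write_json(
    c(list(n_edges = subnetwork$n_edges, n_regions = subnetwork$n_regions,
           primary_threshold = subnetwork$primary_threshold,
           component_pvalue = subnetwork$component_pvalue), meta),
    file.path(dir, paste0(name, ".json")), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(tsv)
}

#' Read back a subnetwork edge list written by [write_subnetwork()]
#' @param tsv path to the `.tsv` edge list.
#' @export
read_subnetwork_edges <- function(tsv) {
  tab <- read.csv(tsv, sep = "\t", stringsAsFactors = FALSE)
  names(tab)[names(tab) == "region_i"] <- "i"
  names(tab)[names(tab) == "region_j"] <- "j"
  tab
}

#' Write a stage's results as seed-stamped JSON
#'
#' @param results a named list of plain values/tables.
#' @param dir output directory.
#' @param name file stem.
#' @param config the `run_config` of the run (hashed into the record).
#' @return The manifest path, invisibly.
#' @export
write_results <- function(results, dir, name = "results", config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- list(results = results)
  if (!is.null(config)) {
    rec$seed <- config$seed
    rec$config_hash <- config_hash(config)
  }
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}
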