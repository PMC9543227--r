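#' Region atlases and edge classification
#'
#' A region atlas is the bookkeeping backbone of every network summary: an
#' ordered table of cortical regions with a hemisphere (`L`/`R`) and a lobe
#' label per region. Connectivity matrices are indexed in atlas order, and
#' edges are classified (intra-left, intra-right, interhemispheric; lobe
#' pair) through the atlas.
#'
#' Region indices are 0-based in all tables and edge lists, matching the
#' convention of connectome tooling; matrix rows/columns are `index + 1`.
#'
#' @name region_atlas
NULL

ATLAS_HEMISPHERES <- c("L", "R")
ATLAS_LOBES <- c("frontal", "temporal", "central", "parietal",
                 "occipital", "limbic", "insular")

#' Construct a region atlas from a region table
#'
#' @param regions data.frame with columns `index` (0-based, contiguous,
#'   unique), `name`, `hemisphere` (`L`/`R`), `lobe` (one of frontal,
#'   temporal, central, parietal, occipital, limbic, insular).
#' @return An object of class `region_atlas`.
#' @export
region_atlas <- function(regions) {
  req <- c("index", "name", "hemisphere", "lobe")
  missing <- setdiff(req, names(regions))
  if (length(missing)) {
    stop_input("region table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  regions <- as.data.frame(regions)[, req]
  regions$index <- as.integer(regions$index)
  regions$name <- as.character(regions$name)
  regions$hemisphere <- as.character(regions$hemisphere)
  regions$lobe <- as.character(regions$lobe)

  dup <- regions$index[duplicated(regions$index)]
  if (length(dup)) {
    stop_input("duplicate region index: %s", paste(unique(dup), collapse = ", "))
  }
  n <- nrow(regions)
  if (!setequal(regions$index, 0:(n - 1))) {
    bad <- setdiff(regions$index, 0:(n - 1))
    stop_input("region indices must be contiguous 0..%d; offending index: %s",
               n - 1, paste(bad, collapse = ", "))
  }
  regions <- regions[order(regions$index), , drop = FALSE]
  rownames(regions) <- NULL
  bad_h <- which(!regions$hemisphere %in% ATLAS_HEMISPHERES)
  if (length(bad_h)) {
    stop_input("unknown hemisphere label '%s' at region index %d",
               regions$hemisphere[bad_h[1]], regions$index[bad_h[1]])
  }
  bad_l <- which(!regions$lobe %in% ATLAS_LOBES)
  if (length(bad_l)) {
    stop_input("unknown lobe label '%s' at region index %d (allowed: %s)",
               regions$lobe[bad_l[1]], regions$index[bad_l[1]],
               paste(ATLAS_LOBES, collapse = ", "))
  }
  structure(list(regions = regions, n_regions = n), class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  tab <- table(x$regions$hemisphere)
  cat(sprintf("<region_atlas> %d regions (L: %d, R: %d)\n",
              x$n_regions, tab[["L"]], tab[["R"]]))
  cat("  lobes:", paste(sprintf("%s=%d", names(table(x$regions$lobe)),
                                table(x$regions$lobe)), collapse = " "), "\n")
  invisible(x)
}

#' Load a region atlas from a delimited table
#'
#' Reads a CSV/TSV region table (columns `index,name,hemisphere,lobe`) and
#' validates it. The delimiter is sniffed from the header line.
#'
#' @param path path to a delimited text file.
#' @return A [region_atlas].
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) stop_input("atlas table not found: %s", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  region_atlas(tab)
}

#' Write a region atlas table
#' @param atlas a [region_atlas].
#' @param path output CSV path.
#' @export
write_atlas <- function(atlas, path) {
  write.csv(atlas$regions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Gyrus pools per lobe for the packaged default parcellation (pair counts
# per hemisphere; they sum to 105).
.default_gyri <- list(
  frontal   = c(SFG = 8, MFG = 8, IFG = 7, OrG = 7),
  temporal  = c(STG = 6, MTG = 6, ITG = 4, FuG = 2, pSTS = 2),
  central   = c(PrG = 6, PoG = 6),
  parietal  = c(SPL = 5, IPL = 7, Pcun = 4),
  occipital = c(MVOcC = 5, LOcC = 7),
  limbic    = c(CG = 7, PhG = 3),
  insular   = c(INS = 5)
)

#' The packaged default 210-region atlas
#'
#' A synthetic parcellation table following the Brainnetome cortical
#' nomenclature: 105 homotopic region pairs interleaved so that even
#' 0-based indices are left-hemisphere and odd are right-hemisphere, with
#' gyrus-level names (SFG, MFG, STG, ...) grouped into seven lobes. The
#' gyrus-to-lobe mapping is the package's own documented assignment, not a
#' coordinate-accurate anatomy.
#'
#' @param central how to treat the pre/postcentral (sensorimotor) strip:
#'   `"separate"` (default) keeps a dedicated central lobe;
#'   `"frontal-parietal"` folds precentral into frontal and postcentral
#'   into parietal.
#' @return A [region_atlas] with 210 regions, 105 per hemisphere.
#' @export
default_atlas <- function(central = c("separate", "frontal-parietal")) {
  central <- match.arg(central)
  pairs <- do.call(rbind, lapply(names(.default_gyri), function(lobe) {
    pool <- .default_gyri[[lobe]]
    do.call(rbind, lapply(names(pool), function(g) {
      data.frame(gyrus = g, k = seq_len(pool[[g]]), lobe = lobe,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (central == "frontal-parietal") {
    pairs$lobe[pairs$gyrus == "PrG"] <- "frontal"
    pairs$lobe[pairs$gyrus == "PoG"] <- "parietal"
  }
  n_pairs <- nrow(pairs)
  stopifnot(n_pairs == 105)
  regions <- data.frame(
    index = 0:(2 * n_pairs - 1),
    name = paste0(rep(pairs$gyrus, each = 2), "_",
                  rep(c("L", "R"), n_pairs), "_",
                  rep(pairs$k, each = 2)),
    hemisphere = rep(c("L", "R"), n_pairs),
    lobe = rep(pairs$lobe, each = 2),
    stringsAsFactors = FALSE
  )
  region_atlas(regions)
}

#' Classify edges by hemisphere and lobe pair
#'
#' @param atlas a [region_atlas].
#' @param edges data.frame with 0-based region index columns `i`, `j`.
#' @return The input with columns `hemisphere_class` (`intra-L`, `intra-R`,
#'   `inter`) and `lobe_pair` (alphabetically ordered, e.g.
#'   `"frontal-temporal"`) appended.
#' @export
classify_edges <- function(atlas, edges) {
  stopifnot(inherits(atlas, "region_atlas"))
  edges <- as.data.frame(edges)
  idx <- c(edges$i, edges$j)
  if (any(idx < 0 | idx >= atlas$n_regions | idx != round(idx))) {
    stop_input("edge endpoint out of range 0..%d", atlas$n_regions - 1)
  }
  hi <- atlas$regions$hemisphere[edges$i + 1]
  hj <- atlas$regions$hemisphere[edges$j + 1]
  edges$hemisphere_class <- ifelse(hi == hj,
                                   ifelse(hi == "L", "intra-L", "intra-R"),
                                   "inter")
  li <- atlas$regions$lobe[edges$i + 1]
  lj <- atlas$regions$lobe[edges$j + 1]
  edges$lobe_pair <- ifelse(li <= lj, paste(li, lj, sep = "-"),
                            paste(lj, li, sep = "-"))
  edges
}

#' Export an atlas as a BrainNet Viewer .node file
#'
#' Writes the six-column whitespace-delimited `.node` format
#' (x, y, z, color, size, label) with synthetic coordinates: regions are
#' laid out on two lateral grids, left hemisphere at negative x.
#'
#' @param atlas a [region_atlas].
#' @param path output path.
#' @param size per-region node size (recycled), e.g. degree.
#' @export
write_brainnet_node <- function(atlas, path, size = 1) {
  r <- atlas$regions
  size <- rep_len(size, nrow(r))
  per_h <- ave(seq_len(nrow(r)), r$hemisphere, FUN = seq_along) - 1
  ncol_grid <- ceiling(sqrt(max(per_h) + 1))
  x <- ifelse(r$hemisphere == "L", -40, 40)
  y <- (per_h %% ncol_grid) * 10 - 50
  z <- (per_h %/% ncol_grid) * 10 - 30
  color <- as.integer(factor(r$lobe, levels = ATLAS_LOBES))
  lines <- paste(x, y, z, color, fmt_num(size), r$name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
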