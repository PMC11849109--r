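# Venous drainage territories: composition and regional aggregation.

#' Compose a vein's total drainage territory
#'
#' Returns the parcellation labels of the vein's exclusive territory
#' together with those of its upstream veins (blood from upstream
#' territories flows through the downstream vein, so its oxygenation
#' samples the pooled territory): SS pools ICVs and BVs; SSS V pools
#' SSS H.  Veins without a composition rule return their exclusive labels.
#'
#' @param atlas A \code{\link{veinTerritoryAtlas}}.
#' @param vein Vein name known to the atlas.
#' @return Sorted integer vector of labels.
#' @export
composeTerritories <- function(atlas, vein) {
  if (!vein %in% veins(atlas)) stop("unknown vein: ", vein)
  members <- c(vein, atlas@upstream[[vein]])
  sort(unique(unlist(atlas@mapping[members])))
}

#' Pooled median of a map over a set of parcellation labels
#'
#' Median over all in-territory voxels pooled across the given labels
#' (not a mean of per-label medians), consistent with the
#' exclusive-territory statistic.
#'
#' @param map Numeric array of voxel values (may contain \code{NA}).
#' @param parcellation Integer label array, same shape.
#' @param labels Integer labels forming the territory.
#' @param combiner "pooled" (default) or "weighted": volume-weighted mean
#'   of per-label medians, available as the alternative combiner.
#' @return Scalar summary.
#' @export
aggregateTerritory <- function(map, parcellation, labels,
                               combiner = c("pooled", "weighted")) {
  combiner <- match.arg(combiner)
  if (!identical(dim(map), dim(parcellation)))
    stop("map and parcellation shapes do not agree")
  sel <- parcellation %in% labels
  if (combiner == "pooled") {
    v <- map[sel]
    v <- v[!is.na(v)]
    if (length(v) == 0)
      stop("empty region: no non-missing voxels in territory")
    return(stats::median(v))
  }
  meds <- ns <- numeric(0)
  for (lab in labels) {
    v <- map[parcellation == lab]
    v <- v[!is.na(v)]
    if (length(v)) {
      meds <- c(meds, stats::median(v))
      ns <- c(ns, length(v))
    }
  }
  if (length(meds) == 0)
    stop("empty region: no non-missing voxels in territory")
  sum(meds * ns) / sum(ns)
}

#' Read a vein-territory atlas from JSON
#'
#' Expects \code{{"mapping": {vein: [labels]}, "upstream": {vein: [veins]}}}.
#'
#' @param path JSON file path.
#' @return A \code{\link{veinTerritoryAtlas}}.
#' @export
readVeinAtlas <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  up <- if (is.null(x$upstream)) list() else as.list(x$upstream)
  up <- lapply(up, as.character)
  veinTerritoryAtlas(lapply(as.list(x$mapping), as.integer), upstream = up)
}

#' Write a vein-territory atlas to JSON
#'
#' @param atlas A \code{\link{veinTerritoryAtlas}}.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
writeVeinAtlas <- function(atlas, path) {
  jsonlite::write_json(list(mapping = atlas@mapping,
                            upstream = atlas@upstream),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Default vein-territory atlas
#'
#' The Destrieux-style label assignment shipped with the package
#' (\code{inst/extdata/vein_territory_atlas_synthetic.json}).  The
#' region-to-vein allocation in the source study was drawn from an
#' anatomical reference and published only pictorially, so this shipped
#' table is a synthetic approximation intended as an editable starting
#' point, not an anatomical ground truth.
#'
#' @return A \code{\link{veinTerritoryAtlas}}.
#' @export
defaultVeinAtlas <- function() {
  readVeinAtlas(system.file("extdata", "vein_territory_atlas_synthetic.json",
                            package = "oxflow", mustWork = TRUE))
}
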