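#' Per-region abnormality weights from a selected connection set
#'
#' The weight of a brain region is the number of selected connections
#' incident to it (its degree in the selected-connection graph); regions
#' touched by no selected connection have weight 0.  Summed over regions
#' the weights equal twice the number of selected connections.
#'
#' @param selected integer vector of connectivity feature indices (1-based,
#'   in the row-major pair convention of [vectorizeUpper()]).
#' @param n_regions region count R (default 90).
#' @param regions optional data.frame of region metadata with columns
#'   `index`, `abbreviation`, `full_name`, `hemisphere`; defaults to the
#'   packaged AAL-90 table when `n_regions` is 90, otherwise generic labels.
#' @return Object of class `regionWeightTable`: data.frame with one row per
#'   region (columns `index`, `abbreviation`, `full_name`, `hemisphere`,
#'   `weight`), in atlas order.
#' @export
computeRegionWeights <- function(selected, n_regions = 90L, regions = NULL) {
  n_regions <- as.integer(n_regions)
  P <- (n_regions * (n_regions - 1L)) %/% 2L
  selected <- as.integer(selected)
  if (length(selected) && (any(selected < 1L) || any(selected > P)))
    stop("selected feature indices must lie in 1..", P)
  if (is.null(regions)) {
    regions <- if (n_regions == 90L) aal90Regions()
               else data.frame(index = seq_len(n_regions),
                               abbreviation = paste0("R", seq_len(n_regions)),
                               full_name = paste0("Region ", seq_len(n_regions)),
                               hemisphere = NA_character_)
  }
  stopifnot(nrow(regions) == n_regions)
  w <- integer(n_regions)
  if (length(selected)) {
    pr <- pairOfIndex(selected, n_regions)
    w <- tabulate(c(pr[, "i"], pr[, "j"]), nbins = n_regions)
  }
  out <- cbind(regions, weight = w)
  structure(out, n_selected = length(selected),
            class = c("regionWeightTable", "data.frame"))
}

#' Regions at or above a weight cut-off
#'
#' @param table a [computeRegionWeights()] result.
#' @param min_weight smallest weight to keep (default 1).
#' @return data.frame of the qualifying regions sorted by weight descending,
#'   then abbreviation ascending.
#' @export
topRegions <- function(table, min_weight = 1L) {
  stopifnot(inherits(table, "regionWeightTable"))
  keep <- table[table$weight >= min_weight, , drop = FALSE]
  keep <- keep[order(-keep$weight, keep$abbreviation), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- "data.frame"   # a plain selection, not a full weight table
  attr(keep, "n_selected") <- NULL
  keep
}

#' @export
print.regionWeightTable <- function(x, max_weight_bands = 6L, ...) {
  cat("Region weights from", attr(x, "n_selected"), "selected connection(s)",
      "( sum of weights =", sum(x$weight), ")\n")
  nz <- topRegions(x, min_weight = 1L)
  if (nrow(nz) == 0L) { cat("  all weights zero\n"); return(invisible(x)) }
  bands <- sort(unique(nz$weight), decreasing = TRUE)
  for (b in utils::head(bands, max_weight_bands)) {
    cat(sprintf("  %d\t%s\n", b,
                paste(nz$abbreviation[nz$weight == b], collapse = " ")))
  }
  if (length(bands) > max_weight_bands) cat("  ...\n")
  invisible(x)
}

#' Export selected connections as a region-pair edge list
#'
#' @param selected integer vector of connectivity feature indices.
#' @param n_regions region count (default 90).
#' @param regions optional region metadata (see [computeRegionWeights()]).
#' @return data.frame with columns `feature`, `region_a`, `region_b`.
#' @export
connectionEdgeList <- function(selected, n_regions = 90L, regions = NULL) {
  if (is.null(regions)) {
    regions <- if (n_regions == 90L) aal90Regions()
               else data.frame(abbreviation = paste0("R", seq_len(n_regions)))
  }
  if (length(selected) == 0L)
    return(data.frame(feature = integer(), region_a = character(),
                      region_b = character()))
  pr <- pairOfIndex(as.integer(selected), n_regions)
  data.frame(feature = as.integer(selected),
             region_a = regions$abbreviation[pr[, "i"]],
             region_b = regions$abbreviation[pr[, "j"]])
}
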