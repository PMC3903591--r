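# Lumen segmentation: global two-class (Otsu) threshold, largest
# 6-connected component, morphological closing.

#' Segment the vascular lumen from an image stack
#'
#' Default method: global Otsu threshold on the intensity histogram,
#' morphological closing (6-neighborhood, \code{closeIter} rounds), then
#' selection of the largest 6-connected component. Fails explicitly when
#' the intensity histogram has no separable classes rather than returning
#' an empty mask.
#'
#' @param stack an \linkS4class{ImageStack} (speckle-filtered recommended).
#' @param method \code{"otsu"} (only supported method).
#' @param closeIter rounds of morphological closing (0 disables).
#' @param minSeparability bimodality guard: the histogram count at the
#'   Otsu threshold must fall below this fraction of the smaller class
#'   mode, otherwise the histogram is declared single-mode.
#' @return a \linkS4class{SegmentationMask}.
#' @export
segmentLumen <- function(stack, method = "otsu", closeIter = 1L,
                         minSeparability = 0.3) {
  method <- match.arg(method, "otsu")
  v <- stack@voxels
  rg <- range(v)
  if (diff(rg) < .Machine$double.eps)
    stop("single-mode histogram: stack is constant, no separable classes")
  vn <- (v - rg[1]) / diff(rg)
  thr <- EBImage::otsu(EBImage::Image(matrix(vn, ncol = 1)), range = c(0, 1),
                       levels = 256)
  cls <- vn > thr
  if (!any(cls) || all(cls))
    stop("single-mode histogram: threshold separates no classes")
  # bimodality guard: the Otsu threshold must sit in a genuine histogram
  # valley between the two class modes
  brk <- seq(0, 1, length.out = 65)
  cnt <- tabulate(pmin(findInterval(vn, brk, all.inside = TRUE), 64), 64)
  thrBin <- pmin(findInterval(thr, brk, all.inside = TRUE), 64)
  modeLow <- max(cnt[seq_len(max(thrBin - 1, 1))])
  modeHigh <- max(cnt[min(thrBin + 1, 64):64])
  valley <- min(cnt[pmax(thrBin - 1, 1):pmin(thrBin + 1, 64)])
  if (valley > minSeparability * min(modeLow, modeHigh))
    stop("single-mode histogram: no valley at the threshold (valley/mode ",
         sprintf("%.2f", valley / min(modeLow, modeHigh)), ")")
  m <- array(cls, dim(v))
  if (closeIter > 0) m <- close6(m, closeIter)
  lab <- label6(m)
  keep <- lab == 1L
  lab[!keep] <- 0L
  new("SegmentationMask", voxels = keep, spacing = stack@spacing,
      labels = lab)
}

#' Dice overlap between two masks
#'
#' @param a,b logical arrays (or \linkS4class{SegmentationMask}s) of equal
#'   dimension.
#' @return Dice coefficient 2|A and B| / (|A| + |B|).
#' @export
diceOverlap <- function(a, b) {
  if (is(a, "SegmentationMask")) a <- a@voxels
  if (is(b, "SegmentationMask")) b <- b@voxels
  2 * sum(a & b) / (sum(a) + sum(b))
}
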