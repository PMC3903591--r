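# Unwrapped wall maps: wall quantities over (arclength from root) x
# (circumferential angle), with masked holes at branch ostia.

#' Unwrap a wall shear field onto an (arclength, azimuth) map
#'
#' Bins wall samples onto a rectangular (arclength x azimuth) grid by
#' averaging, masks elliptical holes at branch ostium landmarks, and
#' records which anatomical direction azimuth 0 corresponds to.
#'
#' @param wall a \linkS4class{WallShearField}.
#' @param quantity \code{"tau"} or \code{"gamma"}.
#' @param landmarks optional data.frame with columns s_mm, theta_deg,
#'   radius_mm (hole half-width along arclength) and optionally
#'   thetaHalfWidth_deg (default 30) marking branch ostia.
#' @param orientation anatomical direction at azimuth 0 (recorded in the
#'   map; the right half of the map is the surface 90--270 degrees away).
#' @param nS,nTheta numbers of arclength/azimuth bins.
#' @return an \linkS4class{UnwrappedMap} (NA where a hole is masked or no
#'   sample falls in a bin).
#' @export
unwrapMap <- function(wall, quantity = c("tau", "gamma"), landmarks = NULL,
                      orientation = "superior", nS = 40L, nTheta = 24L) {
  quantity <- match.arg(quantity)
  val <- if (quantity == "tau") wall@tau else wall@gamma
  sRange <- range(wall@s)
  sEdges <- seq(sRange[1], sRange[2], length.out = nS + 1)
  tEdges <- seq(0, 360, length.out = nTheta + 1)
  sBin <- pmin(pmax(findInterval(wall@s, sEdges, all.inside = TRUE), 1), nS)
  # azimuth bins with a tolerance so samples computed from radians land in
  # the bin whose edge they nominally sit on
  tw <- 360 / nTheta
  tBin <- pmin(floor(((wall@theta %% 360) + 1e-6 * tw) / tw) + 1L, nTheta)
  acc <- matrix(0, nS, nTheta); cnt <- matrix(0, nS, nTheta)
  for (i in seq_along(val)) {
    acc[sBin[i], tBin[i]] <- acc[sBin[i], tBin[i]] + val[i]
    cnt[sBin[i], tBin[i]] <- cnt[sBin[i], tBin[i]] + 1
  }
  vals <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  sc <- (sEdges[-1] + sEdges[-(nS + 1)]) / 2
  tc <- (tEdges[-1] + tEdges[-(nTheta + 1)]) / 2
  holes <- matrix(FALSE, nS, nTheta)
  if (!is.null(landmarks) && nrow(landmarks)) {
    for (li in seq_len(nrow(landmarks))) {
      s0 <- landmarks$s_mm[li]; t0 <- landmarks$theta_deg[li]
      rs <- landmarks$radius_mm[li]
      tw <- if ("thetaHalfWidth_deg" %in% names(landmarks))
        landmarks$thetaHalfWidth_deg[li] else 30
      dS <- outer((sc - s0) / rs, rep(1, nTheta))
      dT <- outer(rep(1, nS),
                  (abs((tc - t0 + 180) %% 360 - 180)) / tw)
      holes <- holes | (dS^2 + dT^2 <= 1)
    }
    vals[holes] <- NA_real_
  }
  new("UnwrappedMap", values = vals, s = sc, theta = tc, holes = holes,
      orientationKey = orientation)
}

#' Count distinct holes in an unwrapped map
#'
#' @param map an \linkS4class{UnwrappedMap}.
#' @return number of connected masked regions (azimuth-periodic
#'   4-connectivity).
#' @export
mapHoleCount <- function(map) {
  hm <- map@holes
  if (!any(hm)) return(0L)
  nS <- nrow(hm); nT <- ncol(hm)
  idx <- which(hm)
  id <- matrix(0L, nS, nT); id[idx] <- seq_along(idx)
  pos <- arrayInd(idx, c(nS, nT))
  edges <- list()
  ok <- pos[, 1] < nS
  nb <- id[cbind(pos[ok, 1] + 1L, pos[ok, 2])]
  sel <- nb > 0L
  edges[[1]] <- cbind(which(ok)[sel], nb[sel])
  k2 <- ifelse(pos[, 2] == nT, 1L, pos[, 2] + 1L)
  nb <- id[cbind(pos[, 1], k2)]
  sel <- nb > 0L
  edges[[2]] <- cbind(which(sel), nb[sel])
  el <- do.call(rbind, edges)
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$no
}
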