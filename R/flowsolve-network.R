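# Reduced-order steady flow: Poiseuille relations on the tree with
# Murray's-law flow assignment. Valid in the viscous-dominated low-Reynolds
# regime of the fetal great arteries.

# Flow routing for the great-artery topology: terminal outlet flows come
# from the boundary set; internal segment flows follow junction mass
# balance.
.routeFlows <- function(tree, bc) {
  q <- stats::setNames(bc@outlets$flow_mm3_s, bc@outlets$role)
  qin <- stats::setNames(bc@inlets$flow_mm3_s, bc@inlets$role)
  segs <- names(tree@segments)
  flow <- stats::setNames(numeric(length(segs)), segs)
  for (r in names(q)) if (r %in% segs) flow[r] <- q[[r]]
  heads <- intersect(c("innominate", "left_common_carotid",
                       "left_subclavian"), segs)
  pas <- intersect(c("left_pulmonary_artery", "right_pulmonary_artery"), segs)
  if ("ascending_aorta" %in% segs) flow["ascending_aorta"] <- qin[["ascending_aorta"]]
  if ("arch" %in% segs)
    flow["arch"] <- qin[["ascending_aorta"]] - sum(q[heads])
  if ("pulmonary_trunk" %in% segs) flow["pulmonary_trunk"] <- qin[["pulmonary_trunk"]]
  if ("ductus" %in% segs)
    flow["ductus"] <- qin[["pulmonary_trunk"]] - sum(q[pas])
  if (any(flow <= 0))
    stop("flow-assignment inconsistency: non-positive flow in segment(s) ",
         paste(segs[flow <= 0], collapse = ", "))
  # junction mass balance at the ductus insertion
  if (all(c("arch", "ductus", "descending_aorta") %in% segs)) {
    imbalance <- abs(flow[["arch"]] + flow[["ductus"]] -
                       flow[["descending_aorta"]])
    if (imbalance > 1e-9 * flow[["descending_aorta"]])
      stop("flow-assignment inconsistency at the ductus insertion (",
           imbalance, " mm3/s)")
  }
  flow
}

#' Reduced-order Poiseuille network solution
#'
#' Assigns each segment its Murray's-law flow (terminal outlets from the
#' boundary set, internal segments by junction mass balance) and evaluates
#' the Poiseuille relations per segment: pressure drop
#' \eqn{\Delta p = 8 \mu L Q/(\pi R^4)}, wall shear stress
#' \eqn{\tau = 4 \mu Q/(\pi R^3)}, peak (centerline) velocity
#' \eqn{V_{max} = 2Q/(\pi R^2)}.
#'
#' @param tree a \linkS4class{VesselTree} (loop-free, radii assigned), or a
#'   plain data.frame with columns role, radius_mm, length_mm, flow_mm3_s
#'   for ad-hoc networks.
#' @param bc a \linkS4class{FlowBoundarySet} for the tree.
#' @param props a \linkS4class{BloodProperties}.
#' @return data.frame with one row per segment: role, length_mm, radius_mm
#'   (flow-weighted representative = mean along segment), flow_mm3_s,
#'   dp_mPa, tau_mPa, gamma_per_s, vmax_mm_s, vmean_mm_s, Re.
#' @export
solvePoiseuilleNetwork <- function(tree, bc, props) {
  mu <- props@mu; nu <- props@nu
  if (is.data.frame(tree)) {
    df <- tree
    flow <- stats::setNames(df$flow_mm3_s, df$role)
    rad <- stats::setNames(df$radius_mm, df$role)
    len <- stats::setNames(df$length_mm, df$role)
  } else {
    flow <- .routeFlows(tree, bc)
    rad <- vapply(tree@segments, function(s) mean(s$radius), numeric(1))
    len <- vapply(tree@segments, function(s) max(segArclength(s)), numeric(1))
  }
  roles <- names(flow)
  Q <- unname(flow[roles]); R <- unname(rad[roles]); L <- unname(len[roles])
  tau <- 4 * mu * Q / (pi * R^3)
  data.frame(role = roles, length_mm = L, radius_mm = R, flow_mm3_s = Q,
             dp_mPa = 8 * mu * L * Q / (pi * R^4),
             tau_mPa = tau, gamma_per_s = tau / mu,
             vmax_mm_s = 2 * Q / (pi * R^2),
             vmean_mm_s = Q / (pi * R^2),
             Re = (2 * Q / (pi * R^2)) * R / nu,
             stringsAsFactors = FALSE)
}

#' Per-station hemodynamics along the tree (reduced order)
#'
#' Expands the network solution to centerline stations: each segment's flow
#' with the local radius profile gives per-station centerline velocity,
#' wall shear and Reynolds/Womersley numbers.
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param bc a \linkS4class{FlowBoundarySet}.
#' @param props a \linkS4class{BloodProperties}.
#' @param config a \linkS4class{StageConfig} (supplies the heart-rate
#'   angular frequency for the Womersley number).
#' @return data.frame with one row per centerline station: role, s_mm,
#'   radius_mm, area_mm2, Vc_mm_s, tau_mPa, gamma_per_s, Re, alpha.
#' @export
networkStations <- function(tree, bc, props, config) {
  flow <- .routeFlows(tree, bc)
  mu <- props@mu; nu <- props@nu; omega <- config@omega
  out <- list()
  for (role in names(tree@segments)) {
    s <- tree@segments[[role]]
    sl <- segArclength(s)
    r <- s$radius
    Q <- flow[[role]]
    vc <- 2 * Q / (pi * r^2)
    tau <- 4 * mu * Q / (pi * r^3)
    out[[role]] <- data.frame(
      role = role, s_mm = sl, radius_mm = r, area_mm2 = pi * r^2,
      Vc_mm_s = vc, tau_mPa = tau, gamma_per_s = tau / mu,
      Re = vc * r / nu, alpha = r * sqrt(omega / nu),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
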