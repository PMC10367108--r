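#' Per-element activation times
#'
#' Mean of the nodal activation times of each tetrahedron; `NA` when any
#' vertex is unreached.
#' @keywords internal
element_times <- function(activation, mesh) {
  (activation[mesh$tets[, 1]] + activation[mesh$tets[, 2]] +
     activation[mesh$tets[, 3]] + activation[mesh$tets[, 4]]) / 4
}

#' Total activation time of a tissue-volume percentile
#'
#' The smallest time by which at least `p` percent of the non-scar
#' myocardial tissue volume has been activated (volume-weighted percentile
#' of element activation times). `TAT95` is `p = 95`; `p = 100` gives the
#' total activation time.
#'
#' @param activation an `activation_map`.
#' @param mesh a `biv_mesh`.
#' @param labels optional `tissue_labels` (scar excluded).
#' @param p percentile in (0, 100].
#' @return time in ms.
#' @export
tat_percentile <- function(activation, mesh, labels = NULL, p = 95) {
  if (p <= 0 || p > 100) stop("p must lie in (0, 100]", call. = FALSE)
  et <- element_times(activation, mesh)
  keep <- if (is.null(labels)) rep(TRUE, length(et)) else labels != "scar"
  if (all(is.na(et[keep]))) stop("all elements unreached", call. = FALSE)
  v <- mesh$volumes[keep]
  t <- et[keep]
  tot <- sum(v)
  o <- order(t, na.last = TRUE)
  cum <- cumsum(v[o]) / tot
  idx <- which(cum >= p / 100 - 1e-12)[1]
  t[o][idx]
}

#' Inter-ventricular activation delay
#'
#' Difference between the LV free-wall and RV free-wall total activation
#' times (maximum element activation time per ventricle, non-scar elements),
#' positive when the LV finishes later.
#'
#' @inheritParams tat_percentile
#' @return delay in ms.
#' @export
ad_rvlv <- function(activation, mesh, labels = NULL) {
  et <- element_times(activation, mesh)
  keep <- if (is.null(labels)) rep(TRUE, length(et)) else labels != "scar"
  lv <- et[keep & mesh$ventricle == "lv"]
  rv <- et[keep & mesh$ventricle == "rv"]
  if (all(is.na(lv)) || all(is.na(rv))) {
    stop("a ventricle is entirely unreached", call. = FALSE)
  }
  max(lv, na.rm = TRUE) - max(rv, na.rm = TRUE)
}

#' Intra-ventricular (septum-to-lateral) dyssynchrony index
#'
#' Relative difference between the volume-weighted mean activation time of
#' the LV free wall and of the septum, normalized by the total activation
#' time: `(mean AT_LVlat - mean AT_ST) / TAT`. Bounded in \[-1, 1\].
#'
#' @inheritParams tat_percentile
#' @return dimensionless index.
#' @export
ad_stlv <- function(activation, mesh, labels = NULL) {
  et <- element_times(activation, mesh)
  keep <- if (is.null(labels)) rep(TRUE, length(et)) else labels != "scar"
  wmean <- function(sel) {
    sel <- sel & !is.na(et)
    if (!any(sel)) stop("region entirely unreached", call. = FALSE)
    sum(et[sel] * mesh$volumes[sel]) / sum(mesh$volumes[sel])
  }
  lat <- wmean(keep & mesh$ventricle == "lv")
  sept <- wmean(keep & mesh$ventricle == "septum")
  tat <- max(et[keep], na.rm = TRUE)
  (lat - sept) / tat
}

#' Late-activation region on the LV epicardium
#'
#' LV epicardial nodes whose baseline (LBBB) activation time lies at or above
#' the `1 - fraction` quantile of LV epicardial times: the LAT area used to
#' define the latest-activation pacing strategy and the LAT-LVPS distance.
#'
#' @param lbbb_map baseline `activation_map`.
#' @param mesh a `biv_mesh`.
#' @param fraction fraction of the LV epicardium included (default 0.10).
#' @return integer vector of node indices.
#' @export
lat_region <- function(lbbb_map, mesh, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]", call. = FALSE)
  nodes <- mesh$surfaces$lv_epi
  t <- as.numeric(lbbb_map[nodes])
  if (all(is.na(t))) stop("LBBB map unreached on the LV epicardium", call. = FALSE)
  thr <- quantile(t, probs = 1 - fraction, na.rm = TRUE, names = FALSE)
  nodes[!is.na(t) & t >= thr]
}

#' Baseline delay between the two electrode positions
#'
#' Activation time of the LV pacing site minus that of the RV pacing site in
#' the baseline LBBB map (the RV-LV delay).
#'
#' @param lbbb_map baseline `activation_map`.
#' @param mesh a `biv_mesh`.
#' @param rv_site,lv_site electrode coordinates (mm) or node indices.
#' @return delay in ms.
#' @export
rv_lv_delay <- function(lbbb_map, mesh, rv_site, lv_site) {
  rv_node <- if (length(rv_site) == 1) as.integer(rv_site)
             else nearest_node(mesh, rv_site, subset = mesh$surfaces$rv_endo)
  lv_node <- if (length(lv_site) == 1) as.integer(lv_site)
             else nearest_node(mesh, lv_site, subset = mesh$surfaces$lv_epi)
  t_rv <- as.numeric(lbbb_map[rv_node]); t_lv <- as.numeric(lbbb_map[lv_node])
  if (is.na(t_rv) || is.na(t_lv)) stop("electrode site unreached", call. = FALSE)
  t_lv - t_rv
}

#' Extract the full simulated feature set for one pacing configuration
#'
#' Computes every model-derived dyssynchrony index from the baseline LBBB and
#' paced BiV activation maps and ECGs: per-protocol TAT95/TAT/QRSd/AD_RVLV/
#' AD_STLV, the pacing-site distances (to scar, to the late-activation area,
#' between electrodes), the baseline RV-LV delay, and the paced-minus-
#' baseline deltas (absolute and normalized to baseline). The scar distance
#' is `NA` (flagged missing) when the model has no scar; it is imputed
#' downstream, never silently zeroed.
#'
#' @param lbbb_map,biv_map activation maps of the two protocols.
#' @param lbbb_ecg,biv_ecg matching `crt_ecg` objects.
#' @param mesh,labels,parcellation patient anatomy.
#' @param rv_site,lv_site electrode coordinates (mm).
#' @param lat_fraction LV-epicardium fraction defining the LAT area.
#' @return one-row tibble of class `sim_features`.
#' @export
extract_features <- function(lbbb_map, biv_map, lbbb_ecg, biv_ecg, mesh,
                             labels, parcellation, rv_site, lv_site,
                             lat_fraction = 0.10) {
  per_protocol <- function(map, ecg) {
    tibble::tibble(
      tat95 = tat_percentile(map, mesh, labels, 95),
      tat = tat_percentile(map, mesh, labels, 100),
      qrsd = detect_qrs(ecg)$qrsd,
      ad_rvlv = ad_rvlv(map, mesh, labels),
      ad_stlv = ad_stlv(map, mesh, labels)
    )
  }
  lb <- per_protocol(lbbb_map, lbbb_ecg)
  bv <- per_protocol(biv_map, biv_ecg)

  lv_node <- nearest_node(mesh, lv_site, subset = mesh$surfaces$lv_epi)
  rv_node <- nearest_node(mesh, rv_site, subset = mesh$surfaces$rv_endo)
  scar_nodes <- unique(as.vector(mesh$tets[labels == "scar", , drop = FALSE]))
  scar_lvps <- if (length(scar_nodes)) {
    geodesic_distance(mesh, lv_node, scar_nodes)
  } else NA_real_
  lat_lvps <- geodesic_distance(mesh, lv_node,
                                lat_region(lbbb_map, mesh, lat_fraction))
  rvlv_dist <- geodesic_distance(mesh, lv_node, rv_node)
  delay <- rv_lv_delay(lbbb_map, mesh, rv_node, lv_node)

  base <- setNames(as.numeric(lb), paste0(names(lb), "_lbbb"))
  paced <- setNames(as.numeric(bv), paste0(names(bv), "_biv"))
  dl <- as.numeric(bv) - as.numeric(lb)
  names(dl) <- paste0("delta_", names(lb))
  dn <- dl / as.numeric(lb)
  names(dn) <- paste0("delta_", names(lb), "_norm")

  out <- tibble::as_tibble(c(as.list(base), as.list(paced),
                             list(scar_lvps = scar_lvps, lat_lvps = lat_lvps,
                                  rvlv_dist = rvlv_dist, rvlv_delay = delay),
                             as.list(dl), as.list(dn)))
  class(out) <- c("sim_features", class(out))
  out
}
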