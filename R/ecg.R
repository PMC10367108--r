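#' Template action potential waveform
#'
#' A fixed transmembrane action-potential template assigned to every element
#' at its local activation time: resting potential, a monotone 1 ms upstroke,
#' a plateau and a smooth repolarization. Only the depolarization upstroke
#' shapes the QRS complex, which is the quantity fitted downstream.
#'
#' @param dt sampling step (ms).
#' @param rest resting potential (mV).
#' @param peak peak potential (mV).
#' @param upstroke_ms upstroke duration (ms, <= 2).
#' @param apd action-potential duration to end of plateau (ms).
#' @param repol_ms repolarization tail duration (ms).
#' @return object of class `ap_template`: `v` (sampled waveform, mV), `t`
#'   (ms), `dt`, `upstroke_index`, `duration`, and `fun`, a vectorized
#'   evaluator returning the membrane voltage at any time offset.
#' @export
ap_template <- function(dt = 1, rest = -85, peak = 25, upstroke_ms = 1,
                        apd = 250, repol_ms = 100) {
  stopifnot(dt > 0, upstroke_ms > 0, upstroke_ms <= 2)
  dur <- apd + repol_ms
  fun <- function(t) {
    v <- rep(rest, length(t))
    up <- t >= 0 & t < upstroke_ms
    v[up] <- rest + (peak - rest) * t[up] / upstroke_ms
    plat <- t >= upstroke_ms & t < apd
    v[plat] <- peak
    rep_ <- t >= apd & t < dur
    v[rep_] <- rest + (peak - rest) * 0.5 * (1 + cos(pi * (t[rep_] - apd) / repol_ms))
    v
  }
  tt <- seq(0, dur, by = dt)
  structure(list(v = fun(tt), t = tt, dt = dt,
                 upstroke_index = 1L + as.integer(ceiling(upstroke_ms / dt)),
                 duration = dur, rest = rest, fun = fun),
            class = "ap_template")
}

#' Standard body-surface electrode positions
#'
#' Places the nine measurement electrodes (RA, LA, LL, V1-V6) on a parametric
#' torso shell around the heart, oriented by the mesh reference frame: the
#' long axis points from apex to base (superior), the lateral LV wall faces
#' the patient's left and the chest lies on the anterior side. All electrodes
#' are far outside the myocardium.
#'
#' @param mesh a `biv_mesh`.
#' @param torso_scale overall scale of the shell (1 = default adult torso).
#' @return 9 x 3 matrix of coordinates (mm) with rownames
#'   `RA, LA, LL, V1..V6`, class `electrode_set`.
#' @export
standard_electrodes <- function(mesh, torso_scale = 1) {
  ctr <- colMeans(mesh$nodes)
  up <- mesh$long_axis / sqrt(sum(mesh$long_axis^2))
  left <- -mesh$septal_axis
  left <- left - sum(left * up) * up
  left <- left / sqrt(sum(left^2))
  ant <- c(up[2] * left[3] - up[3] * left[2],
           up[3] * left[1] - up[1] * left[3],
           up[1] * left[2] - up[2] * left[1])
  local <- rbind(
    RA = c(-180, 20, 250), LA = c(180, 20, 250), LL = c(80, 0, -450),
    V1 = c(-35, 110, 30), V2 = c(5, 115, 30), V3 = c(40, 110, 10),
    V4 = c(75, 95, -5), V5 = c(105, 65, -10), V6 = c(130, 25, -10)
  ) * torso_scale
  pos <- t(apply(local, 1, function(p) ctr + p[1] * left + p[2] * ant + p[3] * up))
  structure(pos, class = c("electrode_set", "matrix"))
}

#' Lead-field matrix for the pseudo-ECG forward model
#'
#' Precomputes the linear map from nodal transmembrane voltages to electrode
#' potentials under the infinite-homogeneous-medium pseudo-ECG model: each
#' element contributes its volume times the dot product of the transmembrane
#' voltage gradient with the gradient of 1/r to the electrode. Scar elements
#' contribute nothing.
#'
#' @param mesh a `biv_mesh`.
#' @param electrodes an `electrode_set`.
#' @param labels optional `tissue_labels`.
#' @return electrodes x nodes matrix.
#' @export
lead_field <- function(mesh, electrodes, labels = NULL) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  if (is.null(labels)) labels <- rep("healthy", m)
  L <- matrix(0, nrow = nrow(electrodes), ncol = n)
  cent <- elem_centroids(mesh)
  for (e in seq_len(m)) {
    if (labels[e] == "scar") next
    idx <- mesh$tets[e, ]
    x1 <- mesh$nodes[idx[1], ]
    M <- rbind(mesh$nodes[idx[2], ] - x1,
               mesh$nodes[idx[3], ] - x1,
               mesh$nodes[idx[4], ] - x1)
    Minv <- tryCatch(solve(M), error = function(err) NULL)
    if (is.null(Minv)) next
    B <- cbind(-rowSums(Minv), Minv)          # 3 x 4: nodal V -> grad V
    r <- electrodes - matrix(cent[e, ], nrow(electrodes), 3, byrow = TRUE)
    rn <- sqrt(rowSums(r^2))
    gl <- r / rn^3                            # grad_source (1/r)
    L[, idx] <- L[, idx] + mesh$volumes[e] * (gl %*% B)
  }
  L
}

#' Synthesize a 12-lead ECG from an activation map
#'
#' Every element depolarizes along the action-potential template shifted by
#' its local activation time; electrode potentials follow the
#' infinite-homogeneous-medium pseudo-ECG sum; limb, augmented and precordial
#' leads are formed by the standard 12-lead definitions (precordials against
#' the Wilson central terminal). Unreached nodes stay at rest.
#'
#' @param mesh a `biv_mesh`.
#' @param activation an `activation_map`.
#' @param electrodes an `electrode_set`; default [standard_electrodes()].
#' @param template an `ap_template`; default [ap_template()].
#' @param dt sampling step (ms).
#' @param labels optional `tissue_labels`.
#' @param L optional precomputed [lead_field()] (reused across repeated
#'   calls on the same mesh).
#' @return tibble of class `crt_ecg`: `time` (ms) plus the 12 lead columns
#'   `I, II, III, aVR, aVL, aVF, V1..V6` (arbitrary consistent units).
#' @export
compute_ecg <- function(mesh, activation, electrodes = standard_electrodes(mesh),
                        template = ap_template(dt), dt = 1, labels = NULL,
                        L = NULL) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  act <- as.numeric(activation)
  if (all(is.na(act))) stop("all nodes unreached", call. = FALSE)
  if (is.null(L)) L <- lead_field(mesh, electrodes, labels)
  tmax <- max(act, na.rm = TRUE) + 2 * template$dt + 10
  ts <- seq(0, tmax, by = dt)
  shifted <- outer(act, ts, function(a, t) t - a)   # n_nodes x n_t
  Vm <- matrix(template$rest, nrow = length(act), ncol = length(ts))
  ok <- !is.na(act)
  Vm[ok, ] <- template$fun(shifted[ok, , drop = FALSE])
  U <- L %*% Vm                                      # 9 x n_t
  ra <- U[1, ]; la <- U[2, ]; ll <- U[3, ]
  wct <- (ra + la + ll) / 3
  out <- tibble::tibble(
    time = ts,
    I = la - ra, II = ll - ra, III = ll - la,
    aVR = ra - (la + ll) / 2, aVL = la - (ra + ll) / 2, aVF = ll - (ra + la) / 2,
    V1 = U[4, ] - wct, V2 = U[5, ] - wct, V3 = U[6, ] - wct,
    V4 = U[7, ] - wct, V5 = U[8, ] - wct, V6 = U[9, ] - wct
  )
  class(out) <- c("crt_ecg", class(out))
  attr(out, "dt") <- dt
  out
}

#' Detect the QRS window on a 12-lead ECG
#'
#' Onset and offset are the first and last times at which the
#' root-mean-square across-lead derivative exceeds a relative threshold
#' (default 2% of its global maximum); above-threshold runs separated by less
#' than the debounce interval are merged, so the window covers the QRS
#' complex across all leads.
#'
#' @param ecg a `crt_ecg`.
#' @param threshold relative threshold on the RMS derivative.
#' @param debounce merge gap (ms).
#' @return list of class `qrs_window` with `onset`, `offset`, `qrsd` (ms).
#' @export
detect_qrs <- function(ecg, threshold = 0.02, debounce = 5) {
  dt <- attr(ecg, "dt")
  if (is.null(dt)) dt <- diff(ecg$time[1:2])
  leads <- as.matrix(ecg[, setdiff(names(ecg), "time")])
  d <- diff(leads) / dt
  rms <- sqrt(rowMeans(d^2))
  mx <- max(rms)
  if (!is.finite(mx) || mx <= 0) stop("no QRS detected (flat signal)", call. = FALSE)
  above <- rms > threshold * mx
  idx <- which(above)
  # merge runs separated by less than the debounce interval
  runs <- split(idx, cumsum(c(1, diff(idx) * dt > debounce)))
  lens <- vapply(runs, function(r) (length(r) - 1) * dt, numeric(1))
  keep <- runs[lens >= 0]
  first <- min(vapply(keep, min, numeric(1)))
  last <- max(vapply(keep, max, numeric(1)))
  onset <- ecg$time[first]
  offset <- ecg$time[last + 1L]
  structure(list(onset = onset, offset = offset, qrsd = offset - onset),
            class = "qrs_window")
}

#' @export
print.qrs_window <- function(x, ...) {
  cat(sprintf("<qrs_window> onset %.1f ms, offset %.1f ms, QRSd %.1f ms\n",
              x$onset, x$offset, x$qrsd))
  invisible(x)
}

#' Fit the global conductivity multiplier to a target QRS duration
#'
#' Personalizes the dimensionless conductivity multiplier `kappa` so that the
#' simulated QRS duration matches a clinically recorded target, using bounded
#' scalar root bracketing that exploits the monotone decrease of QRSd in
#' `kappa`. If the target is unattainable inside the bounds the nearest bound
#' is returned with `boundary = TRUE`.
#'
#' @param mesh,fibers,labels model geometry, fibers and tissue labels.
#' @param protocol either `list(type = "lbbb", tree = <purkinje_tree>)` or
#'   `list(type = "biv", rv_site =, lv_site =)`.
#' @param target_qrsd target QRS duration (ms).
#' @param conduction baseline [conduction_model()]; its `kappa_bounds` are
#'   the search range.
#' @param tol_ms acceptable |QRSd - target| (ms).
#' @param dt ECG sampling step (ms).
#' @return list of class `kappa_fit`: `kappa`, `qrsd`, `boundary`, `trace`.
#' @export
fit_conductivity <- function(mesh, fibers, labels, protocol, target_qrsd,
                             conduction = conduction_model(), tol_ms = 2,
                             dt = 1) {
  if (target_qrsd <= 0) stop("target_qrsd must be positive", call. = FALSE)
  bounds <- conduction$kappa_bounds
  electrodes <- standard_electrodes(mesh)
  L <- lead_field(mesh, electrodes, labels)
  tpl <- ap_template(dt)
  trace <- list()
  qrsd_at <- function(kappa) {
    cm <- conduction_model(v_f = conduction$v_f, anisotropy = conduction$anisotropy,
                           kappa = kappa, kappa_bounds = bounds,
                           fibrosis_factor = conduction$fibrosis_factor,
                           velocity_mapping = conduction$velocity_mapping)
    act <- if (protocol$type == "lbbb") {
      simulate_lbbb(mesh, fibers, cm, protocol$tree, labels)
    } else {
      simulate_biv(mesh, fibers, cm, protocol$rv_site, protocol$lv_site,
                   labels = labels)
    }
    q <- detect_qrs(compute_ecg(mesh, act, electrodes, tpl, dt, labels, L = L))$qrsd
    trace[[length(trace) + 1L]] <<- c(kappa = kappa, qrsd = q)
    q
  }
  lo <- bounds[1]; hi <- bounds[2]
  q_lo <- qrsd_at(lo); q_hi <- qrsd_at(hi)
  finish <- function(kappa, qrsd, boundary) {
    structure(list(kappa = kappa, qrsd = qrsd, boundary = boundary,
                   target = target_qrsd,
                   trace = do.call(rbind, trace)), class = "kappa_fit")
  }
  if (target_qrsd >= q_lo) {          # even the slowest tissue is too fast
    return(finish(lo, q_lo, abs(q_lo - target_qrsd) > tol_ms))
  }
  if (target_qrsd <= q_hi) {          # unattainably short QRS
    return(finish(hi, q_hi, abs(q_hi - target_qrsd) > tol_ms))
  }
  best <- NULL
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    q_mid <- qrsd_at(mid)
    if (is.null(best) || abs(q_mid - target_qrsd) < abs(best[2] - target_qrsd)) {
      best <- c(mid, q_mid)
    }
    if (q_mid > target_qrsd) lo <- mid else hi <- mid
    if ((abs(best[2] - target_qrsd) <= tol_ms && hi - lo < 0.02) ||
        hi - lo < 1e-4) break
  }
  finish(best[1], best[2], abs(best[2] - target_qrsd) > tol_ms)
}

#' @export
print.kappa_fit <- function(x, ...) {
  cat(sprintf("<kappa_fit> kappa = %.3f, QRSd = %.1f ms (target %.1f)%s\n",
              x$kappa, x$qrsd, x$target,
              if (x$boundary) " [boundary hit]" else ""))
  invisible(x)
}
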