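#' Candidate LV epicardial pacing surface
#'
#' The set of LV epicardial nodes eligible for LV lead placement: septal
#' segments (not reachable by transvenous or epicardial access) and
#' scar-labeled tissue (pacing there is ineffective) are excluded.
#'
#' @param mesh a `biv_mesh`.
#' @param parcellation an `aha_parcellation`.
#' @param labels a `tissue_labels` vector.
#' @return tibble of class `candidate_surface`: `node`, `x`, `y`, `z`,
#'   `segment`.
#' @export
candidate_surface <- function(mesh, parcellation, labels) {
  nodes <- mesh$surfaces$lv_epi
  seg <- parcellation$node_segment[nodes]
  keep <- !is.na(seg) & !(seg %in% parcellation$septal_segments)
  scar_nodes <- unique(as.vector(mesh$tets[labels == "scar", , drop = FALSE]))
  keep <- keep & !(nodes %in% scar_nodes)
  if (!any(keep)) stop("no eligible pacing surface", call. = FALSE)
  out <- tibble::tibble(node = nodes[keep],
                        x = mesh$nodes[nodes[keep], 1],
                        y = mesh$nodes[nodes[keep], 2],
                        z = mesh$nodes[nodes[keep], 3],
                        segment = seg[keep])
  class(out) <- c("candidate_surface", class(out))
  out
}

#' Initial pacing-site design at AHA segment centers
#'
#' One site per eligible AHA segment: the candidate node nearest the
#' segment's epicardial centroid. A scar-free model yields 12 sites (17
#' segments minus the 5 septal ones); scarred segments drop out.
#'
#' @param surface a `candidate_surface`.
#' @param parcellation the `aha_parcellation` providing segment centroids.
#' @return tibble with `segment`, `node`, `x`, `y`, `z`.
#' @export
initial_design <- function(surface, parcellation) {
  segs <- sort(unique(surface$segment))
  rows <- lapply(segs, function(s) {
    ctr <- parcellation$centroids[s, ]
    cand <- surface[surface$segment == s, ]
    d2 <- (cand$x - ctr[1])^2 + (cand$y - ctr[2])^2 + (cand$z - ctr[3])^2
    cand[which.min(d2), c("segment", "node", "x", "y", "z")]
  })
  dplyr::bind_rows(rows)
}

run_bo <- function(surface, design, evaluator, max_iter, minimize,
                   acq_beta = 2, convergence_tol = 0) {
  Xc <- as.matrix(surface[, c("x", "y", "z")])
  eval_site <- function(node, coords, ys) {
    val <- tryCatch(evaluator(node, coords), error = function(e) {
      message("evaluator failed at node ", node, " (", conditionMessage(e),
              "); penalty score assigned")
      if (minimize) max(c(ys, 0)) + 100 else 0
    })
    as.numeric(val)
  }
  trace <- design[, c("node", "x", "y", "z")]
  trace$score <- NA_real_
  trace$stage <- "design"
  for (i in seq_len(nrow(trace))) {
    trace$score[i] <- eval_site(trace$node[i],
                                c(trace$x[i], trace$y[i], trace$z[i]),
                                trace$score[seq_len(i - 1)])
  }
  converged <- FALSE
  prev_pick <- NA_integer_
  gp <- NULL
  for (it in seq_len(max_iter)) {
    gp <- gp_fit(as.matrix(trace[, c("x", "y", "z")]), trace$score)
    acq <- acquisition(gp, Xc, minimize = minimize, beta = acq_beta)
    pick <- if (minimize) which.min(acq) else which.max(acq)  # ties: lowest index
    node <- surface$node[pick]
    best_so_far <- if (minimize) min(trace$score) else max(trace$score)
    no_gain <- if (minimize) acq[pick] >= best_so_far - 1e-6
               else acq[pick] <= best_so_far + 1e-6
    if (no_gain) { converged <- TRUE; break }
    if (!is.na(prev_pick)) {
      same <- node == prev_pick ||
        (convergence_tol > 0 &&
           sqrt(sum((Xc[pick, ] - Xc[surface$node == prev_pick, , drop = FALSE][1, ])^2)) < convergence_tol)
      if (same) { converged <- TRUE; break }
    }
    sc <- eval_site(node, Xc[pick, ], trace$score)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      node = node, x = Xc[pick, 1], y = Xc[pick, 2], z = Xc[pick, 3],
      score = sc, stage = "bo"
    ))
    prev_pick <- node
  }
  best_i <- if (minimize) which.min(trace$score) else which.max(trace$score)
  post <- gp_predict(gp, Xc)
  list(trace = trace, best_i = best_i, converged = converged,
       surface = surface, posterior = post, gp = gp)
}

#' Bayesian optimization of the LV pacing site by ML-score
#'
#' Evaluates the segment-center initial design, then iterates: fit the GP
#' surrogate to all evaluated (site, ML-score) pairs, pick the candidate node
#' maximizing the acquisition `mu + 2 sigma`, evaluate it, and repeat. The
#' search stops when two consecutive iterations pick the same node or when no
#' candidate's acquisition exceeds the best observed score (no predicted
#' improvement left; both declared converged), or at `max_iter`. Each iteration costs exactly one expensive
#' model evaluation.
#'
#' @param surface a `candidate_surface`.
#' @param parcellation the matching `aha_parcellation`.
#' @param evaluator `function(node, coords)` returning the ML-score of BiV
#'   pacing at that LV site (runs the electrophysiological model plus the
#'   classifier); failures score 0 and are logged.
#' @param max_iter maximum BO iterations after the initial design.
#' @param seed recorded for reproducibility (the procedure is deterministic).
#' @param cutoff patient-level classification cutoff on the best ML-score.
#' @param map_threshold threshold coloring the predicted score map.
#' @param mesh,ref_site optional: when both are given, `d_ps` (the distance
#'   from the reference site to the optimum) is reported.
#' @param convergence_tol optional distance (mm) under which two successive
#'   picks count as the same point (0 = exact node identity).
#' @return object of class `crt_opt` with the optimum, iteration trace,
#'   convergence flag, patient classification, predicted `score_map` (GP
#'   posterior mean clipped to \[0, 1\]) and optionally `d_ps`.
#' @export
optimize_pacing_site <- function(surface, parcellation, evaluator,
                                 max_iter = 30, seed = 1L, cutoff = 0.51,
                                 map_threshold = 0.5, mesh = NULL,
                                 ref_site = NULL, convergence_tol = 0) {
  design <- initial_design(surface, parcellation)
  r <- run_bo(surface, design, evaluator, max_iter, minimize = FALSE,
              convergence_tol = convergence_tol)
  best <- r$trace[r$best_i, ]
  score_map <- tibble::tibble(
    node = surface$node, x = surface$x, y = surface$y, z = surface$z,
    segment = surface$segment,
    ml_score = pmin(pmax(r$posterior$mean, 0), 1)
  )
  score_map$positive <- score_map$ml_score > map_threshold
  d_ps <- if (!is.null(mesh) && !is.null(ref_site)) {
    d_ps(mesh, ref_site, c(best$x, best$y, best$z))
  } else NA_real_
  structure(list(
    opt_node = best$node,
    opt_coords = c(best$x, best$y, best$z),
    max_score = best$score,
    classification = unname(best$score > cutoff),
    trace = r$trace,
    converged = r$converged,
    n_evaluations = nrow(r$trace),
    score_map = score_map,
    gp = r$gp,
    d_ps = d_ps,
    cutoff = cutoff, map_threshold = map_threshold, seed = seed
  ), class = "crt_opt")
}

#' Bayesian optimization of the LV pacing site by TAT95
#'
#' Same machinery as [optimize_pacing_site()] but minimizing the simulated
#' TAT95 with the lower-confidence-bound acquisition `mu - 2 sigma`; returns
#' the TAT-PS strategy site.
#'
#' @inheritParams optimize_pacing_site
#' @param evaluator_tat `function(node, coords)` returning TAT95 (ms) for LV
#'   pacing at that site.
#' @return a `crt_opt` (scores are TAT95 values; no classification).
#' @export
optimize_tat <- function(surface, parcellation, evaluator_tat, max_iter = 30,
                         seed = 1L, convergence_tol = 0) {
  design <- initial_design(surface, parcellation)
  r <- run_bo(surface, design, evaluator_tat, max_iter, minimize = TRUE,
              convergence_tol = convergence_tol)
  best <- r$trace[r$best_i, ]
  score_map <- tibble::tibble(
    node = surface$node, x = surface$x, y = surface$y, z = surface$z,
    segment = surface$segment, tat95 = r$posterior$mean
  )
  structure(list(
    opt_node = best$node,
    opt_coords = c(best$x, best$y, best$z),
    min_tat95 = best$score,
    trace = r$trace,
    converged = r$converged,
    n_evaluations = nrow(r$trace),
    score_map = score_map,
    gp = r$gp,
    seed = seed
  ), class = "crt_opt")
}

#' Latest-activation pacing site (LAT-PS)
#'
#' The candidate node with the maximum baseline (LBBB) activation time; ties
#' broken toward the lowest node index.
#'
#' @param lbbb_map baseline `activation_map`.
#' @param surface a `candidate_surface`.
#' @return one-row tibble with `node`, `x`, `y`, `z`, `segment`, `time`.
#' @export
lat_site <- function(lbbb_map, surface) {
  t <- as.numeric(lbbb_map[surface$node])
  i <- which(t == max(t, na.rm = TRUE))[1]
  out <- surface[i, ]
  out$time <- t[i]
  out
}

#' Surface distance between two pacing sites
#'
#' Isotropic-eikonal (geodesic) distance between two sites on the LV
#' epicardium, the same distance convention as the other pacing-site
#' distances; used for D_PS, the distance between the clinical reference
#' site and the model-optimal site.
#'
#' @param mesh a `biv_mesh`.
#' @param site_a,site_b coordinates (mm) or node indices.
#' @return distance in mm.
#' @export
d_ps <- function(mesh, site_a, site_b) {
  a <- if (length(site_a) == 1) as.integer(site_a)
       else nearest_node(mesh, site_a, subset = mesh$surfaces$lv_epi)
  b <- if (length(site_b) == 1) as.integer(site_b)
       else nearest_node(mesh, site_b, subset = mesh$surfaces$lv_epi)
  geodesic_distance(mesh, a, b)
}

#' @export
print.crt_opt <- function(x, ...) {
  lab <- if (!is.null(x$max_score)) sprintf("max ML-score %.3f", x$max_score)
         else sprintf("min TAT95 %.1f ms", x$min_tat95)
  cat(sprintf("<crt_opt> node %d, %s, %d evaluations, %s\n",
              x$opt_node, lab, x$n_evaluations,
              if (x$converged) "converged" else "not converged"))
  if (!is.na(x$d_ps)) cat(sprintf("  D_PS = %.1f mm\n", x$d_ps))
  invisible(x)
}

#' @rdname crtsim-tidiers
#' @export
tidy.crt_opt <- function(x, ...) x$trace

#' @rdname crtsim-tidiers
#' @export
glance.crt_opt <- function(x, ...) {
  tibble::tibble(
    opt_node = x$opt_node,
    best = if (!is.null(x$max_score)) x$max_score else x$min_tat95,
    converged = x$converged,
    n_evaluations = x$n_evaluations,
    d_ps = x$d_ps %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
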