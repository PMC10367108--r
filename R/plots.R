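#' @export
autoplot.crt_ecg <- function(object, ...) {
  lead_order <- c("I", "II", "III", "aVR", "aVL", "aVF",
                  "V1", "V2", "V3", "V4", "V5", "V6")
  long <- tidyr::pivot_longer(object, -"time", names_to = "lead",
                              values_to = "potential")
  long$lead <- factor(long$lead, levels = lead_order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$potential)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 3, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "potential (a.u.)",
                  title = "Simulated 12-lead ECG") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @export
autoplot.crt_cv <- function(object, ...) {
  s <- object$scores
  thr <- sort(unique(c(-Inf, s$score, Inf)), decreasing = TRUE)
  roc <- purrr::map_dfr(thr, function(t) {
    pred <- s$score >= t
    tibble::tibble(tpr = mean(pred[s$label == 1]),
                   fpr = mean(pred[s$label == 0]))
  })
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Held-out ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

# polygon geometry of the standard 17-segment bullseye
aha_bullseye_polygons <- function(n_arc = 40) {
  ring <- function(r0, r1, a0, a1, id) {
    th <- seq(a0, a1, length.out = n_arc)
    tibble::tibble(
      segment = id,
      px = c(r1 * cos(th), r0 * cos(rev(th))),
      py = c(r1 * sin(th), r0 * sin(rev(th)))
    )
  }
  out <- list()
  # display convention: septum (segments 2/3, 8/9, 14) on the left
  sector6 <- function(ids, r0, r1) {
    starts <- seq(90, 90 + 300, by = 60) * pi / 180
    purrr::map2_dfr(ids, seq_along(ids), function(id, k)
      ring(r0, r1, starts[k], starts[k] + pi / 3, id))
  }
  sector4 <- function(ids, r0, r1) {
    starts <- (45 + c(0, 90, 180, 270)) * pi / 180
    purrr::map2_dfr(ids, seq_along(ids), function(id, k)
      ring(r0, r1, starts[k], starts[k] + pi / 2, id))
  }
  dplyr::bind_rows(
    sector6(c(2, 1, 6, 5, 4, 3), 2 / 3, 1),          # basal
    sector6(c(8, 7, 12, 11, 10, 9), 1 / 3 + 0.08, 2 / 3),  # mid
    sector4(c(13, 16, 15, 14), 0.12, 1 / 3 + 0.08),  # apical
    ring(0, 0.12, 0, 2 * pi, 17)                     # apex cap
  )
}

#' Bullseye plot of per-segment values on the AHA scheme
#'
#' @param values named or 17-long numeric vector of per-segment values
#'   (index = AHA id), `NA` for absent segments.
#' @param title plot title.
#' @param limits optional fill limits.
#' @return a ggplot.
#' @export
plot_aha_bullseye <- function(values, title = NULL, limits = NULL) {
  stopifnot(length(values) == 17)
  poly <- aha_bullseye_polygons()
  poly$value <- values[poly$segment]
  ggplot2::ggplot(poly, ggplot2::aes(x = .data$px, y = .data$py,
                                     group = .data$segment,
                                     fill = .data$value)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0.5,
                                  limits = limits, na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title, fill = NULL)
}

#' @export
autoplot.crt_opt <- function(object, ...) {
  summ <- aha_summary(object$score_map)
  vals <- rep(NA_real_, 17)
  vals[summ$segment] <- summ$mean
  value_name <- if ("ml_score" %in% names(object$score_map)) "ML-score" else "TAT95"
  plot_aha_bullseye(vals, title = sprintf(
    "Predicted %s by AHA segment (optimum: node %d)", value_name,
    object$opt_node))
}

#' Bullseye view of an activation map on the LV epicardium
#'
#' Averages the nodal activation times of the LV epicardial surface per AHA
#' segment and displays them on the 17-segment scheme.
#'
#' @param mesh a `biv_mesh`.
#' @param activation an `activation_map`.
#' @param parcellation an `aha_parcellation` (recomputed when omitted).
#' @return a ggplot.
#' @export
plot_activation_bullseye <- function(mesh, activation, parcellation = NULL) {
  if (is.null(parcellation)) parcellation <- parcellate_aha(mesh)
  nodes <- mesh$surfaces$lv_epi
  seg <- parcellation$node_segment[nodes]
  t <- as.numeric(activation[nodes])
  vals <- rep(NA_real_, 17)
  for (s in unique(stats::na.omit(seg))) vals[s] <- mean(t[seg == s], na.rm = TRUE)
  p <- plot_aha_bullseye(vals, title = "Mean epicardial activation time (ms)")
  p + ggplot2::scale_fill_viridis_c(na.value = "grey85")
}
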