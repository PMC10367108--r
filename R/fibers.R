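#' Rule-based myocardial fiber architecture
#'
#' Assigns a fiber direction to every element by the standard rule-based
#' convention: the helix angle rotates linearly with normalized transmural
#' depth, from `endo_angle` at the endocardium to `epi_angle` at the
#' epicardium. The fiber lies in the local wall tangent plane; at helix angle
#' 0 it is purely circumferential, positive angles tilt it toward the base
#' along the local longitudinal direction.
#'
#' @param mesh a `biv_mesh`.
#' @param endo_angle helix angle at the endocardium (degrees, default +60).
#' @param epi_angle helix angle at the epicardium (degrees, default -60).
#' @return matrix of unit fiber vectors, one row per element, class
#'   `fiber_field`.
#' @export
assign_fibers <- function(mesh, endo_angle = 60, epi_angle = -60) {
  stopifnot(inherits(mesh, "biv_mesh"))
  if (abs(endo_angle) > 90 || abs(epi_angle) > 90) {
    stop("helix angles must lie in [-90, 90] degrees", call. = FALSE)
  }
  depth <- mesh$depth
  bad <- which(!is.finite(depth))
  if (length(bad)) {
    stop("element ", bad[1], " has an undefined transmural coordinate",
         call. = FALSE)
  }
  n <- mesh$wall_normal                     # outward wall normal per element
  la <- mesh$long_axis
  # circumferential direction: normal x long_axis (tangent to the wall)
  circ <- cbind(n[, 2] * la[3] - n[, 3] * la[2],
                n[, 3] * la[1] - n[, 1] * la[3],
                n[, 1] * la[2] - n[, 2] * la[1])
  cn <- sqrt(rowSums(circ^2))
  # near the apex pole the cross product degenerates; fall back to any
  # tangent orthogonal to the normal
  dg <- cn < 1e-8
  if (any(dg)) {
    ref <- matrix(c(1, 0, 0), nrow = sum(dg), ncol = 3, byrow = TRUE)
    alt <- cbind(n[dg, 2] * ref[, 3] - n[dg, 3] * ref[, 2],
                 n[dg, 3] * ref[, 1] - n[dg, 1] * ref[, 3],
                 n[dg, 1] * ref[, 2] - n[dg, 2] * ref[, 1])
    circ[dg, ] <- alt
    cn[dg] <- sqrt(rowSums(alt^2))
  }
  circ <- circ / cn
  # local longitudinal (apex-to-base) tangent: circ x normal
  longi <- cbind(circ[, 2] * n[, 3] - circ[, 3] * n[, 2],
                 circ[, 3] * n[, 1] - circ[, 1] * n[, 3],
                 circ[, 1] * n[, 2] - circ[, 2] * n[, 1])
  longi <- longi / sqrt(rowSums(longi^2))

  alpha <- (endo_angle + depth * (epi_angle - endo_angle)) * pi / 180
  f <- cos(alpha) * circ + sin(alpha) * longi
  f <- f / sqrt(rowSums(f^2))
  structure(f, class = c("fiber_field", class(f)))
}

#' Recover the helix angle of a fiber field by projection
#'
#' Projects each fiber onto the local circumferential/longitudinal frame and
#' returns the signed helix angle in degrees. Used to verify the linear
#' transmural rule.
#'
#' @param mesh a `biv_mesh`.
#' @param fibers a `fiber_field`.
#' @return numeric vector of angles (degrees), one per element.
#' @export
fiber_helix_angle <- function(mesh, fibers) {
  n <- mesh$wall_normal
  la <- mesh$long_axis
  circ <- cbind(n[, 2] * la[3] - n[, 3] * la[2],
                n[, 3] * la[1] - n[, 1] * la[3],
                n[, 1] * la[2] - n[, 2] * la[1])
  cn <- pmax(sqrt(rowSums(circ^2)), 1e-12)
  circ <- circ / cn
  longi <- cbind(circ[, 2] * n[, 3] - circ[, 3] * n[, 2],
                 circ[, 3] * n[, 1] - circ[, 1] * n[, 3],
                 circ[, 1] * n[, 2] - circ[, 2] * n[, 1])
  longi <- longi / pmax(sqrt(rowSums(longi^2)), 1e-12)
  atan2(rowSums(fibers * longi), rowSums(fibers * circ)) * 180 / pi
}
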