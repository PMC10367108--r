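#' AHA 17-segment left-ventricular parcellation
#'
#' Assigns the standard American Heart Association 17-segment scheme to every
#' LV element (including the septum) and to every LV epicardial node: basal
#' and mid thirds split into six 60-degree circumferential sectors, the apical
#' third into four 90-degree sectors, plus the apical cap (segment 17).
#' Angles are measured in the plane orthogonal to the stored long axis,
#' starting from the stored septal axis, so the assignment is invariant under
#' rigid transformation of the mesh together with its reference frame.
#'
#' Septal segments are \{2, 3, 8, 9, 14\}.
#'
#' @param mesh a `biv_mesh`.
#' @return a list of class `aha_parcellation` with `elem_segment` (per-element
#'   id, NA for RV elements), `node_segment` (per-LV-epicardial-node id, NA
#'   elsewhere), `centroids` (17 x 3 epicardial segment centroids, mm) and
#'   `septal_segments`.
#' @export
parcellate_aha <- function(mesh) {
  stopifnot(inherits(mesh, "biv_mesh"))
  la <- mesh$long_axis
  if (sqrt(sum(la^2)) < 1e-12) stop("degenerate long axis", call. = FALSE)
  la <- la / sqrt(sum(la^2))
  sa <- mesh$septal_axis - sum(mesh$septal_axis * la) * la
  if (sqrt(sum(sa^2)) < 1e-12) stop("degenerate septal axis", call. = FALSE)
  sa <- sa / sqrt(sum(sa^2))
  ya <- c(la[2] * sa[3] - la[3] * sa[2],
          la[3] * sa[1] - la[1] * sa[3],
          la[1] * sa[2] - la[2] * sa[1])

  span <- sum((mesh$base_center - mesh$apex) * la)
  classify <- function(p) {
    rel <- p - matrix(mesh$apex, nrow = nrow(p), ncol = 3, byrow = TRUE)
    ell <- pmin(pmax((rel %*% la) / span, 0), 1)       # 0 apex .. 1 base
    phi <- (atan2(rel %*% ya, rel %*% sa) * 180 / pi) %% 360  # 0 = septum center
    seg <- integer(nrow(p))
    cap <- ell < 0.15
    apical <- !cap & ell < 0.40
    mid <- !cap & !apical & ell < 0.70
    basal <- ell >= 0.70
    sector6 <- function(phi) {
      # 60-degree sectors from the septal axis; phi 0 sits on the 2|3 border
      br <- c(-60, 0, 60, 120, 180, 240, 300)
      ids <- c(2L, 3L, 4L, 5L, 6L, 1L)        # anteroseptal..anterior
      ph <- ifelse(phi >= 300, phi - 360, phi)
      ids[findInterval(ph, br, rightmost.closed = TRUE)]
    }
    sector4 <- function(phi) {
      br <- c(-45, 45, 135, 225, 315)
      ids <- c(14L, 15L, 16L, 13L)            # septal, inferior, lateral, anterior
      ph <- ifelse(phi >= 315, phi - 360, phi)
      ids[findInterval(ph, br, rightmost.closed = TRUE)]
    }
    seg[cap] <- 17L
    seg[apical] <- sector4(phi[apical])
    seg[mid] <- sector6(phi[mid]) + 6L
    seg[basal] <- sector6(phi[basal])
    seg
  }

  elem_segment <- rep(NA_integer_, nrow(mesh$tets))
  lv_el <- mesh$region == "lv_shell"
  elem_segment[lv_el] <- classify(elem_centroids(mesh)[lv_el, , drop = FALSE])

  node_segment <- rep(NA_integer_, nrow(mesh$nodes))
  lv_epi_all <- which(mesh$node_is$lv_epi)
  node_segment[lv_epi_all] <- classify(mesh$nodes[lv_epi_all, , drop = FALSE])

  centroids <- matrix(NA_real_, nrow = 17, ncol = 3)
  for (s in 1:17) {
    nn <- lv_epi_all[node_segment[lv_epi_all] == s]
    if (length(nn)) centroids[s, ] <- colMeans(mesh$nodes[nn, , drop = FALSE])
  }

  structure(list(elem_segment = elem_segment,
                 node_segment = node_segment,
                 centroids = centroids,
                 septal_segments = c(2L, 3L, 8L, 9L, 14L)),
            class = "aha_parcellation")
}

#' @export
print.aha_parcellation <- function(x, ...) {
  cat("<aha_parcellation>",
      length(unique(stats::na.omit(x$elem_segment))), "segments over",
      sum(!is.na(x$elem_segment)), "LV elements\n")
  invisible(x)
}
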