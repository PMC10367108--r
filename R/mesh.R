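#' Generate a synthetic biventricular tetrahedral mesh
#'
#' Builds an idealized two-cavity ventricular geometry: the left ventricle is a
#' thick-walled truncated prolate ellipsoid (truncated at its equatorial plane,
#' which serves as the base), and the right ventricle is a thinner crescent
#' shell wrapped around the septal sector of the LV epicardium. The septum is
#' the LV-wall sector facing the RV cavity, so its right face is RV
#' endocardium, as in real anatomy. The two shells share nodes along the RV
#' attachment rims, giving a single connected conducting mesh.
#'
#' The hexahedral parameter grid is split into tetrahedra through a cell-center
#' node, with quad faces split along the diagonal through their smallest global
#' node index so that neighbouring cells produce conforming faces.
#'
#' @param lv_endo_radius LV endocardial short semi-axis (mm).
#' @param lv_long_radius LV endocardial long semi-axis, apex to base (mm).
#' @param lv_wall LV wall thickness (mm).
#' @param rv_bulge maximal RV cavity depth away from the LV epicardium (mm).
#' @param rv_wall RV free-wall thickness (mm).
#' @param rv_apex_frac fraction of the apex-to-base extent below which the RV
#'   does not reach (the RV attaches to the LV epicardium apexward of this).
#' @param resolution grid-density multiplier (1 = default coarse mesh).
#' @param seed integer recorded with the mesh; generation is deterministic.
#' @return an object of class `biv_mesh`; see Details.
#' @details The returned list contains `nodes` (n x 3, mm), `tets` (m x 4 node
#'   indices, positively oriented), per-element metadata (`ventricle` in
#'   lv/septum/rv, transmural `depth` in \[0,1\] from endo to epi, wall
#'   normals), `volumes` (mm^3), boundary faces with tags
#'   (`lv_endo`, `rv_endo`, `epi`, `base`), node surface sets, and the
#'   anatomical reference frame (`long_axis`, `septal_axis`, `apex`,
#'   `base_center`) used by the AHA parcellation.
#' @export
generate_biventricular_mesh <- function(lv_endo_radius = 33,
                                        lv_long_radius = 72,
                                        lv_wall = 8,
                                        rv_bulge = 12,
                                        rv_wall = 3.5,
                                        rv_apex_frac = 0.45,
                                        resolution = 1,
                                        seed = 1L) {
  if (any(c(lv_endo_radius, lv_long_radius, lv_wall, rv_bulge, rv_wall,
            resolution) <= 0)) {
    stop("all geometry parameters must be positive", call. = FALSE)
  }
  if (lv_wall >= lv_endo_radius) {
    stop("non-physical parameters: lv_wall must be smaller than lv_endo_radius",
         call. = FALSE)
  }
  if (rv_apex_frac <= 0 || rv_apex_frac >= 0.8) {
    stop("rv_apex_frac must lie in (0, 0.8)", call. = FALSE)
  }

  n_mu    <- max(3L, as.integer(round(3 * resolution)))       # cells across LV wall
  n_theta <- max(6L, as.integer(round(10 * resolution)))      # apex-to-base rows
  n_phi   <- 3L * max(4L, as.integer(round(6 * resolution)))  # circumferential
  n_nu    <- max(3L, as.integer(round(3 * resolution)))       # cells across RV wall
  j0      <- max(1L, as.integer(round(rv_apex_frac * n_theta)))
  if (j0 >= n_theta - 1L) stop("resolution too coarse for RV extent", call. = FALSE)

  a0 <- lv_endo_radius; c0 <- lv_long_radius; tw <- lv_wall

  # --- node bookkeeping -------------------------------------------------
  nodes <- matrix(0, nrow = 0, ncol = 3)
  flags <- list(lv_endo = integer(), lv_epi = integer(), rv_endo = integer(),
                rv_epi = integer(), base = integer())
  node_row <- integer()   # theta row index, NA for cell centers
  buf <- new.env()
  buf$nodes <- vector("list", 65536L); buf$n <- 0L
  buf$row <- integer()
  add_node <- function(p, row) {
    buf$n <- buf$n + 1L
    buf$nodes[[buf$n]] <- p
    buf$row[buf$n] <- row
    buf$n
  }

  lv_point <- function(mu, theta, phi) {
    a <- a0 + mu * tw; cc <- c0 + mu * tw
    c(a * sin(theta) * cos(phi), a * sin(theta) * sin(phi), -cc * cos(theta))
  }

  # LV grid nodes: lvid[i+1, j+1, k+1]; j = 0 is the collapsed apex ring
  lvid <- array(NA_integer_, dim = c(n_mu + 1L, n_theta + 1L, n_phi))
  for (i in 0:n_mu) {
    mu <- i / n_mu
    apex_id <- add_node(lv_point(mu, 0, 0), 0L)
    lvid[i + 1L, 1L, ] <- apex_id
    for (j in 1:n_theta) {
      theta <- (j / n_theta) * (pi / 2)
      for (k in 0:(n_phi - 1L)) {
        phi <- 2 * pi * k / n_phi
        lvid[i + 1L, j + 1L, k + 1L] <- add_node(lv_point(mu, theta, phi), j)
      }
    }
  }

  # --- RV shell ---------------------------------------------------------
  k0 <- n_phi %/% 3L            # phi = 120 deg
  M  <- n_phi %/% 3L            # psi intervals across the crescent
  j_g <- j0 + max(1L, (n_theta - j0) %/% 2L)
  bulge <- function(j, m) {
    if (j <= j0 || m == 0L || m == M) return(0)
    g <- sin((pi / 2) * min(1, (j - j0) / (j_g - j0)))
    rv_bulge * sin(pi * m / M) * g
  }
  epi_normal <- function(theta, phi) {
    a <- a0 + tw; cc <- c0 + tw
    p <- lv_point(1, theta, phi)
    v <- c(p[1] / a^2, p[2] / a^2, p[3] / cc^2)
    v / sqrt(sum(v^2))
  }

  rvid <- array(NA_integer_, dim = c(n_nu + 1L, n_theta + 1L, M + 1L))
  for (j in j0:n_theta) {
    theta <- (j / n_theta) * (pi / 2)
    for (m in 0:M) {
      phi <- 2 * pi * (k0 + m) / n_phi
      nrm <- epi_normal(theta, phi)
      b <- bulge(j, m)
      base_pt <- lv_point(1, theta, phi)
      for (v in 0:n_nu) {
        if (v == 0L && b == 0) {
          rvid[1L, j + 1L, m + 1L] <- lvid[n_mu + 1L, j + 1L, (k0 + m) %% n_phi + 1L]
        } else {
          p <- base_pt + (b + (v / n_nu) * rv_wall) * nrm
          rvid[v + 1L, j + 1L, m + 1L] <- add_node(p, j)
        }
      }
    }
  }

  n_grid <- buf$n
  # node flag vectors (logical over grid nodes)
  is_lv_endo <- rep(FALSE, n_grid); is_lv_epi <- rep(FALSE, n_grid)
  is_rv_endo <- rep(FALSE, n_grid); is_rv_epi <- rep(FALSE, n_grid)
  is_lv_endo[unique(as.vector(lvid[1L, , ]))] <- TRUE
  is_lv_epi[unique(as.vector(lvid[n_mu + 1L, , ]))] <- TRUE
  is_rv_endo[unique(as.vector(rvid[1L, , ]))] <- TRUE
  is_rv_epi[unique(as.vector(rvid[n_nu + 1L, , ]))] <- TRUE
  is_base <- rep(FALSE, n_grid)
  is_base[unique(c(as.vector(lvid[, n_theta + 1L, ]),
                   as.vector(rvid[, n_theta + 1L, ])))] <- TRUE

  # --- hex cells --------------------------------------------------------
  septal_lo <- 2 * pi / 3; septal_hi <- 4 * pi / 3
  hex_corners <- list(); hex_meta <- list(); nh <- 0L
  push_hex <- function(corners, ventricle, region, depth, normal) {
    nh <<- nh + 1L
    hex_corners[[nh]] <<- corners
    hex_meta[[nh]] <<- list(ventricle = ventricle, region = region,
                            depth = depth, normal = normal)
  }
  for (i in 0:(n_mu - 1L)) for (j in 0:(n_theta - 1L)) for (k in 0:(n_phi - 1L)) {
    k2 <- (k + 1L) %% n_phi
    corners <- c(lvid[i + 1L, j + 1L, k + 1L],  lvid[i + 2L, j + 1L, k + 1L],
                 lvid[i + 2L, j + 2L, k + 1L],  lvid[i + 1L, j + 2L, k + 1L],
                 lvid[i + 1L, j + 1L, k2 + 1L], lvid[i + 2L, j + 1L, k2 + 1L],
                 lvid[i + 2L, j + 2L, k2 + 1L], lvid[i + 1L, j + 2L, k2 + 1L])
    phi_mid <- 2 * pi * (k + 0.5) / n_phi
    theta_mid <- ((j + 0.5) / n_theta) * (pi / 2)
    vent <- if (phi_mid > septal_lo && phi_mid < septal_hi) "septum" else "lv"
    mu_mid <- (i + 0.5) / n_mu
    depth_i <- if (n_mu > 1) i / (n_mu - 1) else 0.5
    a <- a0 + mu_mid * tw; cc <- c0 + mu_mid * tw
    p <- c(a * sin(theta_mid) * cos(phi_mid), a * sin(theta_mid) * sin(phi_mid),
           -cc * cos(theta_mid))
    nrm <- c(p[1] / a^2, p[2] / a^2, p[3] / cc^2); nrm <- nrm / sqrt(sum(nrm^2))
    push_hex(corners, vent, "lv_shell", depth_i, nrm)
  }
  for (v in 0:(n_nu - 1L)) for (j in j0:(n_theta - 1L)) for (m in 0:(M - 1L)) {
    corners <- c(rvid[v + 1L, j + 1L, m + 1L],  rvid[v + 2L, j + 1L, m + 1L],
                 rvid[v + 2L, j + 2L, m + 1L],  rvid[v + 1L, j + 2L, m + 1L],
                 rvid[v + 1L, j + 1L, m + 2L],  rvid[v + 2L, j + 1L, m + 2L],
                 rvid[v + 2L, j + 2L, m + 2L],  rvid[v + 1L, j + 2L, m + 2L])
    theta_mid <- ((j + 0.5) / n_theta) * (pi / 2)
    phi_mid <- 2 * pi * (k0 + m + 0.5) / n_phi
    push_hex(corners, "rv", "rv_shell",
             if (n_nu > 1) v / (n_nu - 1) else 0.5,
             epi_normal(theta_mid, phi_mid))
  }

  # --- cell-center nodes and tetrahedralization ------------------------
  nodes <- do.call(rbind, buf$nodes[seq_len(buf$n)])
  centers <- matrix(0, nrow = nh, ncol = 3)
  for (h in seq_len(nh)) {
    centers[h, ] <- colMeans(nodes[unique(hex_corners[[h]]), , drop = FALSE])
  }
  center_ids <- n_grid + seq_len(nh)
  nodes <- rbind(nodes, centers)

  # quad faces of the reference hex (corner ordering as pushed above)
  hex_faces <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                     c(4, 3, 7, 8), c(1, 4, 8, 5), c(2, 3, 7, 6))
  tet_list <- vector("list", nh)
  for (h in seq_len(nh)) {
    cn <- hex_corners[[h]]; ctr <- center_ids[h]
    tets_h <- matrix(NA_integer_, nrow = 12L, ncol = 4L); nt <- 0L
    for (f in 1:6) {
      q <- cn[hex_faces[f, ]]
      # split along the diagonal through the smallest global node id
      s <- which.min(q)
      o <- ((s + 1L):(s + 3L) - 1L) %% 4L + 1L
      tris <- rbind(q[c(s, o[1], o[2])], q[c(s, o[2], o[3])])
      for (r in 1:2) {
        tri <- tris[r, ]
        if (anyDuplicated(c(tri, ctr)) == 0L) {
          nt <- nt + 1L; tets_h[nt, ] <- c(tri, ctr)
        }
      }
    }
    tet_list[[h]] <- tets_h[seq_len(nt), , drop = FALSE]
  }
  tets_per_hex <- vapply(tet_list, nrow, integer(1))
  tets <- do.call(rbind, tet_list)
  hex_of_tet <- rep(seq_len(nh), tets_per_hex)

  # orient positively, drop degenerate slivers
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) {
    tmp <- tets[neg, 2L]; tets[neg, 2L] <- tets[neg, 3L]; tets[neg, 3L] <- tmp
    vol <- abs(vol)
  }
  keep <- vol > 1e-9
  tets <- tets[keep, , drop = FALSE]; vol <- vol[keep]
  hex_of_tet <- hex_of_tet[keep]

  ventricle <- vapply(hex_meta, function(x) x$ventricle, character(1))[hex_of_tet]
  region    <- vapply(hex_meta, function(x) x$region, character(1))[hex_of_tet]
  depth     <- vapply(hex_meta, function(x) x$depth, numeric(1))[hex_of_tet]
  normals   <- do.call(rbind, lapply(hex_meta, function(x) x$normal))[hex_of_tet, , drop = FALSE]

  # --- boundary extraction and tagging ---------------------------------
  face_idx <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  all_faces <- matrix(NA_integer_, nrow = 4L * nrow(tets), ncol = 3L)
  for (f in 1:4) {
    all_faces[seq(f, by = 4L, length.out = nrow(tets)), ] <- tets[, face_idx[f, ]]
  }
  sorted <- t(apply(all_faces, 1L, sort))
  key <- paste(sorted[, 1], sorted[, 2], sorted[, 3])
  cnt <- table(key)
  boundary <- all_faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]

  node_row <- c(buf$row[seq_len(n_grid)], rep(NA_integer_, nh))
  pad <- function(x) c(x, rep(FALSE, nh))
  is_lv_endo <- pad(is_lv_endo); is_lv_epi <- pad(is_lv_epi)
  is_rv_endo <- pad(is_rv_endo); is_rv_epi <- pad(is_rv_epi); is_base <- pad(is_base)

  tag <- character(nrow(boundary))
  for (b in seq_len(nrow(boundary))) {
    nn <- boundary[b, ]
    if (all(is_base[nn])) { tag[b] <- "base"; next }
    if (all(is_lv_endo[nn])) { tag[b] <- "lv_endo"; next }
    if (all(is_rv_endo[nn]) && !all(is_lv_epi[nn])) { tag[b] <- "rv_endo"; next }
    if (all(is_lv_epi[nn])) {
      ctr <- colMeans(nodes[nn, , drop = FALSE])
      phi <- atan2(ctr[2], ctr[1]) %% (2 * pi)
      if (phi > septal_lo && phi < septal_hi && min(node_row[nn]) >= j0) {
        tag[b] <- "rv_endo"
      } else tag[b] <- "epi"
      next
    }
    tag[b] <- "epi"
  }

  surf_nodes <- function(which_tag) sort(unique(as.vector(boundary[tag == which_tag, ])))
  epi_nodes <- surf_nodes("epi")
  surfaces <- list(
    lv_endo = surf_nodes("lv_endo"),
    rv_endo = surf_nodes("rv_endo"),
    epi     = epi_nodes,
    base    = surf_nodes("base"),
    lv_epi  = intersect(epi_nodes, which(is_lv_epi))
  )

  mesh <- structure(list(
    nodes = nodes,
    tets = tets,
    volumes = vol,
    ventricle = ventricle,
    region = region,
    depth = depth,
    wall_normal = normals,
    boundary_faces = boundary,
    boundary_tag = tag,
    surfaces = surfaces,
    node_is = list(lv_endo = is_lv_endo, lv_epi = is_lv_epi,
                   rv_endo = is_rv_endo, rv_epi = is_rv_epi, base = is_base),
    long_axis = c(0, 0, 1),
    septal_axis = c(-1, 0, 0),
    apex = c(0, 0, -(c0 + tw)),
    base_center = c(0, 0, 0),
    params = list(lv_endo_radius = lv_endo_radius, lv_long_radius = lv_long_radius,
                  lv_wall = lv_wall, rv_bulge = rv_bulge, rv_wall = rv_wall,
                  rv_apex_frac = rv_apex_frac, resolution = resolution,
                  n_mu = n_mu, n_theta = n_theta, n_phi = n_phi, n_nu = n_nu,
                  j0 = j0),
    seed = as.integer(seed)
  ), class = "biv_mesh")
  stopifnot(all(mesh$volumes > 0))
  mesh
}

#' Signed tetrahedron volumes
#'
#' @param nodes n x 3 coordinate matrix.
#' @param tets m x 4 index matrix.
#' @return numeric vector of signed volumes (mm^3).
#' @keywords internal
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
   a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
   a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' @export
print.biv_mesh <- function(x, ...) {
  cat("<biv_mesh>", nrow(x$nodes), "nodes,", nrow(x$tets), "tets\n")
  cat("  ventricle:", paste(sprintf("%s=%d", names(table(x$ventricle)),
                                    table(x$ventricle)), collapse = ", "), "\n")
  cat("  surfaces :", paste(sprintf("%s=%d", names(x$surfaces),
                                    lengths(x$surfaces)), collapse = ", "), "\n")
  invisible(x)
}

#' Element centroids
#' @keywords internal
elem_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
}

#' Nearest mesh node to a point, optionally within a node subset
#' @param mesh a `biv_mesh`.
#' @param point length-3 coordinates (mm).
#' @param subset optional node index vector to search within.
#' @return a node index.
#' @export
nearest_node <- function(mesh, point, subset = NULL) {
  idx <- if (is.null(subset)) seq_len(nrow(mesh$nodes)) else subset
  d2 <- rowSums((mesh$nodes[idx, , drop = FALSE] -
                   matrix(point, nrow = length(idx), ncol = 3, byrow = TRUE))^2)
  idx[which.min(d2)]
}
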