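test_that("mesh generation yields a valid, reproducible two-cavity geometry", {
  m <- test_mesh()
  expect_true(all(m$volumes > 0))
  expect_true(all(seq_len(nrow(m$nodes)) %in% unique(as.vector(m$tets))))
  expect_gt(length(m$surfaces$lv_endo), 0)
  expect_gt(length(m$surfaces$rv_endo), 0)
  # surface tags partition the boundary
  expect_true(all(m$boundary_tag %in% c("lv_endo", "rv_endo", "epi", "base")))
  expect_equal(length(m$boundary_tag), nrow(m$boundary_faces))
  # every boundary edge is shared by an even number of boundary faces
  ed <- rbind(m$boundary_faces[, c(1, 2)], m$boundary_faces[, c(2, 3)],
              m$boundary_faces[, c(1, 3)])
  ed <- t(apply(ed, 1, sort))
  counts <- table(paste(ed[, 1], ed[, 2]))
  expect_true(all(counts %% 2 == 0))
  # determinism
  m2 <- generate_biventricular_mesh()
  expect_identical(m$nodes, m2$nodes)
  expect_identical(m$tets, m2$tets)
})

test_that("mesh refinement increases node count and parameters are validated", {
  coarse <- test_mesh()
  fine <- generate_biventricular_mesh(resolution = 2)
  expect_gt(nrow(fine$nodes), nrow(coarse$nodes))
  expect_error(generate_biventricular_mesh(lv_wall = 40, lv_endo_radius = 30),
               "non-physical")
  expect_error(generate_biventricular_mesh(lv_endo_radius = -5), "positive")
})

test_that("fiber field follows the linear transmural helix rule", {
  m <- test_mesh()
  f <- assign_fibers(m, 60, -60)
  expect_lt(max(abs(sqrt(rowSums(f^2)) - 1)), 1e-9)
  ha <- fiber_helix_angle(m, f)
  expected <- 60 + m$depth * (-120)
  ok <- sqrt(rowSums((cbind(
    m$wall_normal[, 2] * m$long_axis[3] - m$wall_normal[, 3] * m$long_axis[2],
    m$wall_normal[, 3] * m$long_axis[1] - m$wall_normal[, 1] * m$long_axis[3],
    m$wall_normal[, 1] * m$long_axis[2] - m$wall_normal[, 2] * m$long_axis[1]
  ))^2)) > 1e-3   # skip apex elements where the frame degenerates
  expect_lt(max(abs(ha[ok] - expected[ok])), 2)
  # mid-wall element of a 3-layer wall sits at helix angle 0
  mid <- which(abs(m$depth - 0.5) < 1e-9 & ok)
  expect_gt(length(mid), 0)
  expect_lt(max(abs(ha[mid])), 2)
  # constant rule: equal angles everywhere
  f0 <- assign_fibers(m, 0, 0)
  ha0 <- fiber_helix_angle(m, f0)
  expect_lt(max(abs(ha0[ok])), 1e-6)
  # fibers tangent to the wall
  expect_lt(max(abs(rowSums(f * m$wall_normal))), 1e-6)
  expect_error(assign_fibers(m, 120, 0), "\\[-90, 90\\]")
})

test_that("AHA parcellation produces the standard 17 segments", {
  p <- test_parc()
  m <- test_mesh()
  segs <- sort(unique(stats::na.omit(p$elem_segment)))
  expect_identical(segs, 1:17)
  expect_identical(p$septal_segments, c(2L, 3L, 8L, 9L, 14L))
  # partition over the LV shell
  lv <- m$region == "lv_shell"
  expect_true(all(!is.na(p$elem_segment[lv])))
  expect_true(all(is.na(p$elem_segment[!lv])))
})

test_that("parcellation is invariant under rigid transformation", {
  m <- test_mesh()
  p <- test_parc()
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  R <- R2 %*% R
  shift <- c(10, -4, 25)
  m2 <- m
  m2$nodes <- m$nodes %*% t(R) + matrix(shift, nrow(m$nodes), 3, byrow = TRUE)
  m2$long_axis <- as.numeric(R %*% m$long_axis)
  m2$septal_axis <- as.numeric(R %*% m$septal_axis)
  m2$apex <- as.numeric(R %*% m$apex) + shift
  m2$base_center <- as.numeric(R %*% m$base_center) + shift
  p2 <- parcellate_aha(m2)
  expect_identical(p$elem_segment, p2$elem_segment)
  expect_error(parcellate_aha(within(unclass(m), long_axis <- c(0, 0, 0)) |>
                                structure(class = "biv_mesh")),
               "degenerate")
})

test_that("tissue labels honor segment lists, precedence, and volumes", {
  m <- test_mesh(); p <- test_parc()
  all_h <- label_tissue(m, p)
  expect_true(all(all_h == "healthy"))
  lab <- label_tissue(m, p, scar_segments = 5, fibrosis_segments = c(5, 12))
  expect_true(all(lab[p$elem_segment %in% 5] == "scar"))      # precedence
  expect_true(all(lab[p$elem_segment %in% 12] == "fibrosis"))
  expect_error(label_tissue(m, p, scar_segments = 19), "unknown")

  fr <- tissue_volume_fractions(m, lab)
  expect_equal(fr$scar_fraction + fr$fibrosis_fraction + fr$healthy_fraction,
               1, tolerance = 1e-12)
  # closed form on two equal-volume elements, one scar
  pm <- point_mesh(c(1, 2), volumes = c(3, 3))
  fr2 <- tissue_volume_fractions(pm, structure(c("scar", "healthy"),
                                               class = "tissue_labels"))
  expect_equal(fr2$scar_fraction, 0.5)
  expect_equal(tissue_volume_fractions(
    pm, structure(c("scar", "scar"), class = "tissue_labels"))$scar_fraction, 1)
})
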