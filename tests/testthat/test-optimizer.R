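test_that("candidate surface excludes septum and scar", {
  m <- test_mesh(); p <- test_parc()
  surf <- candidate_surface(m, p, test_labels())
  expect_true(all(surf$node %in% m$surfaces$lv_epi))
  expect_false(any(surf$segment %in% p$septal_segments))
  expect_setequal(unique(surf$segment), setdiff(1:17, p$septal_segments))

  lab5 <- label_tissue(m, p, scar_segments = 5)
  surf5 <- candidate_surface(m, p, lab5)
  expect_false(any(surf5$segment == 5))
})

test_that("initial design places one site per eligible segment", {
  m <- test_mesh(); p <- test_parc()
  surf <- candidate_surface(m, p, test_labels())
  des <- initial_design(surf, p)
  expect_equal(nrow(des), 12)
  lab2 <- label_tissue(m, p, scar_segments = c(5, 11))
  des2 <- initial_design(candidate_surface(m, p, lab2), p)
  expect_equal(nrow(des2), 10)
  # each site's node carries its own segment id
  expect_equal(p$node_segment[des$node], des$segment)
})

test_that("noise-free GP interpolates and its uncertainty grows off-data", {
  set.seed(3)
  X <- matrix(runif(36, -40, 40), ncol = 3)
  y <- sin(X[, 1] / 15) + 0.5 * cos(X[, 2] / 20)
  g <- gp_fit(X, y)
  p <- gp_predict(g, X)
  expect_lt(max(abs(p$mean - y)), 1e-6)
  expect_lt(max(p$sd), 1e-3)
  far <- gp_predict(g, matrix(c(400, 400, 400), ncol = 3))
  expect_gt(far$sd, max(p$sd))
  # constant targets: flat posterior mean
  gc <- gp_fit(X, rep(0.7, nrow(X)))
  pc <- gp_predict(gc, matrix(runif(30, -40, 40), ncol = 3))
  expect_lt(max(abs(pc$mean - 0.7)), 1e-3)
  expect_error(gp_fit(X[1, , drop = FALSE], 1), "at least 2")
})

test_that("adding a training point never increases predictive uncertainty", {
  set.seed(4)
  X <- matrix(runif(30, -40, 40), ncol = 3)
  y <- X[, 1] / 40
  Xq <- matrix(runif(60, -40, 40), ncol = 3)
  g1 <- gp_fit(X, y, lengthscale = 25)
  g2 <- gp_fit(rbind(X, c(0, 0, 0)), c(y, 0), lengthscale = 25)
  s1 <- gp_predict(g1, Xq)$sd
  s2 <- gp_predict(g2, Xq)$sd
  expect_true(all(s2 <= s1 + 1e-8))
})

test_that("acquisition is mu + 2 sigma (and mu - 2 sigma when minimizing)", {
  assign("gp_predict.mock_surrogate",
         function(surrogate, Xnew, ...) tibble::tibble(mean = 0, sd = 1),
         envir = globalenv())
  on.exit(rm("gp_predict.mock_surrogate", envir = globalenv()))
  mock <- structure(list(), class = "mock_surrogate")
  expect_equal(acquisition(mock, c(0, 0, 0)), 2)
  expect_equal(acquisition(mock, c(0, 0, 0), minimize = TRUE), -2)
  g <- gp_fit(matrix(rnorm(9), 3), c(1, 2, 3))
  p <- gp_predict(g, matrix(0, 1, 3))
  expect_equal(acquisition(g, matrix(0, 1, 3)), p$mean + 2 * p$sd)
})

test_that("BO optimum equals exhaustive search on seeded smooth functions", {
  m <- test_mesh(); p <- test_parc()
  surf <- candidate_surface(m, p, test_labels())
  expect_lte(nrow(surf), 2000)
  Xc <- as.matrix(surf[, c("x", "y", "z")])
  mismatches <- 0
  for (s in 1:10) {
    set.seed(s)
    centers <- Xc[sample(nrow(Xc), 2), , drop = FALSE]
    w <- runif(2, 0.5, 1)
    fn <- function(node, coords) {
      sum(w * exp(-colSums((t(centers) - coords)^2) / 1500))
    }
    r <- optimize_pacing_site(surf, p, fn, max_iter = 30)
    truth <- vapply(seq_len(nrow(surf)),
                    function(i) fn(surf$node[i], Xc[i, ]), numeric(1))
    if (abs(r$max_score - max(truth)) > 1e-9) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("BO is deterministic, budgeted, and self-consistent", {
  m <- test_mesh(); p <- test_parc()
  surf <- candidate_surface(m, p, test_labels())
  fn <- function(node, coords) exp(-sum((coords - c(25, 20, -35))^2) / 2000)
  r1 <- optimize_pacing_site(surf, p, fn, max_iter = 25)
  r2 <- optimize_pacing_site(surf, p, fn, max_iter = 25)
  expect_identical(r1$trace, r2$trace)
  # every BO iteration added exactly one evaluation
  expect_equal(r1$n_evaluations, nrow(r1$trace))
  expect_lte(sum(r1$trace$stage == "bo"), 25)
  expect_gte(r1$n_evaluations, 12)
  # GP posterior mean reproduces every observed score
  post <- gp_predict(r1$gp, as.matrix(r1$trace[, c("x", "y", "z")]))
  expect_lt(max(abs(post$mean - r1$trace$score)), 1e-3)
  # constant evaluator converges trivially with that score
  rc <- optimize_pacing_site(surf, p, function(n, co) 0.7, max_iter = 10)
  expect_true(rc$converged)
  expect_equal(rc$max_score, 0.7)
  expect_true(rc$classification)
  # score map values are clipped probabilities on the candidate set
  expect_setequal(rc$score_map$node, surf$node)
  expect_true(all(rc$score_map$ml_score >= 0 & rc$score_map$ml_score <= 1))
})

test_that("failed evaluations are penalized, not fatal", {
  m <- test_mesh(); p <- test_parc()
  surf <- candidate_surface(m, p, test_labels())
  bad_nodes <- surf$node[seq(1, nrow(surf), by = 7)]
  fn <- function(node, coords) {
    if (node %in% bad_nodes) stop("site rejected")
    exp(-sum((coords - c(25, 20, -35))^2) / 2000)
  }
  expect_message(r <- optimize_pacing_site(surf, p, fn, max_iter = 10),
                 "penalty")
  expect_true(all(r$trace$score[r$trace$node %in% bad_nodes] == 0))
})

test_that("TAT95 minimization matches exhaustive argmin", {
  m <- test_mesh(); p <- test_parc()
  surf <- candidate_surface(m, p, test_labels())
  Xc <- as.matrix(surf[, c("x", "y", "z")])
  fn <- function(node, coords) 100 + sum((coords - c(-10, 30, -20))^2) / 100
  r <- optimize_tat(surf, p, fn, max_iter = 30)
  truth <- vapply(seq_len(nrow(surf)), function(i) fn(surf$node[i], Xc[i, ]),
                  numeric(1))
  expect_equal(r$min_tat95, min(truth))
  # the minimizer dominates all of its own design evaluations
  des_scores <- r$trace$score[r$trace$stage == "design"]
  expect_true(all(r$min_tat95 <= des_scores))
  r2 <- optimize_tat(surf, p, fn, max_iter = 30)
  expect_identical(r$trace, r2$trace)
})

test_that("LAT-PS is the latest candidate node with deterministic ties", {
  m <- test_mesh(); p <- test_parc()
  surf <- candidate_surface(m, p, test_labels())
  lb <- test_lbbb()
  ls <- lat_site(lb, surf)
  expect_equal(as.numeric(lb[ls$node]), max(as.numeric(lb[surf$node]), na.rm = TRUE))
  # consistency with the LAT region when it intersects the candidates
  reg <- lat_region(lb, m, 0.10)
  if (length(intersect(reg, surf$node))) expect_true(ls$node %in% reg)
  # tie rule: lowest index among equal maxima
  fake <- structure(rep(1, nrow(m$nodes)), class = c("activation_map", "numeric"))
  expect_equal(lat_site(fake, surf)$node, surf$node[1])
})

test_that("site-to-site surface distance is a symmetric pseudo-metric", {
  m <- test_mesh()
  a <- m$surfaces$lv_epi[3]; b <- m$surfaces$lv_epi[40]
  expect_equal(d_ps(m, a, a), 0)
  dab <- d_ps(m, a, b); dba <- d_ps(m, b, a)
  expect_gt(dab, 0)
  expect_lt(abs(dab - dba) / dab, 0.05)
  # flat patch: geodesic equals Euclidean
  sheet <- generate_slab_mesh(30, 20, 2, h = 2)
  c1 <- nearest_node(sheet, c(0, 0, 1)); c2 <- nearest_node(sheet, c(30, 20, 1))
  d <- geodesic_distance(sheet, c2, c1)
  eu <- sqrt(sum((sheet$nodes[c1, ] - sheet$nodes[c2, ])^2))
  expect_lt(abs(d - eu) / eu, 0.05)
})
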