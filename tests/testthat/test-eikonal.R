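test_that("travel time on a homogeneous isotropic bar matches d/v", {
  sl <- test_slab()
  fib <- slab_fibers(sl)
  cm <- conduction_model(v_f = 1, anisotropy = 1)
  src <- data.frame(node = nearest_node(sl, c(0, 0, 0)), onset = 0)
  t <- solve_eikonal(sl, fib, cm, src)
  t_far <- t[nearest_node(sl, c(40, 0, 0))]
  expect_lt(abs(t_far - 40) / 40, 0.05)
  # causality: no node earlier than straight-line distance over max speed
  d <- sqrt(rowSums((sl$nodes - matrix(sl$nodes[src$node, ], nrow(sl$nodes), 3,
                                       byrow = TRUE))^2))
  expect_true(all(as.numeric(t) >= d - 1e-6))
})

test_that("measured anisotropy ratio on a fiber-aligned slab is 4:1", {
  sl <- test_slab()
  fib <- slab_fibers(sl)
  cm <- conduction_model(v_f = 1, anisotropy = 4)
  src <- data.frame(node = nearest_node(sl, c(0, 0, 0)), onset = 0)
  t <- solve_eikonal(sl, fib, cm, src)
  xline <- which(sl$nodes[, 2] == 0 & sl$nodes[, 3] == 0)
  yline <- which(sl$nodes[, 1] == 0 & sl$nodes[, 3] == 0)
  v_along <- coef(lm(sl$nodes[xline, 1] ~ as.numeric(t[xline])))[2]
  v_across <- coef(lm(sl$nodes[yline, 2] ~ as.numeric(t[yline])))[2]
  expect_lt(abs(v_along / v_across - 4) / 4, 0.05)
})

test_that("mesh refinement reduces the bar-travel-time error monotonically", {
  errs <- vapply(c(5, 2.5, 1.25), function(h) {
    sl <- generate_slab_mesh(20, 5, 5, h = h)
    fib <- slab_fibers(sl)
    t <- solve_eikonal(sl, fib, conduction_model(v_f = 1, anisotropy = 1),
                       data.frame(node = nearest_node(sl, c(0, 2.5, 2.5)),
                                  onset = 0))
    abs(t[nearest_node(sl, c(20, 2.5, 2.5))] - 20)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("solver agrees with Dijkstra on a densified anisotropic graph", {
  sl <- generate_slab_mesh(20, 10, 5, h = 3)
  expect_lt(nrow(sl$nodes), 500)
  fib <- slab_fibers(sl)
  cm <- conduction_model(v_f = 1, anisotropy = 3)
  src_node <- nearest_node(sl, c(0, 0, 0))
  t <- solve_eikonal(sl, fib, cm, data.frame(node = src_node, onset = 0))
  # densified graph: connect each node to its neighbours-of-neighbours
  G <- c(1, 9, 9, 0, 0, 0)  # 1/v^2 along x, 1/(v/3)^2 across
  adj <- vector("list", nrow(sl$nodes))
  for (e in seq_len(nrow(sl$tets))) {
    q <- sl$tets[e, ]
    for (a in q) adj[[a]] <- union(adj[[a]], q)
  }
  hop <- function(sets) lapply(seq_along(sets), function(i)
    unique(unlist(adj[sets[[i]]])))
  k_hop <- hop(hop(hop(hop(adj))))
  k_hop <- lapply(seq_along(k_hop), function(i) setdiff(k_hop[[i]], i))
  edges <- do.call(rbind, lapply(seq_along(k_hop), function(i) {
    js <- k_hop[[i]][k_hop[[i]] > i]
    if (!length(js)) return(NULL)
    matrix(c(rep.int(i, length(js)), js), ncol = 2)
  }))
  dvec <- sl$nodes[edges[, 2], ] - sl$nodes[edges[, 1], ]
  w <- sqrt(G[1] * dvec[, 1]^2 + G[2] * dvec[, 2]^2 + G[3] * dvec[, 3]^2)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  dd <- igraph::distances(g, v = src_node, weights = w)[1, ]
  nontrivial <- dd > 1e-9
  rel <- abs(as.numeric(t)[nontrivial] - dd[nontrivial]) / dd[nontrivial]
  expect_lt(max(rel), 0.05)
})

test_that("kappa never slows activation and scar blocks it", {
  m <- test_mesh(); f <- test_fibers(); tr <- test_tree()
  t1 <- test_lbbb()
  t2 <- simulate_lbbb(m, f, conduction_model(kappa = 1.3), tr)
  expect_true(all(as.numeric(t2) <= as.numeric(t1) + 1e-6))

  # scar island: all elements of one AHA segment are non-conducting, so
  # nodes interior to it are unreached
  p <- test_parc()
  lab <- label_tissue(m, p, scar_segments = 11)
  tm <- simulate_lbbb(m, f, conduction_model(), tr, labels = lab)
  scar_el <- which(lab == "scar")
  scar_nodes <- unique(as.vector(m$tets[scar_el, ]))
  interior <- setdiff(scar_nodes, unique(as.vector(m$tets[-scar_el, ])))
  expect_gt(length(interior), 0)
  expect_true(all(is.na(tm[interior])))
  expect_true(all(!is.na(tm[setdiff(seq_len(nrow(m$nodes)), interior)])))
})

test_that("sources validate and onset times are honored", {
  m <- test_mesh(); f <- test_fibers()
  cm <- conduction_model()
  expect_error(solve_eikonal(m, f, cm, data.frame(node = integer(),
                                                  onset = numeric())), "empty")
  p <- test_parc()
  lab <- label_tissue(m, p, scar_segments = 11)
  scar_el <- which(lab == "scar")
  interior <- setdiff(unique(as.vector(m$tets[scar_el, ])),
                      unique(as.vector(m$tets[-scar_el, ])))
  expect_error(solve_eikonal(m, f, cm, data.frame(node = interior[1], onset = 0),
                             labels = lab), "scar")
})

test_that("LBBB pattern: RV leads, LV lags, PMJ first, sources monotone", {
  m <- test_mesh()
  lb <- test_lbbb()
  et <- (lb[m$tets[, 1]] + lb[m$tets[, 2]] + lb[m$tets[, 3]] + lb[m$tets[, 4]]) / 4
  expect_gt(mean(et[m$ventricle == "lv"]), mean(et[m$ventricle == "rv"]))
  # earliest myocardial node is a PMJ-coupled node
  tr <- test_tree()
  expect_true(which.min(as.numeric(lb)) %in% tr$pmj)
  # dropping half the terminals cannot make any node earlier
  tr_half <- tr
  keep <- seq_along(tr$terminals) %% 2 == 1
  tr_half$terminals <- tr$terminals[keep]
  tr_half$pmj <- tr$pmj[keep]
  lb_half <- simulate_lbbb(m, test_fibers(), conduction_model(), tr_half)
  expect_true(all(as.numeric(lb_half) >= as.numeric(lb) - 1e-6))
})

test_that("BiV pacing honors onsets and the VV delay shifts the LV wavefront", {
  m <- test_mesh(); f <- test_fibers()
  cm <- conduction_model()
  rv_site <- default_rv_site(m)
  lvn <- m$surfaces$lv_epi
  lv_site <- m$nodes[lvn[which.max(m$nodes[lvn, 1] - abs(m$nodes[lvn, 3] + 30))], ]
  bv <- simulate_biv(m, f, cm, rv_site, lv_site)
  expect_equal(as.numeric(bv[attr(bv, "rv_node")]), 0)
  expect_equal(as.numeric(bv[attr(bv, "lv_node")]), 0)
  bv5 <- simulate_biv(m, f, cm, rv_site, lv_site, vv_delay = 5)
  expect_equal(as.numeric(bv5[attr(bv5, "lv_node")]), 5)
  # nodes the LV wavefront reaches well before the RV one shift by exactly +5
  lv_node <- attr(bv, "lv_node")
  d_lv <- sqrt(rowSums((m$nodes - matrix(m$nodes[lv_node, ], nrow(m$nodes), 3,
                                         byrow = TRUE))^2))
  early_lv <- which(as.numeric(bv) < 40 & d_lv < 20 &
                      as.numeric(bv5) - as.numeric(bv) > 4.999)
  expect_gt(length(early_lv), 0)
  expect_true(all(abs((as.numeric(bv5) - as.numeric(bv))[early_lv] - 5) < 1e-6))
  expect_error(simulate_biv(m, f, cm, rv_site, lv_site, stim_radius = 5),
               "stim_radius")
})

test_that("geodesic distances behave like distances", {
  m <- test_mesh()
  region <- m$surfaces$lv_epi[1:10]
  expect_equal(geodesic_distance(m, region[1], region), 0)
  expect_error(geodesic_distance(m, c(0, 0, 0), integer()), "empty")
  # enlarging the region cannot increase the distance
  far <- nearest_node(m, c(40, 0, -10))
  d_small <- geodesic_distance(m, far, region)
  d_big <- geodesic_distance(m, far, c(region, m$surfaces$lv_epi[11:30]))
  expect_lte(d_big, d_small + 1e-9)
  # flat sheet: corner-to-corner equals the Euclidean diagonal
  sheet <- generate_slab_mesh(30, 20, 2, h = 2)
  c1 <- nearest_node(sheet, c(0, 0, 0))
  c2 <- nearest_node(sheet, c(30, 20, 0))
  d <- geodesic_distance(sheet, c2, c1)
  expect_lt(abs(d - sqrt(30^2 + 20^2)) / sqrt(1300), 0.05)
})
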