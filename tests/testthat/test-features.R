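as_map <- function(x) structure(x, class = c("activation_map", "numeric"))

test_that("volume-percentile activation time matches its definition", {
  pm <- point_mesh(rep(0, 1000))
  act <- as_map(seq(0.1, 100, by = 0.1))
  expect_equal(tat_percentile(act, pm, p = 95), 95.0)
  expect_equal(tat_percentile(act, pm, p = 100), 100.0)
  cst <- as_map(rep(7, 1000))
  for (p in c(5, 50, 95)) expect_equal(tat_percentile(cst, pm, p = p), 7)
  expect_error(tat_percentile(act, pm, p = 0), "\\(0, 100\\]")
  # non-decreasing in p
  act2 <- as_map(runif(1000, 0, 50))
  ps <- seq(5, 100, by = 5)
  vals <- vapply(ps, function(p) tat_percentile(act2, pm, p = p), numeric(1))
  expect_true(all(diff(vals) >= 0))
  # volume weighting: duplicating elements at half volume changes nothing
  pm2 <- point_mesh(rep(0, 2000), volumes = rep(0.5, 2000))
  act_dup <- as_map(rep(as.numeric(act), 2))
  pm2$tets <- rbind(pm$tets, pm$tets)
  pm2$nodes <- pm$nodes
  pm2$ventricle <- rep("lv", 2000)
  expect_equal(tat_percentile(act, pm, p = 95),
               tat_percentile(as_map(c(as.numeric(act))), pm2, p = 95),
               tolerance = 1e-9)
})

test_that("inter-ventricular delay is the difference of per-ventricle maxima", {
  vent <- c(rep("lv", 3), rep("rv", 3))
  pm <- point_mesh(rep(0, 6), ventricle = vent)
  act <- as_map(c(120, 90, 100, 80, 60, 70))
  expect_equal(ad_rvlv(act, pm), 40)
  # mirrored maps give zero; swapped tags flip the sign
  act_m <- as_map(c(80, 60, 70, 80, 60, 70))
  expect_equal(ad_rvlv(act_m, pm), 0)
  pm_sw <- pm; pm_sw$ventricle <- rev(vent)
  expect_equal(ad_rvlv(act, pm_sw), -40)
})

test_that("septal-to-lateral index follows its closed form and bounds", {
  vent <- c(rep("lv", 2), rep("septum", 2), "rv")
  pm <- point_mesh(rep(0, 5), ventricle = vent)
  act <- as_map(c(60, 60, 40, 40, 100))
  expect_equal(ad_stlv(act, pm), (60 - 40) / 100)
  uni <- as_map(rep(33, 5))
  expect_equal(ad_stlv(uni, pm), 0)
  for (i in 1:20) {
    a <- as_map(runif(5, 0, 200))
    v <- ad_stlv(a, pm)
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("late-activation region is the top quantile and is nested", {
  pm <- point_mesh(rep(0, 50))
  act <- as_map(seq_len(50) * 2)
  r10 <- lat_region(act, pm, 0.10)
  expect_true(all(act[r10] >= quantile(as.numeric(act), 0.9)))
  r30 <- lat_region(act, pm, 0.30)
  expect_true(all(r10 %in% r30))
  expect_equal(sort(lat_region(act, pm, 1)), 1:50)
  expect_error(lat_region(act, pm, 0), "\\(0, 1\\]")
  # linear field: region concentrates at the late pole
  expect_true(all(r10 >= 45))
})

test_that("electrode delay is a plain difference with sign symmetry", {
  m <- test_mesh()
  lb <- test_lbbb()
  rv_node <- m$surfaces$rv_endo[1]
  lv_node <- m$surfaces$lv_epi[5]
  d <- rv_lv_delay(lb, m, rv_node, lv_node)
  expect_equal(d, as.numeric(lb[lv_node]) - as.numeric(lb[rv_node]))
  expect_equal(rv_lv_delay(lb, m, rv_node, rv_node), 0)
})

test_that("full feature extraction is complete, consistent and deterministic", {
  m <- test_mesh(); f <- test_fibers(); p <- test_parc()
  lab <- test_labels()
  lb <- test_lbbb()
  ecg_lb <- test_lbbb_ecg()
  rv_site <- default_rv_site(m)
  lvn <- m$surfaces$lv_epi
  lv_site <- m$nodes[lvn[which.max(m$nodes[lvn, 1])], ]
  bv <- simulate_biv(m, f, conduction_model(), rv_site, lv_site)
  ecg_bv <- compute_ecg(m, bv)

  ft <- extract_features(lb, bv, ecg_lb, ecg_bv, m, lab, p, rv_site, lv_site)
  expect_true(is.na(ft$scar_lvps))               # scar-free model
  others <- setdiff(names(ft), "scar_lvps")
  expect_no_na(as.numeric(ft[1, others]))
  expect_lte(ft$tat95_lbbb, ft$tat_lbbb)
  expect_gte(ft$lat_lvps, 0)
  expect_gte(ft$rvlv_dist, 0)

  # identical maps: all deltas vanish
  ft0 <- extract_features(lb, lb, ecg_lb, ecg_lb, m, lab, p, rv_site, lv_site)
  delta_cols <- grep("^delta_", names(ft0), value = TRUE)
  expect_true(all(abs(as.numeric(ft0[1, delta_cols])) < 1e-9))

  # determinism
  ft2 <- extract_features(lb, bv, ecg_lb, ecg_bv, m, lab, p, rv_site, lv_site)
  expect_identical(ft, ft2)

  # scarred model reports a finite scar distance
  lab_s <- label_tissue(m, p, scar_segments = 4)
  ft_s <- extract_features(lb, bv, ecg_lb, ecg_bv, m, lab_s, p, rv_site, lv_site)
  expect_false(is.na(ft_s$scar_lvps))
})

test_that("per-protocol conductivity personalization restores resynchronization", {
  # the pre/post QRSd targets fix protocol-specific conductivities, as in the
  # clinical pipeline; under those the paced heart activates faster
  co <- sample_cohort(cohort_spec(n = 2, seed = 7))
  patient <- co[1, ]
  patient$scar_segments <- list(integer())
  patient$fibrosis_segments <- list(integer())
  sim <- simulate_patient(patient)
  expect_lt(sim$features$tat95_biv, sim$features$tat95_lbbb)
  expect_lt(sim$features$qrsd_biv, sim$features$qrsd_lbbb)
  expect_gt(sim$model$kappa_biv$kappa, sim$model$kappa_lbbb$kappa)
})
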