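test_that("Einthoven identity holds to numerical precision", {
  ecg <- test_lbbb_ecg()
  expect_lt(max(abs(ecg$II - ecg$I - ecg$III)), 1e-9)
})

test_that("pseudo-ECG is linear, gradient-driven and translation invariant", {
  m <- test_mesh()
  lb <- test_lbbb()
  el <- standard_electrodes(m)
  L <- lead_field(m, el)
  ecg <- compute_ecg(m, lb, el, L = L)
  leads <- as.matrix(ecg[, -1])

  # spatially uniform activation: no gradients, (almost) no deflection
  uni <- structure(rep(50, nrow(m$nodes)), class = c("activation_map", "numeric"))
  ecg_u <- compute_ecg(m, uni, el, L = L)
  expect_lt(max(abs(as.matrix(ecg_u[, -1]))), 0.01 * max(abs(leads)))

  # doubling the template amplitude doubles every trace
  tpl2 <- ap_template(rest = -170, peak = 50)
  ecg2 <- compute_ecg(m, lb, el, template = tpl2, L = L)
  expect_equal(as.matrix(ecg2[, -1]), 2 * leads, tolerance = 1e-9)

  # rigid translation of heart + electrodes leaves the ECG unchanged
  m2 <- m
  shift <- c(25, -10, 40)
  m2$nodes <- m$nodes + matrix(shift, nrow(m$nodes), 3, byrow = TRUE)
  el2 <- el + matrix(shift, nrow(el), 3, byrow = TRUE)
  class(el2) <- class(el)
  ecg3 <- compute_ecg(m2, lb, el2)
  expect_equal(as.matrix(ecg3[, -1]), leads, tolerance = 1e-6)

  expect_error(compute_ecg(m, lb, el, dt = 0), "dt")
})

test_that("QRS detection recovers a constructed boxcar support", {
  # build traces whose across-lead RMS derivative is (nearly) a boxcar on
  # [20, 140]: a ramp in every lead between those times
  ts <- 0:300
  ramp <- pmin(pmax((ts - 20) / 120, 0), 1)
  ecg <- tibble::tibble(time = ts)
  for (nm in c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")) {
    ecg[[nm]] <- ramp * ifelse(nm %in% c("III", "aVR"), -1, 1)
  }
  ecg$III <- ecg$II - ecg$I
  class(ecg) <- c("crt_ecg", class(ecg))
  attr(ecg, "dt") <- 1
  q <- detect_qrs(ecg)
  expect_lt(abs(q$qrsd - 120), 1 + 1e-9)
  expect_lt(abs(q$onset - 20), 1 + 1e-9)

  # amplitude scaling: identical window (relative threshold)
  ecg10 <- ecg
  for (nm in names(ecg)[-1]) ecg10[[nm]] <- 10 * ecg[[nm]]
  class(ecg10) <- class(ecg); attr(ecg10, "dt") <- 1
  q10 <- detect_qrs(ecg10)
  expect_equal(q10$onset, q$onset)
  expect_equal(q10$qrsd, q$qrsd)

  # time shift: window translates, duration unchanged
  shift_ramp <- pmin(pmax((ts - 50) / 120, 0), 1)
  ecg_s <- ecg
  for (nm in names(ecg)[-1]) {
    ecg_s[[nm]] <- shift_ramp * ifelse(nm %in% c("III", "aVR"), -1, 1)
  }
  ecg_s$III <- ecg_s$II - ecg_s$I
  class(ecg_s) <- class(ecg); attr(ecg_s, "dt") <- 1
  q_s <- detect_qrs(ecg_s)
  expect_equal(q_s$onset - q$onset, 30)
  expect_equal(q_s$qrsd, q$qrsd)

  flat <- ecg
  for (nm in names(ecg)[-1]) flat[[nm]] <- 0
  class(flat) <- class(ecg); attr(flat, "dt") <- 1
  expect_error(detect_qrs(flat), "no QRS")
})

test_that("QRS duration is non-increasing in the conductivity multiplier", {
  m <- test_mesh(); f <- test_fibers(); tr <- test_tree()
  el <- standard_electrodes(m)
  L <- lead_field(m, el)
  q <- vapply(c(0.2, 0.5, 1.0, 1.25, 1.5), function(k) {
    act <- simulate_lbbb(m, f, conduction_model(kappa = k), tr)
    detect_qrs(compute_ecg(m, act, el, L = L))$qrsd
  }, numeric(1))
  expect_true(all(diff(q) <= 0))
  # default model sits in the calibrated LBBB range at kappa = 1
  expect_gt(q[3], 140)
  expect_lt(q[3], 195)
})

test_that("conductivity fitting recovers targets and flags the bounds", {
  m <- test_mesh(); f <- test_fibers(); tr <- test_tree()
  lab <- test_labels()
  proto <- list(type = "lbbb", tree = tr)
  q1 <- detect_qrs(compute_ecg(m, test_lbbb(), dt = 0.5,
                               template = ap_template(0.5)))$qrsd
  fit <- fit_conductivity(m, f, lab, proto, target_qrsd = q1, dt = 0.5)
  expect_false(fit$boundary)
  expect_lt(abs(fit$kappa - 1), 0.02)
  expect_lte(abs(fit$qrsd - q1), 2)
  # shorter target than the kappa=1 QRSd needs faster tissue
  fit2 <- fit_conductivity(m, f, lab, proto, target_qrsd = q1 - 15)
  expect_gt(fit2$kappa, 1)
  # unphysiologically short target pins the upper bound
  fit3 <- fit_conductivity(m, f, lab, proto, target_qrsd = 40)
  expect_true(fit3$boundary)
  expect_equal(fit3$kappa, conduction_model()$kappa_bounds[2])
  expect_error(fit_conductivity(m, f, lab, proto, target_qrsd = -10), "positive")
})
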