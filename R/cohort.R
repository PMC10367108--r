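#' Specification of a synthetic CRT cohort
#'
#' Defines the generative model for a synthetic patient cohort with the
#' statistical structure the response classifier assumes: clinical
#' covariates drawn from truncated normal distributions on the scale of a
#' typical CRT cohort (LVEF ~ N(26, 6) %, BMI ~ N(29, 5), EDD ~ N(66, 9) mm),
#' per-patient scar/fibrosis segments, reference pacing sites preferentially
#' in the lateral wall, pre- and post-implant target QRS durations for
#' conductivity personalization, and a ground-truth logistic model over the
#' seven default features generating the response labels.
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @param prevalence target response prevalence (intercept is calibrated to
#'   it).
#' @param scar_prob probability that a patient carries a scar.
#' @param fibrosis_prob probability of a fibrosis annotation.
#' @param beta named ground-truth coefficients on the standardized scale for
#'   the seven default features.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 57, seed = 1L, prevalence = 0.42,
                        scar_prob = 0.5, fibrosis_prob = 0.35,
                        beta = c(lvef = -0.4, bmi = -0.3, edd = -0.4,
                                 scar_lvps = 0.6, tat95_lbbb = 0.5,
                                 ad_rvlv_lbbb = 0.7, ad_rvlv_biv = -0.6)) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0,1)", call. = FALSE)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 prevalence = prevalence, scar_prob = scar_prob,
                 fibrosis_prob = fibrosis_prob, beta = beta,
                 covariates = list(
                   lvef = c(mean = 26, sd = 6, lo = 10, hi = 45),
                   bmi = c(mean = 29, sd = 5, lo = 16, hi = 45),
                   edd = c(mean = 66, sd = 9, lo = 45, hi = 90)
                 ),
                 qrsd_pre = c(mean = 180, sd = 15, lo = 160, hi = 220),
                 qrsd_reduction = c(mean = 22, sd = 10, lo = 0, hi = 50)),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Sample a synthetic cohort
#'
#' Draws the cohort defined by a [cohort_spec()]: covariates, tissue
#' annotations, reference pacing segments (lateral wall preferred, matching
#' clinical lead-placement practice), target QRS durations, latent simulated
#' dyssynchrony features (the statistical tier), the latent linear predictor
#' and the response labels. If a draw produces a single-class cohort it is
#' automatically redrawn with a shifted seed (logged).
#'
#' @param spec a `cohort_spec`.
#' @return tibble of class `crt_cohort`, one row per patient; the ground
#'   truth (`beta`, calibrated intercept) is attached as attributes.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- spec$seed
  for (attempt in 1:10) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    n <- spec$n
    cv <- spec$covariates
    non_septal <- setdiff(1:17, c(2L, 3L, 8L, 9L, 14L))
    lateral <- c(5L, 6L, 11L, 12L, 16L)
    draw_segs <- function(k) sample(non_septal, k)
    d <- tibble::tibble(
      patient = seq_len(n),
      lvef = rtrunc_norm(n, cv$lvef["mean"], cv$lvef["sd"], cv$lvef["lo"], cv$lvef["hi"]),
      bmi = rtrunc_norm(n, cv$bmi["mean"], cv$bmi["sd"], cv$bmi["lo"], cv$bmi["hi"]),
      edd = rtrunc_norm(n, cv$edd["mean"], cv$edd["sd"], cv$edd["lo"], cv$edd["hi"]),
      qrsd_pre = rtrunc_norm(n, spec$qrsd_pre["mean"], spec$qrsd_pre["sd"],
                             spec$qrsd_pre["lo"], spec$qrsd_pre["hi"]),
      has_scar = runif(n) < spec$scar_prob,
      has_fibrosis = runif(n) < spec$fibrosis_prob,
      # clinical lead placement: lateral wall in most patients
      ref_segment = ifelse(runif(n) < 0.88,
                           lateral[sample.int(length(lateral), n, replace = TRUE)],
                           non_septal[sample.int(length(non_septal), n, replace = TRUE)])
    )
    d$qrsd_post <- d$qrsd_pre - rtrunc_norm(n, spec$qrsd_reduction["mean"],
                                            spec$qrsd_reduction["sd"],
                                            spec$qrsd_reduction["lo"],
                                            spec$qrsd_reduction["hi"])
    d$scar_segments <- lapply(seq_len(n), function(i) {
      if (d$has_scar[i]) draw_segs(sample(1:2, 1)) else integer()
    })
    d$fibrosis_segments <- lapply(seq_len(n), function(i) {
      if (d$has_fibrosis[i]) draw_segs(1) else integer()
    })
    # latent simulated features (statistical tier), on the scales the
    # physics tier produces for this anatomy and conduction model
    d$tat95_lbbb <- rtrunc_norm(n, 167, 12, 120, 220)
    d$ad_rvlv_lbbb <- rnorm(n, 29, 11)
    d$ad_rvlv_biv <- rnorm(n, 29, 14)
    d$scar_lvps <- ifelse(d$has_scar, runif(n, 5, 45), NA_real_)

    b <- spec$beta
    feat <- d[names(b)]
    feat$scar_lvps[is.na(feat$scar_lvps)] <- max(feat$scar_lvps, na.rm = TRUE)
    z <- scale(as.matrix(feat))
    z[!is.finite(z)] <- 0        # degenerate columns at tiny n
    s <- as.numeric(z %*% b)
    b0 <- tryCatch(
      stats::uniroot(function(a) mean(plogis(a + s)) - spec$prevalence,
                     c(-20, 20))$root,
      error = function(e) qlogis(spec$prevalence))
    d$linear_predictor <- b0 + s
    d$response <- rbinom(n, 1, plogis(d$linear_predictor))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    if (length(unique(d$response)) == 2 || spec$prevalence < 0.05 ||
        spec$prevalence > 0.95 || n < 40) {
      attr(d, "beta") <- b
      attr(d, "intercept") <- b0
      attr(d, "seed") <- seed
      attr(d, "spec") <- spec
      class(d) <- c("crt_cohort", class(d))
      return(d)
    }
    message("single-class cohort drawn; resampling with shifted seed")
    seed <- seed + 1000L
  }
  stop("could not draw a two-class cohort", call. = FALSE)
}

#' Build a feature matrix and labels from a cohort
#'
#' Two tiers. The `statistical` tier returns the latent features drawn by the
#' generator directly (fast; isolates the statistical layer for classifier
#' tests). The `physics` tier runs the full per-patient model chain —
#' synthetic anatomy scaled by the patient's EDD, fibers, tissue labels,
#' right-bundle Purkinje tree, per-protocol conductivity personalization to
#' the patient's pre/post QRS durations, LBBB and BiV simulations at the
#' reference pacing sites, ECG synthesis and feature extraction — and joins
#' the result with the clinical covariates. Patients whose simulation fails
#' are dropped with a log message, never silently imputed.
#'
#' @param cohort a `crt_cohort`.
#' @param tier `"statistical"` or `"physics"`.
#' @param resolution mesh resolution for the physics tier.
#' @param verbose print per-patient progress.
#' @return list with `features` (tibble), `labels` (integer vector) and
#'   `cohort` (possibly reduced to simulated patients).
#' @export
make_dataset <- function(cohort, tier = c("statistical", "physics"),
                         resolution = 1, verbose = FALSE) {
  tier <- match.arg(tier)
  stopifnot(inherits(cohort, "crt_cohort"))
  if (tier == "statistical") {
    feats <- cohort[c("lvef", "bmi", "edd", "scar_lvps", "tat95_lbbb",
                      "ad_rvlv_lbbb", "ad_rvlv_biv")]
    return(list(features = tibble::as_tibble(feats),
                labels = cohort$response, cohort = cohort))
  }
  rows <- list(); kept <- integer()
  for (i in seq_len(nrow(cohort))) {
    res <- tryCatch(
      simulate_patient(cohort[i, ], resolution = resolution),
      error = function(e) {
        message("patient ", cohort$patient[i], " dropped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      rows[[length(rows) + 1L]] <- res$features
      kept <- c(kept, i)
    }
    if (verbose) message("patient ", cohort$patient[i], " done")
  }
  if (!length(rows)) stop("all patient simulations failed", call. = FALSE)
  feats <- dplyr::bind_rows(rows)
  clin <- cohort[kept, c("lvef", "bmi", "edd")]
  list(features = dplyr::bind_cols(clin, feats),
       labels = cohort$response[kept],
       cohort = cohort[kept, ])
}

#' Simulate one cohort patient end to end
#'
#' Builds the patient-specific model (anatomy scaled by EDD, scar/fibrosis
#' labels, right-bundle tree), personalizes the conductivity multiplier per
#' protocol against the patient's pre/post QRS durations, runs the LBBB and
#' BiV simulations at the reference pacing sites and extracts all simulated
#' features.
#'
#' @param patient one-row `crt_cohort` slice.
#' @param resolution mesh resolution.
#' @param max_fit_iter unused reserve for fit control.
#' @return list with `features` (one-row tibble), `model` (mesh, maps, fits).
#' @export
simulate_patient <- function(patient, resolution = 1, max_fit_iter = 30) {
  mesh <- generate_biventricular_mesh(
    lv_endo_radius = patient$edd / 2,
    lv_long_radius = 1.08 * patient$edd,
    resolution = resolution,
    seed = patient$patient
  )
  fibers <- assign_fibers(mesh)
  parc <- parcellate_aha(mesh)
  labels <- label_tissue(mesh, parc,
                         scar_segments = patient$scar_segments[[1]],
                         fibrosis_segments = patient$fibrosis_segments[[1]])
  tree <- generate_purkinje_tree(mesh, seed = patient$patient)
  rv_site <- default_rv_site(mesh)
  lv_site <- reference_lv_site(mesh, parc, labels, patient$ref_segment)

  fit_lb <- fit_conductivity(mesh, fibers, labels,
                             list(type = "lbbb", tree = tree),
                             target_qrsd = patient$qrsd_pre)
  fit_bv <- fit_conductivity(mesh, fibers, labels,
                             list(type = "biv", rv_site = rv_site,
                                  lv_site = lv_site),
                             target_qrsd = patient$qrsd_post)
  cm_lb <- conduction_model(kappa = fit_lb$kappa)
  cm_bv <- conduction_model(kappa = fit_bv$kappa)
  lbbb <- simulate_lbbb(mesh, fibers, cm_lb, tree, labels)
  biv <- simulate_biv(mesh, fibers, cm_bv, rv_site, lv_site, labels = labels)
  el <- standard_electrodes(mesh)
  L <- lead_field(mesh, el, labels)
  ecg_lb <- compute_ecg(mesh, lbbb, el, labels = labels, L = L)
  ecg_bv <- compute_ecg(mesh, biv, el, labels = labels, L = L)
  feats <- extract_features(lbbb, biv, ecg_lb, ecg_bv, mesh, labels, parc,
                            rv_site, lv_site)
  list(features = feats,
       model = list(mesh = mesh, fibers = fibers, parcellation = parc,
                    labels = labels, tree = tree, rv_site = rv_site,
                    lv_site = lv_site, kappa_lbbb = fit_lb, kappa_biv = fit_bv,
                    lbbb = lbbb, biv = biv, electrodes = el, lead_field = L))
}

#' Standard apical RV electrode position for a mesh
#'
#' @param mesh a `biv_mesh`.
#' @return coordinates (mm) of the apical septal RV endocardial target.
#' @export
default_rv_site <- function(mesh) {
  a <- mesh$params$lv_endo_radius + mesh$params$lv_wall
  cc <- mesh$params$lv_long_radius + mesh$params$lv_wall
  ctr <- mesh$base_center
  ctr + mesh$septal_axis * a + mesh$long_axis * (-0.64 * cc)
}

#' Reference LV pacing site at an AHA segment center
#'
#' Nearest eligible candidate-surface node to the epicardial centroid of the
#' requested segment; falls back to the nearest eligible node if the segment
#' itself is excluded (e.g. scarred).
#'
#' @param mesh,parcellation,labels patient anatomy.
#' @param segment AHA segment id.
#' @return coordinates (mm).
#' @export
reference_lv_site <- function(mesh, parcellation, labels, segment) {
  surf <- candidate_surface(mesh, parcellation, labels)
  ctr <- parcellation$centroids[segment, ]
  if (any(is.na(ctr))) ctr <- colMeans(as.matrix(surf[, c("x", "y", "z")]))
  sub <- surf[surf$segment == segment, ]
  if (!nrow(sub)) sub <- surf
  d2 <- (sub$x - ctr[1])^2 + (sub$y - ctr[2])^2 + (sub$z - ctr[3])^2
  as.numeric(sub[which.min(d2), c("x", "y", "z")])
}
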