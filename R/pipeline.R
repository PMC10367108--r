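#' Pipeline configuration
#'
#' Builds the validated configuration object used by [run_pipeline()] and the
#' command-line wrapper. Every constant of the modelling chain is overridable
#' here; unknown keys fail fast.
#'
#' @param ... overrides of the defaults listed below.
#' @return object of class `crt_config`.
#' @details Defaults: cohort (`n_patients` 5, `seed` 1, `prevalence` 0.42),
#'   geometry (`resolution` 1), conduction (`v_f` 0.7 mm/ms, `anisotropy` 4,
#'   `fibrosis_factor` 0.5, `kappa_bounds` 0.2-1.5), ECG (`dt` 1 ms,
#'   `qrs_threshold` 0.02, `qrs_debounce` 5 ms), classifier (`cutoff` 0.51,
#'   `cor_threshold` 0.85, `selector` "univariate", `n_select` 7), optimizer
#'   (`acq_beta` 2, `max_iter` 30, `map_threshold` 0.5, `lat_fraction` 0.1).
#' @export
crt_config <- function(...) {
  defaults <- list(
    out_dir = "crtsim-out",
    n_patients = 5L, seed = 1L, prevalence = 0.42,
    resolution = 1,
    v_f = 0.7, anisotropy = 4, fibrosis_factor = 0.5,
    kappa_bounds = c(0.2, 1.5),
    dt = 1, qrs_threshold = 0.02, qrs_debounce = 5,
    cutoff = 0.51, cor_threshold = 0.85, selector = "univariate",
    n_select = 7L,
    acq_beta = 2, max_iter = 30L, map_threshold = 0.5, lat_fraction = 0.1
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "crt_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a `crt_config`.
#' @param path file path.
#' @return the path (write) or a `crt_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(crt_config, yaml::read_yaml(path))
}

config_stamp <- function(config) {
  list(config_hash = rlang::hash(unclass(config)), seed = config$seed,
       timestamp = as.character(Sys.time()))
}

#' Run a pipeline stage
#'
#' Orchestrates the modelling chain on disk artifacts under
#' `config$out_dir`:
#' \describe{
#'   \item{synth}{draw the synthetic cohort, write `cohort.csv` +
#'     `manifest.yaml`.}
#'   \item{simulate}{run the physics tier per patient, write
#'     `features.csv`.}
#'   \item{features}{alias of simulate (features are extracted in the same
#'     pass).}
#'   \item{train}{leave-one-out CV + final model from `features.csv`;
#'     writes `model.yaml` and `cv_report.csv`.}
#'   \item{optimize}{Bayesian optimization of the LV site for one patient
#'     (`patient_id`); writes `optimization_<id>.yaml` and
#'     `score_map_<id>.csv`.}
#'   \item{report}{per-AHA-segment summary of a patient's score map.}
#' }
#' Every artifact embeds the config hash and seed that produced it.
#'
#' @param config a `crt_config`.
#' @param command one of synth, simulate, features, train, optimize, report.
#' @param patient_id patient for optimize/report.
#' @return invisibly, the main artifact path(s) of the stage.
#' @export
run_pipeline <- function(config, command = c("synth", "simulate", "features",
                                             "train", "optimize", "report"),
                         patient_id = 1L) {
  command <- match.arg(command)
  stopifnot(inherits(config, "crt_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    cohort = file.path(config$out_dir, "cohort.csv"),
    manifest = file.path(config$out_dir, "manifest.yaml"),
    features = file.path(config$out_dir, "features.csv"),
    model = file.path(config$out_dir, "model.yaml"),
    cv = file.path(config$out_dir, "cv_report.csv")
  )
  need <- function(p, producer) {
    if (!file.exists(p)) {
      stop("missing artifact ", p, "; run the '", producer,
           "' command first", call. = FALSE)
    }
  }
  cohort <- function() {
    spec <- cohort_spec(n = config$n_patients, seed = config$seed,
                        prevalence = config$prevalence)
    sample_cohort(spec)
  }

  if (command == "synth") {
    co <- cohort()
    flat <- co
    flat$scar_segments <- vapply(co$scar_segments, paste, "", collapse = ";")
    flat$fibrosis_segments <- vapply(co$fibrosis_segments, paste, "", collapse = ";")
    utils::write.csv(as.data.frame(flat), paths$cohort, row.names = FALSE)
    yaml::write_yaml(c(config_stamp(config),
                       list(n = nrow(co), responders = sum(co$response))),
                     paths$manifest)
    return(invisible(paths$cohort))
  }

  if (command %in% c("simulate", "features")) {
    co <- cohort()
    ds <- make_dataset(co, tier = "physics", resolution = config$resolution)
    out <- dplyr::bind_cols(
      tibble::tibble(patient = ds$cohort$patient),
      ds$features,
      tibble::tibble(response = ds$labels)
    )
    utils::write.csv(as.data.frame(out), paths$features, row.names = FALSE)
    yaml::write_yaml(c(config_stamp(config), list(stage = "simulate")),
                     file.path(config$out_dir, "features.log.yaml"))
    return(invisible(paths$features))
  }

  if (command == "train") {
    need(paths$features, "simulate")
    d <- utils::read.csv(paths$features)
    feats <- d[setdiff(names(d), c("patient", "response"))]
    cv <- loo_cv(feats, d$response, selector = config$selector,
                 n_select = min(config$n_select, ncol(feats)),
                 cutoff = config$cutoff, cor_threshold = config$cor_threshold)
    model_feats <- intersect(
      c("lvef", "bmi", "edd", "scar_lvps", "tat95_lbbb", "ad_rvlv_lbbb",
        "ad_rvlv_biv"), names(feats))
    model <- train_final(feats, d$response, features = model_feats,
                         cutoff = config$cutoff)
    write_lr_model(model, paths$model)
    utils::write.csv(as.data.frame(cv$scores), paths$cv, row.names = FALSE)
    yaml::write_yaml(c(config_stamp(config), glance(cv)),
                     file.path(config$out_dir, "cv_summary.yaml"))
    return(invisible(c(paths$model, paths$cv)))
  }

  if (command == "optimize") {
    need(paths$model, "train")
    model <- read_lr_model(paths$model)
    co <- cohort()
    patient <- co[co$patient == patient_id, ]
    if (!nrow(patient)) stop("unknown patient id ", patient_id, call. = FALSE)
    sim <- simulate_patient(patient, resolution = config$resolution)
    opt <- optimize_reference_patient(sim, patient, model,
                                      max_iter = config$max_iter,
                                      cutoff = config$cutoff,
                                      map_threshold = config$map_threshold)
    opath <- file.path(config$out_dir,
                       sprintf("optimization_%d.yaml", patient_id))
    spath <- file.path(config$out_dir,
                       sprintf("score_map_%d.csv", patient_id))
    yaml::write_yaml(c(config_stamp(config), list(
      patient = patient_id, opt_node = opt$opt_node,
      opt_coords = as.numeric(opt$opt_coords),
      max_score = opt$max_score, converged = opt$converged,
      n_evaluations = opt$n_evaluations, d_ps = opt$d_ps,
      classification = opt$classification
    )), opath)
    utils::write.csv(as.data.frame(opt$score_map), spath, row.names = FALSE)
    return(invisible(c(opath, spath)))
  }

  # report
  spath <- file.path(config$out_dir, sprintf("score_map_%d.csv", patient_id))
  need(spath, "optimize")
  sm <- tibble::as_tibble(utils::read.csv(spath))
  summ <- aha_summary(sm)
  rpath <- file.path(config$out_dir, sprintf("aha_report_%d.csv", patient_id))
  utils::write.csv(as.data.frame(summ), rpath, row.names = FALSE)
  invisible(rpath)
}

#' Bayesian-optimize the LV site of a simulated patient
#'
#' Wires a simulated patient model and a trained classifier into the site
#' evaluator expected by [optimize_pacing_site()]: for each candidate LV
#' site, the BiV activation map is recomputed at the patient's personalized
#' BiV conductivity, features are re-extracted and scored by the classifier.
#'
#' @param sim result of [simulate_patient()].
#' @param patient the matching one-row cohort slice.
#' @param model a `crt_lr`.
#' @param ... passed to [optimize_pacing_site()].
#' @param cutoff,map_threshold,max_iter optimizer settings.
#' @return a `crt_opt` (with `d_ps` to the patient's reference site).
#' @export
optimize_reference_patient <- function(sim, patient, model, max_iter = 30,
                                       cutoff = 0.51, map_threshold = 0.5,
                                       ...) {
  md <- sim$model
  parc <- md$parcellation
  surf <- candidate_surface(md$mesh, parc, md$labels)
  cm_bv <- conduction_model(kappa = md$kappa_biv$kappa)
  ecg_lb <- compute_ecg(md$mesh, md$lbbb, md$electrodes, labels = md$labels,
                        L = md$lead_field)
  evaluator <- function(node, coords) {
    biv <- simulate_biv(md$mesh, md$fibers, cm_bv, md$rv_site, coords,
                        labels = md$labels)
    ecg_bv <- compute_ecg(md$mesh, biv, md$electrodes, labels = md$labels,
                          L = md$lead_field)
    f <- extract_features(md$lbbb, biv, ecg_lb, ecg_bv, md$mesh, md$labels,
                          parc, md$rv_site, coords)
    rec <- c(as.list(f),
             list(lvef = patient$lvef, bmi = patient$bmi, edd = patient$edd))
    ml_score(model, rec)
  }
  optimize_pacing_site(surf, parc, evaluator, max_iter = max_iter,
                       cutoff = cutoff, map_threshold = map_threshold,
                       mesh = md$mesh, ref_site = md$lv_site, ...)
}
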