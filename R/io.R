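#' Write a mesh and its data fields as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK format (tetrahedra, cell type 10) with optional per-node
#' (`POINT_DATA`) and per-element (`CELL_DATA`) scalar arrays. Activation
#' maps are written with unreached nodes as the reserved sentinel value -1,
#' noted in the file header comment.
#'
#' @param mesh a `biv_mesh`.
#' @param path output file path.
#' @param point_data named list of per-node numeric vectors.
#' @param cell_data named list of per-element numeric (or factor/character)
#'   vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "crtsim biventricular model (unreached sentinel = -1)",
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(apply(cbind(4L, mesh$tets - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  fmt_num <- function(v) {
    v <- as.numeric(v)
    v[is.na(v)] <- -1
    format(v, digits = 10, trim = TRUE, scientific = FALSE)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(point_data[[nm]]), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.character(v) || is.factor(v)) v <- as.integer(factor(v))
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(v), con)
    }
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [write_vtk()]
#'
#' @param path file path.
#' @return list with `nodes`, `tets`, `point_data`, `cell_data` (sentinel -1
#'   restored to `NA` is left to the caller, since -1 is documented as the
#'   unreached value).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ptr <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ptr], " ")[[1]][2])
  nodes <- do.call(rbind, lapply(lines[(ptr + 1):(ptr + n)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  cptr <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[cptr], " ")[[1]][2])
  tets <- do.call(rbind, lapply(lines[(cptr + 1):(cptr + m)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]])[-1] + 1L))
  read_arrays <- function(start, count) {
    out <- list()
    i <- start
    while (!is.na(i) && i <= length(lines)) {
      if (grepl("^SCALARS", lines[i])) {
        nm <- strsplit(lines[i], " ")[[1]][2]
        vals <- as.numeric(lines[(i + 2):(i + 1 + count)])
        out[[nm]] <- vals
        i <- i + 2 + count
      } else if (grepl("^(POINT_DATA|CELL_DATA)", lines[i])) {
        break
      } else i <- i + 1
    }
    out
  }
  pd <- grep("^POINT_DATA", lines)[1]
  cd <- grep("^CELL_DATA", lines)[1]
  list(nodes = nodes, tets = tets,
       point_data = if (!is.na(pd)) read_arrays(pd + 1, n) else list(),
       cell_data = if (!is.na(cd)) read_arrays(cd + 1, m) else list())
}

#' Serialize a Purkinje tree as an edge-list file
#'
#' Plain-text YAML with node coordinates, the directed edge list with
#' lengths, and the terminal-to-mesh-node coupling map.
#'
#' @param tree a `purkinje_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_purkinje_tree <- function(tree, path) {
  yaml::write_yaml(list(
    v_purkinje = tree$v_purkinje, side = tree$side, seed = tree$seed,
    root = tree$root,
    nodes = apply(tree$nodes, 1, function(r) as.numeric(r), simplify = FALSE),
    edges = as.list(as.data.frame(tree$edges)),
    terminals = tree$terminals, pmj = tree$pmj
  ), path, precision = 15)
  invisible(path)
}

#' Read a Purkinje tree edge-list file
#' @param path file path.
#' @return a `purkinje_tree`.
#' @export
read_purkinje_tree <- function(path) {
  d <- yaml::read_yaml(path)
  structure(list(
    nodes = do.call(rbind, d$nodes),
    edges = data.frame(from = as.integer(d$edges$from),
                       to = as.integer(d$edges$to),
                       length = as.numeric(d$edges$length)),
    root = as.integer(d$root),
    terminals = as.integer(d$terminals),
    pmj = as.integer(d$pmj),
    v_purkinje = d$v_purkinje, side = d$side, seed = as.integer(d$seed)
  ), class = "purkinje_tree")
}

#' Serialize a fitted logistic response model
#'
#' Structured YAML: feature names, normalization statistics, coefficients
#' and the classification cutoff — everything needed to reproduce the
#' transform exactly.
#'
#' @param model a `crt_lr`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lr_model <- function(model, path) {
  yaml::write_yaml(list(
    features = model$features,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    center = as.list(model$center),
    scale = as.list(model$scale),
    impute = as.list(model$impute),
    cutoff = model$cutoff, n = model$n
  ), path, precision = 15)
  invisible(path)
}

#' Read a serialized logistic response model
#' @param path file path.
#' @return a `crt_lr`.
#' @export
read_lr_model <- function(path) {
  d <- yaml::read_yaml(path)
  structure(list(
    features = unlist(d$features),
    coefficients = unlist(d$coefficients),
    intercept = d$intercept,
    center = unlist(d$center),
    scale = unlist(d$scale),
    impute = unlist(d$impute),
    cutoff = d$cutoff, n = d$n
  ), class = "crt_lr")
}

#' Write a 12-lead ECG as CSV
#'
#' Fixed column order: `time, I, II, III, aVR, aVL, aVF, V1..V6`.
#' @param ecg a `crt_ecg`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(ecg, path) {
  utils::write.csv(as.data.frame(ecg), path, row.names = FALSE)
  invisible(path)
}

#' Per-AHA-segment summary of a predicted score map
#'
#' @param score_map the `score_map` tibble of a `crt_opt`.
#' @return tibble with one row per segment: mean and max predicted value,
#'   node count.
#' @export
aha_summary <- function(score_map) {
  value_col <- if ("ml_score" %in% names(score_map)) "ml_score" else "tat95"
  score_map |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(mean = mean(.data[[value_col]]),
                     max = max(.data[[value_col]]),
                     n_nodes = dplyr::n(), .groups = "drop")
}
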