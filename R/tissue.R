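#' Label scar and fibrosis tissue by AHA segment
#'
#' Applies expert-annotation-style tissue classes at whole-segment,
#' transmural granularity: every LV element belonging to a listed segment is
#' labeled `scar` (non-conducting, non-excitable) or `fibrosis` (conductivity
#' halved downstream). Scar takes precedence when a segment appears in both
#' lists; all remaining elements are `healthy`.
#'
#' @param mesh a `biv_mesh`.
#' @param parcellation an `aha_parcellation`.
#' @param scar_segments integer AHA ids (1..17) labeled as scar.
#' @param fibrosis_segments integer AHA ids labeled as fibrosis.
#' @return character vector of per-element classes, class `tissue_labels`.
#' @export
label_tissue <- function(mesh, parcellation, scar_segments = integer(),
                         fibrosis_segments = integer()) {
  stopifnot(inherits(mesh, "biv_mesh"), inherits(parcellation, "aha_parcellation"))
  ids <- c(scar_segments, fibrosis_segments)
  if (length(ids) && (any(ids < 1 | ids > 17) || any(ids != round(ids)))) {
    stop("unknown AHA segment id: ",
         paste(ids[ids < 1 | ids > 17 | ids != round(ids)], collapse = ", "),
         call. = FALSE)
  }
  lab <- rep("healthy", nrow(mesh$tets))
  seg <- parcellation$elem_segment
  lab[!is.na(seg) & seg %in% fibrosis_segments] <- "fibrosis"
  lab[!is.na(seg) & seg %in% scar_segments] <- "scar"
  structure(lab, class = c("tissue_labels", "character"))
}

#' Volume fractions of scar and fibrosis tissue
#'
#' @param mesh a `biv_mesh`.
#' @param labels a `tissue_labels` vector.
#' @return tibble with `scar_fraction`, `fibrosis_fraction`,
#'   `healthy_fraction` (volume-weighted, summing to 1).
#' @export
tissue_volume_fractions <- function(mesh, labels) {
  stopifnot(length(labels) == nrow(mesh$tets))
  v <- mesh$volumes
  tot <- sum(v)
  tibble::tibble(
    scar_fraction = sum(v[labels == "scar"]) / tot,
    fibrosis_fraction = sum(v[labels == "fibrosis"]) / tot,
    healthy_fraction = sum(v[labels == "healthy"]) / tot
  )
}
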