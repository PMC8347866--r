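#' Annotation configuration for intact-mass matching
#'
#' Tolerances for proteoform annotation of deconvoluted intact-protein
#' features: masses are matched within +/- `mass_tol` Da and retention
#' times gated within +/- `rt_tol` minutes.
#'
#' @param mass_tol mass window half-width, Da (default 1.0).
#' @param rt_tol retention-time window half-width, minutes (default 1.0).
#' @param rt_gate which database-annotated features anchor the RT gate for
#'   theoretical matches: `"any"` (default; any identified proteoform of the
#'   protein in the same run) or `"same_backbone"` (only those with the same
#'   phospho count).
#' @return a list of class `annotation_config`.
#' @export
annotation_config <- function(mass_tol = 1.0, rt_tol = 1.0,
                              rt_gate = c("any", "same_backbone")) {
  rt_gate <- match.arg(rt_gate)
  if (!is.numeric(mass_tol) || mass_tol <= 0) stop("mass_tol must be > 0", call. = FALSE)
  if (!is.numeric(rt_tol) || rt_tol <= 0) stop("rt_tol must be > 0", call. = FALSE)
  structure(list(mass_tol = mass_tol, rt_tol = rt_tol, rt_gate = rt_gate),
            class = "annotation_config")
}

.check_features <- function(features) {
  need <- c("mass", "rt", "intensity")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(features$run_id)) features$run_id <- "run1"
  if (is.null(features$resolution_mode)) features$resolution_mode <- "high"
  if (any(features$mass <= 0, na.rm = TRUE)) stop("feature masses must be > 0", call. = FALSE)
  if (any(features$intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0", call. = FALSE)
  features
}

.blank_annotation <- function(features) {
  n <- nrow(features)
  features$proteoform_label <- rep(NA_character_, n)
  features$method <- rep("unannotated", n)
  features$mass_error <- rep(NA_real_, n)
  features$ambiguity <- rep(0L, n)
  features$normalized_intensity <- rep(NA_real_, n)
  features
}

#' Annotate features against a PrSM identification table
#'
#' A feature is annotated `method = "database"` when at least one
#' proteoform-spectrum match (PrSM) lies within the mass window and within
#' the retention-time window, in the same run. Among candidates the nearest
#' precursor mass wins; the number of in-window candidates is recorded as
#' `ambiguity`, and `mass_error` is the signed PrSM-minus-feature mass
#' difference.
#'
#' @param features data frame of deconvoluted features with columns `mass`
#'   (Da), `rt` (min), `intensity`, and optionally `run_id`,
#'   `resolution_mode`.
#' @param prsm_table data frame with columns `proteoform_label`,
#'   `precursor_mass`, `rt`, and optionally `run_id`.
#' @param cfg an [annotation_config()].
#' @return the feature table with annotation columns `proteoform_label`,
#'   `method`, `mass_error`, `ambiguity` added; unmatched features pass
#'   through with `method = "unannotated"`.
#' @export
match_to_prsm <- function(features, prsm_table, cfg = annotation_config()) {
  features <- .check_features(features)
  ann <- .blank_annotation(features)
  if (is.null(prsm_table) || nrow(prsm_table) == 0L) return(ann)
  if (is.null(prsm_table$run_id)) prsm_table$run_id <- "run1"
  if (any(prsm_table$precursor_mass <= 0)) {
    stop("PrSM precursor masses must be > 0", call. = FALSE)
  }
  for (i in seq_len(nrow(ann))) {
    cand <- prsm_table[prsm_table$run_id == ann$run_id[i], , drop = FALSE]
    dm <- cand$precursor_mass - ann$mass[i]
    drt <- cand$rt - ann$rt[i]
    ok <- abs(dm) <= cfg$mass_tol & abs(drt) <= cfg$rt_tol
    if (!any(ok)) next
    dm <- dm[ok]; cand <- cand[ok, , drop = FALSE]
    best <- order(abs(dm))[1]
    ann$proteoform_label[i] <- cand$proteoform_label[best]
    ann$method[i] <- "database"
    ann$mass_error[i] <- dm[best]
    ann$ambiguity[i] <- sum(ok)
  }
  ann
}

#' Annotate remaining features by theoretical library mass
#'
#' Features not already database-annotated gain `method = "theoretical"`
#' when a library entry lies within the mass window *and* the feature
#' elutes within the RT window of at least one database-annotated feature
#' of the same run. High-resolution features are matched against
#' monoisotopic library masses, low-resolution against average masses.
#' Ties on |mass delta| prefer fewer total modifications, then the
#' lexicographically smaller label.
#'
#' @param annotations output of [match_to_prsm()] (annotation columns
#'   present).
#' @param lib a `proteoform_library`.
#' @param cfg an [annotation_config()].
#' @return the annotation table with theoretical annotations filled in.
#' @export
match_to_library <- function(annotations, lib, cfg = annotation_config()) {
  stopifnot(inherits(lib, "proteoform_library"))
  if (nrow(lib) == 0L) stop("empty proteoform library", call. = FALSE)
  if (is.null(annotations$method)) {
    stop("run match_to_prsm() first (annotation columns missing)", call. = FALSE)
  }
  if (nrow(annotations) == 0L) return(annotations)
  idx_mono <- mass_index(lib, "mono")
  idx_avg <- mass_index(lib, "avg")
  anchors <- annotations[annotations$method == "database", , drop = FALSE]
  for (i in seq_len(nrow(annotations))) {
    if (annotations$method[i] != "unannotated") next
    idx <- if (identical(annotations$resolution_mode[i], "low")) idx_avg else idx_mono
    hits <- query_mass(idx, annotations$mass[i], cfg$mass_tol)
    if (nrow(hits) == 0L) next
    anch <- anchors[anchors$run_id == annotations$run_id[i], , drop = FALSE]
    if (cfg$rt_gate == "same_backbone") {
      p <- sub("P.*$", "", hits$label[1])
      anch <- anch[sub("P.*$", "", anch$proteoform_label) == p, , drop = FALSE]
    }
    if (nrow(anch) == 0L) next
    if (!any(abs(anch$rt - annotations$rt[i]) <= cfg$rt_tol)) next
    annotations$proteoform_label[i] <- hits$label[1]
    annotations$method[i] <- "theoretical"
    annotations$mass_error[i] <- hits$delta[1]
    annotations$ambiguity[i] <- nrow(hits)
  }
  annotations
}

#' Normalize annotated proteoform intensities
#'
#' Each annotated feature's intensity is divided by the summed intensity of
#' all annotated features of the protein (per run), so normalized
#' intensities sum to one per run. Unannotated features keep `NA`.
#'
#' @param annotations annotation table (after matching).
#' @return the table with `normalized_intensity` populated.
#' @export
normalize_intensities <- function(annotations) {
  ann_rows <- annotations$method != "unannotated"
  if (!any(ann_rows)) stop("no annotated features to normalize", call. = FALSE)
  for (run in unique(annotations$run_id[ann_rows])) {
    sel <- ann_rows & annotations$run_id == run
    total <- sum(annotations$intensity[sel])
    if (total <= 0) {
      stop("all annotated intensities are zero in run ", run, call. = FALSE)
    }
    annotations$normalized_intensity[sel] <- annotations$intensity[sel] / total
  }
  annotations
}

#' Annotate an intact run end to end
#'
#' Convenience wrapper: [match_to_prsm()], then [match_to_library()], then
#' [normalize_intensities()]. Database identification always pre-empts
#' theoretical matching for a given feature.
#'
#' @inheritParams match_to_prsm
#' @param lib a `proteoform_library`.
#' @return fully annotated feature table.
#' @export
annotate_intact <- function(features, prsm_table, lib, cfg = annotation_config()) {
  ann <- match_to_prsm(features, prsm_table, cfg)
  ann <- match_to_library(ann, lib, cfg)
  normalize_intensities(ann)
}
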