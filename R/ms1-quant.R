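#' Glycosylated fraction from MS1 peptidoform areas
#'
#' Area-based occupancy for one peptide span (and usually one week):
#' summed area of glycosylated peptidoforms divided by the summed area of
#' all peptidoforms. Singly and doubly glycosylated forms both count as
#' glycoforms; the per-form detail stays in the input table. The fraction
#' is invariant to rescaling all areas by a common factor.
#'
#' @param areas data frame with columns `area` and `mods` (serialized
#'   modification strings; a row is a glycoform when `mods` contains a
#'   glycan), or columns `area` and logical `is_glyco`.
#' @return fraction in `[0, 1]`.
#' @examples
#' glyco_fraction(data.frame(area = c(95, 5), is_glyco = c(FALSE, TRUE)))  # 0.05
#' @export
glyco_fraction <- function(areas) {
  if (is.null(areas$area)) stop("areas table needs an 'area' column", call. = FALSE)
  if (any(areas$area < 0)) stop("areas must be >= 0", call. = FALSE)
  total <- sum(areas$area)
  if (nrow(areas) == 0L || total <= 0) {
    stop("degenerate input: total MS1 area is zero", call. = FALSE)
  }
  if (!is.null(areas$is_glyco)) {
    gly <- as.logical(areas$is_glyco)
  } else if (!is.null(areas$mods)) {
    gly <- grepl(":glycan", areas$mods, fixed = TRUE)
  } else {
    stop("areas table needs 'is_glyco' or 'mods'", call. = FALSE)
  }
  sum(areas$area[gly]) / total
}

#' Glyco fraction per span, week, donor and dataset
#'
#' Groupwise application of [glyco_fraction()] over a full peptidoform
#' area table.
#'
#' @param areas data frame with `start`, `end`, `area`, `mods` (or
#'   `is_glyco`), and optionally `donor`, `week`, `dataset`.
#' @return data frame with one row per group and a `glyco_fraction` column.
#' @export
glyco_fraction_table <- function(areas) {
  for (col in c("donor", "week", "dataset")) {
    if (is.null(areas[[col]])) areas[[col]] <- NA
  }
  key <- interaction(areas$start, areas$end, areas$donor, areas$week,
                     areas$dataset, drop = TRUE, lex.order = TRUE)
  out <- lapply(levels(key), function(k) {
    sub <- areas[key == k, , drop = FALSE]
    data.frame(start = sub$start[1], end = sub$end[1], donor = sub$donor[1],
               week = sub$week[1], dataset = sub$dataset[1],
               glyco_fraction = glyco_fraction(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group peptidoforms into C-terminal ladder series
#'
#' Endogenous beta-casein peptides form "ladders": families sharing one
#' C-terminal end position with progressively trimmed N-termini. Rows are
#' grouped by `end`; within a series, members are ordered by ascending
#' `start`.
#'
#' @param peptidoforms data frame with at least `start` and `end`.
#' @return list of class `ladder_series_set`, one element per shared end
#'   position (named by it); each element is the corresponding sub-table
#'   sorted by `start`, with attribute `starts` (the distinct member
#'   starts).
#' @export
build_ladder <- function(peptidoforms) {
  if (nrow(peptidoforms) == 0L) {
    return(structure(list(), class = "ladder_series_set"))
  }
  ends <- sort(unique(peptidoforms$end))
  out <- lapply(ends, function(e) {
    sub <- peptidoforms[peptidoforms$end == e, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    rownames(sub) <- NULL
    attr(sub, "starts") <- sort(unique(sub$start))
    sub
  })
  names(out) <- as.character(ends)
  structure(out, class = "ladder_series_set")
}

#' @export
print.ladder_series_set <- function(x, ...) {
  cat(sprintf("<ladder series set> %d shared C-termini\n", length(x)))
  for (e in names(x)) {
    cat(sprintf("  end %s: starts %s\n", e,
                paste(attr(x[[e]], "starts"), collapse = ", ")))
  }
  invisible(x)
}
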