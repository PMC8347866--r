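#' Default beta-casein PTM site set
#'
#' The ten Ser/Thr positions routinely profiled on mature beta-casein, in
#' precursor (signal-peptide-inclusive) numbering: the N-terminal
#' phosphorylation cluster Thr18, Ser21, Ser23, Ser24, Ser25, Ser28, Thr30
#' and the C-terminal region Thr207, Thr214, Ser225. Positions are a
#' configurable default, not hard-wired into any computation.
#'
#' @return named integer vector; names are residue-letter + position labels
#'   (e.g. `"S24"`).
#' @export
beta_casein_sites <- function() {
  c(T18 = 18L, S21 = 21L, S23 = 23L, S24 = 24L, S25 = 25L,
    S28 = 28L, T30 = 30L, T207 = 207L, T214 = 214L, S225 = 225L)
}

.site_vector <- function(sites) {
  sites <- stats::setNames(as.integer(sites), names(sites))
  if (is.null(names(sites)) || any(!nzchar(names(sites)))) {
    stop("sites must be a named integer vector (e.g. c(S24 = 24))", call. = FALSE)
  }
  sites
}

#' Per-site PTM occupancy table from curated PSMs
#'
#' PSM counting: for each (site, donor, week, dataset) cell, `n_covering`
#' is the number of curated PSMs whose peptide span contains the site,
#' `n_phospho` / `n_glyco` the numbers of those with a localized
#' phosphorylation / glycan at the site, and occupancy the modified
#' fraction of detections. Cells with no covering PSM emit no record.
#' PSMs flagged by [flag_implausible_glyco()] contribute to coverage but
#' their glycan localizations are excluded (switch with `exclude_flagged`).
#'
#' @param psms curated (and ideally flagged) PSM data frame.
#' @param sites named integer vector of precursor positions (default
#'   [beta_casein_sites()]).
#' @param reference optional `aa_sequence` in precursor coordinates; when
#'   given, each site must be Ser/Thr in it.
#' @param exclude_flagged drop flagged glycan localizations from `n_glyco`
#'   (default TRUE; needs the flag columns to be present).
#' @return data frame of class `site_occupancy` with columns `site`,
#'   `position`, `donor`, `week`, `dataset`, `n_covering`, `n_phospho`,
#'   `n_glyco`, `occupancy_phospho`, `occupancy_glyco`.
#' @export
occupancy_table <- function(psms, sites = beta_casein_sites(),
                            reference = NULL, exclude_flagged = TRUE) {
  psms <- .check_psm_table(psms)
  sites <- .site_vector(sites)
  if (!is.null(reference)) {
    res <- residue_at(reference, sites)
    bad <- !res %in% c("S", "T")
    if (any(bad)) {
      stop("site(s) not Ser/Thr in the reference: ",
           paste(names(sites)[bad], collapse = ", "), call. = FALSE)
    }
  }
  for (col in c("donor", "week", "dataset")) {
    if (is.null(psms[[col]])) psms[[col]] <- NA
  }
  pm <- parse_mods(psms$mods)
  if (exclude_flagged && !is.null(psms$flag_excess_glycans)) {
    flagged <- psms$flag_excess_glycans | psms$flag_nterm_glyco
    pm <- pm[!(pm$kind == "glycan" & flagged[pm$row]), , drop = FALSE]
  }
  out <- list()
  group <- interaction(psms$donor, psms$week, psms$dataset, drop = TRUE, lex.order = TRUE)
  for (g in levels(group)) {
    rows <- which(group == g)
    sub <- psms[rows, , drop = FALSE]
    sub_mods <- pm[pm$row %in% rows, , drop = FALSE]
    for (s in seq_along(sites)) {
      pos <- sites[s]
      cov <- sub$start <= pos & sub$end >= pos
      n_cov <- sum(cov)
      if (n_cov == 0L) next
      at_site <- sub_mods[sub_mods$site == pos & sub_mods$row %in% rows[cov], , drop = FALSE]
      n_p <- sum(at_site$kind == "phospho")
      n_g <- sum(at_site$kind == "glycan")
      out[[length(out) + 1L]] <- data.frame(
        site = names(sites)[s], position = pos,
        donor = sub$donor[1], week = sub$week[1], dataset = sub$dataset[1],
        n_covering = n_cov, n_phospho = n_p, n_glyco = n_g,
        occupancy_phospho = n_p / n_cov, occupancy_glyco = n_g / n_cov,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    out <- data.frame(site = character(), position = integer(), donor = integer(),
                      week = integer(), dataset = character(), n_covering = integer(),
                      n_phospho = integer(), n_glyco = integer(),
                      occupancy_phospho = numeric(), occupancy_glyco = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, out)
  }
  rownames(out) <- NULL
  class(out) <- c("site_occupancy", "data.frame")
  out
}

# round half away from zero, the convention used for reported PSM means
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Mean modified-PSM count per sampling week
#'
#' Lactation-wide total of modified PSMs at one site divided by the number
#' of sampling weeks (nine in the underlying longitudinal design), rounded
#' half-up to the nearest integer. This is the "mean PSMs per time point"
#' summary used for reporting site abundance.
#'
#' @param records a `site_occupancy` table (or any data frame with `site`,
#'   `donor`, `dataset` and the count column).
#' @param site site label (e.g. `"T214"`).
#' @param donor donor identifier.
#' @param dataset `"proteome"` or `"peptidome"`.
#' @param mod `"glyco"` (default) or `"phospho"`: which count to average.
#' @param n_weeks number of sampling weeks (default 9).
#' @return integer mean per-week modified-PSM count.
#' @examples
#' recs <- data.frame(site = "T207", donor = 1, dataset = "proteome",
#'                    n_glyco = 813)
#' mean_site_psms(recs, "T207", 1, "proteome")   # 90
#' @export
mean_site_psms <- function(records, site, donor, dataset,
                           mod = c("glyco", "phospho"), n_weeks = 9L) {
  mod <- match.arg(mod)
  if (n_weeks < 1L) stop("need at least one sampling week", call. = FALSE)
  sel <- records$site == site & records$donor == donor & records$dataset == dataset
  if (!any(sel)) stop("no records for the requested site/donor/dataset", call. = FALSE)
  col <- if (mod == "glyco") "n_glyco" else "n_phospho"
  total <- sum(records[[col]][sel])
  as.integer(round_half_up(total / n_weeks))
}

#' Rank sites by total phospho-PSM count
#'
#' @param records a `site_occupancy` table.
#' @param donor donor identifier.
#' @param dataset dataset identifier.
#' @return data frame with `site`, `position`, `n_phospho`, ordered by
#'   descending count; ties broken by ascending position.
#' @export
phosphosite_rank <- function(records, donor, dataset) {
  sel <- records$donor == donor & records$dataset == dataset
  sub <- records[sel, , drop = FALSE]
  if (nrow(sub) == 0L || sum(sub$n_phospho) == 0L) {
    stop("no phospho PSMs for the requested donor/dataset", call. = FALSE)
  }
  agg <- stats::aggregate(n_phospho ~ site + position, data = sub, FUN = sum)
  agg <- agg[order(-agg$n_phospho, agg$position), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("site", "position", "n_phospho")]
}

#' Per-site glycan species breakdown
#'
#' Partitions localized (unflagged) glycan PSMs at each site by canonical
#' glycan composition, per donor and dataset — the stacked-bar view of
#' which species occupy each glycosite.
#'
#' @param psms curated, flagged PSM data frame.
#' @param sites named integer vector of precursor positions.
#' @param exclude_flagged as in [occupancy_table()].
#' @return data frame with columns `site`, `position`, `donor`, `dataset`,
#'   `glycan`, `n_psms`. Sites with no glycan PSMs contribute no rows.
#' @export
glycan_species_breakdown <- function(psms, sites = beta_casein_sites(),
                                     exclude_flagged = TRUE) {
  psms <- .check_psm_table(psms)
  sites <- .site_vector(sites)
  for (col in c("donor", "dataset")) {
    if (is.null(psms[[col]])) psms[[col]] <- NA
  }
  pm <- parse_mods(psms$mods)
  pm <- pm[pm$kind == "glycan", , drop = FALSE]
  if (exclude_flagged && !is.null(psms$flag_excess_glycans)) {
    flagged <- psms$flag_excess_glycans | psms$flag_nterm_glyco
    pm <- pm[!flagged[pm$row], , drop = FALSE]
  }
  pm <- pm[pm$site %in% sites, , drop = FALSE]
  if (nrow(pm) == 0L) {
    return(data.frame(site = character(), position = integer(), donor = integer(),
                      dataset = character(), glycan = character(),
                      n_psms = integer(), stringsAsFactors = FALSE))
  }
  pm$glycan <- vapply(pm$glycan, function(g) format_glycan_composition(g), character(1))
  df <- data.frame(position = pm$site,
                   donor = psms$donor[pm$row],
                   dataset = psms$dataset[pm$row],
                   glycan = pm$glycan,
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(n_psms = rep(1L, nrow(df))) ~ position + donor + dataset + glycan,
                          data = df, FUN = sum)
  agg$site <- names(sites)[match(agg$position, sites)]
  agg <- agg[order(agg$donor, agg$dataset, agg$position, -agg$n_psms), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("site", "position", "donor", "dataset", "glycan", "n_psms")]
}

#' Longitudinal occupancy series and trend signs
#'
#' For each (site, donor, dataset, modification) with at least three
#' sampled weeks, reports the per-week occupancy series and the sign of
#' the least-squares slope of occupancy against week index (1, 2, ... in
#' week order). A negative sign captures the decline of occupancy over
#' lactation.
#'
#' @param records a `site_occupancy` table.
#' @param mod `"phospho"`, `"glyco"` or `"both"` (default).
#' @param min_weeks minimum number of weeks to fit a trend (default 3).
#' @return list of class `occupancy_trends` with elements `series` (long
#'   data frame: site, donor, dataset, mod, week, occupancy) and `trend`
#'   (site, donor, dataset, mod, slope, slope_sign).
#' @export
longitudinal_summary <- function(records, mod = c("both", "phospho", "glyco"),
                                 min_weeks = 3L) {
  mod <- match.arg(mod)
  mods <- if (mod == "both") c("phospho", "glyco") else mod
  series <- list(); trend <- list()
  key <- interaction(records$site, records$donor, records$dataset,
                     drop = TRUE, lex.order = TRUE)
  for (k in levels(key)) {
    sub <- records[key == k, , drop = FALSE]
    sub <- sub[order(sub$week), , drop = FALSE]
    if (nrow(sub) < min_weeks) next
    for (m in mods) {
      occ <- if (m == "phospho") sub$occupancy_phospho else sub$occupancy_glyco
      series[[length(series) + 1L]] <- data.frame(
        site = sub$site, donor = sub$donor, dataset = sub$dataset,
        mod = m, week = sub$week, occupancy = occ, stringsAsFactors = FALSE)
      idx <- seq_len(nrow(sub))
      slope <- unname(stats::coef(stats::lm(occ ~ idx))[2])
      trend[[length(trend) + 1L]] <- data.frame(
        site = sub$site[1], donor = sub$donor[1], dataset = sub$dataset[1],
        mod = m, slope = slope, slope_sign = sign(round(slope, 12)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(series) == 0L) stop("no site series with >= ", min_weeks, " weeks",
                                 call. = FALSE)
  structure(list(series = do.call(rbind, series), trend = do.call(rbind, trend)),
            class = "occupancy_trends")
}

#' @export
print.occupancy_trends <- function(x, ...) {
  cat(sprintf("<occupancy trends> %d site series\n", nrow(x$trend)))
  print(x$trend)
  invisible(x)
}
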