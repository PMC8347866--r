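#' Curation configuration for bottom-up PSM tables
#'
#' Thresholds mirror the strict filtering used for beta-casein PSMs:
#' signal-peptide PSMs removed (mature chain starts at precursor position
#' 16), decoy/reverse hits removed, and score gates |log Prob| >= 1.5,
#' search score >= 150, Delta Mod > 5 (strict). The Delta Mod gate doubles
#' as the modification-localization gate downstream.
#'
#' @param min_log_prob_abs minimum |log Prob| (inclusive, default 1.5).
#' @param min_score minimum search-engine score (inclusive, default 150).
#' @param min_delta_mod_exclusive Delta Mod must exceed this (strict,
#'   default 5).
#' @param mature_start first precursor position of the mature chain
#'   (default 16); PSMs starting before it are signal-peptide hits.
#' @param max_glycans_per_psm glycan count above which a PSM is flagged
#'   implausible (default 2).
#' @param excluded_glyco_region integer length-2 vector; glycan
#'   localizations inside this precursor-coordinate interval are flagged as
#'   unsupported N-terminal calls (default `c(16, 100)`). A documented,
#'   user-confirmable default — no fragment-level evidence is re-examined
#'   here.
#' @param drop_decoys remove decoy rows (default TRUE).
#' @return a list of class `curation_config`.
#' @export
curation_config <- function(min_log_prob_abs = 1.5,
                            min_score = 150,
                            min_delta_mod_exclusive = 5,
                            mature_start = 16L,
                            max_glycans_per_psm = 2L,
                            excluded_glyco_region = c(16L, 100L),
                            drop_decoys = TRUE) {
  stopifnot(min_log_prob_abs >= 0, min_score >= 0, min_delta_mod_exclusive >= 0,
            mature_start >= 1, max_glycans_per_psm >= 0,
            length(excluded_glyco_region) == 2L,
            excluded_glyco_region[1] <= excluded_glyco_region[2])
  structure(list(min_log_prob_abs = min_log_prob_abs,
                 min_score = min_score,
                 min_delta_mod_exclusive = min_delta_mod_exclusive,
                 mature_start = as.integer(mature_start),
                 max_glycans_per_psm = as.integer(max_glycans_per_psm),
                 excluded_glyco_region = as.integer(excluded_glyco_region),
                 drop_decoys = isTRUE(drop_decoys)),
            class = "curation_config")
}

.check_psm_table <- function(psms) {
  need <- c("peptide", "start", "end", "mods", "log_prob_abs", "score",
            "delta_mod", "is_decoy")
  miss <- setdiff(need, names(psms))
  if (length(miss)) stop("PSM table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(psms) == 0L) return(psms)
  stopifnot(all(psms$start >= 1L), all(psms$end >= psms$start),
            all(psms$log_prob_abs >= 0), all(psms$score >= 0),
            all(psms$delta_mod >= 0))
  psms
}

#' Curate a PSM table
#'
#' Applies the removal rules in a fixed order — signal peptide, decoy,
#' |log Prob|, score, Delta Mod — and attributes every removed row to the
#' *first* rule it fails, so the rejection log is reproducible. Kept rows
#' satisfy: `start >= mature_start`, not a decoy, `log_prob_abs >= 1.5`,
#' `score >= 150`, `delta_mod > 5` (defaults).
#'
#' @param psms PSM data frame (see [simulate_psm_table()] for the schema).
#' @param cfg a [curation_config()].
#' @return object of class `psm_curation`: list with `kept` (data frame),
#'   `rejected` (data frame with a `reject_rule` column) and `log` (named
#'   integer vector of per-rule rejection counts plus `kept` and `input`).
#' @examples
#' \dontrun{
#' cur <- curate_psms(psms)
#' cur$log
#' }
#' @export
curate_psms <- function(psms, cfg = curation_config()) {
  psms <- .check_psm_table(psms)
  rules <- c("signal_peptide", "decoy", "log_prob", "score", "delta_mod")
  if (nrow(psms) == 0L) {
    log <- stats::setNames(integer(length(rules)), rules)
    return(structure(list(kept = psms,
                          rejected = cbind(psms, reject_rule = character(0)),
                          log = c(log, kept = 0L, input = 0L)),
                     class = "psm_curation"))
  }
  fail <- list(
    signal_peptide = psms$start < cfg$mature_start,
    decoy = if (cfg$drop_decoys) psms$is_decoy else rep(FALSE, nrow(psms)),
    log_prob = psms$log_prob_abs < cfg$min_log_prob_abs,
    score = psms$score < cfg$min_score,
    delta_mod = psms$delta_mod <= cfg$min_delta_mod_exclusive
  )
  first_fail <- rep(NA_character_, nrow(psms))
  for (r in rules) {
    hit <- is.na(first_fail) & fail[[r]]
    first_fail[hit] <- r
  }
  kept <- psms[is.na(first_fail), , drop = FALSE]
  rejected <- psms[!is.na(first_fail), , drop = FALSE]
  rejected$reject_rule <- first_fail[!is.na(first_fail)]
  counts <- vapply(rules, function(r) sum(first_fail == r, na.rm = TRUE), integer(1))
  rownames(kept) <- rownames(rejected) <- NULL
  structure(list(kept = kept, rejected = rejected,
                 log = c(counts, kept = nrow(kept), input = nrow(psms))),
            class = "psm_curation")
}

#' @export
print.psm_curation <- function(x, ...) {
  cat(sprintf("<psm curation> %d rows in, %d kept, %d rejected\n",
              x$log[["input"]], x$log[["kept"]],
              x$log[["input"]] - x$log[["kept"]]))
  rej <- x$log[setdiff(names(x$log), c("kept", "input"))]
  for (r in names(rej)) cat(sprintf("  %-15s %d\n", r, rej[[r]]))
  invisible(x)
}

#' Flag implausible glycopeptide PSMs
#'
#' Advisory plausibility flags standing in for manual spectral inspection:
#' `flag_excess_glycans` marks rows carrying more glycans than
#' `max_glycans_per_psm`, and `flag_nterm_glyco` marks rows with a glycan
#' localized inside the excluded N-terminal region, where automated
#' glycosite calls lack supportive fragmentation evidence. Rows are never
#' removed here; downstream site counting excludes flagged glycan
#' localizations by default.
#'
#' @param psms curated PSM data frame.
#' @param cfg a [curation_config()].
#' @return the table with logical columns `flag_excess_glycans` and
#'   `flag_nterm_glyco` added.
#' @export
flag_implausible_glyco <- function(psms, cfg = curation_config()) {
  psms$flag_excess_glycans <- FALSE
  psms$flag_nterm_glyco <- FALSE
  if (nrow(psms) == 0L) return(psms)
  pm <- parse_mods(psms$mods)
  pm <- pm[pm$kind == "glycan", , drop = FALSE]
  if (nrow(pm)) {
    n_gly <- tabulate(pm$row, nbins = nrow(psms))
    psms$flag_excess_glycans <- n_gly > cfg$max_glycans_per_psm
    reg <- cfg$excluded_glyco_region
    in_reg <- pm$site >= reg[1] & pm$site <= reg[2]
    psms$flag_nterm_glyco[unique(pm$row[in_reg])] <- TRUE
  }
  psms
}
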