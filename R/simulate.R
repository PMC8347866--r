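#' Ground-truthed simulation design
#'
#' Bundles every parameter of the synthetic-data generators with the truth
#' they encode, so recovery can be checked against known values. The
#' default design mirrors the longitudinal milk study shape: two donors,
#' sampling weeks 1, 2, 3, 4, 6, 8, 10, 12 and 16, and parallel proteome
#' (tryptic) and peptidome (endogenous) datasets. Default occupancies are
#' plausible, clearly non-normative values following the qualitative
#' pattern reported for beta-casein: a dominant N-terminal phospho cluster
#' with Ser24/Ser25 highest and declining over lactation, and C-terminal
#' O-glycosylation at Thr207 (~12%) and Thr214 (~17%) dominated by the
#' species N1H1 > N1 > N1F1.
#'
#' @param seed integer seed; mandatory, drives every generator.
#' @param donors donor identifiers (default `1:2`).
#' @param weeks sampling weeks (default `c(1,2,3,4,6,8,10,12,16)`).
#' @param datasets dataset identifiers (default proteome and peptidome).
#' @param sites named integer site vector (default [beta_casein_sites()]).
#' @param reference precursor `aa_sequence` (default the packaged synthetic
#'   stand-in, [beta_casein_reference()]).
#' @param phospho_occupancy named list/vector: per-site phospho occupancy,
#'   each either one fraction or one fraction per week.
#' @param glyco_occupancy same shape for glycan occupancy.
#' @param glycan_species named numeric vector of species weights (summing
#'   to 1) used at every glyco site.
#' @param n_covering named vector: covering PSMs per region, week, donor
#'   and dataset, by dataset.
#' @param decoy_fraction fraction of extra decoy rows (default 0.01).
#' @param implausible_fraction fraction of extra implausible glyco rows
#'   (default 0.01) exercising the advisory flags.
#' @param score_params list of target/decoy score-distribution parameters
#'   (normal location/spread for `log_prob_abs`, `score`, `delta_mod`).
#' @param proteoform_abundance named numeric over library labels: relative
#'   intact-level abundances.
#' @param identified_labels proteoform labels emitted as PrSMs (the
#'   "identified by database search" set; default the phospho backbones).
#' @param mass_sigma intact mass error SD, Da (default 0.05).
#' @param rt_jitter retention-time jitter SD, minutes (default 0.2).
#' @param noise_frac noise features as a fraction of real ones (default 0.1).
#' @param intensity_cv multiplicative intensity noise CV (default 0).
#' @param ladder_starts N-terminal start positions of the C-terminal ladder
#'   members (shared end 226).
#' @param ms1_glyco_fraction per-week glycosylated MS1 area fraction truth.
#' @param ms1_area_cv multiplicative MS1 area noise CV (default 0.1).
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(seed,
                             donors = 1:2,
                             weeks = c(1, 2, 3, 4, 6, 8, 10, 12, 16),
                             datasets = c("proteome", "peptidome"),
                             sites = beta_casein_sites(),
                             reference = beta_casein_reference(),
                             phospho_occupancy = NULL,
                             glyco_occupancy = NULL,
                             glycan_species = c(N1H1 = 0.6, N1 = 0.3, N1F1 = 0.1),
                             n_covering = c(proteome = 750, peptidome = 575),
                             decoy_fraction = 0.01,
                             implausible_fraction = 0.01,
                             score_params = NULL,
                             proteoform_abundance = NULL,
                             identified_labels = paste0(0:5, "P"),
                             mass_sigma = 0.05,
                             rt_jitter = 0.2,
                             noise_frac = 0.1,
                             intensity_cv = 0,
                             ladder_starts = c(190L, 193L, 197L, 200L),
                             ms1_glyco_fraction = NULL,
                             ms1_area_cv = 0.1) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  sites <- .site_vector(sites)
  nw <- length(weeks)

  decline <- seq(0.90, 0.65, length.out = nw)
  if (is.null(phospho_occupancy)) {
    phospho_occupancy <- list(S24 = decline, S25 = decline, S23 = 0.45,
                              S21 = 0.30, T18 = 0.12, S28 = 0.05, T30 = 0.02)
  }
  if (is.null(glyco_occupancy)) {
    glyco_occupancy <- list(T207 = 0.12, T214 = 0.17, S225 = 0.01)
  }
  occ_matrix <- function(spec) {
    m <- matrix(0, nrow = length(sites), ncol = nw,
                dimnames = list(names(sites), as.character(weeks)))
    for (nm in names(spec)) {
      if (!nm %in% names(sites)) next
      v <- spec[[nm]]
      if (!length(v) %in% c(1L, nw)) {
        stop("occupancy for ", nm, " must have length 1 or ", nw, call. = FALSE)
      }
      m[nm, ] <- v
    }
    if (any(m < 0 | m > 1)) stop("occupancy fractions must lie in [0, 1]", call. = FALSE)
    m
  }
  phospho_m <- occ_matrix(phospho_occupancy)
  glyco_m <- occ_matrix(glyco_occupancy)
  if (any(phospho_m + glyco_m > 1)) {
    stop("phospho + glyco occupancy exceeds 1 at some site/week", call. = FALSE)
  }
  if (abs(sum(glycan_species) - 1) > 1e-8 || any(glycan_species < 0)) {
    stop("glycan_species weights must be a probability vector", call. = FALSE)
  }
  if (is.null(score_params)) {
    score_params <- list(
      target = list(log_prob = c(3, 0.8), score = c(400, 120), delta_mod = c(20, 8)),
      decoy = list(log_prob = c(0.5, 0.4), score = c(80, 40), delta_mod = c(2, 2)))
  }
  if (is.null(proteoform_abundance)) {
    proteoform_abundance <- c("0P" = 0.05, "1P" = 0.10, "2P" = 0.28, "3P" = 0.15,
                              "4P" = 0.24, "5P" = 0.08, "0P+N1" = 0.02,
                              "0P+N1H1" = 0.03, "1P+N1H1" = 0.05)
  }
  if (is.null(ms1_glyco_fraction)) {
    ms1_glyco_fraction <- seq(0.08, 0.03, length.out = nw)
  }
  if (length(ms1_glyco_fraction) == 1L) {
    ms1_glyco_fraction <- rep(ms1_glyco_fraction, nw)
  }
  stopifnot(length(ms1_glyco_fraction) == nw,
            all(ms1_glyco_fraction >= 0 & ms1_glyco_fraction <= 1),
            mass_sigma >= 0, rt_jitter >= 0, noise_frac >= 0, intensity_cv >= 0,
            decoy_fraction >= 0, implausible_fraction >= 0)
  if (is.null(names(n_covering))) names(n_covering) <- datasets

  structure(list(
    seed = seed, donors = donors, weeks = weeks, datasets = datasets,
    sites = sites, reference = reference,
    phospho_occupancy = phospho_m, glyco_occupancy = glyco_m,
    glycan_species = glycan_species, n_covering = n_covering,
    decoy_fraction = decoy_fraction, implausible_fraction = implausible_fraction,
    score_params = score_params,
    proteoform_abundance = proteoform_abundance,
    identified_labels = identified_labels,
    mass_sigma = mass_sigma, rt_jitter = rt_jitter, noise_frac = noise_frac,
    intensity_cv = intensity_cv,
    ladder_starts = as.integer(ladder_starts),
    ms1_glyco_fraction = ms1_glyco_fraction,
    ms1_area_cv = ms1_area_cv,
    regions = list(nterm = c(16L, 30L), cterm = c(190L, 226L))
  ), class = "simulation_truth")
}

.rtrunc0 <- function(n, mu, sd) pmax(0, stats::rnorm(n, mu, sd))

.draw_scores <- function(n, p) {
  data.frame(log_prob_abs = .rtrunc0(n, p$log_prob[1], p$log_prob[2]),
             score = .rtrunc0(n, p$score[1], p$score[2]),
             delta_mod = .rtrunc0(n, p$delta_mod[1], p$delta_mod[2]))
}

#' Simulate a bottom-up PSM table
#'
#' Draws covering PSMs per peptide region (the N-terminal phospho cluster
#' 16-30 and the C-terminal ladder region ending at 226), per donor, week
#' and dataset. Each PSM independently carries each tracked site it covers
#' modified with that site's truth occupancy (phosphorylation drawn first;
#' a residue carries at most one modification), glycan species drawn from
#' the species multinomial. Target and decoy scores come from the
#' configured distributions; extra decoy rows and deliberately implausible
#' glyco rows exercise the curation and flagging rules. Fully
#' deterministic given `truth$seed`.
#'
#' @param truth a [simulation_truth()].
#' @return list with `psms` (the table) and `truth` (echoed).
#' @export
simulate_psm_table <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed)
  ref <- truth$reference
  sites <- truth$sites
  blocks <- list()
  for (dataset in truth$datasets) {
    n_block <- as.integer(truth$n_covering[[dataset]])
    for (donor in truth$donors) {
      for (wi in seq_along(truth$weeks)) {
        week <- truth$weeks[wi]
        for (region_name in names(truth$regions)) {
          reg <- truth$regions[[region_name]]
          in_reg <- sites >= reg[1] & sites <= reg[2]
          if (!any(in_reg)) next
          n <- n_block
          if (region_name == "cterm") {
            start <- sample(truth$ladder_starts, n, replace = TRUE)
          } else {
            start <- rep(reg[1], n)
          }
          end <- rep(reg[2], n)
          site_parts <- list()
          for (s in which(in_reg)) {
            pos <- sites[s]
            covered <- start <= pos
            p_ph <- truth$phospho_occupancy[s, wi]
            p_gl <- truth$glyco_occupancy[s, wi]
            u <- stats::runif(n)
            is_ph <- covered & u < p_ph
            is_gl <- covered & !is_ph & u < p_ph + p_gl
            part <- character(n)
            part[is_ph] <- paste0(pos, ":phospho")
            if (any(is_gl)) {
              sp <- sample(names(truth$glycan_species), sum(is_gl), replace = TRUE,
                           prob = truth$glycan_species)
              part[is_gl] <- paste0(pos, ":glycan:", sp)
            }
            site_parts[[length(site_parts) + 1L]] <- part
          }
          mods_str <- do.call(paste, c(site_parts, sep = ";"))
          mods_str <- gsub(";{2,}", ";", mods_str)
          mods_str <- gsub("^;|;$", "", mods_str)
          sc <- .draw_scores(n, truth$score_params$target)
          blocks[[length(blocks) + 1L]] <- data.frame(
            peptide = substring(ref$residues, start, end),
            start = start, end = end, mods = mods_str,
            log_prob_abs = sc$log_prob_abs, score = sc$score,
            delta_mod = sc$delta_mod, is_decoy = FALSE,
            donor = donor, week = week, dataset = dataset,
            frag_type = ifelse(nzchar(mods_str) & grepl("glycan", mods_str),
                               "EThcD", "HCD"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  psms <- do.call(rbind, blocks)

  n_extra <- function(frac) as.integer(round(nrow(psms) * frac))
  nd <- n_extra(truth$decoy_fraction)
  if (nd > 0L) {
    sc <- .draw_scores(nd, truth$score_params$decoy)
    reg <- truth$regions$nterm
    decoys <- data.frame(
      peptide = substring(ref$residues, reg[1], reg[2]),
      start = reg[1], end = reg[2], mods = "",
      log_prob_abs = sc$log_prob_abs, score = sc$score, delta_mod = sc$delta_mod,
      is_decoy = TRUE,
      donor = sample(truth$donors, nd, replace = TRUE),
      week = sample(truth$weeks, nd, replace = TRUE),
      dataset = sample(truth$datasets, nd, replace = TRUE),
      frag_type = "HCD", stringsAsFactors = FALSE)
    psms <- rbind(psms, decoys)
  }
  ni <- n_extra(truth$implausible_fraction)
  if (ni > 0L) {
    sc <- .draw_scores(ni, truth$score_params$target)
    reg <- truth$regions$cterm
    # triply glycosylated rows plus an unsupported N-terminal glyco call
    bad_mods <- rep(c("207:glycan:N1;214:glycan:N1H1;225:glycan:N1",
                      "24:glycan:N1"), length.out = ni)
    bad_start <- rep(c(reg[1], truth$regions$nterm[1]), length.out = ni)
    bad_end <- rep(c(reg[2], truth$regions$nterm[2]), length.out = ni)
    bad <- data.frame(
      peptide = substring(ref$residues, bad_start, bad_end),
      start = bad_start, end = bad_end, mods = bad_mods,
      log_prob_abs = sc$log_prob_abs, score = sc$score, delta_mod = sc$delta_mod,
      is_decoy = FALSE,
      donor = sample(truth$donors, ni, replace = TRUE),
      week = sample(truth$weeks, ni, replace = TRUE),
      dataset = sample(truth$datasets, ni, replace = TRUE),
      frag_type = "EThcD", stringsAsFactors = FALSE)
    psms <- rbind(psms, bad)
  }
  rownames(psms) <- NULL
  list(psms = psms, truth = truth)
}

#' Simulate a deconvoluted intact run with its PrSM table
#'
#' Emits one deconvoluted feature per abundant proteoform: mass is the
#' theoretical library mass plus Gaussian error (`mass_sigma`), retention
#' time clusters by phospho backbone with Gaussian jitter, intensity is
#' proportional to the configured abundance (optionally with multiplicative
#' noise). The `identified_labels` subset is also emitted as PrSM records —
#' the "identified by database search" anchor set; glycoproteoforms are
#' left for theoretical mass matching. Uniform-mass noise features are
#' appended. Deterministic given `truth$seed`.
#'
#' @param truth a [simulation_truth()].
#' @param lib optional `proteoform_library`; defaults to the full default
#'   enumeration over the mature chain of `truth$reference`.
#' @return list with `features`, `prsms`, `feature_truth` (feature id and
#'   true label, `NA` for noise) and `truth`.
#' @export
simulate_intact_run <- function(truth, lib = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed + 1L)
  if (is.null(lib)) {
    lib <- enumerate_proteoforms(mature_chain(truth$reference))
  }
  ab <- truth$proteoform_abundance
  miss <- setdiff(names(ab), lib$label)
  if (length(miss)) stop("abundance labels not in library: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rows <- lib[match(names(ab), lib$label), , drop = FALSE]
  n <- nrow(rows)
  rel <- ab / sum(ab)
  rt_center <- 20 + rows$n_phospho * 1.5
  intensity <- 1e6 * rel
  if (truth$intensity_cv > 0) {
    sdlog <- sqrt(log(1 + truth$intensity_cv^2))
    intensity <- intensity * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  features <- data.frame(
    feature_id = seq_len(n),
    mass = rows$mono_mass + stats::rnorm(n, 0, truth$mass_sigma),
    rt = rt_center + stats::rnorm(n, 0, truth$rt_jitter),
    intensity = intensity,
    run_id = "sim_run", resolution_mode = "high",
    stringsAsFactors = FALSE)
  feature_truth <- data.frame(feature_id = features$feature_id,
                              true_label = names(ab), stringsAsFactors = FALSE)

  id_rows <- lib[match(intersect(truth$identified_labels, names(ab)), lib$label), ,
                 drop = FALSE]
  prsms <- data.frame(
    proteoform_label = id_rows$label,
    precursor_mass = id_rows$mono_mass + stats::rnorm(nrow(id_rows), 0,
                                                      min(truth$mass_sigma, 0.01)),
    rt = 20 + id_rows$n_phospho * 1.5 +
      stats::rnorm(nrow(id_rows), 0, truth$rt_jitter / 2),
    run_id = "sim_run", stringsAsFactors = FALSE)

  n_noise <- as.integer(round(n * truth$noise_frac))
  if (n_noise > 0L) {
    mrange <- range(lib$mono_mass)
    noise <- data.frame(
      feature_id = n + seq_len(n_noise),
      mass = stats::runif(n_noise, mrange[1] - 50, mrange[2] + 50),
      rt = stats::runif(n_noise, min(rt_center) - 3, max(rt_center) + 3),
      intensity = stats::runif(n_noise, 0.001, 0.01) * 1e6,
      run_id = "sim_run", resolution_mode = "high", stringsAsFactors = FALSE)
    features <- rbind(features, noise)
    feature_truth <- rbind(feature_truth,
                           data.frame(feature_id = noise$feature_id,
                                      true_label = NA_character_,
                                      stringsAsFactors = FALSE))
  }
  list(features = features, prsms = prsms, feature_truth = feature_truth,
       truth = truth, library = lib)
}

#' Simulate MS1 peptidoform area tables
#'
#' For every ladder member (starts `truth$ladder_starts`, shared end 226),
#' donor, week and dataset, emits a non-modified row and singly/doubly
#' glycosylated rows whose areas split the member baseline by the per-week
#' glyco-fraction truth (single:double 4:1 within the glyco share), under
#' multiplicative log-normal noise with CV `ms1_area_cv`. Deterministic
#' given `truth$seed`.
#'
#' @param truth a [simulation_truth()].
#' @return list with `areas` (data frame: start, end, mods, is_glyco, area,
#'   donor, week, dataset) and `truth`.
#' @export
simulate_ms1_areas <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed + 2L)
  sdlog <- sqrt(log(1 + truth$ms1_area_cv^2))
  lnoise <- function(n) if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  rows <- list()
  end <- truth$regions$cterm[2]
  for (dataset in truth$datasets) {
    for (donor in truth$donors) {
      for (wi in seq_along(truth$weeks)) {
        f <- truth$ms1_glyco_fraction[wi]
        for (st in truth$ladder_starts) {
          base <- 1e5
          a <- c(base * (1 - f), base * f * 0.8, base * f * 0.2) * lnoise(3)
          rows[[length(rows) + 1L]] <- data.frame(
            start = st, end = end,
            mods = c("", "214:glycan:N1H1", "207:glycan:N1;214:glycan:N1H1"),
            is_glyco = c(FALSE, TRUE, TRUE),
            area = a, donor = donor, week = truth$weeks[wi], dataset = dataset,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  areas <- do.call(rbind, rows)
  rownames(areas) <- NULL
  list(areas = areas, truth = truth)
}
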