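make_psms <- function(n, pos, n_mod, kind = "phospho", glycan = "N1H1",
                      start = 16L, end = 30L, donor = 1, week = 1,
                      dataset = "proteome") {
  mods <- rep("", n)
  if (n_mod > 0) {
    mods[seq_len(n_mod)] <- if (kind == "phospho") paste0(pos, ":phospho") else
      paste0(pos, ":glycan:", glycan)
  }
  data.frame(peptide = "X", start = start, end = end, mods = mods,
             log_prob_abs = 3, score = 400, delta_mod = 20, is_decoy = FALSE,
             donor = donor, week = week, dataset = dataset,
             stringsAsFactors = FALSE)
}

test_that("occupancy is modified count over covering count, per cell", {
  tbl <- make_psms(10, 24, 2)
  occ <- occupancy_table(tbl, sites = c(S24 = 24L))
  expect_equal(occ$n_covering, 10L)
  expect_equal(occ$occupancy_phospho, 0.20)

  # no covering PSMs at a site: no record emitted
  occ2 <- occupancy_table(tbl, sites = c(S24 = 24L, T207 = 207L))
  expect_equal(nrow(occ2), 1L)
  expect_equal(occ2$site, "S24")

  # non-Ser/Thr site against a reference sequence is a configuration error
  ref <- beta_casein_reference()
  expect_error(occupancy_table(tbl, sites = c(R16 = 16L), reference = ref),
               "not Ser/Thr")
  expect_silent(occupancy_table(tbl, sites = c(S24 = 24L), reference = ref))
})

test_that("occupancy bounds and covering invariants hold on simulated data", {
  set.seed(31)
  sim <- simulate_psm_table(small_truth(31))
  cur <- flag_implausible_glyco(curate_psms(sim$psms)$kept)
  occ <- occupancy_table(cur)
  expect_true(all(occ$occupancy_phospho >= 0 & occ$occupancy_phospho <= 1))
  expect_true(all(occ$occupancy_glyco >= 0 & occ$occupancy_glyco <= 1))
  expect_true(all(occ$n_phospho + occ$n_glyco <= occ$n_covering))
  expect_true(all(occ$n_covering >= 1))
})

test_that("binomial occupancy recovery at truth 0.17 with 500 covering PSMs", {
  truth <- simulation_truth(seed = 202, donors = 1, weeks = 1,
                            datasets = "proteome",
                            n_covering = c(proteome = 500),
                            glyco_occupancy = list(T214 = 0.17),
                            phospho_occupancy = list(),
                            decoy_fraction = 0, implausible_fraction = 0,
                            score_params = list(
                              target = list(log_prob = c(3, 0), score = c(400, 0),
                                            delta_mod = c(20, 0)),
                              decoy = list(log_prob = c(0, 0), score = c(0, 0),
                                           delta_mod = c(0, 0))))
  sim <- simulate_psm_table(truth)
  occ <- occupancy_table(curate_psms(sim$psms)$kept, sites = c(T214 = 214L))
  expect_equal(occ$n_covering, 500L)
  expect_lt(abs(occ$occupancy_glyco - 0.17), 0.05)
})

test_that("mean per-week PSM counts use half-up rounding over the sampling weeks", {
  path <- system.file("extdata", "glyco_psm_totals.csv", package = "casoform")
  totals <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(mean_site_psms(totals, "T207", 1, "proteome"), 90L)
  expect_equal(mean_site_psms(totals, "T214", 1, "proteome"), 120L)
  expect_equal(mean_site_psms(totals, "T207", 1, "peptidome"), 69L)
  expect_equal(mean_site_psms(totals, "T214", 1, "peptidome"), 95L)
  expect_equal(mean_site_psms(totals, "T207", 2, "proteome"), 52L)
  expect_equal(mean_site_psms(totals, "T214", 2, "peptidome"), 80L)
  # trivial and error cases
  zero <- data.frame(site = "T207", donor = 1, dataset = "proteome", n_glyco = 0)
  expect_equal(mean_site_psms(zero, "T207", 1, "proteome"), 0L)
  expect_error(mean_site_psms(zero, "T207", 1, "proteome", n_weeks = 0), "week")
  # half-up: 4.5 per week rounds to 5
  hf <- data.frame(site = "S24", donor = 1, dataset = "proteome", n_glyco = 40.5)
  expect_equal(mean_site_psms(hf, "S24", 1, "proteome"), 5L)
})

test_that("phosphosite ranking is deterministic with ascending-position ties", {
  recs <- data.frame(site = c("S24", "S25", "S23", "S21", "T18"),
                     position = c(24L, 25L, 23L, 21L, 18L),
                     donor = 1, dataset = "proteome",
                     n_phospho = c(197L, 150L, 90L, 40L, 10L))
  rk <- phosphosite_rank(recs, 1, "proteome")
  expect_equal(rk$site, c("S24", "S25", "S23", "S21", "T18"))

  ties <- transform(recs, n_phospho = 50L)
  expect_equal(phosphosite_rank(ties, 1, "proteome")$position,
               c(18L, 21L, 23L, 24L, 25L))
})

test_that("simulated phosphosite ordering is recovered from 2000 PSMs", {
  truth <- simulation_truth(seed = 77, donors = 1, weeks = 1,
                            datasets = "proteome", n_covering = c(proteome = 2000),
                            phospho_occupancy = list(S24 = 0.60, S25 = 0.45,
                                                     S23 = 0.30, S21 = 0.15,
                                                     T18 = 0.05),
                            glyco_occupancy = list(),
                            decoy_fraction = 0, implausible_fraction = 0)
  sim <- simulate_psm_table(truth)
  occ <- occupancy_table(curate_psms(sim$psms)$kept,
                         sites = beta_casein_sites()[c("T18", "S21", "S23", "S24", "S25")])
  rk <- phosphosite_rank(occ, 1, "proteome")
  expect_equal(rk$site, c("S24", "S25", "S23", "S21", "T18"))
})

test_that("glycan species breakdown partitions glyco PSMs by composition", {
  tbl <- rbind(make_psms(3, 214, 3, kind = "glycan", glycan = "N1H1",
                         start = 190, end = 226),
               make_psms(1, 214, 1, kind = "glycan", glycan = "N1",
                         start = 190, end = 226))
  bd <- glycan_species_breakdown(tbl, sites = c(T214 = 214L))
  expect_equal(bd$n_psms[bd$glycan == "N1H1"], 3L)
  expect_equal(bd$n_psms[bd$glycan == "N1"], 1L)

  # sum consistency with the occupancy record
  occ <- occupancy_table(tbl, sites = c(T214 = 214L))
  expect_equal(sum(bd$n_psms), sum(occ$n_glyco))

  # no glyco PSMs: empty profile
  expect_equal(nrow(glycan_species_breakdown(make_psms(5, 24, 0),
                                             sites = c(S24 = 24L))), 0L)
})

test_that("multinomial species proportions are recovered within +/- 0.07", {
  truth <- simulation_truth(seed = 55, donors = 1, weeks = 1,
                            datasets = "proteome", n_covering = c(proteome = 1000),
                            glyco_occupancy = list(T214 = 0.30),
                            phospho_occupancy = list(),
                            decoy_fraction = 0, implausible_fraction = 0)
  sim <- simulate_psm_table(truth)
  cur <- flag_implausible_glyco(curate_psms(sim$psms)$kept)
  bd <- glycan_species_breakdown(cur, sites = c(T214 = 214L))
  prop <- bd$n_psms / sum(bd$n_psms)
  names(prop) <- bd$glycan
  for (sp in names(truth$glycan_species)) {
    expect_lt(abs(prop[[sp]] - truth$glycan_species[[sp]]), 0.07)
  }
})

test_that("longitudinal summaries report per-week series and slope signs", {
  weeks <- c(1, 2, 3, 4, 6)
  occ <- seq(0.92, 0.65, length.out = 5)
  recs <- data.frame(site = "S24", position = 24L, donor = 1, week = weeks,
                     dataset = "proteome", n_covering = 100L,
                     n_phospho = round(100 * occ), n_glyco = 0L,
                     occupancy_phospho = occ, occupancy_glyco = 0)
  tr <- longitudinal_summary(recs, mod = "phospho")
  expect_equal(tr$trend$slope_sign, -1)
  expect_equal(nrow(tr$series), 5L)

  flat <- transform(recs, occupancy_phospho = 0.5)
  expect_equal(longitudinal_summary(flat, mod = "phospho")$trend$slope_sign, 0)
})
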