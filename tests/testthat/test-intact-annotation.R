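mature <- casoform::beta_casein_reference(mature = TRUE)
lib <- casoform::enumerate_proteoforms(mature)
M0 <- lib$mono_mass[lib$label == "0P"]

feat <- function(mass, rt, intensity = 100, run_id = "r1") {
  data.frame(mass = mass, rt = rt, intensity = intensity, run_id = run_id,
             resolution_mode = "high", stringsAsFactors = FALSE)
}
prsm <- function(label, mass, rt, run_id = "r1") {
  data.frame(proteoform_label = label, precursor_mass = mass, rt = rt,
             run_id = run_id, stringsAsFactors = FALSE)
}

test_that("PrSM matching honours the mass and RT windows and tie-breaks by nearest mass", {
  f <- feat(M0, 10.0)
  ann <- match_to_prsm(f, prsm("0P", M0 + 0.4, 10.5))
  expect_equal(ann$method, "database")
  expect_equal(ann$mass_error, 0.4, tolerance = 1e-9)

  # RT outside +/- 1 min: no database annotation
  ann2 <- match_to_prsm(f, prsm("0P", M0 + 0.4, 12.0))
  expect_equal(ann2$method, "unannotated")

  # two candidates in window: nearest mass wins, ambiguity recorded
  p <- rbind(prsm("0P", M0 + 0.4, 10.2), prsm("0P", M0 - 0.2, 10.3))
  ann3 <- match_to_prsm(f, p)
  expect_equal(ann3$mass_error, -0.2, tolerance = 1e-9)
  expect_equal(ann3$ambiguity, 2L)

  # boundary: |delta mass| exactly 1 Da is inside the window
  ann4 <- match_to_prsm(f, prsm("0P", M0 + 1.0, 10.0))
  expect_equal(ann4$method, "database")
})

test_that("theoretical matching requires a library hit plus RT gating on identified features", {
  glyco_mass <- M0 + glycan_mass("N1H1")
  f <- rbind(feat(M0, 10.0), feat(glyco_mass + 0.3, 10.4))
  ann <- match_to_prsm(f, prsm("0P", M0, 10.0))
  ann <- match_to_library(ann, lib)
  expect_equal(ann$method, c("database", "theoretical"))
  expect_equal(ann$proteoform_label[2], "0P+N1H1")

  # same mass but eluting 5 min from every identified feature: stays bare
  f2 <- rbind(feat(M0, 10.0), feat(glyco_mass + 0.3, 15.0))
  ann2 <- match_to_library(match_to_prsm(f2, prsm("0P", M0, 10.0)), lib)
  expect_equal(ann2$method[2], "unannotated")

  # database annotation pre-empts theoretical for the same feature
  f3 <- feat(M0 + 0.1, 10.0)
  ann3 <- match_to_library(match_to_prsm(f3, prsm("0P", M0, 10.0)), lib)
  expect_equal(ann3$method, "database")

  expect_error(match_to_library(ann, lib[0, ]), "empty")

  # empty feature table passes through
  ann0 <- match_to_prsm(feat(M0, 10)[0, ], prsm("0P", M0, 10))
  expect_equal(nrow(match_to_library(ann0, lib)), 0L)
})

test_that("widening the mass tolerance never decreases annotated features", {
  set.seed(11)
  run <- simulate_intact_run(simulation_truth(seed = 11, mass_sigma = 0.4,
                                              noise_frac = 0.2), lib = lib)
  n_ann <- function(tol) {
    cfg <- annotation_config(mass_tol = tol)
    a <- match_to_library(match_to_prsm(run$features, run$prsms, cfg), lib, cfg)
    sum(a$method != "unannotated")
  }
  counts <- vapply(c(0.2, 0.5, 1.0, 2.0), n_ann, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("normalized intensities sum to one over annotated features", {
  f <- rbind(feat(M0, 10.0, 2), feat(M0 + 79.9663, 11.5, 3),
             feat(M0 + 2 * 79.9663, 13.0, 5), feat(M0 + 5000, 10.0, 99))
  p <- rbind(prsm("0P", M0, 10.0), prsm("1P", M0 + 79.9663, 11.5),
             prsm("2P", M0 + 2 * 79.9663, 13.0))
  ann <- annotate_intact(f, p, lib)
  expect_equal(ann$normalized_intensity[1:3], c(0.2, 0.3, 0.5))
  expect_true(is.na(ann$normalized_intensity[4]))
  expect_equal(sum(ann$normalized_intensity, na.rm = TRUE), 1, tolerance = 1e-9)

  # single annotated feature
  ann1 <- annotate_intact(feat(M0, 10), prsm("0P", M0, 10), lib)
  expect_equal(ann1$normalized_intensity, 1.0)

  # all-zero intensities over annotated features is a degenerate input
  fz <- feat(M0, 10, 0)
  expect_error(annotate_intact(fz, prsm("0P", M0, 10), lib), "zero")
})

test_that("noiseless simulated run is recovered perfectly", {
  truth <- simulation_truth(seed = 5, mass_sigma = 0, rt_jitter = 0,
                            noise_frac = 0, intensity_cv = 0)
  run <- simulate_intact_run(truth, lib = lib)
  ann <- annotate_intact(run$features, run$prsms, lib)
  expect_equal(ann$proteoform_label, run$feature_truth$true_label)
  want <- unname(truth$proteoform_abundance / sum(truth$proteoform_abundance))
  expect_equal(ann$normalized_intensity, want, tolerance = 1e-12)
})

test_that("same seed reproduces the identical intact run", {
  t1 <- simulation_truth(seed = 42)
  expect_identical(simulate_intact_run(t1, lib = lib)$features,
                   simulate_intact_run(t1, lib = lib)$features)
})
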