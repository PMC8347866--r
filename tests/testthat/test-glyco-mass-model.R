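test_that("glycan composition strings parse, serialize and round-trip", {
  g <- parse_glycan_composition("N1H1")
  expect_s3_class(g, "glycan_composition")
  expect_equal(unclass(g), c(N = 1L, H = 1L, F = 0L, S = 0L))

  g2 <- parse_glycan_composition("N1H1S2")
  expect_equal(unclass(g2), c(N = 1L, H = 1L, F = 0L, S = 2L))

  # canonical order N,H,F,S regardless of input order; zero counts omitted
  expect_identical(format_glycan_composition(parse_glycan_composition("S1N2")),
                   "N2S1")

  # round-trip property over all compositions with counts <= 3
  grid <- expand.grid(N = 0:3, H = 0:3, F = 0:3, S = 0:3)
  for (i in seq_len(nrow(grid))) {
    counts <- unlist(grid[i, ])
    if (sum(counts) == 0) next
    g <- as_glycan_composition(counts)
    expect_equal(unclass(parse_glycan_composition(format_glycan_composition(g))),
                 unclass(g))
  }
})

test_that("malformed composition strings fail with a named offending token", {
  expect_error(parse_glycan_composition("X1"), "X")
  expect_error(parse_glycan_composition("N"), "missing count")
  expect_error(parse_glycan_composition(""), "non-empty")
  expect_error(parse_glycan_composition("N1Q2"), "Q")
})

test_that("glycan masses equal elemental-composition sums", {
  expect_equal(glycan_mass("N1"), 203.079373, tolerance = 1e-6)
  expect_equal(glycan_mass("N1H1"), 365.132197, tolerance = 1e-6)
  expect_equal(glycan_mass(as_glycan_composition(c(N = 0))), 0)

  for (comp in c("N1", "N1H1", "N1F1", "N1H1S2", "N2H2F1S1")) {
    g <- parse_glycan_composition(comp)
    expect_equal(glycan_mass(g, "mono"), oracle_glycan_mass(unclass(g), "mono"),
                 tolerance = 1e-5)
    expect_equal(glycan_mass(g, "avg"), oracle_glycan_mass(unclass(g), "avg"),
                 tolerance = 1e-3)
  }
})

test_that("peptide masses match the elemental oracle and enforce localization", {
  expect_equal(peptide_mass("G"), 75.032028, tolerance = 1e-4)
  expect_equal(peptide_mass(aa_sequence("T"), list(mod_delta("phospho", 1))),
               199.024570, tolerance = 1e-4)
  expect_error(peptide_mass(aa_sequence("G"), list(mod_delta("phospho", 1))),
               "requires S/T")
  expect_error(peptide_mass(aa_sequence("ST", offset = 10),
                            list(mod_delta("phospho", 30))), "outside")
  # oxidation is mass bookkeeping only, Met-restricted
  expect_equal(peptide_mass(aa_sequence("M"), list(mod_delta("oxidation", 1))),
               peptide_mass("M") + 15.994915, tolerance = 1e-5)
})

test_that("mass computation agrees with the elemental oracle for random modified peptides", {
  set.seed(421)
  max_err_mono <- 0
  for (i in 1:100) {
    pep <- random_peptide(sample(1:40, 1))
    seq <- aa_sequence(pep, offset = sample(1:50, 1))
    chars <- strsplit(pep, "")[[1]]
    st_pos <- which(chars %in% c("S", "T")) + seq$offset - 1L
    n_mods <- min(sample(0:3, 1), length(st_pos))
    mods <- list(); oracle_mods <- list()
    if (n_mods > 0) {
      pos <- st_pos[sample.int(length(st_pos), n_mods)]
      for (p in pos) {
        if (stats::runif(1) < 0.5) {
          mods[[length(mods) + 1L]] <- mod_delta("phospho", p)
          oracle_mods[[length(oracle_mods) + 1L]] <- list(kind = "phospho")
        } else {
          comp <- sample(c("N1", "N1H1", "N1F1", "N1H1S1"), 1)
          mods[[length(mods) + 1L]] <- mod_delta("glycan", p, comp)
          oracle_mods[[length(oracle_mods) + 1L]] <-
            list(kind = "glycan", counts = unclass(parse_glycan_composition(comp)))
        }
      }
    }
    err_mono <- abs(peptide_mass(seq, mods, "mono") -
                      oracle_peptide_mass(pep, oracle_mods, "mono"))
    err_avg <- abs(peptide_mass(seq, mods, "avg") -
                     oracle_peptide_mass(pep, oracle_mods, "avg"))
    max_err_mono <- max(max_err_mono, err_mono)
    expect_lt(err_mono, 1e-4)
    expect_lt(err_avg, 1e-2)
  }
  expect_lt(max_err_mono, 1e-4)
})

test_that("modification deltas are exactly additive", {
  set.seed(99)
  for (i in 1:20) {
    pep <- paste0(random_peptide(10), "STST")
    seq <- aa_sequence(pep)
    mods <- list(mod_delta("phospho", 11), mod_delta("glycan", 12, "N1H1"),
                 mod_delta("phospho", 13))
    delta_sum <- sum(vapply(mods, function(m) m$mono_mass, numeric(1)))
    expect_equal(peptide_mass(seq, mods) - peptide_mass(seq), delta_sum,
                 tolerance = 1e-10)
  }
})

test_that("serialized modification lists round-trip through parse_mods", {
  mods <- c("24:phospho;214:glycan:N1H1", "", "18:phospho",
            "207:glycan:N1;214:glycan:N1F1;225:glycan:N1")
  pm <- parse_mods(mods)
  expect_equal(nrow(pm), 6L)
  expect_equal(pm$site[pm$row == 1], c(24L, 214L))
  expect_equal(pm$kind[pm$row == 4], rep("glycan", 3))
  expect_equal(sum(pm$row == 2), 0L)
  expect_error(parse_mods("24:banana"), "malformed")
  expect_error(parse_mods("24:glycan"), "without composition")
})
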