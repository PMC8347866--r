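# Independent mass oracle: sums elemental compositions from atomic masses.
# Deliberately does NOT use the package's residue mass tables, so that
# agreement between the two routes is a real cross-check.

.atomic_mono <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                  O = 15.9949146196, S = 31.97207100, P = 30.97376163)
.atomic_avg <- c(H = 1.00794, C = 12.0107, N = 14.0067,
                 O = 15.9994, S = 32.065, P = 30.973762)

.residue_formula <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),  R = c(C = 6, H = 12, N = 4, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1), E = c(C = 5, H = 7, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  I = c(C = 6, H = 11, N = 1, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), K = c(C = 6, H = 12, N = 2, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  P = c(C = 5, H = 7, N = 1, O = 1),  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),  V = c(C = 5, H = 9, N = 1, O = 1))

.glycan_formula <- list(
  N = c(C = 8, H = 13, N = 1, O = 5),   # HexNAc residue
  H = c(C = 6, H = 10, O = 5),          # hexose residue
  F = c(C = 6, H = 10, O = 4),          # deoxyhexose residue
  S = c(C = 11, H = 17, N = 1, O = 8))  # NeuAc residue

.mod_formula <- list(phospho = c(H = 1, P = 1, O = 3), oxidation = c(O = 1))

.formula_mass <- function(formula, scale) {
  at <- if (scale == "mono") .atomic_mono else .atomic_avg
  sum(at[names(formula)] * formula)
}

# glycan composition counts (named N/H/F/S) -> mass by elemental sum
oracle_glycan_mass <- function(counts, scale = "mono") {
  total <- 0
  for (letter in names(counts)) {
    if (counts[[letter]] > 0) {
      total <- total + counts[[letter]] * .formula_mass(.glycan_formula[[letter]], scale)
    }
  }
  total
}

# peptide string + mods (data.frame with kind, glycan counts list) -> mass
oracle_peptide_mass <- function(residues, mods = list(), scale = "mono") {
  chars <- strsplit(residues, "")[[1]]
  total <- sum(vapply(chars, function(ch) .formula_mass(.residue_formula[[ch]], scale),
                      numeric(1)))
  total <- total + .formula_mass(c(H = 2, O = 1), scale)
  for (m in mods) {
    if (m$kind == "glycan") {
      total <- total + oracle_glycan_mass(m$counts, scale)
    } else {
      total <- total + .formula_mass(.mod_formula[[m$kind]], scale)
    }
  }
  total
}

# Brute-force proteoform-count oracle: enumerates phospho counts crossed
# with glycan multisets via sorted tuples of an expanded grid, then counts
# the distinct ones. Independent of the package's recursive enumerator.
oracle_proteoform_count <- function(max_phospho, max_glycans, n_catalog) {
  multisets <- 0L
  for (k in 0:max_glycans) {
    if (k == 0L) { multisets <- multisets + 1L; next }
    if (n_catalog == 0L) next
    grid <- do.call(expand.grid, rep(list(seq_len(n_catalog)), k))
    keys <- apply(grid, 1, function(r) paste(sort(r), collapse = "-"))
    multisets <- multisets + length(unique(keys))
  }
  (max_phospho + 1L) * multisets
}

random_peptide <- function(len) {
  paste(sample(names(.residue_formula), len, replace = TRUE), collapse = "")
}

# default simulation design scaled down to keep unit tests fast
small_truth <- function(seed, ...) {
  simulation_truth(seed = seed, donors = 1, weeks = c(1, 2, 3),
                   datasets = "proteome", n_covering = c(proteome = 60), ...)
}
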