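#' Enumerate the theoretical proteoform library
#'
#' Builds every combination of a phosphorylation count (0 to `max_phospho`,
#' labelled `"0P"` ... `"5P"`) with an order-insensitive multiset of 0 to
#' `max_glycans` O-glycans drawn with repetition from the catalog. The
#' intact level encodes the phospho *count* only — site assignment belongs
#' to the bottom-up tier. Monoisotopic and average masses are the base
#' chain mass plus the modification deltas.
#'
#' With the defaults (0-5 phospho, 0-2 glycans, nine catalog compositions)
#' the library has 6 x 55 = 330 entries.
#'
#' @param base an `aa_sequence`, the mature chain (or a plain string).
#' @param max_phospho maximum phosphorylation count (default 5).
#' @param max_glycans maximum number of O-glycans per proteoform (default 2).
#' @param catalog character vector of distinct canonical glycan composition
#'   strings (default [default_glycan_catalog()]).
#' @return a `proteoform_library`: a data frame with columns `label`,
#'   `n_phospho`, `glycans` (comma-joined canonical strings, `""` if none),
#'   `n_glycans`, `n_mods`, `mono_mass`, `avg_mass`; the base sequence and
#'   catalog are kept as attributes.
#' @examples
#' lib <- enumerate_proteoforms(aa_sequence("RETIESLSSSEESITK", offset = 16))
#' nrow(lib)   # 330
#' @export
enumerate_proteoforms <- function(base,
                                  max_phospho = 5L,
                                  max_glycans = 2L,
                                  catalog = default_glycan_catalog()) {
  if (is.character(base)) base <- aa_sequence(base)
  stopifnot(inherits(base, "aa_sequence"))
  max_phospho <- as.integer(max_phospho)
  max_glycans <- as.integer(max_glycans)
  if (max_phospho < 0L || max_glycans < 0L) {
    stop("max_phospho and max_glycans must be >= 0", call. = FALSE)
  }
  catalog <- vapply(catalog, function(g) format_glycan_composition(g), character(1),
                    USE.NAMES = FALSE)
  if (anyDuplicated(catalog)) {
    stop("glycan catalog entries must be distinct (after canonicalization)",
         call. = FALSE)
  }
  if (max_glycans > 0L && length(catalog) == 0L) catalog <- character(0)

  multisets <- .glycan_multisets(catalog, max_glycans)
  base_mono <- peptide_mass(base, scale = "mono")
  base_avg <- peptide_mass(base, scale = "avg")
  g_mono <- vapply(catalog, glycan_mass, numeric(1), scale = "mono")
  g_avg <- vapply(catalog, glycan_mass, numeric(1), scale = "avg")

  rows <- vector("list", (max_phospho + 1L) * length(multisets))
  k <- 0L
  for (p in 0:max_phospho) {
    for (ms in multisets) {
      k <- k + 1L
      glyc_sorted <- sort(ms)  # lexicographic canonical order within the multiset
      label <- paste0(p, "P")
      if (length(glyc_sorted)) {
        label <- paste(c(label, glyc_sorted), collapse = "+")
      }
      rows[[k]] <- data.frame(
        label = label,
        n_phospho = p,
        glycans = paste(glyc_sorted, collapse = ","),
        n_glycans = length(glyc_sorted),
        n_mods = p + length(glyc_sorted),
        mono_mass = base_mono + p * .MASS_PHOSPHO[["mono"]] +
          sum(g_mono[glyc_sorted]),
        avg_mass = base_avg + p * .MASS_PHOSPHO[["avg"]] +
          sum(g_avg[glyc_sorted]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$label))
  structure(out,
            base = base,
            catalog = catalog,
            max_phospho = max_phospho,
            max_glycans = max_glycans,
            class = c("proteoform_library", "data.frame"))
}

# all multisets (combinations with repetition) of size 0..max_k from catalog,
# as a list of character vectors; recursion over non-decreasing index tuples
.glycan_multisets <- function(catalog, max_k) {
  out <- list(character(0))
  if (max_k == 0L || length(catalog) == 0L) return(out)
  recurse <- function(prefix, start, depth) {
    if (depth == 0L) return(invisible())
    for (i in start:length(catalog)) {
      ms <- c(prefix, catalog[i])
      out[[length(out) + 1L]] <<- ms
      recurse(ms, i, depth - 1L)
    }
  }
  recurse(character(0), 1L, max_k)
  out
}

#' @export
print.proteoform_library <- function(x, ...) {
  cat(sprintf("<proteoform library> %d entries: phospho 0-%d x 0-%d glycans from %d compositions\n",
              nrow(x), attr(x, "max_phospho"), attr(x, "max_glycans"),
              length(attr(x, "catalog"))))
  cat(sprintf("  base: %d aa (precursor %d-%d), mono %.4f Da / avg %.4f Da\n",
              nchar(attr(x, "base")$residues), attr(x, "base")$offset,
              attr(x, "base")$offset + nchar(attr(x, "base")$residues) - 1L,
              x$mono_mass[x$label == "0P"], x$avg_mass[x$label == "0P"]))
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more entries\n")
  invisible(x)
}

#' Build a sorted mass index over a proteoform library
#'
#' @param lib a `proteoform_library`.
#' @param scale `"mono"` or `"avg"`; which theoretical mass to index.
#' @return a `proteoform_mass_index` supporting [query_mass()].
#' @export
mass_index <- function(lib, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  stopifnot(inherits(lib, "proteoform_library"))
  if (nrow(lib) == 0L) stop("cannot index an empty library", call. = FALSE)
  m <- if (scale == "mono") lib$mono_mass else lib$avg_mass
  ord <- order(m)
  structure(list(mass = m[ord], entry = ord, scale = scale, lib = lib),
            class = "proteoform_mass_index")
}

#' Query a mass index within a tolerance window
#'
#' Returns all library entries with |theoretical - mass| <= `tol`, nearest
#' first. Ties on |delta| are broken by fewer total modifications, then by
#' lexicographic label (parsimony first).
#'
#' @param index a `proteoform_mass_index` from [mass_index()].
#' @param mass observed neutral mass (Da).
#' @param tol tolerance window half-width in Da (default 1.0).
#' @return data frame of matching library rows with an extra `delta` column
#'   (theoretical minus observed); zero rows if nothing is within `tol`.
#' @export
query_mass <- function(index, mass, tol = 1.0) {
  stopifnot(inherits(index, "proteoform_mass_index"), tol > 0)
  lo <- findInterval(mass - tol, index$mass, left.open = TRUE) + 1L
  hi <- findInterval(mass + tol, index$mass)
  if (lo > hi) {
    out <- as.data.frame(index$lib)[0, , drop = FALSE]
    out$delta <- numeric(0)
    return(out)
  }
  sel <- index$entry[lo:hi]
  out <- as.data.frame(index$lib)[sel, , drop = FALSE]
  out$delta <- index$mass[lo:hi] - mass
  ord <- order(abs(out$delta), out$n_mods, out$label)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
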