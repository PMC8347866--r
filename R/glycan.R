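#' Parse a compositional glycan string
#'
#' Compositions are written in the field's compact letter-count notation,
#' e.g. `"N1H1"` (one HexNAc, one hexose) or `"N1H1S2"` (a di-sialylated
#' core 1 glycan). Letters are `N` = N-acetylhexosamine, `H` = hexose,
#' `F` = deoxyhexose (fucose), `S` = N-acetylneuraminic acid; counts are
#' positive integers and the canonical letter order is N, H, F, S with zero
#' counts omitted.
#'
#' @param text a single composition string, e.g. `"N1H1F1"`.
#' @return an object of class `glycan_composition`: a named integer vector
#'   with elements `N`, `H`, `F`, `S`.
#' @examples
#' parse_glycan_composition("N1H1")
#' glycan_mass(parse_glycan_composition("N1H1S2"))
#' @export
parse_glycan_composition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("glycan composition string must be a single non-empty string", call. = FALSE)
  }
  tokens <- regmatches(text, gregexpr("[A-Za-z]+|[0-9]+|[^A-Za-z0-9]+", text))[[1]]
  counts <- c(N = 0L, H = 0L, F = 0L, S = 0L)
  i <- 1L
  while (i <= length(tokens)) {
    letter <- tokens[i]
    if (!letter %in% .GLYCAN_LETTERS) {
      stop(sprintf("unknown monosaccharide token '%s' in composition '%s'", letter, text),
           call. = FALSE)
    }
    if (i + 1L > length(tokens) || !grepl("^[0-9]+$", tokens[i + 1L])) {
      stop(sprintf("missing count after monosaccharide '%s' in composition '%s'", letter, text),
           call. = FALSE)
    }
    n <- as.integer(tokens[i + 1L])
    if (n < 1L) {
      stop(sprintf("count for '%s' must be positive in composition '%s'", letter, text),
           call. = FALSE)
    }
    counts[letter] <- counts[letter] + n
    i <- i + 2L
  }
  new_glycan_composition(counts)
}

new_glycan_composition <- function(counts) {
  stopifnot(all(.GLYCAN_LETTERS %in% names(counts)))
  counts <- as.integer(counts[.GLYCAN_LETTERS])
  names(counts) <- .GLYCAN_LETTERS
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("glycan monosaccharide counts must be non-negative integers", call. = FALSE)
  }
  structure(counts, class = "glycan_composition")
}

#' Serialize a glycan composition to its canonical string
#'
#' Letters appear in fixed order N, H, F, S; zero counts are omitted. The
#' empty composition serializes to `""`.
#'
#' @param g a `glycan_composition` or a composition string.
#' @return canonical composition string.
#' @export
format_glycan_composition <- function(g) {
  g <- as_glycan_composition(g)
  nz <- g[g > 0L]
  if (length(nz) == 0L) return("")
  paste0(names(nz), nz, collapse = "")
}

#' @export
format.glycan_composition <- function(x, ...) format_glycan_composition(x)

#' @export
print.glycan_composition <- function(x, ...) {
  s <- format_glycan_composition(x)
  cat("<glycan composition> ", if (nzchar(s)) s else "(empty)",
      sprintf("  [%.6f Da mono]\n", glycan_mass(x, "mono")), sep = "")
  invisible(x)
}

#' Coerce to a glycan composition
#'
#' @param g a `glycan_composition`, a composition string, or a named
#'   numeric vector with names among N, H, F, S.
#' @return a `glycan_composition`.
#' @export
as_glycan_composition <- function(g) {
  if (inherits(g, "glycan_composition")) return(g)
  if (is.character(g)) return(parse_glycan_composition(g))
  if (is.numeric(g) && !is.null(names(g))) {
    counts <- c(N = 0L, H = 0L, F = 0L, S = 0L)
    bad <- setdiff(names(g), .GLYCAN_LETTERS)
    if (length(bad)) {
      stop("unknown monosaccharide letter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    counts[names(g)] <- as.integer(g)
    return(new_glycan_composition(counts))
  }
  stop("cannot interpret object as a glycan composition", call. = FALSE)
}

#' Mass of a compositional glycan
#'
#' Sum of monosaccharide residue masses (the masses added upon glycosidic
#' bond formation), on the monoisotopic or average scale.
#'
#' @param g a `glycan_composition` or composition string.
#' @param scale `"mono"` (default) or `"avg"`.
#' @return mass in Da; `0` for the empty composition.
#' @examples
#' glycan_mass("N1")        # HexNAc, 203.079373
#' glycan_mass("N1H1")      # core 1 disaccharide
#' @export
glycan_mass <- function(g, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  g <- as_glycan_composition(g)
  tab <- if (scale == "mono") .MONO_GLYCAN else .AVG_GLYCAN
  sum(tab * as.integer(g))
}

#' Default core 1 O-glycan catalog
#'
#' Nine compositional core 1 type O-glycans used as the default library
#' catalog for beta-casein glycoproteoform enumeration: the neutral,
#' fucosylated and sialylated elaborations of the GalNAc/core 1 scaffold.
#' The set is a documented, overridable default — confirm it against the
#' glycan database used by your own search before relying on it.
#'
#' @return character vector of nine canonical composition strings.
#' @export
default_glycan_catalog <- function() {
  c("N1", "N1H1", "N1F1", "N1H1F1", "N1H1S1",
    "N1H1S2", "N1H1F1S1", "N1S1", "N2H2")
}
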