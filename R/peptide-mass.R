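#' Amino acid sequence with precursor numbering
#'
#' A thin container for a peptide or protein sequence together with the
#' 1-based precursor-coordinate position of its first residue. Beta-casein
#' site labels in the literature use precursor numbering that includes the
#' 15-residue signal peptide, so the mature chain starts at offset 16.
#'
#' @param residues a single string over the 20 canonical one-letter codes.
#' @param offset 1-based precursor position of the first residue (default 1).
#' @return an object of class `aa_sequence` with fields `residues` and
#'   `offset`.
#' @examples
#' aa_sequence("RETIESLSSSEESIT", offset = 16)
#' @export
aa_sequence <- function(residues, offset = 1L) {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues) ||
      nchar(residues) < 1L) {
    stop("residues must be a single non-empty string", call. = FALSE)
  }
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), names(.MONO_RESIDUE))
  if (length(bad)) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L) stop("offset must be an integer >= 1", call. = FALSE)
  structure(list(residues = residues, offset = offset), class = "aa_sequence")
}

#' @export
print.aa_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("<aa sequence> %d aa, precursor positions %d-%d\n",
              n, x$offset, x$offset + n - 1L))
  cat(" ", x$residues, "\n")
  invisible(x)
}

#' @export
length.aa_sequence <- function(x) nchar(x$residues)

#' Residue letter at a precursor position
#'
#' @param seq an `aa_sequence`.
#' @param pos precursor-coordinate position(s).
#' @return one-letter code(s); errors if any position is outside the span.
#' @export
residue_at <- function(seq, pos) {
  stopifnot(inherits(seq, "aa_sequence"))
  idx <- as.integer(pos) - seq$offset + 1L
  if (any(idx < 1L | idx > nchar(seq$residues))) {
    stop("position outside the sequence span", call. = FALSE)
  }
  substring(seq$residues, idx, idx)
}

#' Create a modification delta
#'
#' A localized modification: phosphorylation or an O-glycan on Ser/Thr, or
#' methionine oxidation (supported for mass bookkeeping only). `site` is in
#' precursor coordinates.
#'
#' @param kind `"phospho"`, `"glycan"` or `"oxidation"`.
#' @param site precursor-coordinate position.
#' @param glycan composition (string or `glycan_composition`), required when
#'   `kind = "glycan"`; must have total monosaccharide count >= 1.
#' @return an object of class `mod_delta` with `mono_mass`/`avg_mass` fields.
#' @export
mod_delta <- function(kind = c("phospho", "glycan", "oxidation"), site, glycan = NULL) {
  kind <- match.arg(kind)
  site <- as.integer(site)
  if (is.na(site) || site < 1L) stop("site must be an integer >= 1", call. = FALSE)
  if (kind == "glycan") {
    if (is.null(glycan)) stop("a glycan modification needs a composition", call. = FALSE)
    glycan <- as_glycan_composition(glycan)
    if (sum(glycan) < 1L) {
      stop("a glycan attached as a modification must have total count >= 1", call. = FALSE)
    }
    mono <- glycan_mass(glycan, "mono"); avg <- glycan_mass(glycan, "avg")
  } else if (kind == "phospho") {
    glycan <- NULL
    mono <- .MASS_PHOSPHO[["mono"]]; avg <- .MASS_PHOSPHO[["avg"]]
  } else {
    glycan <- NULL
    mono <- .MASS_OXIDATION[["mono"]]; avg <- .MASS_OXIDATION[["avg"]]
  }
  structure(list(kind = kind, site = site, glycan = glycan,
                 mono_mass = mono, avg_mass = avg),
            class = "mod_delta")
}

.mod_allowed_residues <- function(kind) {
  switch(kind, phospho = c("S", "T"), glycan = c("S", "T"), oxidation = "M")
}

#' Neutral mass of a (modified) peptide
#'
#' Incremental residue-mass computation: sum of residue masses plus one
#' water, plus the deltas of any modifications. Ser/Thr localization is
#' enforced for phospho and glycan modifications, Met for oxidation.
#'
#' @param seq an `aa_sequence` (or plain string, taken with offset 1).
#' @param mods list of `mod_delta` objects (default none).
#' @param scale `"mono"` (default) or `"avg"`.
#' @return neutral mass in Da.
#' @examples
#' peptide_mass(aa_sequence("G"))                        # glycine, 75.0320 Da
#' peptide_mass(aa_sequence("T"), list(mod_delta("phospho", 1)))
#' @export
peptide_mass <- function(seq, mods = list(), scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  if (is.character(seq)) seq <- aa_sequence(seq)
  stopifnot(inherits(seq, "aa_sequence"))
  if (inherits(mods, "mod_delta")) mods <- list(mods)
  tab <- if (scale == "mono") .MONO_RESIDUE else .AVG_RESIDUE
  chars <- strsplit(seq$residues, "")[[1]]
  mass <- sum(tab[chars]) + .MASS_WATER[[scale]]
  for (m in mods) {
    stopifnot(inherits(m, "mod_delta"))
    last <- seq$offset + nchar(seq$residues) - 1L
    if (m$site < seq$offset || m$site > last) {
      stop(sprintf("modification site %d outside peptide span %d-%d",
                   m$site, seq$offset, last), call. = FALSE)
    }
    res <- residue_at(seq, m$site)
    if (!res %in% .mod_allowed_residues(m$kind)) {
      stop(sprintf("%s modification at position %d sits on '%s' (requires %s)",
                   m$kind, m$site, res,
                   paste(.mod_allowed_residues(m$kind), collapse = "/")),
           call. = FALSE)
    }
    mass <- mass + if (scale == "mono") m$mono_mass else m$avg_mass
  }
  unname(mass)
}

# "pos:kind" or "pos:glycan:N1H1" items joined by ";" — the serialized form
# used in all tabular I/O.
parse_mod_string <- function(s) {
  if (length(s) != 1L) stop("parse_mod_string takes one string")
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(site = integer(), kind = character(),
                      glycan = character(), stringsAsFactors = FALSE))
  }
  items <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- strsplit(items, ":", fixed = TRUE)
  site <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  kind <- vapply(parts, function(p) p[2], character(1))
  glyc <- vapply(parts, function(p) if (length(p) >= 3L) p[3] else NA_character_,
                 character(1))
  if (any(is.na(site)) || !all(kind %in% c("phospho", "glycan", "oxidation"))) {
    stop("malformed modification string: ", s, call. = FALSE)
  }
  if (any(kind == "glycan" & (is.na(glyc) | !nzchar(glyc)))) {
    stop("glycan modification without composition in: ", s, call. = FALSE)
  }
  data.frame(site = site, kind = kind, glycan = glyc, stringsAsFactors = FALSE)
}

format_mod_string <- function(site, kind, glycan = NULL) {
  if (length(site) == 0L) return("")
  item <- ifelse(kind == "glycan", paste(site, kind, glycan, sep = ":"),
                 paste(site, kind, sep = ":"))
  paste(item, collapse = ";")
}

#' Parse serialized modification lists
#'
#' Tabular inputs carry per-row modification lists in the compact form
#' `"pos:kind"` or `"pos:glycan:COMPOSITION"`, joined by `";"`, e.g.
#' `"24:phospho;214:glycan:N1H1"`. This expands a vector of such strings to
#' one long data frame.
#'
#' @param mods character vector (empty string / `NA` mean no modifications).
#' @return data frame with columns `row` (index into `mods`), `site`,
#'   `kind`, `glycan`.
#' @export
parse_mods <- function(mods) {
  empty <- data.frame(row = integer(), site = integer(), kind = character(),
                      glycan = character(), stringsAsFactors = FALSE)
  if (length(mods) == 0L) return(empty)
  mods[is.na(mods)] <- ""
  items <- strsplit(mods, ";", fixed = TRUE)
  rows <- rep(seq_along(mods), lengths(items))
  flat <- unlist(items, use.names = FALSE)
  keep <- nzchar(flat)
  rows <- rows[keep]; flat <- flat[keep]
  if (length(flat) == 0L) return(empty)
  parts <- strsplit(flat, ":", fixed = TRUE)
  np <- lengths(parts)
  pv <- unlist(parts, use.names = FALSE)
  first <- cumsum(c(1L, np[-length(np)]))
  site <- suppressWarnings(as.integer(pv[first]))
  kind <- pv[first + 1L]
  glyc <- ifelse(np >= 3L, pv[first + 2L], NA_character_)
  bad <- is.na(site) | np < 2L | !kind %in% c("phospho", "glycan", "oxidation")
  if (any(bad)) {
    stop("malformed modification string: ", flat[which(bad)[1]], call. = FALSE)
  }
  if (any(kind == "glycan" & (is.na(glyc) | !nzchar(glyc)))) {
    stop("glycan modification without composition in: ",
         flat[which(kind == "glycan" & (is.na(glyc) | !nzchar(glyc)))[1]],
         call. = FALSE)
  }
  data.frame(row = rows, site = site, kind = kind, glycan = glyc,
             stringsAsFactors = FALSE)
}
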