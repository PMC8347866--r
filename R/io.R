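#' Read a protein sequence from FASTA
#'
#' Reads the first record of a FASTA file (via Biostrings) and returns it
#' as an `aa_sequence` in precursor coordinates. The accession is parsed
#' from the header (UniProt-style `db|ACCESSION|NAME` headers supported)
#' and kept as the `accession` attribute.
#'
#' @param path FASTA file path.
#' @param offset precursor position of the first residue (default 1).
#' @return an `aa_sequence` with attribute `accession`.
#' @export
read_protein_fasta <- function(path, offset = 1L) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 1L) stop("no FASTA records in ", path, call. = FALSE)
  header <- names(set)[1]
  acc <- header
  if (grepl("|", header, fixed = TRUE)) {
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) acc <- parts[2]
  } else {
    acc <- strsplit(header, "[ \t]")[[1]][1]
  }
  seq <- aa_sequence(as.character(set[[1]]), offset = offset)
  attr(seq, "accession") <- acc
  seq
}

#' Packaged synthetic beta-casein stand-in sequence
#'
#' Returns the packaged SYNTHETIC stand-in for the human beta-casein
#' precursor (226 aa, signal peptide 1-15, mature chain 16-226). Residues
#' 16-30 (the N-terminal phosphorylation cluster) and 190-226 (the
#' C-terminal glycosylation/ladder region) carry the documented beta-casein
#' fragments; the signal peptide and residues 31-189 are synthetic filler
#' with no Ser/Thr, composed so that the precursor length (226) and average
#' mass (~25.4 kDa) match the real entry's headline values. It is NOT the
#' UniProtKB P05814 sequence: substitute the real FASTA via
#' [read_protein_fasta()] for any analysis of real data.
#'
#' @param mature return only the mature chain 16-226 (default FALSE).
#' @return an `aa_sequence` (offset 1 for the precursor, 16 for the mature
#'   chain).
#' @export
beta_casein_reference <- function(mature = FALSE) {
  path <- system.file("extdata", "synthetic_P05814_like.fasta",
                      package = "casoform", mustWork = TRUE)
  seq <- read_protein_fasta(path, offset = 1L)
  if (mature) mature_chain(seq) else seq
}

#' Extract the mature chain from a precursor sequence
#'
#' @param seq precursor `aa_sequence` (offset 1).
#' @param mature_start first precursor position of the mature chain
#'   (default 16).
#' @return an `aa_sequence` with `offset = mature_start`.
#' @export
mature_chain <- function(seq, mature_start = 16L) {
  stopifnot(inherits(seq, "aa_sequence"), seq$offset == 1L)
  aa_sequence(substring(seq$residues, mature_start, nchar(seq$residues)),
              offset = mature_start)
}

#' Headline checks on a reference precursor sequence
#'
#' Computes the two headline descriptors used to sanity-check a candidate
#' beta-casein precursor: sequence length in residues and full-length
#' average mass (kDa). For the canonical human entry these are 226 aa and
#' ~25 kDa.
#'
#' @param seq precursor `aa_sequence`.
#' @return list with `length_aa`, `avg_mass_da`, `avg_mass_kda` (rounded to
#'   the nearest kDa) and `mono_mass_da`.
#' @export
check_reference_sequence <- function(seq) {
  stopifnot(inherits(seq, "aa_sequence"))
  avg <- peptide_mass(seq, scale = "avg")
  list(length_aa = nchar(seq$residues),
       avg_mass_da = avg,
       avg_mass_kda = as.integer(round_half_up(avg / 1000)),
       mono_mass_da = peptide_mass(seq, scale = "mono"))
}

.read_delim_schema <- function(path, required, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a bottom-up PSM table
#'
#' Delimited text with the fixed schema `peptide, start, end, mods,
#' log_prob_abs, score, delta_mod, is_decoy, donor, week, dataset`
#' (optionally `frag_type`). Modifications are serialized as
#' `"pos:kind[:composition]"` items joined by `";"`.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return PSM data frame.
#' @export
read_psm_table <- function(path, sep = ",") {
  df <- .read_delim_schema(path, c("peptide", "start", "end", "mods",
                                   "log_prob_abs", "score", "delta_mod",
                                   "is_decoy", "donor", "week", "dataset"), sep)
  df$mods[is.na(df$mods)] <- ""
  df$is_decoy <- as.logical(df$is_decoy)
  .check_psm_table(df)
}

#' Read a deconvoluted feature list
#'
#' Schema: `mass, rt, intensity` plus optional `run_id, resolution_mode`.
#'
#' @inheritParams read_psm_table
#' @return feature data frame.
#' @export
read_feature_table <- function(path, sep = ",") {
  .check_features(.read_delim_schema(path, c("mass", "rt", "intensity"), sep))
}

#' Read a PrSM identification table
#'
#' Schema: `proteoform_label, precursor_mass, rt` plus optional `run_id`.
#'
#' @inheritParams read_psm_table
#' @return PrSM data frame.
#' @export
read_prsm_table <- function(path, sep = ",") {
  .read_delim_schema(path, c("proteoform_label", "precursor_mass", "rt"), sep)
}

#' Read an MS1 peptidoform area table
#'
#' Schema: `start, end, mods, area` plus optional `donor, week, dataset`.
#'
#' @inheritParams read_psm_table
#' @return peptidoform area data frame.
#' @export
read_area_table <- function(path, sep = ",") {
  df <- .read_delim_schema(path, c("start", "end", "mods", "area"), sep)
  df$mods[is.na(df$mods)] <- ""
  df
}

#' Write a pipeline table as delimited text
#'
#' @param df data frame.
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_pipeline_table <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
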