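# Minimum-free-energy secondary structure under the package's embedded
# stacking-only nearest-neighbor model (Watson-Crick + G:U wobble, linear
# hairpin/bulge/internal-loop penalties, affine multiloops, no dangles).
# T and U are interchangeable on input. Energies are model-internal
# kcal/mol: screens downstream are calibrated against this engine, and
# `fold_engine` hooks let a caller substitute an external folder.

.encode_seq <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) stop("seq must be a single string")
  if (nchar(seq) < 1L) stop("empty sequence")
  up <- chartr("u", "U", toupper(seq))
  up <- gsub("T", "U", up, fixed = TRUE)
  codes <- match(strsplit(up, "")[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) stop("invalid alphabet in sequence (expected A/C/G/U/T)")
  codes
}

.new_fold_result <- function(seq, res) {
  structure(
    list(sequence = toupper(seq), structure = res$structure,
         energy = res$energy, partner = res$partner),
    class = "fold_result"
  )
}

#' Predict the minimum-free-energy secondary structure
#'
#' Dynamic-programming MFE fold over all non-crossing structures with a
#' 3-nt minimum hairpin loop. The empty structure (energy 0) is always a
#' candidate, so any returned structure containing pairs has energy <= 0.
#'
#' @param seq RNA or DNA string (A/C/G/U/T, case-insensitive).
#' @return `fold_result`: list with `sequence`, dot-bracket `structure`,
#'   `energy` (kcal/mol) and `partner` (1-based pairing partner per
#'   position, 0 if unpaired).
#' @export
fold_mfe <- function(seq) {
  codes <- .encode_seq(seq)
  res <- .c_fold(codes, rep(FALSE, length(codes)))
  .new_fold_result(seq, res)
}

#' MFE structure with positions constrained to stay unpaired
#'
#' Used for target-site accessibility: the unpaired energy (UPE) to open a
#' site is `fold_constrained(seq, site)$energy - fold_mfe(seq)$energy`.
#'
#' @param seq RNA or DNA string.
#' @param unpaired `NULL` (no constraint) or `c(start, end)`, a 1-based
#'   inclusive interval forced to remain unpaired.
#' @return `fold_result`; its energy is >= `fold_mfe(seq)$energy`.
#' @export
fold_constrained <- function(seq, unpaired = NULL) {
  codes <- .encode_seq(seq)
  forbid <- rep(FALSE, length(codes))
  if (!is.null(unpaired) && length(unpaired) > 0L) {
    if (length(unpaired) != 2L) stop("unpaired must be NULL or c(start, end)")
    s <- as.integer(unpaired[1]); e <- as.integer(unpaired[2])
    if (s < 1L || e > length(codes) || s > e) stop("constraint interval out of bounds")
    forbid[s:e] <- TRUE
  }
  res <- .c_fold(codes, forbid)
  .new_fold_result(seq, res)
}

#' Minimum hybridization energy of two short RNAs
#'
#' Minimum energy over intermolecular-only pairings between `a` (5'->3')
#' and `b` in reverse orientation (antiparallel duplex); no intramolecular
#' pairs. Returns 0 when no pairing is favorable or possible.
#'
#' @param a,b sequences of at most 40 nt.
#' @return energy in kcal/mol (<= 0).
#' @export
duplex_energy <- function(a, b) {
  ca <- .encode_seq(a); cb <- .encode_seq(b)
  if (length(ca) > 40L || length(cb) > 40L) stop("duplex sequences must be <= 40 nt")
  .c_duplex(ca, cb)
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", format(x$energy), " kcal/mol)\n", sep = "")
  invisible(x)
}
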