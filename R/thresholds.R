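# Every numeric threshold used by the pipeline lives in one auditable object,
# so all stages share a single parameter set.

.threshold_defaults <- list(
  read_len_min       = 15L,    # clean-library length window, nt
  read_len_max       = 30L,
  mirna_len_min      = 18L,    # mature miRNA candidate lengths, nt
  mirna_len_max      = 26L,
  pirna_len_min      = 26L,    # piRNA-like lengths, nt
  pirna_len_max      = 30L,
  window_min         = 60L,    # precursor scan windows, nt
  window_max         = 300L,
  window_step        = 20L,
  mfe_coeff          = -0.35,  # kcal/mol per nt: precursor must fold below coeff*length
  max_mismatch_mature = 4L,    # mismatched (facing) mature positions allowed
  max_bulge_mature   = 2L,     # unopposed bulge runs allowed in the mature
  max_bulge_len      = 2L,     # nt per bulge run
  min_paired_frac    = 0.5,    # paired fraction of the precursor window
  overhang           = 2L,     # 3' overhang of the miRNA:miRNA* duplex, nt
  min_abund_with_star = 3L,    # library count needed when a star read exists
  min_abund_no_star  = 100L,   # library count needed without a star read
  plant_max_mismatch = 3,      # weighted mismatches (G:U = 0.5) in plant mode
  plant_max_upe      = 30,     # kcal/mol to open the target site
  animal_seed_start  = 2L,     # seed positions from the miRNA 5' end
  animal_seed_end    = 8L,
  animal_max_energy  = -20,    # kcal/mol duplex bound in animal mode
  phase_len          = 21L,    # ta-siRNA phase register, nt
  phase_window       = 231L,   # ta-siRNA scan window, nt
  phase_alpha        = 0.001,  # hypergeometric significance level
  nat_min_overlap    = 25L     # minimum sense/antisense gene-pair overlap, nt
)

.threshold_integer_keys <- names(.threshold_defaults)[vapply(
  .threshold_defaults, is.integer, logical(1)
)]

validate_thresholds <- function(th) {
  need <- function(ok, msg) if (!isTRUE(ok)) stop("invalid thresholds: ", msg, call. = FALSE)
  need(th$read_len_min <= th$read_len_max, "read_len_min > read_len_max")
  need(th$mirna_len_min <= th$mirna_len_max, "mirna_len_min > mirna_len_max")
  need(th$pirna_len_min <= th$pirna_len_max, "pirna_len_min > pirna_len_max")
  need(th$window_min <= th$window_max, "window_min > window_max")
  need(th$window_step > 0, "window_step must be > 0")
  need(th$mfe_coeff < 0, "mfe_coeff must be negative")
  need(th$phase_window > 0 && th$phase_window %% th$phase_len == 0,
       "phase_window must be a positive multiple of phase_len")
  need(th$phase_alpha > 0 && th$phase_alpha < 1, "phase_alpha must be in (0,1)")
  need(th$animal_seed_start >= 1 && th$animal_seed_end >= th$animal_seed_start,
       "animal seed interval is empty")
  need(th$overhang >= 0, "overhang must be >= 0")
  need(th$nat_min_overlap >= 1, "nat_min_overlap must be >= 1")
  invisible(th)
}

#' Default pipeline thresholds
#'
#' Returns the full set of numeric thresholds used by every pipeline stage:
#' read-length windows, precursor-scan window geometry, the MFE screen
#' coefficient (-0.35 kcal/mol per nt), hairpin curation limits (at most four
#' mismatches and two short bulges in the mature region, at least half of the
#' precursor paired), duplex overhang, abundance rules (count >= 3 with a
#' star read, >= 100 without), target-prediction bounds, the 21-nt/231-nt
#' phasing geometry with alpha = 0.001, and the 25-nt antisense gene-pair
#' overlap.
#'
#' @return an object of class `smrna_thresholds` (a named list).
#' @export
default_thresholds <- function() {
  structure(.threshold_defaults, class = "smrna_thresholds")
}

#' Load thresholds from a flat key/value config file
#'
#' The file format is one `key = value` per line, `#` comments and blank
#' lines allowed. Absent keys take their defaults; unknown keys are an error
#' (they are almost always typos, and thresholds drive the science).
#'
#' @param path path to a config file, or `NULL` for all defaults.
#' @return validated `smrna_thresholds` object.
#' @export
load_thresholds <- function(path = NULL) {
  th <- .threshold_defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        stop("malformed config line (expected key = value): '", ln, "'", call. = FALSE)
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(th)) stop("unknown threshold key: '", key, "'", call. = FALSE)
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("non-numeric value for key '", key, "': '", val, "'", call. = FALSE)
      th[[key]] <- if (key %in% .threshold_integer_keys) as.integer(num) else num
    }
  }
  validate_thresholds(structure(th, class = "smrna_thresholds"))
}

#' Write thresholds to a flat key/value config file
#'
#' @param th `smrna_thresholds` object.
#' @param path output file path.
#' @return `path`, invisibly. `load_thresholds(path)` round-trips to an
#'   equal object.
#' @export
write_thresholds <- function(th, path) {
  stopifnot(inherits(th, "smrna_thresholds"))
  lines <- vapply(names(th), function(k) {
    sprintf("%s = %s", k, format(th[[k]], scientific = FALSE))
  }, character(1))
  writeLines(c("# pipeline thresholds", lines), path)
  invisible(path)
}

#' @export
print.smrna_thresholds <- function(x, ...) {
  cat("<smrna_thresholds>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
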