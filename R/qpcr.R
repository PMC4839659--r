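# Stem-loop RT-qPCR arithmetic: relative expression (2^-dCT), differential
# expression (2^-ddCT) and primer efficiency from a dilution-series slope.

#' Expression relative to a reference gene (2^-dCT)
#'
#' @param ct_target,ct_ref cycle-threshold values (replicates allowed; the
#'   arithmetic mean of CTs is taken before exponentiation, the standard
#'   Livak convention).
#' @return fold expression relative to the reference.
#' @export
relative_expression <- function(ct_target, ct_ref) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_ref)))
  2^-(mean(ct_target) - mean(ct_ref))
}

#' Differential expression between two conditions (2^-ddCT)
#'
#' ddCT = (CT_target_A - CT_ref_A) - (CT_target_B - CT_ref_B); the fold
#' change of condition A relative to B is 2^-ddCT. With replicate CTs,
#' means are used for the point estimate and two dispersion estimates are
#' emitted: the SD of per-replicate folds and the fold range implied by the
#' propagated CT standard deviation (the conventions behind "99x +/- 43x"
#' style reporting differ between labs, so both are given).
#'
#' @param ct_t_a,ct_ref_a target/reference CTs in condition A (vectors).
#' @param ct_t_b,ct_ref_b target/reference CTs in condition B.
#' @return list `fold`, `ddct`, `sd_ddct`, `fold_sd` (SD of per-replicate
#'   folds, NA without matched replicates), class `qpcr_fold`.
#' @export
fold_change <- function(ct_t_a, ct_ref_a, ct_t_b, ct_ref_b) {
  stopifnot(all(is.finite(c(ct_t_a, ct_ref_a, ct_t_b, ct_ref_b))))
  ddct <- (mean(ct_t_a) - mean(ct_ref_a)) - (mean(ct_t_b) - mean(ct_ref_b))
  n <- length(ct_t_a)
  matched <- n > 1L && length(ct_ref_a) == n && length(ct_t_b) == n &&
    length(ct_ref_b) == n
  fold_sd <- NA_real_
  sd_ddct <- NA_real_
  if (matched) {
    rep_ddct <- (ct_t_a - ct_ref_a) - (ct_t_b - ct_ref_b)
    sd_ddct <- sd(rep_ddct)
    fold_sd <- sd(2^-rep_ddct)
  }
  structure(list(fold = 2^-ddct, ddct = ddct, sd_ddct = sd_ddct,
                 fold_sd = fold_sd),
            class = "qpcr_fold")
}

#' @export
print.qpcr_fold <- function(x, ...) {
  cat(sprintf("fold change 2^-ddCT = %.4g (ddCT = %.4g)\n", x$fold, x$ddct))
  if (!is.na(x$fold_sd)) cat(sprintf("  +/- %.4g (SD of replicate folds)\n", x$fold_sd))
  invisible(x)
}

#' PCR amplification efficiency from a standard-curve slope
#'
#' E = 10^(-1/slope); a perfect doubling per cycle gives slope -3.3219 and
#' E = 2. Reported both raw and as percent efficiency (E - 1) x 100, the
#' scale on which ranges like 95.8-99.2 are quoted.
#'
#' @param slope cycles per log10 dilution; must be negative.
#' @return list `E` (amplification factor) and `percent`.
#' @export
pcr_efficiency <- function(slope) {
  if (!is.finite(slope) || slope >= 0) stop("slope must be negative")
  E <- 10^(-1 / slope)
  list(E = E, percent = (E - 1) * 100)
}

#' Relative-expression table from a CT table
#'
#' @param ct data.frame `sample`,`target`,`ct` (one row per replicate).
#' @param reference reference target id (e.g. "U6").
#' @return data.frame `sample`,`target`,`rel_expr` (2^-dCT vs the reference,
#'   replicate means), skipping the reference itself.
#' @export
qpcr_table <- function(ct, reference = "U6") {
  stopifnot(all(c("sample", "target", "ct") %in% names(ct)))
  out <- list()
  for (smp in unique(ct$sample)) {
    sub <- ct[ct$sample == smp, , drop = FALSE]
    ref <- sub$ct[sub$target == reference]
    if (length(ref) == 0L) stop("no reference '", reference, "' CTs for sample ", smp)
    for (tg in setdiff(unique(sub$target), reference)) {
      out[[length(out) + 1L]] <- data.frame(
        sample = smp, target = tg,
        rel_expr = relative_expression(sub$ct[sub$target == tg], ref),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sample = character(0), target = character(0),
                      rel_expr = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
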