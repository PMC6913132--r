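## Writer/eraser perturbation-sensitivity scoring.
##
## The methylation signal spikes 1-3 nt upstream (5') of the motif start,
## i.e. at offsets -5..-3 from the central A. A site is sensitive to a
## writer-depletion (or eraser-overexpression) condition when its mean
## fraction-modified value over the peak offsets is strictly greater in the
## baseline condition than in the perturbed one.

#' Score per-site sensitivity to a perturbation
#'
#' Pairs windows from the baseline (wild-type) and perturbed conditions by
#' site identity `(ref, a_pos, strand)` and compares the mean signal over the
#' peak offsets. Strict inequality defines sensitivity, so exact ties are not
#' sensitive. Sites present in only one condition (e.g. lost to the coverage
#' filter) are excluded and counted in the `n_unpaired` attribute; the paired
#' definition needs both means.
#'
#' @param wt Baseline-condition `m6a_windows`.
#' @param perturbed Perturbed-condition `m6a_windows` with the same flank.
#' @param peak_offsets Offsets of the signal spike relative to the central A
#'   (default `c(-5, -4, -3)`, the three bases immediately 5' of the motif).
#' @return Data frame with one row per paired site: `ref`, `a_pos`, `strand`,
#'   `motif`, `wt_peak_mean`, `perturbed_peak_mean`, `sensitive`; attribute
#'   `n_unpaired` counts single-condition sites.
#' @export
site_sensitivity <- function(wt, perturbed, peak_offsets = c(-5L, -4L, -3L)) {
  stopifnot(inherits(wt, "m6a_windows"), inherits(perturbed, "m6a_windows"))
  if (!identical(wt$flank, perturbed$flank))
    stop("pairing error: conditions extracted with different flanks (",
         wt$flank, " vs ", perturbed$flank, ")")
  if (any(peak_offsets < -wt$flank | peak_offsets > wt$flank))
    stop("peak offsets must lie within [-flank, flank]")
  cols <- as.character(as.integer(peak_offsets))
  key_wt <- paste(wt$sites$ref, wt$sites$a_pos, wt$sites$strand, sep = "\r")
  key_pt <- paste(perturbed$sites$ref, perturbed$sites$a_pos,
                  perturbed$sites$strand, sep = "\r")
  i_wt <- which(key_wt %in% key_pt)
  if (length(i_wt) == 0L)
    stop("pairing error: no site present in both conditions")
  i_pt <- match(key_wt[i_wt], key_pt)
  wt_mean <- rowMeans(wt$values[i_wt, cols, drop = FALSE])
  pt_mean <- rowMeans(perturbed$values[i_pt, cols, drop = FALSE])
  out <- data.frame(ref = wt$sites$ref[i_wt],
                    a_pos = wt$sites$a_pos[i_wt],
                    strand = wt$sites$strand[i_wt],
                    motif = wt$sites$motif[i_wt],
                    wt_peak_mean = wt_mean,
                    perturbed_peak_mean = pt_mean,
                    sensitive = wt_mean > pt_mean,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unpaired") <-
    (nrow(wt$sites) - length(i_wt)) + (nrow(perturbed$sites) - length(i_pt))
  out
}

#' Sensitive-site fractions by prediction class
#'
#' Joins per-site sensitivity results with methylation calls and reports, for
#' each class (`m6A`, `not_m6A`), the fraction of sites sensitive to the
#' perturbation. If predicted sites are real, the m6A class should lose
#' signal under writer depletion far more often than the not_m6A class. A
#' class with no members gets an undefined (`NA`) fraction, not 0.
#'
#' @param sensitivity Data frame from [site_sensitivity()].
#' @param predictions An `m6a_predictions` data frame covering every paired
#'   site.
#' @return Data frame with one row per class: `call`, `n`, `n_sensitive`,
#'   `fraction_sensitive`.
#' @export
sensitivity_fractions <- function(sensitivity, predictions) {
  key_s <- paste(sensitivity$ref, sensitivity$a_pos, sensitivity$strand,
                 sep = "\r")
  key_p <- paste(predictions$ref, predictions$a_pos, predictions$strand,
                 sep = "\r")
  idx <- match(key_s, key_p)
  if (anyNA(idx)) {
    miss <- sensitivity[is.na(idx), c("ref", "a_pos")]
    stop("no prediction for paired site(s): ",
         paste(miss$ref, miss$a_pos, sep = ":", collapse = ", "))
  }
  call <- predictions$call[idx]
  out <- do.call(rbind, lapply(c("m6A", "not_m6A"), function(cl) {
    sel <- call == cl
    n <- sum(sel)
    data.frame(call = cl, n = n, n_sensitive = sum(sensitivity$sensitive[sel]),
               fraction_sensitive = if (n == 0L) NA_real_ else
                 mean(sensitivity$sensitive[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
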