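## Applying qualifying per-motif models to candidate windows.

#' Predict methylation status of candidate windows
#'
#' Applies the per-motif forests to every window whose motif is on the
#' whitelist. The default whitelist is the four motifs whose models qualify
#' on real data (AGACT, GGACA, GGACC, GGACT); windows with other motifs are
#' skipped and counted in the `skipped_motifs` attribute. A site is called
#' `m6A` when its predicted probability is at least `threshold`.
#'
#' @param windows An `m6a_windows` object (extracted with the same flank the
#'   models were trained with).
#' @param models An `m6a_model_set`.
#' @param threshold Call threshold on predicted probability (default 0.5).
#' @param motifs Motif whitelist; every whitelisted motif must have a model.
#' @return An `m6a_predictions` data frame sorted by coordinate: `ref`,
#'   `a_pos`, `motif`, `strand`, `probability`, `call`, with attribute
#'   `skipped_motifs` (count of non-whitelisted windows).
#' @export
predict_sites <- function(windows, models, threshold = 0.5,
                          motifs = c("AGACT", "GGACA", "GGACC", "GGACT")) {
  stopifnot(inherits(windows, "m6a_windows"),
            inherits(models, "m6a_model_set"))
  if (!identical(as.integer(windows$flank), as.integer(models$flank)))
    stop("flank mismatch: windows have flank ", windows$flank,
         " but models were trained with flank ", models$flank)
  missing <- setdiff(motifs, names(models$models))
  if (length(missing) > 0L)
    stop("configuration error: no model for whitelisted motif(s): ",
         paste(missing, collapse = ", "))
  sel <- windows$sites$motif %in% motifs
  skipped <- sum(!sel)
  s <- windows$sites[sel, , drop = FALSE]
  v <- windows$values[sel, , drop = FALSE]
  prob <- numeric(nrow(s))
  for (m in unique(s$motif)) {
    rows <- which(s$motif == m)
    prob[rows] <- .forest_prob(models$models[[m]]$classifier,
                               v[rows, , drop = FALSE])
  }
  out <- data.frame(ref = s$ref, a_pos = s$a_pos, motif = s$motif,
                    strand = s$strand, probability = prob,
                    call = ifelse(prob >= threshold, "m6A", "not_m6A"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$ref, out$a_pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_motifs") <- skipped
  class(out) <- c("m6a_predictions", "data.frame")
  out
}

#' @describeIn predict_sites S3 `predict` method for a fitted model set.
#' @param object An `m6a_model_set`.
#' @param ... Passed on to [predict_sites()].
#' @export
predict.m6a_model_set <- function(object, windows, ...) {
  predict_sites(windows, object, ...)
}

#' @export
print.m6a_predictions <- function(x, ...) {
  cat("<m6a_predictions> ", nrow(x), " sites (",
      sum(x$call == "m6A"), " m6A, ", sum(x$call == "not_m6A"),
      " not_m6A); ", attr(x, "skipped_motifs") %||% 0L,
      " window(s) skipped off-whitelist\n", sep = "")
  NextMethod()
}
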