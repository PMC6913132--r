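## Feature-window extraction and truth labeling.
##
## A feature window is the vector of fraction-modified values at offsets
## -flank..+flank around a candidate A, ordered 5'->3' in transcript sense,
## plus the read coverage at the central A and a truth label.

.track_lookup <- function(tracks) {
  # tracks: one track object or a list of them (plus/minus split);
  # returns per (ref, strand) position/value tables
  if (inherits(tracks, "signal_track") || inherits(tracks, "coverage_track"))
    tracks <- list(tracks)
  out <- list()
  for (tr in tracks) {
    for (rn in unique(tr$data$ref)) {
      key <- paste0(rn, "\r", tr$strand)
      d <- tr$data[tr$data$ref == rn, , drop = FALSE]
      out[[key]] <- list(pos = d$pos, value = d$value)
    }
  }
  out
}

#' Extract fixed-length signal windows around candidate sites
#'
#' For each candidate site, collects the fraction-modified values at offsets
#' `-flank..+flank` from the central A (21 values at the default `flank = 10`)
#' and the read coverage at the central A. A window is retained only if
#' coverage at the central A is at least `min_coverage` (the low-coverage
#' error-rate filter) *and* a signal value exists at every offset: the
#' classifiers need complete fixed-length vectors and no imputation is done.
#' Minus-strand sites draw values from the minus-strand track and reverse the
#' offset order, so index 1 is always the most 5' position in transcript
#' sense.
#'
#' Dropped windows are tallied by reason (`out_of_bounds`, `low_coverage`,
#' `incomplete_signal`) in the object's drop report; positions absent from the
#' coverage track count as zero coverage.
#'
#' @param sites Candidate-site data frame from [scan_reference()].
#' @param signal A `signal_track`, or a list of two strand-split tracks.
#' @param coverage A `coverage_track`, or a list of two strand-split tracks.
#' @param flank Half-window width in nt (default 10, i.e. 21 values).
#' @param min_coverage Minimum read count at the central A (default 5).
#' @return An `m6a_windows` object: site table, value matrix (one row per
#'   retained window, columns named by offset), center coverage, labels
#'   (initially `"unknown"`), the flank, and a drop report.
#' @export
extract_windows <- function(sites, signal, coverage, flank = 10L,
                            min_coverage = 5L) {
  stopifnot(flank >= 0L, min_coverage >= 0L)
  flank <- as.integer(flank)
  sig <- .track_lookup(signal)
  cov <- .track_lookup(coverage)
  offs <- seq.int(-flank, flank)
  n <- nrow(sites)
  keep <- logical(n)
  dropped <- c(out_of_bounds = 0L, low_coverage = 0L, incomplete_signal = 0L)
  values <- matrix(NA_real_, nrow = n, ncol = 2L * flank + 1L,
                   dimnames = list(NULL, as.character(offs)))
  centre_cov <- integer(n)
  key <- paste0(sites$ref, "\r", sites$strand)
  for (k in unique(key)) {
    rows <- which(key == k)
    sg <- sig[[k]]
    cv <- cov[[k]]
    a <- sites$a_pos[rows]
    sgn <- ifelse(sites$strand[rows] == "-", -1L, 1L)
    # genomic positions per offset, transcript-sense order
    gpos <- a + sgn * matrix(offs, nrow = length(a), ncol = length(offs),
                             byrow = TRUE)
    oob <- apply(gpos, 1L, function(p) any(p < 0L))
    ccov <- if (is.null(cv)) rep(NA_integer_, length(a)) else
      cv$value[match(a, cv$pos)]
    ccov[is.na(ccov)] <- 0L
    centre_cov[rows] <- ccov
    vals <- if (is.null(sg)) {
      matrix(NA_real_, nrow = length(a), ncol = length(offs))
    } else {
      matrix(sg$value[match(as.vector(gpos), sg$pos)], nrow = length(a))
    }
    incomplete <- apply(vals, 1L, anyNA)
    ok <- !oob & ccov >= min_coverage & !incomplete
    dropped[["out_of_bounds"]] <- dropped[["out_of_bounds"]] + sum(oob)
    dropped[["low_coverage"]] <-
      dropped[["low_coverage"]] + sum(!oob & ccov < min_coverage)
    dropped[["incomplete_signal"]] <-
      dropped[["incomplete_signal"]] + sum(!oob & ccov >= min_coverage &
                                             incomplete)
    keep[rows] <- ok
    values[rows, ] <- vals
  }
  out <- list(sites = sites[keep, , drop = FALSE],
              values = values[keep, , drop = FALSE],
              coverage = centre_cov[keep],
              label = rep("unknown", sum(keep)),
              flank = flank,
              min_coverage = as.integer(min_coverage),
              dropped = dropped)
  rownames(out$sites) <- NULL
  class(out) <- "m6a_windows"
  out
}

#' Label windows against a truth-interval set
#'
#' A window is labeled `positive` when its central A coordinate falls inside
#' any truth interval (0-based half-open) on the same reference — and same
#' strand, when the truth set carries strands — otherwise `negative`. This is
#' single-base containment of the site midpoint, the natural reading of
#' intersecting candidate regions with single-base CLIP calls. Labeling is
#' idempotent and independent of window order.
#'
#' @param windows An `m6a_windows` object.
#' @param truth Data frame with columns `ref`, `start`, `end` and optionally
#'   `strand` (see [read_truth_bed()]), or a path to a BED file.
#' @return The windows with `label` filled in.
#' @export
label_windows <- function(windows, truth) {
  stopifnot(inherits(windows, "m6a_windows"))
  if (is.character(truth)) truth <- read_truth_bed(truth)
  if (any(truth$end <= truth$start))
    stop("truth validation error: interval with end <= start")
  if (is.null(truth$strand)) truth$strand <- NA_character_
  stranded <- !any(is.na(truth$strand)) && nrow(truth) > 0L
  s <- windows$sites
  if (nrow(s) == 0L) return(windows)
  q <- GenomicRanges::GRanges(
    s$ref, IRanges::IRanges(start = s$a_pos + 1L, width = 1L),
    strand = if (stranded) s$strand else "*")
  subj <- GenomicRanges::GRanges(
    truth$ref, IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = if (stranded) truth$strand else "*")
  # truth sets covering none of the windows' references are legitimate
  # (empty overlap), so the disjoint-seqlevels warning is noise here
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(q, subj, ignore.strand = !stranded)) > 0L
  windows$label <- ifelse(hit, "positive", "negative")
  windows
}

#' Per-run drop report
#'
#' @param windows An `m6a_windows` object.
#' @return Data frame of drop reasons and counts.
#' @export
drop_report <- function(windows) {
  stopifnot(inherits(windows, "m6a_windows"))
  data.frame(reason = names(windows$dropped),
             count = as.integer(windows$dropped),
             stringsAsFactors = FALSE)
}

#' Write the drop report as TSV
#'
#' @param windows An `m6a_windows` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_drop_report <- function(windows, path) {
  utils::write.table(drop_report(windows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset windows
#'
#' @param x An `m6a_windows` object.
#' @param i Row index (logical or integer) over retained windows.
#' @param ... Unused.
#' @return The subsetted `m6a_windows`.
#' @export
`[.m6a_windows` <- function(x, i, ...) {
  x$sites <- x$sites[i, , drop = FALSE]
  rownames(x$sites) <- NULL
  x$values <- x$values[i, , drop = FALSE]
  x$coverage <- x$coverage[i]
  x$label <- x$label[i]
  x
}

#' @export
print.m6a_windows <- function(x, ...) {
  tab <- table(factor(x$label, levels = c("positive", "negative", "unknown")))
  cat("<m6a_windows> ", nrow(x$sites), " windows (flank ", x$flank, ", ",
      2L * x$flank + 1L, " values each)\n", sep = "")
  cat("  labels: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  dropped:", paste(names(x$dropped), x$dropped, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}
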