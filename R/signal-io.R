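## Readers/writers for the per-position track formats emitted by nanopore
## signal-level preprocessing (fraction-modified wiggle, coverage bedgraph)
## and for BED interval output.
##
## Wiggle positions are 1-based on disk and shifted to 0-based internally;
## bedgraph and BED are already 0-based half-open. Positions absent from a
## track are missing, not zero: a measured fraction of 0.0 is data, absence
## of signal is not.

.new_track <- function(data, strand, class) {
  stopifnot(strand %in% c("+", "-"))
  data <- data[order(data$ref, data$pos), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, strand = strand), class = class)
}

#' Read a fraction-modified wiggle track
#'
#' Parses a wiggle file in either `variableStep` or `fixedStep` dialect
#' (span 1, the convention of signal-level modification detectors) into a
#' per-position signal track. Declared 1-based positions are shifted to
#' 0-based. Values must lie in `[0, 1]` — they are fractions of reads whose
#' current deviates from the canonical model at that base.
#'
#' @param path Path to a wiggle file.
#' @param strand Strand tag for the track (`"+"` or `"-"`). Genomic-mode
#'   preprocessing emits separate plus/minus files; cDNA mode uses a single
#'   sense-strand file (the default tag).
#' @return A `signal_track`: per-reference mapping from 0-based position to
#'   fraction-modified value.
#' @export
read_wiggle <- function(path, strand = "+") {
  lines <- trimws(readLines(path))
  skip <- lines == "" | startsWith(lines, "#") | startsWith(lines, "track")
  is_header <- startsWith(lines, "variableStep") | startsWith(lines, "fixedStep")
  first_data <- which(!skip & !is_header)
  if (length(first_data) > 0L &&
      (!any(is_header) || first_data[[1L]] < which(is_header)[[1L]]))
    stop("wiggle parse error at line ", first_data[[1L]],
         ": data before any step header")
  blocks <- list()
  header_at <- which(is_header)
  for (b in seq_along(header_at)) {
    i <- header_at[[b]]
    last <- if (b < length(header_at)) header_at[[b + 1L]] - 1L
            else length(lines)
    data_idx <- setdiff(seq.int(i, last), which(skip))
    data_idx <- data_idx[data_idx != i]
    mode <- sub("\\s.*$", "", lines[[i]])
    fields <- .parse_wig_header(lines[[i]], i)
    if (!is.na(fields[["span"]]) && fields[["span"]] != 1L)
      stop("wiggle parse error at line ", i, ": only span=1 is supported")
    if (length(data_idx) == 0L) next
    toks <- strsplit(lines[data_idx], "[ \t]+")
    nt <- lengths(toks)
    if (mode == "variableStep") {
      if (any(nt != 2L))
        stop("wiggle parse error at line ", data_idx[[which(nt != 2L)[1L]]],
             ": expected 'position value'")
      tk <- matrix(unlist(toks), nrow = 2L)
      pos1 <- suppressWarnings(as.integer(tk[1L, ]))
      val <- suppressWarnings(as.numeric(tk[2L, ]))
      if (anyNA(pos1) || any(pos1 < 1L))
        stop("wiggle parse error at line ",
             data_idx[[which(is.na(pos1) | pos1 < 1L)[1L]]],
             ": bad position")
    } else {
      if (is.na(fields[["start"]]))
        stop("wiggle parse error at line ", i, ": fixedStep needs start=")
      if (fields[["start"]] < 1L)
        stop("wiggle parse error at line ", i, ": start must be >= 1")
      step <- if (is.na(fields[["step"]])) 1L else fields[["step"]]
      if (step < 1L)
        stop("wiggle parse error at line ", i, ": step must be >= 1")
      if (any(nt != 1L))
        stop("wiggle parse error at line ", data_idx[[which(nt != 1L)[1L]]],
             ": expected a single value")
      val <- suppressWarnings(as.numeric(unlist(toks)))
      pos1 <- fields[["start"]] + step * (seq_along(val) - 1L)
    }
    if (anyNA(val))
      stop("wiggle parse error at line ", data_idx[[which(is.na(val))[1L]]],
           ": non-numeric value")
    bad <- val < 0 | val > 1
    if (any(bad))
      stop("wiggle validation error at line ", data_idx[[which(bad)[1L]]],
           ": value ", val[which(bad)[1L]], " outside [0, 1]")
    blocks[[b]] <- data.frame(ref = rep(fields[["chrom"]], length(val)),
                              pos = pos1 - 1L, value = val,
                              stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, blocks)
  if (is.null(data))
    data <- data.frame(ref = character(), pos = integer(), value = numeric(),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(data[c("ref", "pos")]))
    stop("wiggle validation error: duplicate positions in ", path)
  .new_track(data, strand, "signal_track")
}

.parse_wig_header <- function(line, lineno) {
  get <- function(key) {
    m <- regmatches(line, regexec(paste0("\\b", key, "=([^ \t]+)"), line))[[1]]
    if (length(m) < 2L) return(NA_character_)
    m[[2]]
  }
  chrom <- get("chrom")
  if (is.na(chrom))
    stop("wiggle parse error at line ", lineno, ": missing chrom=")
  as_int <- function(x, key) {
    if (is.na(x)) return(NA_integer_)
    v <- suppressWarnings(as.integer(x))
    if (is.na(v))
      stop("wiggle parse error at line ", lineno, ": bad ", key, "=", x)
    v
  }
  list(chrom = chrom,
       start = as_int(get("start"), "start"),
       step = as_int(get("step"), "step"),
       span = as_int(get("span"), "span"))
}

#' Write a signal track as variableStep wiggle
#'
#' Inverse of [read_wiggle()]: 0-based internal positions are written back as
#' 1-based `variableStep` records, one declaration per reference, values at
#' full double precision so that read-write round trips are exact.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_wiggle <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (rn in unique(track$data$ref)) {
    d <- track$data[track$data$ref == rn, , drop = FALSE]
    writeLines(sprintf("variableStep chrom=%s", rn), con)
    writeLines(sprintf("%d %s", d$pos + 1L, sprintf("%.17g", d$value)), con)
  }
  invisible(path)
}

#' Read a read-coverage bedgraph track
#'
#' Parses a 4-column bedgraph of 0-based half-open intervals and expands each
#' interval `(ref, s, e, v)` to per-position counts at `s .. e-1`. Counts must
#' be non-negative integers. Overlapping intervals are rejected: disjoint
#' output is the emitter's contract and overlap indicates a corrupted file.
#'
#' @param path Path to a bedgraph file.
#' @param strand Strand tag, as in [read_wiggle()].
#' @return A `coverage_track`: per-reference mapping from 0-based position to
#'   read count.
#' @export
read_bedgraph <- function(path, strand = "+") {
  lines <- trimws(readLines(path))
  idx <- which(!grepl("^($|#|track)", lines))
  if (length(idx) == 0L)
    return(.new_track(data.frame(ref = character(), pos = integer(),
                                 value = integer(),
                                 stringsAsFactors = FALSE),
                      strand, "coverage_track"))
  toks <- strsplit(lines[idx], "[ \t]+")
  nt <- lengths(toks)
  if (any(nt != 4L))
    stop("bedgraph parse error at line ", idx[[which(nt != 4L)[1L]]],
         ": expected 4 columns")
  tk <- matrix(unlist(toks), nrow = 4L)
  ref <- tk[1L, ]
  s <- suppressWarnings(as.integer(tk[2L, ]))
  e <- suppressWarnings(as.integer(tk[3L, ]))
  v <- suppressWarnings(as.numeric(tk[4L, ]))
  if (anyNA(s) || anyNA(e) || anyNA(v))
    stop("bedgraph parse error at line ",
         idx[[which(is.na(s) | is.na(e) | is.na(v))[1L]]],
         ": non-numeric field")
  if (any(e <= s)) {
    i <- which(e <= s)[1L]
    stop("bedgraph validation error at line ", idx[[i]],
         ": empty or inverted interval [", s[[i]], ", ", e[[i]], ")")
  }
  if (any(s < 0L))
    stop("bedgraph validation error at line ", idx[[which(s < 0L)[1L]]],
         ": negative start")
  if (any(v < 0 | v != round(v)))
    stop("bedgraph validation error at line ",
         idx[[which(v < 0 | v != round(v))[1L]]],
         ": coverage must be a non-negative integer")
  # overlap check per reference on the interval list
  for (rn in unique(ref)) {
    k <- which(ref == rn)
    o <- order(s[k])
    ss <- s[k][o]; ee <- e[k][o]
    if (length(ss) > 1L && any(ss[-1L] < ee[-length(ee)]))
      stop("bedgraph validation error: overlapping intervals on ", rn,
           " in ", path)
  }
  widths <- e - s
  data <- data.frame(ref = rep(ref, widths),
                     pos = sequence(widths) - 1L + rep(s, widths),
                     value = rep(as.integer(v), widths),
                     stringsAsFactors = FALSE)
  .new_track(data, strand, "coverage_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a signal or coverage track from a data frame
#'
#' Programmatic constructor used by tests and simulations; equivalent to
#' reading a file with the same per-position content.
#'
#' @param data Data frame with columns `ref`, `pos` (0-based), `value`.
#' @param strand Strand tag.
#' @param type `"signal"` (values validated to `[0, 1]`) or `"coverage"`
#'   (non-negative integers).
#' @return A `signal_track` or `coverage_track`.
#' @export
as_track <- function(data, strand = "+", type = c("signal", "coverage")) {
  type <- match.arg(type)
  stopifnot(all(c("ref", "pos", "value") %in% names(data)))
  if (anyDuplicated(data[c("ref", "pos")]))
    stop("duplicate positions in track data")
  if (any(data$pos < 0)) stop("negative positions in track data")
  if (type == "signal") {
    if (any(data$value < 0 | data$value > 1))
      stop("signal values outside [0, 1]")
    cls <- "signal_track"
  } else {
    if (any(data$value < 0 | data$value != round(data$value)))
      stop("coverage values must be non-negative integers")
    cls <- "coverage_track"
  }
  .new_track(data.frame(ref = as.character(data$ref),
                        pos = as.integer(data$pos),
                        value = data$value, stringsAsFactors = FALSE),
             strand, cls)
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> strand", x$strand, "-", nrow(x$data), "positions on",
      length(unique(x$data$ref)), "reference(s)\n")
  invisible(x)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> strand", x$strand, "-", nrow(x$data), "positions on",
      length(unique(x$data$ref)), "reference(s)\n")
  invisible(x)
}

#' Read a truth-interval BED file
#'
#' Reads known-m6A intervals (e.g. CLIP-derived single-base calls) as 0-based
#' half-open intervals. Strand is taken from column 6 when present, otherwise
#' labels are applied strand-blind.
#'
#' @param path Path to a BED3+ file.
#' @return Data frame with columns `ref`, `start`, `end`, `strand` (`NA` when
#'   the file has no strand column).
#' @export
read_truth_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = paste0("V", 1:12), fill = TRUE)[, 1:6]
  out <- data.frame(ref = as.character(tab$V1),
                    start = as.integer(tab$V2),
                    end = as.integer(tab$V3),
                    strand = ifelse(tab$V6 %in% c("+", "-"),
                                    as.character(tab$V6), NA_character_),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$start) | is.na(out$end)))
    stop("truth BED parse error: non-integer coordinates in ", path)
  if (any(out$end <= out$start))
    stop("truth BED validation error: interval with end <= start in ", path)
  out
}

#' Write methylation calls as BED6
#'
#' One line per prediction record:
#' `chrom, a_pos, a_pos + 1, motif:call, round(1000 * probability), strand`,
#' sorted by `(chrom, start)`. Both calls (`m6A` and `not_m6A`) are written by
#' default because downstream perturbation-sensitivity analysis needs both
#' classes; `positive_only` restricts output to `m6A` calls.
#'
#' @param records Prediction data frame from [predict_sites()].
#' @param path Output path.
#' @param positive_only Write only `m6A` calls.
#' @return The path, invisibly.
#' @export
write_bed <- function(records, path, positive_only = FALSE) {
  if (positive_only) records <- records[records$call == "m6A", , drop = FALSE]
  records <- records[order(records$ref, records$a_pos), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s:%s\t%d\t%s",
                   records$ref, records$a_pos, records$a_pos + 1L,
                   records$motif, records$call,
                   as.integer(round(1000 * records$probability)),
                   records$strand)
  writeLines(lines, path)
  invisible(path)
}
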