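## Transcript-to-genome coordinate lifting and cross-isoform classification
## of shared genomic positions.

#' Read transcript exon structures from a GTF
#'
#' Imports exon features and groups them by `transcript_id` into transcript
#' models with 0-based half-open genomic exon intervals ordered 5'->3' in
#' transcript direction (increasing starts on `+`, decreasing on `-`).
#'
#' @param path Path to a GTF file.
#' @return A named `transcript_models` list; each element holds
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` (two-column
#'   matrix `start`, `end`, 0-based half-open) and `length`.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in GTF: ", path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,  # to 0-based
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   transcript_id = gr$transcript_id,
                   gene_id = gr$gene_id,
                   stringsAsFactors = FALSE)
  out <- lapply(split(df, df$transcript_id), function(d) {
    transcript_model(transcript_id = d$transcript_id[[1]],
                     gene_id = d$gene_id[[1]],
                     chrom = d$chrom[[1]],
                     strand = d$strand[[1]],
                     exons = cbind(start = d$start, end = d$end))
  })
  structure(out, class = "transcript_models")
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id,chrom,strand Identifiers and location.
#' @param exons Two-column matrix of 0-based half-open genomic intervals in
#'   any order; they are sorted into 5'->3' transcript order and checked for
#'   overlap.
#' @return A `transcript_model` list.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-"), ncol(exons) == 2L)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript ", transcript_id, ": exon with end <= start")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript ", transcript_id, ": overlapping exons")
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  colnames(exons) <- c("start", "end")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 length = sum(exons[, 2L] - exons[, 1L])),
            class = "transcript_model")
}

#' Lift a transcript coordinate to the genome
#'
#' Walks the exons 5'->3' to find the genomic base under the `tx_pos`-th
#' transcript base (both 0-based). On the minus strand transcript offsets run
#' against the genomic axis, so offset 0 maps to the last base of the 5'-most
#' exon interval.
#'
#' @param tx A `transcript_model`.
#' @param tx_pos 0-based transcript offset(s); vectorized.
#' @return Data frame with columns `chrom`, `genomic_pos`, `strand`.
#' @export
transcript_to_genome <- function(tx, tx_pos) {
  stopifnot(inherits(tx, "transcript_model"))
  tx_pos <- as.integer(tx_pos)
  if (any(tx_pos < 0L | tx_pos >= tx$length))
    stop("transcript position out of range [0, ", tx$length, ") for ",
         tx$transcript_id)
  lens <- tx$exons[, "end"] - tx$exons[, "start"]
  cum <- cumsum(lens)
  exon <- findInterval(tx_pos, c(0L, cum), rightmost.closed = FALSE)
  within <- tx_pos - c(0L, cum)[exon]
  gpos <- if (tx$strand == "+") {
    tx$exons[exon, "start"] + within
  } else {
    tx$exons[exon, "end"] - 1L - within
  }
  data.frame(chrom = tx$chrom, genomic_pos = as.integer(gpos),
             strand = tx$strand, stringsAsFactors = FALSE)
}

#' Lift a genomic coordinate back to transcript space
#'
#' Inverse of [transcript_to_genome()] for positions covered by the
#' transcript's exons.
#'
#' @param tx A `transcript_model`.
#' @param genomic_pos 0-based genomic position(s); vectorized.
#' @return Integer vector of 0-based transcript offsets.
#' @export
genome_to_transcript <- function(tx, genomic_pos) {
  stopifnot(inherits(tx, "transcript_model"))
  genomic_pos <- as.integer(genomic_pos)
  lens <- tx$exons[, "end"] - tx$exons[, "start"]
  offsets <- c(0L, cumsum(lens))
  out <- rep(NA_integer_, length(genomic_pos))
  for (k in seq_len(nrow(tx$exons))) {
    s <- tx$exons[k, "start"]; e <- tx$exons[k, "end"]
    inside <- genomic_pos >= s & genomic_pos < e
    within <- if (tx$strand == "+") genomic_pos - s else e - 1L - genomic_pos
    out[inside] <- offsets[k] + within[inside]
  }
  if (anyNA(out))
    stop("genomic position(s) not covered by exons of ", tx$transcript_id,
         ": ", paste(genomic_pos[is.na(out)], collapse = ", "))
  out
}

#' Classify shared genomic positions by cross-isoform agreement
#'
#' Lifts transcript-space predictions to genomic coordinates and groups them
#' by `(chrom, genomic_pos, strand)`. Positions covered by at least two
#' isoforms are classified: `never` when no isoform is called m6A,
#' `consistent` when all are, `isoform_specific` otherwise. Motif identity is
#' recorded but not required to match across isoforms (exon-boundary contexts
#' can differ). Predictions whose signal window spans an exon junction are
#' flagged, since their signal context and genomic context diverge; only the
#' central A is lifted.
#'
#' The gene-level summary counts genes with at least one m6A call and genes
#' whose shared positions include an isoform-specific category.
#'
#' @param predictions An `m6a_predictions` data frame whose `ref` values are
#'   transcript ids.
#' @param tx_models A `transcript_models` list covering every predicted
#'   transcript.
#' @param flank Half-window width used at prediction time, for junction
#'   flagging (default 10).
#' @return A `shared_site_classification` list: `lifted` (per-prediction
#'   genomic coordinates and junction flags), `shared` (classified positions
#'   with >= 2 covering isoforms), `genes` (per-gene table) and `summary`
#'   (category and gene counts).
#' @export
classify_shared_sites <- function(predictions, tx_models, flank = 10L) {
  stopifnot(inherits(tx_models, "transcript_models"))
  unknown <- setdiff(unique(predictions$ref), names(tx_models))
  if (length(unknown) > 0L)
    stop("prediction(s) on transcript(s) absent from the annotation: ",
         paste(unknown, collapse = ", "))
  n <- nrow(predictions)
  chrom <- character(n); gpos <- integer(n); strand <- character(n)
  gene <- character(n); junction <- logical(n)
  for (tid in unique(predictions$ref)) {
    rows <- which(predictions$ref == tid)
    tx <- tx_models[[tid]]
    lift <- transcript_to_genome(tx, predictions$a_pos[rows])
    chrom[rows] <- lift$chrom
    gpos[rows] <- lift$genomic_pos
    strand[rows] <- lift$strand
    gene[rows] <- tx$gene_id
    # a window spans a junction when its in-range ends map to different exons
    lens <- tx$exons[, "end"] - tx$exons[, "start"]
    cum <- c(0L, cumsum(lens))
    lo <- pmax(predictions$a_pos[rows] - flank, 0L)
    hi <- pmin(predictions$a_pos[rows] + flank, tx$length - 1L)
    junction[rows] <- findInterval(lo, cum, rightmost.closed = FALSE) !=
      findInterval(hi, cum, rightmost.closed = FALSE)
  }
  lifted <- cbind(predictions,
                  data.frame(chrom = chrom, genomic_pos = gpos,
                             genomic_strand = strand, gene_id = gene,
                             junction_spanning = junction,
                             stringsAsFactors = FALSE))
  class(lifted) <- "data.frame"
  key <- paste(chrom, gpos, strand, sep = "\r")
  grp <- split(seq_len(n), key)
  shared_rows <- grp[lengths(grp) >= 2L]
  shared <- do.call(rbind, lapply(shared_rows, function(rows) {
    calls <- predictions$call[rows]
    category <- if (all(calls == "not_m6A")) "never"
      else if (all(calls == "m6A")) "consistent"
      else "isoform_specific"
    data.frame(chrom = chrom[rows[1L]], genomic_pos = gpos[rows[1L]],
               strand = strand[rows[1L]], n_isoforms = length(rows),
               n_m6a = sum(calls == "m6A"),
               isoforms = paste(predictions$ref[rows], collapse = ","),
               calls = paste(calls, collapse = ","),
               genes = paste(unique(gene[rows]), collapse = ","),
               category = category, stringsAsFactors = FALSE)
  }))
  if (is.null(shared))
    shared <- data.frame(chrom = character(), genomic_pos = integer(),
                         strand = character(), n_isoforms = integer(),
                         n_m6a = integer(), isoforms = character(),
                         calls = character(), genes = character(),
                         category = character(), stringsAsFactors = FALSE)
  shared <- shared[order(shared$chrom, shared$genomic_pos), , drop = FALSE]
  rownames(shared) <- NULL
  gene_m6a <- tapply(predictions$call == "m6A", gene, any)
  iso_genes <- unique(unlist(strsplit(
    shared$genes[shared$category == "isoform_specific"], ",")))
  genes <- data.frame(gene_id = names(gene_m6a),
                      any_m6a = as.logical(gene_m6a),
                      isoform_specific = names(gene_m6a) %in% iso_genes,
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(
    lifted = lifted,
    shared = shared,
    genes = genes,
    summary = list(
      n_positions = length(grp),
      n_shared = nrow(shared),
      n_never = sum(shared$category == "never"),
      n_consistent = sum(shared$category == "consistent"),
      n_isoform_specific = sum(shared$category == "isoform_specific"),
      n_m6a_genes = sum(genes$any_m6a),
      n_isoform_specific_genes = sum(genes$isoform_specific))),
    class = "shared_site_classification")
}

#' @export
print.shared_site_classification <- function(x, ...) {
  s <- x$summary
  cat("<shared_site_classification>\n")
  cat("  genomic positions analyzed:", s$n_positions, "\n")
  cat("  covered by >= 2 isoforms:  ", s$n_shared,
      sprintf(" (never %d, consistent %d, isoform-specific %d)\n",
              s$n_never, s$n_consistent, s$n_isoform_specific))
  cat("  m6A-containing genes:", s$n_m6a_genes,
      "- with isoform-specific methylation:", s$n_isoform_specific_genes,
      "\n")
  invisible(x)
}

#' Write the shared-site table as TSV
#'
#' BED-style 0-based coordinates, one row per multi-isoform genomic position.
#'
#' @param x A `shared_site_classification`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_shared_sites <- function(x, path) {
  stopifnot(inherits(x, "shared_site_classification"))
  utils::write.table(x$shared, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
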