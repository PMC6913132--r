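## DRACH motif enumeration and candidate-site scanning.
##
## All coordinates are 0-based internally; conversion to/from 1-based happens
## only at file boundaries (wiggle reading/writing).

# IUPAC classes of the DRACH consensus, DNA form
.DRACH_D <- c("A", "G", "T")
.DRACH_R <- c("A", "G")
.DRACH_H <- c("A", "C", "T")

#' Enumerate the DRACH motif family
#'
#' Expands the degenerate 5-mer consensus `[AGT][AG]AC[ACT]` (DRACH in IUPAC
#' codes, DNA form) into the full set of resolved 5-mers. Every member has an
#' adenosine at position 3 — the candidate methylation site — followed by a C.
#' One classifier is trained per member, so this set also enumerates the
#' possible per-motif models.
#'
#' @return A sorted character vector of 18 distinct 5-mers.
#' @examples
#' drach_motifs()
#' @export
drach_motifs <- function() {
  grid <- expand.grid(h = .DRACH_H, r = .DRACH_R, d = .DRACH_D,
                      stringsAsFactors = FALSE)
  sort(paste0(grid$d, grid$r, "A", "C", grid$h))
}

#' Read a reference FASTA into normalized DNA strings
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file, uppercases the
#' sequences and normalizes U to T so that RNA-alphabet cDNA references can be
#' scanned with DNA-form motifs.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record, over the alphabet
#'   `A,C,G,T,N`.
#' @export
read_reference <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-DNA characters (beyond N) in FASTA record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  # keep only the first whitespace token of each header, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Locate DRACH candidate sites in one sequence
#'
#' Scans a single reference sequence for occurrences of (a subset of) the 18
#' DRACH 5-mers and reports one candidate site per occurrence, anchored on the
#' central A. Overlapping occurrences are all reported; any occurrence whose
#' 5-mer contains an N is not reported because it cannot be resolved to one of
#' the per-motif models.
#'
#' On the minus strand the motif is read 5'->3' on the reverse complement, but
#' `a_pos` is always the plus-strand (reference) coordinate of the central
#' base, matching BED conventions.
#'
#' @param ref_name Reference sequence identifier used in the output.
#' @param sequence A single string over `A,C,G,T,U,N` (case-insensitive;
#'   U is normalized to T).
#' @param strand `"+"` or `"-"`.
#' @param motifs Subset of [drach_motifs()] to report.
#' @return A data frame with columns `ref`, `a_pos` (0-based coordinate of the
#'   central A), `motif` (resolved 5-mer as read on `strand`), `strand`,
#'   sorted by `a_pos`.
#' @examples
#' scan_sequence("tx1", "GGACTGACTA")
#' @export
scan_sequence <- function(ref_name, sequence, strand = "+",
                          motifs = drach_motifs()) {
  stopifnot(length(sequence) == 1L, strand %in% c("+", "-"))
  bad_motif <- setdiff(motifs, drach_motifs())
  if (length(bad_motif) > 0L)
    stop("motif subset contains non-DRACH 5-mers: ",
         paste(bad_motif, collapse = ", "))
  seq <- chartr("U", "T", toupper(sequence))
  if (grepl("[^ACGTN]", seq))
    stop("sequence for '", ref_name,
         "' contains non-DNA characters beyond N")
  subject <- Biostrings::DNAString(seq)
  n <- length(subject)
  if (strand == "-") subject <- Biostrings::reverseComplement(subject)
  # pattern ambiguities expand, subject letters are literal: N never matches
  hits <- Biostrings::matchPattern("DRACH", subject, fixed = "subject")
  starts0 <- BiocGenerics::start(hits) - 1L           # 0-based match starts
  found <- as.character(hits)
  keep <- found %in% motifs
  starts0 <- starts0[keep]
  found <- found[keep]
  centre <- starts0 + 2L                               # central A, scan frame
  if (strand == "-") centre <- n - 1L - centre        # reflect to + frame
  out <- data.frame(ref = rep(ref_name, length(centre)),
                    a_pos = centre, motif = found,
                    strand = rep(strand, length(centre)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$a_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate DRACH candidate sites across a reference set
#'
#' @param seqs Named character vector of sequences (e.g. from
#'   [read_reference()]), or a path to a FASTA file.
#' @param motifs Subset of [drach_motifs()] to report.
#' @param strands Strands to scan: `"+"` for cDNA/transcriptomic references
#'   (the default), `c("+", "-")` for genomic references where both strands
#'   carry genes.
#' @return A data frame as in [scan_sequence()], sorted by
#'   `(ref, a_pos, strand)`.
#' @export
scan_reference <- function(seqs, motifs = drach_motifs(), strands = "+") {
  if (is.character(seqs) && length(seqs) == 1L && is.null(names(seqs)) &&
      file.exists(seqs)) {
    seqs <- read_reference(seqs)
  }
  stopifnot(!is.null(names(seqs)), all(strands %in% c("+", "-")))
  parts <- list()
  for (rn in names(seqs)) {
    for (st in strands) {
      parts[[length(parts) + 1L]] <- scan_sequence(rn, seqs[[rn]], st, motifs)
    }
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(ref = character(), a_pos = integer(),
                      motif = character(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$ref, out$a_pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write candidate sites as BED6
#'
#' One line per site: `chrom, a_pos, a_pos + 1, motif, 0, strand`.
#'
#' @param sites Data frame of sites from [scan_reference()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  sites <- sites[order(sites$ref, sites$a_pos), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   sites$ref, sites$a_pos, sites$a_pos + 1L,
                   sites$motif, sites$strand)
  writeLines(lines, path)
  invisible(path)
}
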