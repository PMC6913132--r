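# Independent oracles and small fixture builders shared across tests.

# Naive degenerate-pattern scan: test every 5-mer window against the DRACH
# regex. Deliberately independent of the Biostrings-based implementation.
brute_drach_scan <- function(sequence, motifs = drach_motifs()) {
  s <- chartr("U", "T", toupper(sequence))
  n <- nchar(s)
  a_pos <- integer(0); motif <- character(0)
  if (n >= 5L) {
    for (i in seq_len(n - 4L)) {
      k <- substr(s, i, i + 4L)
      if (grepl("^[AGT][AG]AC[ACT]$", k) && k %in% motifs) {
        a_pos <- c(a_pos, i + 1L)   # 0-based central A of match at 1-based i
        motif <- c(motif, k)
      }
    }
  }
  data.frame(a_pos = a_pos, motif = motif, stringsAsFactors = FALSE)
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Closed-form pairwise AUC (Mann-Whitney with half-credit for ties);
# independent of the pROC-based implementation.
auc_pairs <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Build an m6a_windows object directly, bypassing track files: one motif,
# n_pos positive and n_neg negative windows, Gaussian noise around baseline
# with an additive peak at offsets -5..-3 for positives.
make_windows <- function(n_pos, n_neg, flank = 10L, motif = "GGACT",
                         baseline = 0.5, peak = 0.3, noise = 0.1,
                         seed = 1L) {
  set.seed(seed)
  n <- n_pos + n_neg
  offs <- seq.int(-flank, flank)
  values <- matrix(pmin(pmax(rnorm(n * length(offs), baseline, noise), 0), 1),
                   nrow = n, dimnames = list(NULL, as.character(offs)))
  if (n_pos > 0L && peak != 0) {
    pk <- as.character(c(-5L, -4L, -3L))
    values[seq_len(n_pos), pk] <-
      pmin(values[seq_len(n_pos), pk, drop = FALSE] + peak, 1)
  }
  structure(list(
    sites = data.frame(ref = "tx1",
                       a_pos = flank + 25L * (seq_len(n) - 1L),
                       motif = motif, strand = "+",
                       stringsAsFactors = FALSE),
    values = values,
    coverage = rep(10L, n),
    label = rep(c("positive", "negative"), c(n_pos, n_neg)),
    flank = as.integer(flank),
    min_coverage = 5L,
    dropped = c(out_of_bounds = 0L, low_coverage = 0L,
                incomplete_signal = 0L)),
    class = "m6a_windows")
}

# Track builders for hand-crafted per-position data.
signal_from_df <- function(ref, pos, value, strand = "+") {
  as_track(data.frame(ref = ref, pos = pos, value = value), strand, "signal")
}

coverage_from_df <- function(ref, pos, value, strand = "+") {
  as_track(data.frame(ref = ref, pos = pos, value = value), strand,
           "coverage")
}

# End-to-end convenience: scan + extract + label a generated fixture.
fixture_windows <- function(fx, which = c("wt", "perturbed"),
                            flank = 10L, min_coverage = 5L) {
  which <- match.arg(which)
  sites <- scan_reference(fx$paths$reference)
  sig <- read_wiggle(fx$paths[[paste0(which, "_signal")]])
  cov <- read_bedgraph(fx$paths[[paste0(which, "_coverage")]])
  label_windows(extract_windows(sites, sig, cov, flank = flank,
                                min_coverage = min_coverage),
                fx$paths$truth)
}
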