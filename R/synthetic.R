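## Synthetic fixture generator.
##
## Emulates the statistical structure the classifiers assume: fraction-
## modified tracks with baseline ~0.5, an additive signal spike at the peak
## offsets (1-3 nt 5' of planted methylated DRACH motifs), uniform read
## coverage, a perturbed condition with the spike attenuated, and an
## intentionally incomplete truth BED (a fraction of truly methylated sites
## is unlabeled, mimicking sites missed by CLIP).

#' Configuration for a synthetic fixture
#'
#' Defaults encode the study conditions the generator emulates: baseline
#' fraction-modified 0.5, a planted peak of +0.3 at offsets -5..-3, Gaussian
#' noise with sd 0.1 (clipped to `[0, 1]`), coverage uniform on 5..50, 70% of
#' methylated sites carried in the truth BED, and full peak removal in the
#' perturbed condition.
#'
#' @param n_sequences Number of reference sequences.
#' @param seq_length Length of each sequence (nt).
#' @param n_methylated_sites Planted methylated DRACH sites.
#' @param n_unmethylated_drach_decoys Planted unmethylated DRACH sites.
#' @param motifs 5-mers to plant (subset of [drach_motifs()]).
#' @param baseline_mean Baseline fraction-modified value.
#' @param peak_delta Additive spike at peak offsets of methylated sites.
#' @param noise_sd Gaussian noise sd on every position.
#' @param peak_offsets Spike offsets relative to the central A.
#' @param coverage_range Inclusive integer range of uniform per-position
#'   read coverage.
#' @param truth_label_fraction Fraction of methylated sites written to
#'   `truth.bed`.
#' @param perturbation_attenuation Fraction of the spike removed in the
#'   perturbed condition (1 = fully removed, 0 = null perturbation).
#' @param flank Half-window width assumed downstream; sites are spaced
#'   `2 * flank + 5` apart so windows never overlap.
#' @param seed Integer seed; fixtures are byte-identical for equal seeds.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_sequences = 20L, seq_length = 2500L,
                             n_methylated_sites = 500L,
                             n_unmethylated_drach_decoys = 500L,
                             motifs = c("AGACT", "GGACA", "GGACC", "GGACT"),
                             baseline_mean = 0.5, peak_delta = 0.3,
                             noise_sd = 0.1,
                             peak_offsets = c(-5L, -4L, -3L),
                             coverage_range = c(5L, 50L),
                             truth_label_fraction = 0.7,
                             perturbation_attenuation = 1,
                             flank = 10L, seed = 1L) {
  stopifnot(baseline_mean >= 0, baseline_mean <= 1,
            truth_label_fraction >= 0, truth_label_fraction <= 1,
            perturbation_attenuation >= 0, perturbation_attenuation <= 1,
            noise_sd >= 0, flank >= 0L, length(coverage_range) == 2L,
            coverage_range[1L] <= coverage_range[2L],
            all(motifs %in% drach_motifs()),
            all(peak_offsets >= -flank & peak_offsets <= flank))
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length),
                 n_methylated_sites = as.integer(n_methylated_sites),
                 n_unmethylated_drach_decoys =
                   as.integer(n_unmethylated_drach_decoys),
                 motifs = motifs,
                 baseline_mean = baseline_mean,
                 peak_delta = peak_delta,
                 noise_sd = noise_sd,
                 peak_offsets = as.integer(peak_offsets),
                 coverage_range = as.integer(coverage_range),
                 truth_label_fraction = truth_label_fraction,
                 perturbation_attenuation = perturbation_attenuation,
                 flank = as.integer(flank),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.random_clean_sequence <- function(len, planted_a, planted_motif) {
  # random ACGT sequence with the planted motifs written in and every
  # accidental DRACH occurrence broken by a single substitution outside the
  # planted footprints
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (k in seq_along(planted_a)) {
    a <- planted_a[[k]]
    s[(a - 1L):(a + 3L)] <- strsplit(planted_motif[[k]], "")[[1]]
    # 0-based a -> R indices a-2+1 .. a+2+1
  }
  footprint <- logical(len)
  for (a in planted_a) footprint[(a - 1L):(a + 3L)] <- TRUE
  breaker <- c("C", "C", "C", "G", "G")  # safe substitution per motif index
  for (iter in 1:10) {
    hits <- scan_sequence("x", paste(s, collapse = ""), "+")
    acc <- setdiff(hits$a_pos, planted_a)
    if (length(acc) == 0L) return(paste(s, collapse = ""))
    for (a in acc) {
      idx <- (a - 2L):(a + 2L) + 1L          # R indices of the 5-mer
      free <- which(!footprint[idx])
      if (length(free) == 0L) next           # cannot happen for DRACH
      j <- free[[1L]]
      s[idx[j]] <- breaker[[j]]
    }
  }
  stop("internal error: could not scrub accidental DRACH occurrences")
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

.write_fixedstep_wig <- function(values_by_ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rn in names(values_by_ref)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", rn), con)
    writeLines(sprintf("%.6f", values_by_ref[[rn]]), con)
  }
  invisible(path)
}

.write_rle_bedgraph <- function(counts_by_ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rn in names(counts_by_ref)) {
    r <- rle(counts_by_ref[[rn]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%d", rn, starts, ends, r$values), con)
  }
  invisible(path)
}

#' Generate a self-contained synthetic fixture
#'
#' Writes to `out_dir`:
#' * `reference.fa` — random sequences with DRACH motifs planted at recorded,
#'   non-overlapping positions and no accidental DRACH occurrences;
#' * `wt.wig` / `wt.bedgraph` — baseline fraction-modified and coverage
#'   tracks; methylated sites add `peak_delta` at the peak offsets;
#' * `perturbed.wig` / `perturbed.bedgraph` — independent noise redraw with
#'   the spike attenuated by `perturbation_attenuation`;
#' * `truth.bed` — a random `truth_label_fraction` subset of the methylated
#'   sites (the deliberately incomplete training labels);
#' * `manifest.tsv` — every planted site with its true status and whether it
#'   was labeled.
#'
#' All values are `clip(baseline + spike + N(0, noise_sd), 0, 1)`. Equal
#' seeds give byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the `manifest` data
#'   frame.
#' @export
generate_fixture <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cf$seed)
  spacing <- 2L * cf$flank + 5L
  lo <- cf$flank                          # window must fit: a - flank >= 0
  hi <- cf$seq_length - 1L - cf$flank
  slot_a <- seq.int(lo + 2L, hi - 2L, by = spacing)  # motif fits too
  n_total <- cf$n_methylated_sites + cf$n_unmethylated_drach_decoys
  slots <- expand.grid(seq_i = seq_len(cf$n_sequences), a = slot_a)
  if (n_total > nrow(slots))
    stop("configuration error: ", n_total, " sites requested but only ",
         nrow(slots), " placeable slots (", cf$n_sequences, " x ",
         length(slot_a), ")")
  pick <- slots[sample(nrow(slots), n_total), , drop = FALSE]
  refs <- sprintf("synth_tx%03d", pick$seq_i)
  motif <- sample(cf$motifs, n_total, replace = TRUE)
  methylated <- logical(n_total)
  methylated[sample(n_total, cf$n_methylated_sites)] <- TRUE
  manifest <- data.frame(ref = refs, a_pos = pick$a, motif = motif,
                         methylated = methylated, labeled = FALSE,
                         stringsAsFactors = FALSE)
  n_labeled <- round(cf$truth_label_fraction * cf$n_methylated_sites)
  meth_idx <- which(manifest$methylated)
  manifest$labeled[sample(meth_idx, n_labeled)] <- TRUE
  manifest <- manifest[order(manifest$ref, manifest$a_pos), , drop = FALSE]
  rownames(manifest) <- NULL

  ref_names <- sprintf("synth_tx%03d", seq_len(cf$n_sequences))
  seqs <- character(cf$n_sequences)
  for (i in seq_len(cf$n_sequences)) {
    sel <- manifest$ref == ref_names[[i]]
    seqs[[i]] <- .random_clean_sequence(cf$seq_length,
                                        manifest$a_pos[sel],
                                        manifest$motif[sel])
  }
  names(seqs) <- ref_names

  spike <- function(attenuation) {
    out <- lapply(ref_names, function(rn) numeric(cf$seq_length))
    names(out) <- ref_names
    meth <- manifest[manifest$methylated, , drop = FALSE]
    for (k in seq_len(nrow(meth))) {
      p <- meth$a_pos[[k]] + cf$peak_offsets + 1L   # R indices
      out[[meth$ref[[k]]]][p] <- cf$peak_delta * (1 - attenuation)
    }
    out
  }
  make_tracks <- function(attenuation) {
    sp <- spike(attenuation)
    sig <- lapply(ref_names, function(rn)
      .clip01(cf$baseline_mean + sp[[rn]] +
                stats::rnorm(cf$seq_length, 0, cf$noise_sd)))
    names(sig) <- ref_names
    cov <- lapply(ref_names, function(rn)
      sample(cf$coverage_range[1L]:cf$coverage_range[2L], cf$seq_length,
             replace = TRUE))
    names(cov) <- ref_names
    list(signal = sig, coverage = cov)
  }
  wt <- make_tracks(0)
  perturbed <- make_tracks(cf$perturbation_attenuation)

  paths <- list(reference = file.path(out_dir, "reference.fa"),
                wt_signal = file.path(out_dir, "wt.wig"),
                wt_coverage = file.path(out_dir, "wt.bedgraph"),
                perturbed_signal = file.path(out_dir, "perturbed.wig"),
                perturbed_coverage = file.path(out_dir,
                                               "perturbed.bedgraph"),
                truth = file.path(out_dir, "truth.bed"),
                manifest = file.path(out_dir, "manifest.tsv"))
  fa <- unlist(lapply(ref_names, function(rn)
    c(paste0(">", rn), substring(seqs[[rn]],
                                 seq(1L, cf$seq_length, 70L),
                                 pmin(seq(1L, cf$seq_length, 70L) + 69L,
                                      cf$seq_length)))))
  writeLines(fa, paths$reference)
  .write_fixedstep_wig(wt$signal, paths$wt_signal)
  .write_rle_bedgraph(wt$coverage, paths$wt_coverage)
  .write_fixedstep_wig(perturbed$signal, paths$perturbed_signal)
  .write_rle_bedgraph(perturbed$coverage, paths$perturbed_coverage)
  lab <- manifest[manifest$labeled, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\tm6A\t0\t+", lab$ref, lab$a_pos,
                     lab$a_pos + 1L), paths$truth)
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, manifest = manifest))
}

#' Read a fixture's ground-truth manifest
#'
#' @param out_dir Directory written by [generate_fixture()].
#' @return Data frame of every planted site: `ref`, `a_pos`, `motif`,
#'   `methylated`, `labeled`.
#' @export
manifest_truth <- function(out_dir) {
  path <- file.path(out_dir, "manifest.tsv")
  if (!file.exists(path))
    stop("no manifest found at ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
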