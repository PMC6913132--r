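# Per-base enumeration oracle: walk every exon base 5'->3' and list genomic
# positions in transcript order.
enumerate_tx <- function(exons, strand) {
  if (strand == "-") exons <- exons[order(-exons[, 1]), , drop = FALSE]
  else exons <- exons[order(exons[, 1]), , drop = FALSE]
  unlist(lapply(seq_len(nrow(exons)), function(k) {
    g <- exons[k, 1]:(exons[k, 2] - 1L)
    if (strand == "-") rev(g) else g
  }))
}

test_that("transcript-to-genome lift matches per-base enumeration", {
  # single exon, plus strand: offset addition
  tx <- transcript_model("t1", "g1", "chr1", "+",
                         cbind(100L, 200L))
  expect_equal(transcript_to_genome(tx, 10)$genomic_pos, 110L)
  # multi-exon, plus strand
  tx2 <- transcript_model("t2", "g1", "chr1", "+",
                          cbind(c(100L, 200L), c(150L, 250L)))
  expect_equal(transcript_to_genome(tx2, 60)$genomic_pos, 210L)
  # single exon, minus strand: transcript 5' end is the interval's last base
  tx3 <- transcript_model("t3", "g1", "chr1", "-", cbind(100L, 200L))
  expect_equal(transcript_to_genome(tx3, 0)$genomic_pos, 199L)
  # enumeration oracle over random multi-exon structures, both strands
  set.seed(21)
  for (i in 1:20) {
    n_ex <- sample(1:5, 1)
    starts <- sort(sample(seq(0L, 5000L, by = 300L), n_ex))
    ends <- starts + sample(50:200, n_ex, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    tx <- transcript_model(paste0("t", i), "g", "chr2", strand,
                           cbind(starts, ends))
    want <- enumerate_tx(cbind(starts, ends), strand)
    got <- transcript_to_genome(tx, seq_len(tx$length) - 1L)
    expect_equal(got$genomic_pos, want)
    expect_equal(unique(got$strand), strand)
  }
})

test_that("lift round-trips through genome_to_transcript", {
  set.seed(22)
  for (strand in c("+", "-")) {
    tx <- transcript_model("t", "g", "chr1", strand,
                           cbind(c(10L, 120L, 300L), c(60L, 180L, 320L)))
    p <- seq_len(tx$length) - 1L
    g <- transcript_to_genome(tx, p)$genomic_pos
    expect_equal(genome_to_transcript(tx, g), p)
  }
})

test_that("lift validates bounds and exon structure", {
  tx <- transcript_model("t", "g", "chr1", "+", cbind(100L, 150L))
  expect_error(transcript_to_genome(tx, 50), "out of range")
  expect_error(transcript_to_genome(tx, -1), "out of range")
  expect_error(genome_to_transcript(tx, 90L), "not covered")
  expect_error(transcript_model("t", "g", "chr1", "+",
                                cbind(c(100L, 120L), c(130L, 160L))),
               "overlapping")
  expect_error(transcript_model("t", "g", "chr1", "+", cbind(100L, 100L)),
               "end <= start")
})

test_that("GTF exon structures import grouped by transcript", {
  gtf <- tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "g1"; transcript_id "t1";'
  attr2 <- 'gene_id "g1"; transcript_id "t2";'
  writeLines(c(
    paste("chr1", "test", "exon", "101", "150", ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "test", "exon", "201", "250", ".", "+", ".", attr1,
          sep = "\t"),
    paste("chr1", "test", "exon", "101", "250", ".", "+", ".", attr2,
          sep = "\t")), gtf)
  models <- read_transcript_models(gtf)
  expect_named(models, c("t1", "t2"))
  expect_equal(models$t1$exons,
               cbind(start = c(100L, 200L), end = c(150L, 250L)))
  expect_equal(models$t1$length, 100L)
  expect_equal(models$t2$gene_id, "g1")
  # GTF is 1-based closed; 0-based half-open internally
  expect_equal(transcript_to_genome(models$t1, 0)$genomic_pos, 100L)
})

.three_isoforms <- function() {
  # three isoforms of one gene sharing genomic base 210 (and 110)
  structure(list(
    t1 = transcript_model("t1", "g1", "chr1", "+",
                          cbind(c(100L, 200L), c(150L, 250L))),
    t2 = transcript_model("t2", "g1", "chr1", "+",
                          cbind(c(100L, 200L), c(120L, 250L))),
    t3 = transcript_model("t3", "g1", "chr1", "+", cbind(200L, 260L))),
    class = "transcript_models")
}

.pred <- function(ref, a_pos, call) {
  data.frame(ref = ref, a_pos = a_pos, motif = "GGACT", strand = "+",
             probability = ifelse(call == "m6A", 0.9, 0.1), call = call,
             stringsAsFactors = FALSE)
}

test_that("shared genomic positions classify by cross-isoform agreement", {
  txs <- .three_isoforms()
  # genomic 210 = t1 offset 60, t2 offset 30, t3 offset 10
  p <- rbind(.pred("t1", 60L, "m6A"), .pred("t2", 30L, "m6A"),
             .pred("t3", 10L, "not_m6A"))
  res <- classify_shared_sites(p, txs)
  expect_equal(res$shared$category, "isoform_specific")
  expect_equal(res$shared$genomic_pos, 210L)
  expect_equal(res$shared$n_isoforms, 3L)
  # all m6A -> consistent; none -> never
  res2 <- classify_shared_sites(rbind(.pred("t1", 60L, "m6A"),
                                      .pred("t2", 30L, "m6A")), txs)
  expect_equal(res2$shared$category, "consistent")
  res3 <- classify_shared_sites(rbind(.pred("t1", 60L, "not_m6A"),
                                      .pred("t2", 30L, "not_m6A")), txs)
  expect_equal(res3$shared$category, "never")
})

test_that("single-isoform positions are excluded and categories partition", {
  txs <- .three_isoforms()
  p <- rbind(.pred("t1", 60L, "m6A"),  # genomic 210, shared with t2/t3
             .pred("t2", 30L, "not_m6A"),
             .pred("t1", 10L, "m6A"),  # genomic 110, t1 only covered here
             .pred("t3", 50L, "m6A"))  # genomic 250, t3 only
  res <- classify_shared_sites(p, txs)
  expect_equal(res$summary$n_positions, 3L)
  expect_equal(res$summary$n_shared, 1L)
  expect_equal(res$summary$n_never + res$summary$n_consistent +
                 res$summary$n_isoform_specific, res$summary$n_shared)
  # gene summary
  expect_equal(res$summary$n_m6a_genes, 1L)
  expect_equal(res$summary$n_isoform_specific_genes, 1L)
})

test_that("junction-spanning windows are flagged and unknown transcripts rejected", {
  txs <- .three_isoforms()
  # t1 offset 55 sits 5 nt into exon 2: a flank-10 window reaches exon 1
  res <- classify_shared_sites(.pred("t1", 55L, "m6A"), txs, flank = 10L)
  expect_true(res$lifted$junction_spanning)
  res2 <- classify_shared_sites(.pred("t1", 55L, "m6A"), txs, flank = 5L)
  expect_false(res2$lifted$junction_spanning)
  expect_error(classify_shared_sites(.pred("tX", 5L, "m6A"), txs), "tX")
})
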