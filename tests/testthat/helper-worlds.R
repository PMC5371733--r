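# Shared fixtures: worlds are expensive, so they are built lazily once per
# test run and cached.

.memo <- new.env(parent = emptyenv())
with_memo <- function(key, expr) {
  if (!exists(key, envir = .memo)) assign(key, force(expr), envir = .memo)
  get(key, envir = .memo)
}

small_config <- function(...) {
  sim_config(chrom_lengths = c(chr1 = 2e6), n_mrna = 30, n_lincrna = 4,
             n_ncrna = 15, n_erna = 20, n_pairs = 10,
             n_neighborhoods = 8, mrna_len = c(2000, 12000), ...)
}

small_world <- function() with_memo("sw", simulate_world(small_config(), seed = 11))
small_obs <- function() with_memo("sobs", simulate_counts(small_world(), seed = 11))

default_world <- function() with_memo("dw", simulate_world(seed = 7))
# counts only (no tracks): enough for kinetics/pairing/diffexpr fixtures
default_obs <- function()
  with_memo("dobs", simulate_counts(default_world(), seed = 7,
                                    tracks_for = character(0)))

# toy annotation: 2 genes (one protein-coding with 2 isoforms, one lincRNA)
toy_annotation <- function() {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 20000), c(10000, 24000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"),
    gene_biotype = c("protein_coding", "lincRNA"))
  exons <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1000, 6000, 1000, 4000, 20000),
                     c(2000, 10000, 2000, 10000, 24000)),
    strand = c("+", "+", "+", "+", "-"),
    gene_id = c("gA", "gA", "gA", "gA", "gB"),
    transcript_id = c("gA.1", "gA.1", "gA.2", "gA.2", "gB.1"))
  tx_annotation(genes, exons)
}

# TT-style sample metadata for hand-built count matrices
tt_samples <- function(times = c(0, 5, 10, 15), reps = 2) {
  df <- expand.grid(replicate = seq_len(reps), time = times,
                    stringsAsFactors = FALSE)
  df$assay <- "TT"
  df$sample_id <- sprintf("TT_t%02d_r%d", df$time, df$replicate)
  df
}
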