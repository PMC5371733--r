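# Independent oracle for the Poisson-log-normal emission density:
# adaptive numeric integration over the latent log-rate.
pln_oracle <- function(k, m, sdlog) {
  vapply(k, function(kk)
    integrate(function(y) dpois(kk, exp(y)) * dnorm(y, m, sdlog),
              m - 8 * sdlog, m + 8 * sdlog, rel.tol = 1e-10)$value,
    numeric(1))
}

test_that("Gauss-Hermite PLN density matches numeric integration", {
  gh <- ttseqr:::gauss_hermite(30)
  for (par in list(c(0, 0.5), c(2, 1), c(-1, 0.3))) {
    k <- c(0, 1, 2, 5, 10, 50)
    got <- exp(ttseqr:::pln_logdens(k, par[1], par[2], gh))
    want <- pln_oracle(k, par[1], par[2])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

# planted 50:1 world used by several tests
planted_seqs <- function(seed = 21, n_bins = 2000, n_tracks = 2) {
  set.seed(seed)
  truth <- rep(FALSE, n_bins)
  starts <- seq(100, n_bins - 100, by = 200)
  for (s in starts) truth[s:(s + sample(20:60, 1))] <- TRUE
  x <- vapply(seq_len(n_tracks), function(j)
    rpois(n_bins, ifelse(truth, 50, 1)), numeric(n_bins))
  list(seqs = list("chr1:+" = x + 1), truth = truth)  # +1 pseudo-count
}

test_that("HMM separates planted 50:1 signal and EM is monotone", {
  ps <- planted_seqs()
  fit <- fit_hmm(ps$seqs, max_iter = 15)
  expect_false(fit$degenerate)
  means <- rowMeans(exp(fit$m + fit$sdlog^2 / 2))
  expect_gt(means[2] / means[1], 10)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  # posterior decoding recovers the planted intervals
  tus <- decode_transcribed(fit, ps$seqs, bin_size = 200,
                            genome = c(chr1 = 2000 * 200))
  truth_gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = (which(diff(c(FALSE, ps$truth)) == 1) - 1) * 200 + 1,
    end = which(diff(c(ps$truth, FALSE)) == -1) * 200))
  expect_gte(jaccard_index(tus, truth_gr), 0.9)
  # decoding is deterministic
  tus2 <- decode_transcribed(fit, ps$seqs, bin_size = 200,
                             genome = c(chr1 = 2000 * 200))
  expect_identical(start(tus), start(tus2))
})

test_that("degenerate and background-only inputs are handled", {
  expect_warning(fit <- fit_hmm(matrix(1L, 500, 1)), "degenerate")
  expect_true(fit$degenerate)
  # all-background track: decoded set is empty
  set.seed(1)
  bg <- matrix(rpois(2000, 1) + 1L, ncol = 1)
  ps <- planted_seqs()
  fit <- fit_hmm(ps$seqs, max_iter = 10)
  tus <- decode_transcribed(fit, list("chr1:+" = bg), bin_size = 200)
  expect_equal(length(tus), 0)
})

test_that("jaccard_index matches hand arithmetic", {
  g <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  expect_equal(jaccard_index(g(1, 100), g(1, 100)), 1)
  expect_equal(jaccard_index(g(1, 100), g(201, 300)), 0)
  # [0,100) vs [50,150) in 0-based half-open = 1-based [1,100], [51,150]
  expect_equal(jaccard_index(g(1, 100), g(51, 150)), 1 / 3)
  expect_warning(j0 <- jaccard_index(GenomicRanges::GRanges(),
                                     GenomicRanges::GRanges()), "empty")
  expect_equal(j0, 0)
})

test_that("RPK threshold optimization separates planted groups", {
  g <- function(s, e, rpk) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
    S4Vectors::mcols(gr)$rpk <- rpk
    gr
  }
  true_tus <- g(c(1, 5001, 10001), c(2000, 7000, 12000), 40)
  noise_tus <- g(c(20001, 25001), c(20600, 25600), 2)
  tus <- c(true_tus, noise_tus)
  reference <- g(c(1, 5001, 10001), c(2000, 7000, 12000), NA)
  opt <- optimize_rpk_threshold(tus, reference, candidates = 1:50)
  expect_gt(opt$threshold, 2)
  expect_lte(opt$threshold, 40)
  # invariant to candidate ordering
  opt2 <- optimize_rpk_threshold(tus, reference, candidates = sample(1:50))
  expect_equal(opt$threshold, opt2$threshold)
  # single candidate; and reference == all TUs keeps the smallest
  expect_equal(optimize_rpk_threshold(tus, reference, 7)$threshold, 7)
  expect_equal(optimize_rpk_threshold(tus, tus, 1:50)$threshold, 1)
  expect_error(optimize_rpk_threshold(tus, reference, numeric(0)), "empty")
})

test_that("boundary refinement finds abrupt coverage steps", {
  cov <- c(rep(0, 2429), rep(30, 2000), rep(0, 5571))
  # step up at position 2430: boundary initially at bin edge 2400
  expect_equal(refine_boundary(cov, 2400, 200), 2430)
  # boundary already at the step stays
  expect_equal(refine_boundary(cov, 2430, 200), 2430)
  # flat window: unchanged
  expect_equal(refine_boundary(rep(5, 10000), 5000, 200), 5000)
  # never moves further than 2 bins
  expect_lte(abs(refine_boundary(cov, 2450, 200) - 2450), 400)
  # GRanges-level wrapper
  tus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2400, 4200),
                                strand = "+")
  ref <- refine_boundaries(tus, list(chr1 = list("+" = cov)), 200)
  expect_equal(start(ref), 2430)
})

test_that("classification rules assign and merge TU classes", {
  ann <- toy_annotation()
  mk <- function(s, e, strand = "+", rpk = 20) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e),
                                 strand = strand)
    S4Vectors::mcols(gr)$rpk <- rpk
    gr
  }
  # 71% overlap with gA and touching an exon -> mRNA
  tu <- mk(5000, 12000)
  out <- classify_tus(tu, ann)
  expect_equal(S4Vectors::mcols(out)$class, "mRNA")
  expect_equal(S4Vectors::mcols(out)$gene_id, "gA")
  # ~7% overlap -> ncRNA
  tu <- mk(9500, 16500)
  out <- classify_tus(tu, ann)
  expect_equal(S4Vectors::mcols(out)$class, "ncRNA")
  # two ncRNAs 150 bp apart are merged
  tus <- c(mk(40000, 41000), mk(41151, 42000))
  out <- classify_tus(tus, ann)
  expect_equal(length(out), 1)
  expect_equal(S4Vectors::mcols(out)$class, "ncRNA")
  # 300 bp apart: not merged
  tus <- c(mk(40000, 41000), mk(41301, 42000))
  expect_equal(length(classify_tus(tus, ann)), 2)
  # two TUs on exons of the same gene are combined
  tus <- c(mk(1000, 2500), mk(6000, 10000))
  out <- classify_tus(tus, ann)
  expect_equal(length(out), 1)
  expect_equal(S4Vectors::mcols(out)$class, "mRNA")
  # readthrough: ncRNA starting <=1 kb downstream of gA end (10000, +)
  tus <- mk(10500, 11500)
  out <- classify_tus(tus, ann)
  expect_true(S4Vectors::mcols(out)$readthrough)
  # same interval on the - strand is not readthrough
  out <- classify_tus(mk(10500, 11500, strand = "-"), ann)
  expect_false(S4Vectors::mcols(out)$readthrough)
})

test_that("ambiguous multi-gene TUs are removed and short mRNAs demoted", {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1000, 4000), c(2000, 5000)), strand = "+",
    gene_id = c("g1", "g2"),
    gene_biotype = c("protein_coding", "protein_coding"))
  exons <- genes
  S4Vectors::mcols(exons)$transcript_id <- c("g1.1", "g2.1")
  ann2 <- tx_annotation(genes, exons)
  tu <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 5100),
                               strand = "+")
  S4Vectors::mcols(tu)$rpk <- 50
  expect_equal(length(classify_tus(tu, ann2)), 0)  # covers both genes
  # short "mRNA" with <10% protein-coding overlap is demoted
  genes3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1400),
    strand = "+", gene_id = "g3", gene_biotype = "protein_coding")
  exons3 <- genes3
  S4Vectors::mcols(exons3)$transcript_id <- "g3.1"
  ann3 <- tx_annotation(genes3, exons3)
  tu <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1300, 4800),
                               strand = "+")
  S4Vectors::mcols(tu)$rpk <- 50
  out <- classify_tus(tu, ann3, min_overlap = 0.02)
  expect_equal(S4Vectors::mcols(out)$class, "ncRNA")
})

test_that("constitutive exons are isoform intersections", {
  ann <- toy_annotation()
  ce <- constitutive_exons(ann)
  # single-isoform gene: exons unchanged
  expect_equal(start(ce$gB), 20000)
  expect_equal(end(ce$gB), 24000)
  # two isoforms of gA share [1000,2000] and [6000,10000]
  expect_equal(start(ce$gA), c(1000, 6000))
  expect_equal(end(ce$gA), c(2000, 10000))
  # disjoint isoforms: empty intersection
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
    strand = "+", gene_id = "g", gene_biotype = "protein_coding")
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 501), c(400, 900)), strand = "+",
    gene_id = "g", transcript_id = c("t1", "t2"))
  ce2 <- constitutive_exons(tx_annotation(genes, exons))
  expect_equal(length(ce2$g), 0)
})
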