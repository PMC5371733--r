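mk_gr <- function(starts, ends, strand = "+", ids = NULL, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = strand)
  if (!is.null(ids)) S4Vectors::mcols(gr)$tu_id <- ids
  gr
}

test_that("eRNA promotion follows the overlap-or-1kb-upstream rule", {
  states <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4000, 4500))
  # + strand ncRNA at 5500..6500: upstream window [4500,5499] touches the
  # state by exactly 1 bp
  tus <- mk_gr(5500, 6500, ids = "n1")
  S4Vectors::mcols(tus)$class <- "ncRNA"
  S4Vectors::mcols(tus)$readthrough <- FALSE
  out <- classify_ernas(tus, states)
  expect_equal(S4Vectors::mcols(out)$class, "eRNA")
  # 1 bp further away: no overlap anywhere -> stays ncRNA
  tus2 <- mk_gr(5501, 6500, ids = "n1")
  S4Vectors::mcols(tus2)$class <- "ncRNA"
  S4Vectors::mcols(tus2)$readthrough <- FALSE
  expect_equal(S4Vectors::mcols(classify_ernas(tus2, states))$class, "ncRNA")
  # readthrough ncRNAs are never promoted
  S4Vectors::mcols(tus)$readthrough <- TRUE
  expect_equal(S4Vectors::mcols(classify_ernas(tus, states))$class, "ncRNA")
})

test_that("planted eRNAs are recovered from the default world", {
  w <- default_world()
  feats <- w$features
  cls <- S4Vectors::mcols(feats)$class
  demoted <- feats
  S4Vectors::mcols(demoted)$class <- ifelse(cls == "eRNA", "ncRNA", cls)
  out <- classify_ernas(demoted, w$enhancer_states)
  recovered <- S4Vectors::mcols(out)$class[cls == "eRNA"] == "eRNA"
  expect_gte(mean(recovered), 0.95)
})

test_that("pairing enumerates combinations within neighborhoods", {
  nb <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
  S4Vectors::mcols(nb)$name <- "NB1"
  ernas <- mk_gr(10000, 11000, ids = "e1")
  mrnas <- mk_gr(c(50000, 90000), c(60000, 95000), ids = c("m1", "m2"))
  p <- pair_within_neighborhoods(ernas, mrnas, nb)
  expect_equal(nrow(p), 2)
  expect_setequal(p$mrna_id, c("m1", "m2"))
  # signed distance: eRNA TSS 10000 - mRNA TSS 50000, both + strand
  expect_equal(p$distance_bp[p$mrna_id == "m1"], -40000)
  expect_false(any(p$proximal))
  # exclusion zone: eRNA TSS at mRNA TSS + 500 is dropped
  e2 <- mk_gr(50500, 51500, ids = "e2")
  expect_equal(nrow(pair_within_neighborhoods(e2, mrnas[1], nb)), 0)
  # different neighborhoods: no pair
  nb2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 40000), c(20000, 100000)))
  S4Vectors::mcols(nb2)$name <- c("NB1", "NB2")
  expect_equal(nrow(pair_within_neighborhoods(ernas, mrnas, nb2)), 0)
})

test_that("pair correlations handle exact and degenerate profiles", {
  prof <- rbind(e1 = c(1, 2, 3, 4), m1 = c(1, 2, 3, 4),
                m2 = c(4, 3, 2, 1), m3 = c(2, 2, 2, 2))
  colnames(prof) <- c(0, 5, 10, 15)
  pairs <- data.frame(erna_id = c("e1", "e1", "e1"),
                      mrna_id = c("m1", "m2", "m3"),
                      neighborhood_id = "NB1", distance_bp = 5000,
                      proximal = TRUE)
  out <- pair_correlations(pairs, prof)
  expect_equal(out$r[1], 1)
  expect_equal(out$r[2], -1)
  expect_true(is.na(out$r[3]))
  expect_false(out$r_defined[3])
  expect_error(pair_correlations(pairs, prof[, 1:2]), "3 time points")
})

test_that("permutation test is deterministic and add-one corrected", {
  set.seed(10)
  nt <- 4
  prof <- matrix(rnorm(40 * nt), 40,
                 dimnames = list(c(paste0("e", 1:20), paste0("m", 1:20)),
                                 c(0, 5, 10, 15)))
  # perfectly co-regulated pairs
  for (i in 1:20) prof[20 + i, ] <- prof[i, ] + rnorm(nt, 0, 0.1)
  pairs <- data.frame(erna_id = paste0("e", 1:20),
                      mrna_id = paste0("m", 1:20))
  pairs <- pair_correlations(pairs, prof)
  res <- permutation_test(pairs, prof, erna_pool = paste0("e", 1:20),
                          mrna_pool = paste0("m", 1:20),
                          n_perm = 200, seed = 5)
  expect_equal(res$p_value, 1 / 201)
  res2 <- permutation_test(pairs, prof, erna_pool = paste0("e", 1:20),
                           mrna_pool = paste0("m", 1:20),
                           n_perm = 200, seed = 5)
  expect_identical(res$null, res2$null)
  # exchangeable world: shared profile -> p near 1
  prof2 <- prof
  for (i in seq_len(nrow(prof2)))
    prof2[i, ] <- c(1, 2, 3, 4) + rnorm(nt, 0, 1e-3)
  pairs2 <- pair_correlations(pairs[, 1:2], prof2)
  res3 <- permutation_test(pairs2, prof2,
                           erna_pool = paste0("e", 1:20),
                           mrna_pool = paste0("m", 1:20),
                           n_perm = 200, seed = 5)
  expect_gt(res3$p_value, 0.05)
  expect_error(permutation_test(pairs, prof, n_perm = 0), "n_perm")
})

test_that("closest pairing picks nearest eRNA with deterministic ties", {
  mrnas <- mk_gr(50000, 60000, ids = "m1")
  # single eRNA: every promoter pairs to it
  e1 <- mk_gr(10000, 11000, ids = "e1")
  nb <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
  res <- closest_pairing(e1, mrnas, nb)
  expect_equal(res$pairs$erna_id, "e1")
  # equidistant tie: smaller coordinate wins
  es <- mk_gr(c(40000, 60000), c(41000, 61000), ids = c("eA", "eB"))
  res <- closest_pairing(es, mrnas, nb)
  expect_equal(res$pairs$erna_id, "eA")
  expect_warning(closest_pairing(es[0], mrnas, nb), "no eRNAs")
})

test_that("within-neighborhood co-regulation shows up in closest pairing", {
  w <- default_world()
  obs <- default_obs()
  tt <- obs$counts$samples$assay == "TT"
  cmtt <- count_matrix(obs$counts$counts[, tt], obs$counts$lengths,
                       obs$counts$samples[tt, ])
  sf <- size_factors(cmtt,
    S4Vectors::mcols(w$annotation$genes)$gene_id[
      S4Vectors::mcols(w$annotation$genes)$gene_biotype == "protein_coding"])
  prof <- timepoint_profile(cmtt, sf)
  feats <- w$features
  S4Vectors::mcols(feats)$tu_id <- S4Vectors::mcols(feats)$feature_id
  # restrict to truly paired members so co-regulation is planted
  er <- feats[S4Vectors::mcols(feats)$tu_id %in% w$truth$pairs$erna_id]
  mr <- feats[S4Vectors::mcols(feats)$tu_id %in% w$truth$pairs$mrna_id]
  res <- closest_pairing(er, mr, w$neighborhoods, profile = prof)
  expect_true(!is.null(res$same_loop_test))
  same <- res$pairs$same_neighborhood
  expect_gt(median(res$pairs$r[same], na.rm = TRUE),
            median(res$pairs$r[!same], na.rm = TRUE))
})

test_that("tss_metaprofile is strand-oriented and edge-safe", {
  sig <- list(chr1 = rep(7, 10000))
  tss <- mk_gr(5000, 5400)
  prof <- tss_metaprofile(sig, tss, window = 100)
  expect_equal(length(prof), 201)
  expect_true(all(prof == 7))
  # asymmetric signal: peak 200 bp upstream of a + TSS ...
  sig2 <- list(chr1 = c(rep(0, 4799), 100, rep(0, 5200)))
  up <- tss_metaprofile(sig2, tss, window = 300)
  expect_equal(which(up > 0), 300 - 200 + 1)
  # ... appears at the mirrored position for a - strand TSS
  tss_minus <- mk_gr(4600, 5000, strand = "-")
  sig3 <- list(chr1 = c(rep(0, 5199), 100, rep(0, 4800)))  # peak at 5200
  dn <- tss_metaprofile(sig3, tss_minus, window = 300)
  expect_equal(which(dn > 0), 300 - 200 + 1)  # upstream after orientation
  # single TSS profile equals the local signal
  one <- tss_metaprofile(sig2, tss, window = 250)
  expect_equal(sum(one), 100 / 1)
  expect_error(tss_metaprofile(sig, tss[0], 100), "empty")
})
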