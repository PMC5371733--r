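## Differential synthesis testing: median-of-ratios size factors
## restricted to protein-coding units, and a negative-binomial Wald test
## (method-of-moments dispersion, moderated towards the common value) as a
## self-contained stand-in for DESeq2.

#' Median-of-ratios size factors
#'
#' Computed on a reference feature subset (here: protein-coding units):
#' s_j = median over features of k_ij / geometric-mean_i(k_i.), using only
#' features with nonzero counts in all samples.
#'
#' @param cm `count_matrix` (or plain matrix).
#' @param reference_ids feature ids to restrict to (default: all).
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(cm, reference_ids = NULL) {
  k <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (!is.null(reference_ids)) k <- k[rownames(k) %in% reference_ids, ,
                                      drop = FALSE]
  k <- k[apply(k, 1, function(r) all(r > 0)), , drop = FALSE]
  if (nrow(k) == 0)
    stop("no reference feature with nonzero counts in all samples")
  loggm <- rowMeans(log(k))
  apply(k, 2, function(col) exp(median(log(col) - loggm)))
}

#' Negative-binomial Wald test per time point against 0 min
#'
#' For each feature and contrast (each time point vs the first), a Wald
#' test on the log fold change of size-factor-normalized means is carried
#' out under a negative-binomial model.  The dispersion is estimated per
#' feature by the method of moments pooled across conditions and moderated
#' towards the across-feature mean (prior weight `prior_df`); there is no
#' DESeq2-style shrinkage of dispersions or fold changes.  P-values are
#' BH-adjusted across features within each contrast.
#'
#' @param cm `count_matrix`; samples carry `time` and `replicate`.
#' @param sf size factors (one per sample).
#' @param assay which assay's samples to test (default "TT").
#' @param prior_df prior weight for dispersion moderation.
#' @return data.frame feature_id, contrast time, baseMean, log2fc,
#'   pvalue, padj, flag.
#' @export
test_differential <- function(cm, sf, assay = "TT", prior_df = 20) {
  meta <- cm$samples
  use <- if (all(is.na(meta$assay))) seq_len(nrow(meta))
         else which(meta$assay == assay)
  k <- cm$counts[, use, drop = FALSE]
  sfu <- sf[use]
  times <- meta$time[use]
  t0 <- min(times)
  q <- sweep(k, 2, sfu, "/")
  conds <- sort(unique(times))

  ## pooled method-of-moments dispersion per feature
  disp_num <- disp_den <- numeric(nrow(k))
  for (tp in conds) {
    idx <- which(times == tp)
    if (length(idx) < 2) next
    m <- rowMeans(q[, idx, drop = FALSE])
    v <- apply(q[, idx, drop = FALSE], 1, var)
    ok <- m > 0
    a <- numeric(nrow(k))
    a[ok] <- pmax((v[ok] - m[ok]) / m[ok]^2, 0)
    disp_num <- disp_num + (length(idx) - 1) * a
    disp_den <- disp_den + (length(idx) - 1)
  }
  if (all(disp_den == 0)) {
    disp <- rep(0, nrow(k))  # Poisson fallback: no replicates anywhere
    warning("no condition has replicates; falling back to Poisson test")
    common <- 0
  } else {
    disp_raw <- disp_num / pmax(disp_den, 1)
    common <- mean(disp_raw, trim = 0.05)
    disp <- (disp_den * disp_raw + prior_df * common) /
      (disp_den + prior_df)
  }

  out <- list()
  base_idx <- which(times == t0)
  m0 <- rowMeans(q[, base_idx, drop = FALSE])
  n0 <- length(base_idx)
  for (tp in setdiff(conds, t0)) {
    idx <- which(times == tp)
    mt <- rowMeans(q[, idx, drop = FALSE])
    nt <- length(idx)
    pseudo <- 0.5
    l2fc <- log2((mt + pseudo) / (m0 + pseudo))
    ## delta-method variance of log mean under NB(mu, disp)
    vlog <- (1 / pmax(mt, pseudo) + disp) / nt +
      (1 / pmax(m0, pseudo) + disp) / n0
    z <- log((mt + pseudo) / (m0 + pseudo)) / sqrt(vlog)
    p <- 2 * pnorm(-abs(z))
    allzero <- mt == 0 & m0 == 0
    p[allzero] <- 1; l2fc[allzero] <- 0
    out[[as.character(tp)]] <- data.frame(
      feature_id = rownames(k), contrast = tp,
      baseMean = (m0 + mt) / 2, log2fc = l2fc, pvalue = p,
      padj = p.adjust(p, method = "BH"),
      flag = ifelse(allzero, "all_zero", ""),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify differential results into up/down/unchanged
#'
#' Inclusive cutoffs: a contrast is "up" when the fold change is at least
#' `fc_cutoff` and the BH-adjusted p-value at most `padj_cutoff`
#' ("down" symmetrically).  A feature is "changed" when any contrast
#' passes both cutoffs.
#'
#' @param de output of [test_differential()].
#' @param fc_cutoff fold-change cutoff (linear scale).
#' @param padj_cutoff adjusted p-value cutoff.
#' @param strict use strict (>, <) instead of inclusive comparisons.
#' @return `de` with a `direction` column plus attribute `changed`
#'   (named logical per feature: changed at any time point).
#' @export
classify_changes <- function(de, fc_cutoff = 2, padj_cutoff = 0.05,
                             strict = FALSE) {
  lfc <- log2(fc_cutoff)
  pass_fc_up <- if (strict) de$log2fc > lfc else de$log2fc >= lfc
  pass_fc_dn <- if (strict) de$log2fc < -lfc else de$log2fc <= -lfc
  pass_p <- if (strict) de$padj < padj_cutoff else de$padj <= padj_cutoff
  dir <- rep("unchanged", nrow(de))
  dir[pass_fc_up & pass_p] <- "up"
  dir[pass_fc_dn & pass_p] <- "down"
  de$direction <- dir
  ch <- tapply(dir != "unchanged", de$feature_id, any)
  attr(de, "changed") <- ch
  de
}
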