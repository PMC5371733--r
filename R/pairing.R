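## Transcribed-enhancer (eRNA) calling, enhancer-promoter pairing within
## insulated neighborhoods, correlation and permutation-null analyses,
## closest-pair baseline, temporal profiles and TSS metaprofiles.

#' Promote ncRNA units to eRNA against enhancer-state intervals
#'
#' An ncRNA becomes an eRNA when its body or the 1-kb region upstream of
#' its TSS (strand-aware) overlaps at least one enhancer-state interval.
#' Readthrough-flagged ncRNAs (likely continuation of an upstream mRNA)
#' are never promoted.
#'
#' @param tus classified GRanges (from [classify_tus()] or equivalent,
#'   with `class` and optionally `readthrough` columns).
#' @param enhancer_states GRanges of enhancer chromatin-state intervals.
#' @param upstream width of the upstream window (bp).
#' @return `tus` with eligible ncRNAs relabeled "eRNA".
#' @export
classify_ernas <- function(tus, enhancer_states, upstream = 1000L) {
  isnc <- mcols(tus)$class == "ncRNA"
  rt <- mcols(tus)$readthrough %||% rep(FALSE, length(tus))
  cand <- which(isnc & !rt)
  if (!length(cand)) return(tus)
  nc <- tus[cand]
  up <- promoters(nc, upstream = upstream, downstream = 0)
  up <- trim(up)
  hit <- overlapsAny(nc, enhancer_states, ignore.strand = TRUE) |
    overlapsAny(up, enhancer_states, ignore.strand = TRUE)
  mcols(tus)$class[cand[hit]] <- "eRNA"
  tus
}

#' Pair eRNAs and mRNAs within insulated neighborhoods
#'
#' All cross combinations whose TSSs fall inside the same neighborhood,
#' minus pairs where the eRNA TSS lies within +/- `exclusion` bp of the
#' mRNA TSS.  The signed TSS distance is oriented by the mRNA's strand
#' (negative = enhancer upstream of the promoter).
#'
#' @param ernas,mrnas stranded GRanges with ids (names or `tu_id`).
#' @param neighborhoods GRanges with ids (names or `name`).
#' @param exclusion half-width of the promoter exclusion zone (bp).
#' @param proximal_cut distance below which a pair is "proximal" (bp).
#' @return data.frame erna_id, mrna_id, neighborhood_id, distance_bp,
#'   proximal.
#' @export
pair_within_neighborhoods <- function(ernas, mrnas, neighborhoods,
                                      exclusion = 1000L,
                                      proximal_cut = 10000L) {
  eid <- pairing_ids(ernas); mid <- pairing_ids(mrnas)
  nid <- pairing_ids(neighborhoods, "NB")
  etss <- GenomicRanges::GRanges(seqnames(ernas),
            IRanges::IRanges(tss_position(ernas), width = 1))
  mtss <- GenomicRanges::GRanges(seqnames(mrnas),
            IRanges::IRanges(tss_position(mrnas), width = 1))
  eo <- findOverlaps(etss, neighborhoods, ignore.strand = TRUE)
  mo <- findOverlaps(mtss, neighborhoods, ignore.strand = TRUE)
  out <- list()
  for (nb in unique(subjectHits(eo))) {
    eidx <- queryHits(eo)[subjectHits(eo) == nb]
    midx <- queryHits(mo)[subjectHits(mo) == nb]
    if (!length(eidx) || !length(midx)) next
    grid <- expand.grid(e = eidx, m = midx)
    ep <- tss_position(ernas)[grid$e]
    mp <- tss_position(mrnas)[grid$m]
    keep <- abs(ep - mp) > exclusion
    if (!any(keep)) next
    orient <- ifelse(as.character(strand(mrnas))[grid$m] == "-", -1L, 1L)
    dist <- (ep - mp) * orient
    out[[as.character(nb)]] <- data.frame(
      erna_id = eid[grid$e], mrna_id = mid[grid$m],
      neighborhood_id = nid[nb], distance_bp = dist,
      proximal = abs(dist) < proximal_cut,
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  if (!length(out))
    return(data.frame(erna_id = character(), mrna_id = character(),
                      neighborhood_id = character(),
                      distance_bp = integer(), proximal = logical()))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[!duplicated(res[, c("erna_id", "mrna_id")]), , drop = FALSE]
}

pairing_ids <- function(gr, prefix = "F") {
  if (!is.null(mcols(gr)$tu_id)) mcols(gr)$tu_id
  else if (!is.null(mcols(gr)$name)) mcols(gr)$name
  else if (!is.null(names(gr)) && length(names(gr))) names(gr)
  else paste0(prefix, seq_along(gr))
}

#' Replicate-averaged normalized time series from a count matrix
#'
#' @param cm `count_matrix`.
#' @param sf size factors.
#' @param assay assay to use (default "TT").
#' @return matrix features x time points (columns named by time).
#' @export
timepoint_profile <- function(cm, sf, assay = "TT") {
  meta <- cm$samples
  use <- which(meta$assay == assay)
  q <- sweep(cm$counts[, use, drop = FALSE], 2, sf[use], "/")
  times <- sort(unique(meta$time[use]))
  prof <- vapply(times, function(tp)
    rowMeans(q[, meta$time[use] == tp, drop = FALSE]),
    numeric(nrow(q)))
  colnames(prof) <- times
  prof
}

#' Pearson correlation of paired eRNA/mRNA temporal profiles
#'
#' @param pairs data.frame from [pair_within_neighborhoods()].
#' @param profile matrix features x time points (replicate-averaged,
#'   normalized), rownames = feature ids.
#' @return `pairs` with an `r` column; constant profiles give NA and are
#'   flagged in `r_defined`.
#' @export
pair_correlations <- function(pairs, profile) {
  if (ncol(profile) < 3) stop("need at least 3 time points")
  if (nrow(pairs) == 0) { pairs$r <- numeric(0); pairs$r_defined <- logical(0); return(pairs) }
  miss <- setdiff(unique(c(pairs$erna_id, pairs$mrna_id)),
                  rownames(profile))
  if (length(miss))
    stop("profiles missing for: ", paste(head(miss), collapse = ", "))
  e <- profile[pairs$erna_id, , drop = FALSE]
  m <- profile[pairs$mrna_id, , drop = FALSE]
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    if (sd(e[i, ]) == 0 || sd(m[i, ]) == 0) return(NA_real_)
    cor(e[i, ], m[i, ])
  }, numeric(1))
  pairs$r <- r
  pairs$r_defined <- !is.na(r)
  pairs
}

#' Permutation test of enhancer-promoter co-regulation
#'
#' The observed statistic (mean or median pair correlation) is compared
#' with a null built by re-pairing enhancers and promoters uniformly at
#' random, ignoring insulated neighborhoods, keeping the number of pairs.
#' Empirical p-value with the add-one estimator:
#' (#\{null >= observed\} + 1) / (n_perm + 1).
#'
#' @param pairs data.frame with `r` (from [pair_correlations()]).
#' @param profile time-series matrix as in [pair_correlations()].
#' @param erna_pool,mrna_pool ids to draw random pairs from (defaults:
#'   ids present in `pairs`).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param statistic "mean" or "median".
#' @return list(observed, null, p_value, n_perm).
#' @export
permutation_test <- function(pairs, profile, erna_pool = NULL,
                             mrna_pool = NULL, n_perm = 1000L, seed = 1L,
                             statistic = c("mean", "median")) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "mean") function(x) mean(x, na.rm = TRUE)
              else function(x) median(x, na.rm = TRUE)
  observed <- stat_fun(pairs$r)
  if (is.null(erna_pool)) erna_pool <- unique(pairs$erna_id)
  if (is.null(mrna_pool)) mrna_pool <- unique(pairs$mrna_id)
  n <- nrow(pairs)
  set.seed(seed)
  null <- numeric(n_perm)
  ep <- profile[erna_pool, , drop = FALSE]
  mp <- profile[mrna_pool, , drop = FALSE]
  for (b in seq_len(n_perm)) {
    ei <- sample.int(nrow(ep), n, replace = TRUE)
    mi <- sample.int(nrow(mp), n, replace = TRUE)
    rs <- vapply(seq_len(n), function(i) {
      x <- ep[ei[i], ]; y <- mp[mi[i], ]
      if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
      cor(x, y)
    }, numeric(1))
    null[b] <- stat_fun(rs)
  }
  p <- (sum(null >= observed) + 1) / (n_perm + 1)
  list(observed = observed, null = null, p_value = p, n_perm = n_perm)
}

#' Closest-enhancer baseline pairing
#'
#' Pairs every promoter (mRNA) with the nearest eRNA TSS genome-wide
#' (same chromosome; equidistant ties go to the smaller coordinate) and
#' reports whether the pair falls in one insulated neighborhood, plus
#' correlation diagnostics when a profile matrix is supplied.
#'
#' @param ernas,mrnas stranded GRanges.
#' @param neighborhoods GRanges.
#' @param profile optional time-series matrix for correlations.
#' @return list(pairs, spearman_dist_r, same_loop_test).
#' @export
closest_pairing <- function(ernas, mrnas, neighborhoods, profile = NULL) {
  if (!length(ernas)) {
    warning("no eRNAs; empty closest pairing")
    return(list(pairs = data.frame(), spearman_dist_r = NA_real_,
                same_loop_test = NULL))
  }
  eid <- pairing_ids(ernas); mid <- pairing_ids(mrnas)
  etss_pos <- tss_position(ernas); mtss_pos <- tss_position(mrnas)
  echr <- as.character(seqnames(ernas)); mchr <- as.character(seqnames(mrnas))
  rows <- lapply(seq_along(mrnas), function(i) {
    on_chr <- which(echr == mchr[i])
    if (!length(on_chr)) return(NULL)
    d <- abs(etss_pos[on_chr] - mtss_pos[i])
    best <- on_chr[order(d, etss_pos[on_chr])][1]
    data.frame(erna_id = eid[best], mrna_id = mid[i],
               distance_bp = abs(etss_pos[best] - mtss_pos[i]),
               e_idx = best, m_idx = i, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  ## same-neighborhood flag
  nbs <- neighborhoods
  same <- vapply(seq_len(nrow(pairs)), function(j) {
    ei <- pairs$e_idx[j]; mi <- pairs$m_idx[j]
    ep <- GenomicRanges::GRanges(echr[ei], IRanges::IRanges(etss_pos[ei], width = 1))
    mp <- GenomicRanges::GRanges(mchr[mi], IRanges::IRanges(mtss_pos[mi], width = 1))
    enb <- subjectHits(findOverlaps(ep, nbs, ignore.strand = TRUE))
    mnb <- subjectHits(findOverlaps(mp, nbs, ignore.strand = TRUE))
    length(intersect(enb, mnb)) > 0
  }, logical(1))
  pairs$same_neighborhood <- same
  spearman <- NA_real_; slt <- NULL
  if (!is.null(profile)) {
    pr <- pair_correlations(pairs, profile)
    pairs$r <- pr$r
    ok <- !is.na(pairs$r)
    if (sum(ok) > 3)
      spearman <- suppressWarnings(
        cor(pairs$distance_bp[ok], pairs$r[ok], method = "spearman"))
    if (any(same & ok) && any(!same & ok))
      slt <- suppressWarnings(
        wilcox.test(pairs$r[same & ok], pairs$r[!same & ok]))
  }
  pairs$e_idx <- pairs$m_idx <- NULL
  list(pairs = pairs, spearman_dist_r = spearman, same_loop_test = slt)
}

#' Temporal profile summaries for co-changed pairs
#'
#' For pair sets whose two members are both significantly up- (or down-)
#' regulated at the last time point, reports per-time-point medians and
#' quartiles of size-factor-normalized counts over the whole eRNA and
#' over the first `mrna_prefix` bp of the mRNA (strand-aware), each
#' scaled to its own 0-min value.
#'
#' @param pairs pairing data.frame.
#' @param ernas,mrnas GRanges matching the ids used in `pairs`.
#' @param tracks list of `coverage_track` (typically TT samples).
#' @param sample_meta data.frame (sample_id, assay, time, replicate) for
#'   `tracks`.
#' @param sf size factors for `tracks`.
#' @param de classified differential result (with `direction`).
#' @param at_time contrast time point used for the selection (default:
#'   max contrast).
#' @param mrna_prefix prefix length (bp); mRNAs shorter than this are used
#'   whole and flagged.
#' @return list(up, down): each a data.frame time, who ("eRNA"/"mRNA"),
#'   median, q25, q75, n.
#' @export
temporal_profiles <- function(pairs, ernas, mrnas, tracks, sample_meta, sf,
                              de, at_time = NULL, mrna_prefix = 2200L) {
  if (is.null(at_time)) at_time <- max(de$contrast)
  dir_at <- de$direction[de$contrast == at_time]
  names(dir_at) <- de$feature_id[de$contrast == at_time]
  eid <- pairing_ids(ernas); mid <- pairing_ids(mrnas)
  ## strand-aware mRNA prefix
  short <- width(mrnas) < mrna_prefix
  pref <- promoters(mrnas, upstream = 0, downstream = mrna_prefix)
  pref <- trim(pref)
  mcols(pref)$name <- mid
  mcols(ernas)$name <- eid
  prof_e <- norm_profile(tracks, ernas, sample_meta, sf)
  prof_m <- norm_profile(tracks, pref, sample_meta, sf)
  res <- list()
  for (d in c("up", "down")) {
    sel <- pairs[dir_at[pairs$erna_id] == d &
                   dir_at[pairs$mrna_id] == d, , drop = FALSE]
    sel <- sel[complete.cases(sel[, c("erna_id", "mrna_id")]), ,
               drop = FALSE]
    if (!nrow(sel)) { res[[d]] <- NULL; next }
    summarize <- function(mat, ids, who) {
      m <- mat[ids, , drop = FALSE]
      base <- m[, 1]
      keep <- base > 0
      m <- m[keep, , drop = FALSE] / base[keep]
      do.call(rbind, lapply(seq_len(ncol(m)), function(j)
        data.frame(time = as.numeric(colnames(mat))[j], who = who,
                   median = median(m[, j]), q25 = quantile(m[, j], 0.25),
                   q75 = quantile(m[, j], 0.75), n = nrow(m))))
    }
    res[[d]] <- rbind(summarize(prof_e, sel$erna_id, "eRNA"),
                      summarize(prof_m, sel$mrna_id, "mRNA"))
    res[[d]]$flag_short_mrna <- any(short[match(sel$mrna_id, mid)])
  }
  res
}

## replicate-averaged normalized per-time-point counts over features,
## computed from tracks
norm_profile <- function(tracks, features, sample_meta, sf) {
  ks <- vapply(tracks, count_features, numeric(length(features)),
               features = features)
  if (is.null(dim(ks))) ks <- matrix(ks, nrow = length(features))
  rownames(ks) <- feature_ids(features)
  q <- sweep(ks, 2, sf, "/")
  times <- sort(unique(sample_meta$time))
  prof <- vapply(times, function(tp)
    rowMeans(q[, sample_meta$time == tp, drop = FALSE]),
    numeric(nrow(q)))
  colnames(prof) <- times
  prof
}

#' Strand-oriented average signal profile around TSSs
#'
#' @param signal list chrom -> numeric vector (nucleotide resolution,
#'   strandless signal such as DNase hypersensitivity).
#' @param tss stranded GRanges of TSS anchors (width-1 or full features,
#'   the strand-aware 5' end is used).
#' @param window half-width in bp.
#' @return numeric vector of length 2*window+1 (position -window..window
#'   relative to the TSS, oriented in transcription direction).
#' @export
tss_metaprofile <- function(signal, tss, window = 2000L) {
  if (!length(tss)) stop("empty TSS set")
  pos <- tss_position(tss)
  chr <- as.character(seqnames(tss))
  neg <- as.character(strand(tss)) == "-"
  L <- 2L * window + 1L
  acc <- matrix(NA_real_, length(tss), L)
  for (i in seq_along(tss)) {
    v <- signal[[chr[i]]]
    idx <- (pos[i] - window):(pos[i] + window)
    ok <- idx >= 1 & idx <= length(v)
    row <- rep(NA_real_, L)
    row[ok] <- v[idx[ok]]
    if (neg[i]) row <- rev(row)
    acc[i, ] <- row
  }
  colMeans(acc, na.rm = TRUE)
}
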