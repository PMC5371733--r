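## Transcription-unit calling on top of the HMM segmentation: RPK
## thresholding by Jaccard optimization, boundary refinement and the
## rule-based classification into mRNA / lincRNA / ncRNA / eRNA.

#' Nucleotide Jaccard index between two interval sets
#'
#' @param a,b GRanges (strand ignored; callers pass per-strand sets when
#'   strandedness matters).
#' @return |a intersect b| / |a union b| in nucleotides.
#' @export
jaccard_index <- function(a, b) {
  a <- reduce(a, ignore.strand = TRUE)
  b <- reduce(b, ignore.strand = TRUE)
  if (length(a) == 0 && length(b) == 0) {
    warning("both interval sets empty; Jaccard defined as 0")
    return(0)
  }
  inter <- sum(width(GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
  uni <- sum(width(GenomicRanges::union(a, b, ignore.strand = TRUE)))
  inter / uni
}

#' Optimize the minimal-RPK threshold for TU filtering
#'
#' Scans candidate thresholds and returns the one maximizing the
#' nucleotide Jaccard index between the retained TUs and a reference
#' annotation (ties resolved towards the smallest threshold, i.e. the
#' least filtering).
#'
#' @param tus GRanges with an `rpk` metadata column.
#' @param reference GRanges of reference intervals.
#' @param candidates numeric vector of candidate thresholds.
#' @return list with `threshold`, `jaccard` (named by candidate).
#' @export
optimize_rpk_threshold <- function(tus, reference, candidates) {
  if (!length(candidates)) stop("empty candidate threshold list")
  if (is.null(mcols(tus)$rpk)) stop("TUs must carry an 'rpk' column")
  candidates <- sort(candidates)
  js <- vapply(candidates, function(th)
    suppressWarnings(jaccard_index(tus[mcols(tus)$rpk >= th], reference)),
    numeric(1))
  names(js) <- candidates
  list(threshold = candidates[which.max(js)], jaccard = js)
}

#' Refine a boundary by a two-segment constant fit
#'
#' Within the +/- 2-bin window around an initially assigned boundary, the
#' breakpoint minimizing the residual sum of squares of a piecewise
#' constant (two-plateau) fit to nucleotide-resolution coverage becomes the
#' new boundary.  A flat window keeps the original boundary.
#'
#' @param coverage numeric coverage vector for the whole chromosome
#'   (1-based, nucleotide resolution).
#' @param boundary original boundary position (1-based bp).
#' @param bin_size bin width defining the window half-width (2 bins).
#' @return refined boundary position.
#' @export
refine_boundary <- function(coverage, boundary, bin_size = 200L) {
  lo <- boundary - 2L * bin_size
  hi <- boundary + 2L * bin_size
  if (lo < 1L || hi > length(coverage)) {
    warning("refinement window clipped at chromosome end")
    lo <- max(lo, 1L); hi <- min(hi, length(coverage))
  }
  y <- coverage[lo:hi]
  n <- length(y)
  if (n < 3L || all(y == y[1])) return(boundary)
  ## RSS of two constant segments split after position b (1..n-1)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  b <- seq_len(n - 1L)
  s1 <- cs[b]; q1 <- cs2[b]
  s2 <- cs[n] - s1; q2 <- cs2[n] - q1
  rss <- (q1 - s1^2 / b) + (q2 - s2^2 / (n - b))
  best <- which.min(rss)
  cand <- lo + best  # first position of the right-hand segment
  orig_rss <- {
    ob <- boundary - lo
    if (ob >= 1 && ob <= n - 1) rss[ob] else Inf
  }
  if (is.finite(orig_rss) && orig_rss <= min(rss) + 1e-9) boundary else cand
}

#' Refine the start and end of each TU
#'
#' @param tus GRanges.
#' @param nt_coverage list chrom -> list("+"/"-" -> nucleotide coverage
#'   vector) summed over samples.
#' @param bin_size bin width.
#' @return GRanges with adjusted boundaries.
#' @export
refine_boundaries <- function(tus, nt_coverage, bin_size = 200L) {
  for (i in seq_along(tus)) {
    chrom <- as.character(seqnames(tus)[i])
    str <- as.character(strand(tus)[i])
    cov <- nt_coverage[[chrom]][[str]]
    if (is.null(cov)) next
    ns <- refine_boundary(cov, start(tus)[i], bin_size)
    ne <- refine_boundary(cov, end(tus)[i], bin_size)
    if (ns < ne) { start(tus)[i] <- ns; end(tus)[i] <- ne }
  }
  tus
}

#' Classify transcription units against a reference annotation
#'
#' Rules, applied in order:
#' 1. a TU overlapping at least `min_overlap` (default 20%) of its length
#'    with a protein-coding or lincRNA gene on the same strand, and
#'    touching an exon of that gene, is classified mRNA / lincRNA and
#'    linked to the gene; everything else is ncRNA;
#' 2. TUs linked to the same gene are combined into one unit;
#' 3. ncRNAs up to `merge_gap` bp (default 200, one bin) apart on the same
#'    strand are merged;
#' 4. TUs covering at least 75% of the length of two or more
#'    protein-coding genes while those genes cover at least 20% of the TU
#'    are removed as ambiguous;
#' 5. mRNA units shorter than 5 kb with less than 10% overlap with any
#'    protein-coding gene are downgraded to ncRNA;
#' 6. ncRNAs starting up to 1 kb downstream of a protein-coding gene on
#'    the same strand are flagged `readthrough` (excluded from enhancer
#'    analyses, not removed).
#'
#' @param tus GRanges with `rpk` column.
#' @param annotation `tx_annotation`.
#' @param min_overlap fraction of TU length for rule 1.
#' @param merge_gap gap for ncRNA merging (bp).
#' @return GRanges with `tu_id`, `class`, `gene_id`, `readthrough`, `rpk`.
#' @export
classify_tus <- function(tus, annotation, min_overlap = 0.2,
                         merge_gap = 200L) {
  genes <- annotation$genes
  exons <- annotation$exons
  coding <- genes[mcols(genes)$gene_biotype %in% c("protein_coding",
                                                   "lincRNA")]
  cls <- rep("ncRNA", length(tus))
  gid <- rep(NA_character_, length(tus))
  if (length(coding)) {
    ov <- findOverlaps(tus, coding)
    if (length(ov)) {
      ow <- width(pintersect(tus[queryHits(ov)], coding[subjectHits(ov)]))
      frac <- ow / width(tus)[queryHits(ov)]
      keep <- frac >= min_overlap
      ## exon-touch requirement per candidate gene
      if (any(keep)) {
        cand <- which(keep)
        for (ii in cand) {
          q <- queryHits(ov)[ii]; s <- subjectHits(ov)[ii]
          gexons <- exons[mcols(exons)$gene_id == mcols(coding)$gene_id[s]]
          if (!length(gexons))
            stop(sprintf("reference gene %s has no exon records",
                         mcols(coding)$gene_id[s]))
          if (!any(overlapsAny(gexons, tus[q]))) next
          ## link to the gene with the largest overlap
          if (is.na(gid[q]) || ow[ii] > attr(gid, "best")[q] %||% -1) {
            gid[q] <- mcols(coding)$gene_id[s]
            bb <- attr(gid, "best"); if (is.null(bb)) bb <- rep(-1, length(tus))
            bb[q] <- ow[ii]; attr(gid, "best") <- bb
            cls[q] <- if (mcols(coding)$gene_biotype[s] == "protein_coding")
              "mRNA" else "lincRNA"
          }
        }
      }
    }
  }
  attr(gid, "best") <- NULL
  out <- tus
  mcols(out)$class <- cls
  mcols(out)$gene_id <- gid
  rpkv <- mcols(out)$rpk %||% rep(NA_real_, length(out))

  ## rule 2: combine TUs linked to the same gene
  combined <- list()
  linked <- !is.na(gid)
  if (any(linked)) {
    for (g in unique(gid[linked])) {
      idx <- which(gid == g)
      rng <- range(out[idx])
      mcols(rng)$class <- cls[idx][1]
      mcols(rng)$gene_id <- g
      mcols(rng)$rpk <- weighted.mean(rpkv[idx], width(out)[idx])
      combined[[g]] <- rng
    }
  }
  rest <- out[!linked]
  mcols(rest)$rpk <- rpkv[!linked]
  out <- do.call(c, c(unname(combined), list(rest)))

  ## rule 3: merge nearby ncRNAs per strand
  isnc <- mcols(out)$class == "ncRNA"
  if (any(isnc)) {
    nc <- out[isnc]
    merged <- reduce(nc, min.gapwidth = merge_gap + 1L)
    ## carry length-weighted rpk
    mo <- findOverlaps(nc, merged)
    rpk_m <- vapply(seq_along(merged), function(i) {
      src <- queryHits(mo)[subjectHits(mo) == i]
      weighted.mean(mcols(nc)$rpk[src], width(nc)[src])
    }, numeric(1))
    mcols(merged)$class <- "ncRNA"
    mcols(merged)$gene_id <- NA_character_
    mcols(merged)$rpk <- rpk_m
    out <- c(out[!isnc], merged)
  }

  ## rule 4: remove TUs consuming several protein-coding genes
  pc <- genes[mcols(genes)$gene_biotype == "protein_coding"]
  if (length(pc)) {
    ov <- findOverlaps(out, pc)
    if (length(ov)) {
      ow <- width(pintersect(out[queryHits(ov)], pc[subjectHits(ov)]))
      strong <- ow >= 0.75 * width(pc)[subjectHits(ov)] &
        ow >= 0.2 * width(out)[queryHits(ov)]
      nstrong <- tabulate(queryHits(ov)[strong], nbins = length(out))
      out <- out[nstrong < 2]
    }
  }

  ## rule 5: short weakly-supported mRNAs become ncRNA
  ismr <- mcols(out)$class == "mRNA" & width(out) < 5000
  if (any(ismr) && length(pc)) {
    ov <- findOverlaps(out[ismr], pc)
    fr <- numeric(sum(ismr))
    if (length(ov)) {
      ow <- width(pintersect(out[ismr][queryHits(ov)], pc[subjectHits(ov)]))
      agg <- rowsum(ow, queryHits(ov))
      fr[as.integer(rownames(agg))] <- agg[, 1] / width(out[ismr])[as.integer(rownames(agg))]
    }
    demote <- which(ismr)[fr < 0.1]
    if (length(demote)) {
      mcols(out)$class[demote] <- "ncRNA"
      mcols(out)$gene_id[demote] <- NA_character_
    }
  }

  ## rule 6: readthrough flag for ncRNAs just downstream of coding genes
  rt <- rep(FALSE, length(out))
  isnc <- mcols(out)$class == "ncRNA"
  if (any(isnc) && length(pc)) {
    nc <- out[isnc]
    ncs <- tss_position(nc)
    pe <- ifelse(as.character(strand(pc)) == "+", end(pc), start(pc))
    same_chr <- outer(as.character(seqnames(nc)),
                      as.character(seqnames(pc)), "==")
    same_str <- outer(as.character(strand(nc)),
                      as.character(strand(pc)), "==")
    dwn <- outer(ncs, pe, "-")
    dwn[as.character(strand(nc)) == "-", ] <-
      -dwn[as.character(strand(nc)) == "-", , drop = FALSE]
    hit <- same_chr & same_str & dwn >= 0 & dwn <= 1000
    rt[isnc] <- rowSums(hit) > 0
  }
  mcols(out)$readthrough <- rt
  out <- sort(out, ignore.strand = TRUE)
  mcols(out)$tu_id <- sprintf("TU%05d", seq_along(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strand-aware TSS position of features
#'
#' @param gr stranded GRanges.
#' @return integer vector of 5' end positions.
#' @export
tss_position <- function(gr) {
  ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
}

#' Constitutive exons per gene
#'
#' The intersection of exonic nucleotides across all annotated isoforms of
#' each gene; used for counting so that isoform-variable regions do not
#' bias amount estimates.
#'
#' @param annotation `tx_annotation`.
#' @return GRangesList-like named list gene_id -> GRanges (possibly empty,
#'   flagged via the `empty` attribute).
#' @export
constitutive_exons <- function(annotation) {
  exons <- annotation$exons
  out <- list()
  for (g in unique(mcols(exons)$gene_id)) {
    ge <- exons[mcols(exons)$gene_id == g]
    txs <- unique(mcols(ge)$transcript_id)
    if (!length(txs)) stop(sprintf("gene %s has no isoforms", g))
    cur <- reduce(ge[mcols(ge)$transcript_id == txs[1]])
    for (tx in txs[-1])
      cur <- GenomicRanges::intersect(cur,
               reduce(ge[mcols(ge)$transcript_id == tx]))
    out[[g]] <- cur
  }
  out
}

#' Segment the genome of a set of TT-seq tracks into TUs
#'
#' Runs the two-state HMM per strand on pseudo-counted bins across all
#' tracks, decodes transcribed intervals, attaches the mean RPK across
#' tracks, and (optionally) filters at a threshold optimized against a
#' reference by Jaccard index.
#'
#' @param tracks list of antisense-corrected `coverage_track`s.
#' @param pseudo_count added to each bin before the HMM (masks noise).
#' @param rpk_candidates candidate thresholds; NULL skips filtering.
#' @param reference GRanges used by the threshold optimization.
#' @param ... passed to [fit_hmm()].
#' @return list with `tus` (GRanges with rpk), `fit` per strand,
#'   `threshold`.
#' @export
segment_genome <- function(tracks, pseudo_count = 1L, rpk_candidates = NULL,
                           reference = NULL, ...) {
  genome <- tracks[[1]]$genome
  bs <- tracks[[1]]$bin_size
  fits <- list(); tus <- GenomicRanges::GRanges()
  for (s in c("+", "-")) {
    seqs <- list()
    for (chrom in names(genome)) {
      mat <- vapply(tracks, function(tr) tr$bins[[chrom]][[s]],
                    numeric(length(tracks[[1]]$bins[[chrom]][[s]])))
      if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(tracks))
      seqs[[paste0(chrom, ":", s)]] <- round(mat) + pseudo_count
    }
    fit <- fit_hmm(seqs, ...)
    fits[[s]] <- fit
    if (!fit$degenerate)
      tus <- c(tus, decode_transcribed(fit, seqs, bin_size = bs,
                                       genome = genome))
  }
  if (length(tus)) {
    ks <- vapply(tracks, count_features, numeric(length(tus)),
                 features = tus)
    if (is.null(dim(ks))) ks <- matrix(ks, nrow = length(tus))
    mcols(tus)$rpk <- rowMeans(rpk(ks, width(tus)))
  }
  threshold <- NA_real_
  if (!is.null(rpk_candidates) && !is.null(reference) && length(tus)) {
    opt <- optimize_rpk_threshold(tus, reference, rpk_candidates)
    threshold <- opt$threshold
    tus <- tus[mcols(tus)$rpk >= threshold]
  }
  list(tus = tus, fits = fits, threshold = threshold)
}
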