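## Strand-specific binned coverage tracks, antisense-bias estimation and
## correction, feature counting and RPK.

#' Construct an empty stranded coverage track
#'
#' Coverage is stored per chromosome and strand as a numeric vector of
#' bin counts.  Bin b (0-based) covers [b*bin_size, (b+1)*bin_size); the
#' last bin of a chromosome may be partial.
#'
#' @param genome named integer vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 200, the resolution at which
#'   fragment midpoints are aggregated).
#' @param sample_id optional sample identifier.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(genome, bin_size = 200L, sample_id = NA_character_) {
  genome <- genome_info(genome)
  bins <- lapply(genome, function(len) {
    nb <- as.integer(ceiling(len / bin_size))
    list("+" = numeric(nb), "-" = numeric(nb))
  })
  structure(list(genome = genome, bin_size = as.integer(bin_size),
                 sample_id = sample_id, bins = bins),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- vapply(x$bins, function(ch) sum(ch[["+"]]) + sum(ch[["-"]]),
                numeric(1))
  cat(sprintf("coverage_track '%s': %d chromosome(s), bin %d bp, total %.0f\n",
              x$sample_id, length(x$bins), x$bin_size, sum(tot)))
  invisible(x)
}

#' Bin fragment midpoints into a stranded coverage track
#'
#' @param fragments data.frame with columns chrom, midpoint (0-based bp),
#'   strand ("+"/"-").
#' @param genome named chromosome lengths.
#' @param bin_size bin width (bp).
#' @param sample_id sample label.
#' @return `coverage_track`.
#' @export
bin_midpoints <- function(fragments, genome, bin_size = 200L,
                          sample_id = NA_character_) {
  tr <- coverage_track(genome, bin_size, sample_id)
  if (nrow(fragments) == 0) return(tr)
  bad <- !(fragments$chrom %in% names(genome)) |
    fragments$midpoint < 0 |
    fragments$midpoint >= genome[fragments$chrom]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("fragment midpoint out of bounds: %s:%d",
                 fragments$chrom[i], fragments$midpoint[i]))
  }
  for (chrom in unique(fragments$chrom)) {
    for (s in c("+", "-")) {
      mp <- fragments$midpoint[fragments$chrom == chrom &
                                 fragments$strand == s]
      if (!length(mp)) next
      b <- mp %/% bin_size + 1L
      tab <- tabulate(b, nbins = length(tr$bins[[chrom]][[s]]))
      tr$bins[[chrom]][[s]] <- tr$bins[[chrom]][[s]] + tab
    }
  }
  tr
}

#' Estimate the antisense bias of a sample
#'
#' Selects strand-specific annotated regions with no annotated feature on
#' the opposite strand, and over all positions (bins) there whose sense
#' coverage exceeds `min_sense` computes the median ratio of
#' antisense-to-sense coverage, each with a pseudo-count.  The resulting
#' fraction c estimates how much of the real coverage of one strand leaks
#' onto the other during library preparation.
#'
#' @param track `coverage_track` (bin or nucleotide resolution).
#' @param annotation `tx_annotation` or GRanges of stranded features.
#' @param min_sense minimum sense coverage for a position to qualify.
#' @param pseudo_count added to both numerator and denominator.
#' @return list with `c`, `n_positions_used`, `pseudo_count`
#'   (class `antisense_bias`).
#' @export
estimate_antisense_bias <- function(track, annotation, min_sense = 100,
                                    pseudo_count = 1) {
  genes <- if (inherits(annotation, "tx_annotation")) annotation$genes
           else annotation
  ratios <- numeric(0)
  bs <- track$bin_size
  for (chrom in names(track$bins)) {
    g <- genes[as.character(seqnames(genes)) == chrom]
    if (!length(g)) next
    nb <- length(track$bins[[chrom]][["+"]])
    cov_mask <- function(s) {
      gs <- g[as.character(strand(g)) == s]
      m <- logical(nb)
      if (length(gs)) {
        b0 <- (start(gs) - 1L) %/% bs + 1L
        b1 <- (end(gs) - 1L) %/% bs + 1L
        for (i in seq_along(gs)) m[b0[i]:b1[i]] <- TRUE
      }
      m
    }
    plus_mask <- cov_mask("+"); minus_mask <- cov_mask("-")
    for (s in c("+", "-")) {
      sense_ok <- if (s == "+") plus_mask & !minus_mask
                  else minus_mask & !plus_mask
      if (!any(sense_ok)) next
      sense <- track$bins[[chrom]][[s]][sense_ok]
      anti <- track$bins[[chrom]][[if (s == "+") "-" else "+"]][sense_ok]
      keep <- sense > min_sense
      ratios <- c(ratios, (anti[keep] + pseudo_count) /
                           (sense[keep] + pseudo_count))
    }
  }
  if (!length(ratios))
    stop("insufficient coverage: no strand-specific position exceeds min_sense")
  structure(list(c = median(ratios), n_positions_used = length(ratios),
                 pseudo_count = pseudo_count),
            class = "antisense_bias")
}

#' Invert the antisense mixing model
#'
#' The observed coverage of each strand is modelled as the real coverage of
#' that strand plus a fraction c of the real coverage of the opposite
#' strand: obs_s = real_s + c * real_a and obs_a = real_a + c * real_s.
#' Solving the 2x2 system gives real_s = (obs_s - c * obs_a) / (1 - c^2).
#'
#' @param obs_sense,obs_antisense non-negative numeric vectors (same length).
#' @param c antisense bias, 0 <= c < 1.
#' @param smooth_antisense_window odd window size (positions) over which the
#'   antisense input is averaged before inversion; use 51 for
#'   nucleotide-resolution coverage profiles, NULL (default) for counts.
#' @param round round the corrected values to the nearest integer
#'   (feature-count mode).
#' @return list with `sense` and `antisense` corrected vectors.
#' @export
correct_antisense <- function(obs_sense, obs_antisense, c,
                              smooth_antisense_window = NULL, round = FALSE) {
  if (c < 0 || c >= 1) stop("antisense bias c must satisfy 0 <= c < 1")
  stopifnot(length(obs_sense) == length(obs_antisense))
  a_for_s <- obs_antisense
  s_for_a <- obs_sense
  if (!is.null(smooth_antisense_window)) {
    a_for_s <- running_mean(obs_antisense, smooth_antisense_window)
    s_for_a <- running_mean(obs_sense, smooth_antisense_window)
  }
  real_s <- (obs_sense - c * a_for_s) / (1 - c^2)
  real_a <- (obs_antisense - c * s_for_a) / (1 - c^2)
  real_s <- pmax(real_s, 0)
  real_a <- pmax(real_a, 0)
  if (round) { real_s <- round(real_s); real_a <- round(real_a) }
  list(sense = real_s, antisense = real_a)
}

## symmetric running mean with edge truncation
running_mean <- function(x, window) {
  stopifnot(window %% 2 == 1)
  h <- (window - 1L) / 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Apply antisense correction to a whole track
#'
#' @param track `coverage_track`.
#' @param c antisense bias for this sample.
#' @return corrected `coverage_track`.
#' @export
correct_track <- function(track, c) {
  for (chrom in names(track$bins)) {
    res <- correct_antisense(track$bins[[chrom]][["+"]],
                             track$bins[[chrom]][["-"]], c)
    track$bins[[chrom]][["+"]] <- res$sense
    track$bins[[chrom]][["-"]] <- res$antisense
  }
  track
}

#' Count matrix container
#'
#' @param counts numeric matrix, features x samples, rownames = feature ids.
#' @param lengths feature lengths in bp.
#' @param samples data.frame with sample_id, assay ("TT"/"RNA"),
#'   time (min), replicate.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, samples = NULL) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0),
            all(counts >= 0))
  if (is.null(samples))
    samples <- data.frame(sample_id = colnames(counts),
                          assay = NA_character_, time = NA_real_,
                          replicate = NA_integer_)
  structure(list(counts = counts, lengths = lengths, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Count track coverage over a set of stranded features
#'
#' A bin contributes to feature i when the bin midpoint lies inside the
#' feature and the strands match.  Antisense correction, if any, is applied
#' to the track beforehand.
#'
#' @param track `coverage_track`.
#' @param features stranded GRanges (names or `name` column as feature ids).
#' @return numeric vector of counts, one per feature.
#' @export
count_features <- function(track, features) {
  if (any(as.character(strand(features)) == "*"))
    stop("count_features requires stranded features")
  bs <- track$bin_size
  k <- numeric(length(features))
  chr <- as.character(seqnames(features))
  str <- as.character(strand(features))
  for (i in seq_along(features)) {
    v <- track$bins[[chr[i]]][[str[i]]]
    nb <- length(v)
    b <- seq_len(nb)
    mid <- (b - 1) * bs + bs / 2
    sel <- mid >= start(features)[i] - 1L & mid < end(features)[i]
    k[i] <- sum(v[sel])
  }
  names(k) <- feature_ids(features)
  k
}

feature_ids <- function(gr) {
  if (!is.null(mcols(gr)$name)) mcols(gr)$name
  else if (!is.null(names(gr)) && length(names(gr))) names(gr)
  else paste0("feature_", seq_along(gr))
}

#' Build a count matrix from several tracks
#'
#' @param tracks list of `coverage_track` objects.
#' @param features stranded GRanges.
#' @param samples sample metadata data.frame (one row per track).
#' @return `count_matrix`.
#' @export
count_matrix_from_tracks <- function(tracks, features, samples = NULL) {
  counts <- vapply(tracks, count_features, numeric(length(features)),
                   features = features)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(features))
  rownames(counts) <- feature_ids(features)
  colnames(counts) <- vapply(tracks, `[[`, character(1), "sample_id")
  count_matrix(counts, width(features), samples)
}

#' Reads per kilobase
#'
#' @param k counts.
#' @param L feature lengths (bp).
#' @return k / (L/1000).
#' @export
rpk <- function(k, L) {
  if (any(L <= 0)) stop("feature length must be positive")
  k / (L / 1000)
}
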