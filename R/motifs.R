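## PWM scanning with the 80%-of-maximal-score occurrence rule, exact
## consensus scanning, and set-level enrichment (odds ratio + Fisher test
## + BH correction).

BASES <- c("A", "C", "G", "T")

#' Construct a PWM from a count matrix
#'
#' Counts are converted to probabilities with a small pseudo-weight and
#' then to log2-odds against a uniform background.  The maximal score is
#' the column-wise best-base sum.
#'
#' @param counts 4 x w numeric matrix, rows A, C, G, T.
#' @param id motif identifier.
#' @param pseudo pseudo-weight added to each count.
#' @param background per-base background probabilities (default uniform).
#' @return object of class `pwm` with `mat` (log2-odds), `max_score`,
#'   `consensus`, `width`.
#' @export
pwm <- function(counts, id = "motif", pseudo = 0.01,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM counts must have 4 rows (A,C,G,T)")
  rownames(counts) <- BASES
  p <- sweep(counts + pseudo, 2, colSums(counts + pseudo), "/")
  mat <- log2(p / background)
  cons <- paste(BASES[apply(mat, 2, which.max)], collapse = "")
  structure(list(id = id, mat = mat, counts = counts,
                 max_score = sum(apply(mat, 2, max)),
                 min_score = sum(apply(mat, 2, min)),
                 consensus = cons, width = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: width %d, consensus %s, max score %.2f\n",
              x$id, x$width, x$consensus, x$max_score))
  invisible(x)
}

#' Build a PWM from a consensus string
#'
#' @param consensus DNA string.
#' @param id identifier.
#' @param weight count given to the consensus base per position.
#' @export
pwm_from_consensus <- function(consensus, id = consensus, weight = 100) {
  b <- strsplit(toupper(consensus), "")[[1]]
  counts <- matrix(0, 4, length(b), dimnames = list(BASES, NULL))
  counts[cbind(match(b, BASES), seq_along(b))] <- weight
  pwm(counts, id = id)
}

dna_codes <- function(seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  match(x, c(BASES, "N"))
}

#' Reverse complement of a DNA string
#' @param seq DNA string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a sequence with a PWM
#'
#' Windows scoring at least `frac` of the maximal achievable score are
#' reported; `N` scores as the position minimum.  With
#' `both_strands = TRUE` the reverse complement is scanned too and hits
#' are reported in forward coordinates.
#'
#' @param seq DNA string over A, C, G, T, N.
#' @param pwm_obj a [pwm()].
#' @param frac score threshold as fraction of the maximal score.
#' @param both_strands scan the reverse strand as well.
#' @return data.frame position (1-based window start on the forward
#'   strand), strand, score.  Sequences shorter than the motif give an
#'   empty result.
#' @export
scan_sequence <- function(seq, pwm_obj, frac = 0.8, both_strands = TRUE) {
  w <- pwm_obj$width
  thr <- frac * pwm_obj$max_score
  scan_one <- function(s) {
    codes <- dna_codes(s)
    n <- length(codes)
    if (n < w) return(list(pos = integer(0), score = numeric(0)))
    nwin <- n - w + 1L
    sc <- numeric(nwin)
    colmin <- apply(pwm_obj$mat, 2, min)
    for (j in seq_len(w)) {
      cj <- codes[j:(j + nwin - 1L)]
      val <- pwm_obj$mat[, j][cj]      # NA for N (code 5)
      val[cj == 5L | is.na(val)] <- colmin[j]
      sc <- sc + val
    }
    list(pos = which(sc >= thr), score = sc[sc >= thr])
  }
  fwd <- scan_one(seq)
  out <- data.frame(position = fwd$pos, strand = rep("+", length(fwd$pos)),
                    score = fwd$score, stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- scan_one(revcomp(seq))
    n <- nchar(seq)
    if (length(rc$pos))
      out <- rbind(out, data.frame(position = n - w + 2L - rc$pos,
                                   strand = "-", score = rc$score,
                                   stringsAsFactors = FALSE))
  }
  out[order(out$position), , drop = FALSE]
}

#' Exact consensus occurrence within a TSS-relative window
#'
#' Sequences are assumed strand-oriented 5'->3' with the TSS at position
#' `tss_pos`; the window is given in TSS-relative coordinates (e.g.
#' c(-500, -100) for the promoter-proximal region).
#'
#' @param seqs character vector of sequences.
#' @param consensus exact motif string (e.g. "TGACTCA" for AP-1).
#' @param window c(from, to) relative to the TSS.
#' @param tss_pos TSS position within each sequence (recycled).
#' @param both_strands also match the reverse complement.
#' @return logical flag per sequence; attribute `clipped` marks sequences
#'   whose window was truncated.
#' @export
consensus_scan <- function(seqs, consensus, window = c(-500L, -100L),
                           tss_pos = nchar(seqs) + 1L,
                           both_strands = TRUE) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  tss_pos <- rep_len(tss_pos, length(seqs))
  w <- nchar(consensus)
  pats <- consensus
  if (both_strands) pats <- c(pats, revcomp(consensus))
  clipped <- logical(length(seqs))
  flags <- vapply(seq_along(seqs), function(i) {
    from <- tss_pos[i] + window[1]
    to <- tss_pos[i] + window[2] + w - 1L   # allow motif starting at 'to'
    n <- nchar(seqs[i])
    if (from < 1L || to > n) { clipped[i] <<- TRUE }
    from <- max(from, 1L); to <- min(to, n)
    if (to - from + 1L < w) return(FALSE)
    sub <- substr(seqs[i], from, to)
    any(vapply(pats, function(p) grepl(p, sub, fixed = TRUE), logical(1)))
  }, logical(1))
  attr(flags, "clipped") <- clipped
  flags
}

#' Motif enrichment between a positive and a negative sequence set
#'
#' Counts sequences containing at least one hit in each set; odds ratio
#' (a/(A-a)) / (b/(B-b)) with the Haldane-Anscombe +0.5 correction when
#' any cell is zero (flagged), two-sided Fisher exact p-value.
#'
#' @param pos_flags,neg_flags logical hit flags per sequence.
#' @return one-row data.frame a, A, b, B, odds_ratio, p, corrected.
#' @export
enrichment <- function(pos_flags, neg_flags) {
  A <- length(pos_flags); B <- length(neg_flags)
  if (A == 0 || B == 0) stop("both sequence sets must be non-empty")
  a <- sum(pos_flags); b <- sum(neg_flags)
  cells <- c(a, A - a, b, B - b)
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] / cc[2]) / (cc[3] / cc[4])
  p <- fisher.test(matrix(c(a, A - a, b, B - b), 2, 2,
                          byrow = TRUE))$p.value
  data.frame(a = a, A = A, b = b, B = B, odds_ratio = or, p = p,
             corrected = corrected)
}

#' Scan a PWM collection against positive/negative sets and rank by
#' enrichment
#'
#' @param pwms named list of [pwm()] objects.
#' @param pos_seqs,neg_seqs character vectors of sequences.
#' @param frac score threshold fraction.
#' @param both_strands scan both strands.
#' @return data.frame pwm_id, a, A, b, B, odds_ratio, p, padj (BH across
#'   PWMs).
#' @export
motif_enrichment <- function(pwms, pos_seqs, neg_seqs, frac = 0.8,
                             both_strands = TRUE) {
  rows <- lapply(pwms, function(pw) {
    pf <- vapply(pos_seqs, function(s)
      nrow(scan_sequence(s, pw, frac, both_strands)) > 0, logical(1))
    nf <- vapply(neg_seqs, function(s)
      nrow(scan_sequence(s, pw, frac, both_strands)) > 0, logical(1))
    cbind(pwm_id = pw$id, enrichment(pf, nf))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$padj <- p.adjust(out$p, method = "BH")
  out
}
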