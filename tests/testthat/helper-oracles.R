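# brute-force PWM scanning oracle: enumerate every window and score by
# direct lookup, independently of the vectorized implementation
scan_oracle <- function(seq, pw, frac = 0.8, both_strands = TRUE) {
  score_at <- function(s, i) {
    sum(vapply(seq_len(pw$width), function(j) {
      b <- substr(s, i + j - 1, i + j - 1)
      if (b == "N") min(pw$mat[, j]) else pw$mat[b, j]
    }, numeric(1)))
  }
  hits <- list()
  n <- nchar(seq)
  if (n >= pw$width) {
    rc <- revcomp(seq)
    for (i in 1:(n - pw$width + 1)) {
      if (score_at(seq, i) >= frac * pw$max_score)
        hits[[length(hits) + 1]] <- c(i, 1L)
      if (both_strands) {
        ii <- n - pw$width + 2L - i
        if (score_at(rc, ii) >= frac * pw$max_score)
          hits[[length(hits) + 1]] <- c(i, 2L)
      }
    }
  }
  if (!length(hits)) return(data.frame(position = integer(0),
                                       strand = character(0)))
  m <- do.call(rbind, hits)
  out <- data.frame(position = m[, 1], strand = c("+", "-")[m[, 2]])
  out[order(out$position, out$strand), ]
}
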