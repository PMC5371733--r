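## Two-state hidden Markov model with Poisson-log-normal emissions for
## genome segmentation into "transcribed" and "untranscribed" states.
## The emission for a bin with count k in state s (one term per sample
## track, independence across tracks) is
##   P(k | s) = Int Pois(k; e^y) Normal(y; m_s, sd_s^2) dy,
## evaluated by Gauss-Hermite quadrature over the latent log-rate y.

## Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[idx])
}

## Adaptive Gauss-Hermite log PLN density on a vector of unique counts:
## the quadrature is re-centered per count at the mode of the integrand
## (Laplace point), which keeps 30 nodes accurate across the count range.
pln_logdens_u <- function(uk, m, sdlog, gh) {
  s2 <- sdlog^2
  y <- ifelse(uk > 0, log(uk), m)      # Newton init near the mode
  for (it in 1:10) {
    g <- uk - exp(y) - (y - m) / s2
    h <- -exp(y) - 1 / s2
    y <- y - g / h
  }
  shat <- 1 / sqrt(exp(y) + 1 / s2)
  G <- length(gh$nodes)
  n <- length(uk)
  YG <- matrix(y, n, G) + sqrt(2) * shat %o% gh$nodes
  LT <- dpois(rep(uk, G), exp(as.vector(YG)), log = TRUE) +
    dnorm(as.vector(YG), m, sdlog, log = TRUE)
  LT <- matrix(LT, n, G)
  LT <- sweep(LT, 2, log(gh$weights) + gh$nodes^2, "+")
  mx <- apply(LT, 1, max)
  0.5 * log(2) + log(shat) + mx + log(rowSums(exp(LT - mx)))
}

## log PLN density for integer counts k (vectorized via unique values)
pln_logdens <- function(k, m, sdlog, gh) {
  uk <- sort(unique(k))
  pln_logdens_u(uk, m, sdlog, gh)[match(k, uk)]
}

## weighted PLN log-likelihood on an aggregated (value, weight) table
pln_wll <- function(par, uk, w, gh) {
  sum(w * pln_logdens_u(uk, par[1], exp(par[2]), gh))
}

## moment-based (m, sdlog) init from a weighted sample of counts
pln_moment_init <- function(k, w) {
  w <- w / sum(w)
  mu <- max(sum(w * k), 1e-3)
  v <- sum(w * (k - mu)^2)
  s2 <- log(1 + max(v - mu, 0) / mu^2)
  s2 <- min(max(s2, 1e-2), 4)
  c(m = log(mu) - s2 / 2, logsd = 0.5 * log(s2))
}

#' Fit a two-state Poisson-log-normal HMM by EM
#'
#' Baum-Welch with the per-bin emission likelihood computed by
#' Gauss-Hermite quadrature over the log-normal latent rate; the M-step for
#' the emission parameters maximizes the expected complete-data
#' log-likelihood numerically on a table of unique count values, so the
#' data log-likelihood is non-decreasing across iterations (up to optimizer
#' and quadrature tolerance).
#'
#' @param seqs list of integer matrices (bins x sample tracks), one per
#'   observation sequence (typically one per chromosome and strand).
#'   Pseudo-counts must already be added.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood improves by less than `tol`.
#' @param seed controls the (deterministic) initialization split; kept for
#'   interface stability.
#' @param n_nodes Gauss-Hermite node count.
#' @return object of class `hmm_fit` with elements `A` (transition matrix,
#'   rows: from-state), `pi0`, `m`/`sdlog` (2 x n_samples emission
#'   parameters; state 1 = untranscribed, state 2 = transcribed),
#'   `loglik_trace`, `degenerate`.
#' @export
fit_hmm <- function(seqs, max_iter = 50L, tol = 1e-3, seed = 1L,
                    n_nodes = 30L) {
  if (is.matrix(seqs)) seqs <- list(seqs)
  stopifnot(length(seqs) >= 1)
  seqs <- lapply(seqs, function(x) {
    x <- as.matrix(x)
    if (any(x < 0)) stop("all bins must be non-negative")
    storage.mode(x) <- "integer"
    x
  })
  J <- ncol(seqs[[1]])
  gh <- gauss_hermite(n_nodes)
  allk <- do.call(rbind, seqs)
  if (all(allk == allk[1])) {
    warning("degenerate input: all bins identical; single-state fallback")
    init <- pln_moment_init(as.numeric(allk), rep(1, length(allk)))
    return(structure(list(A = matrix(0.5, 2, 2), pi0 = c(0.5, 0.5),
                          m = matrix(init[1], 2, J),
                          sdlog = matrix(exp(init[2]), 2, J),
                          loglik_trace = numeric(0), degenerate = TRUE,
                          n_nodes = n_nodes),
                     class = "hmm_fit"))
  }

  ## init: split bins at the 90th percentile of the per-bin total
  tot <- rowSums(allk)
  thr <- quantile(tot, 0.9)
  hi <- tot > thr
  if (!any(hi)) hi <- tot > median(tot)
  m <- matrix(0, 2, J); sdlog <- matrix(0.5, 2, J)
  for (j in seq_len(J)) {
    p1 <- pln_moment_init(allk[!hi, j], rep(1, sum(!hi)))
    p2 <- pln_moment_init(allk[hi, j], rep(1, sum(hi)))
    m[1, j] <- p1[1]; sdlog[1, j] <- exp(p1[2])
    m[2, j] <- p2[1]; sdlog[2, j] <- exp(p2[2])
  }
  A <- matrix(c(0.99, 0.01, 0.05, 0.95), 2, 2, byrow = TRUE)
  pi0 <- c(0.9, 0.1)

  emission_ll <- function(x) {
    ll <- matrix(0, nrow(x), 2)
    for (s in 1:2) for (j in seq_len(J))
      ll[, s] <- ll[, s] + pln_logdens(x[, j], m[s, j], sdlog[s, j], gh)
    ll
  }

  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ## E-step (scaled forward-backward per sequence)
    tr_num <- matrix(0, 2, 2); pi_num <- c(0, 0); ll_total <- 0
    gammas <- vector("list", length(seqs))
    for (q in seq_along(seqs)) {
      x <- seqs[[q]]; n <- nrow(x)
      ell <- emission_ll(x)
      lmax <- apply(ell, 1, max)
      B <- exp(ell - lmax)
      alpha <- matrix(0, n, 2); scal <- numeric(n)
      a <- pi0 * B[1, ]; scal[1] <- sum(a); alpha[1, ] <- a / scal[1]
      for (ti in 2:n) {
        a <- (alpha[ti - 1, ] %*% A) * B[ti, ]
        scal[ti] <- sum(a); alpha[ti, ] <- a / scal[ti]
      }
      beta <- matrix(0, n, 2); beta[n, ] <- 1
      for (ti in (n - 1):1)
        beta[ti, ] <- (A %*% (B[ti + 1, ] * beta[ti + 1, ])) / scal[ti + 1]
      g <- alpha * beta
      g <- g / rowSums(g)
      gammas[[q]] <- g
      for (ti in 1:(n - 1)) {
        xi <- (alpha[ti, ] %o% (B[ti + 1, ] * beta[ti + 1, ])) * A /
          scal[ti + 1]
        tr_num <- tr_num + xi
      }
      pi_num <- pi_num + g[1, ]
      ll_total <- ll_total + sum(log(scal)) + sum(lmax)
    }
    trace <- c(trace, ll_total)

    ## M-step
    A <- tr_num / rowSums(tr_num)
    pi0 <- pi_num / sum(pi_num)
    gall <- do.call(rbind, gammas)
    for (s in 1:2) for (j in seq_len(J)) {
      w_by_k <- rowsum(gall[, s], allk[, j])
      uk <- as.integer(rownames(w_by_k)); w <- w_by_k[, 1]
      op <- optim(c(m[s, j], log(sdlog[s, j])), function(p)
        -pln_wll(p, uk, w, gh), method = "Nelder-Mead",
        control = list(maxit = 200, reltol = 1e-8))
      m[s, j] <- op$par[1]; sdlog[s, j] <- max(exp(op$par[2]), 1e-3)
    }
    if (iter > 1 && abs(trace[iter] - trace[iter - 1]) < tol) break
  }

  ## order states so state 2 is "transcribed" (higher mean)
  mean_s <- rowMeans(exp(m + sdlog^2 / 2))
  if (mean_s[1] > mean_s[2]) {
    m <- m[2:1, , drop = FALSE]; sdlog <- sdlog[2:1, , drop = FALSE]
    A <- A[2:1, 2:1]; pi0 <- pi0[2:1]
  }
  structure(list(A = A, pi0 = pi0, m = m, sdlog = sdlog,
                 loglik_trace = trace, degenerate = FALSE,
                 n_nodes = n_nodes),
            class = "hmm_fit")
}

#' Posterior state probabilities under a fitted HMM
#'
#' @param fit `hmm_fit`.
#' @param x integer matrix (bins x samples).
#' @return numeric vector of per-bin P(transcribed).
#' @export
hmm_posterior <- function(fit, x) {
  x <- as.matrix(x)
  gh <- gauss_hermite(fit$n_nodes)
  n <- nrow(x); J <- ncol(x)
  ll <- matrix(0, n, 2)
  for (s in 1:2) for (j in seq_len(J))
    ll[, s] <- ll[, s] + pln_logdens(x[, j], fit$m[s, j], fit$sdlog[s, j], gh)
  lmax <- apply(ll, 1, max)
  B <- exp(ll - lmax)
  A <- fit$A
  alpha <- matrix(0, n, 2); scal <- numeric(n)
  a <- fit$pi0 * B[1, ]; scal[1] <- sum(a); alpha[1, ] <- a / scal[1]
  if (n > 1) for (ti in 2:n) {
    a <- (alpha[ti - 1, ] %*% A) * B[ti, ]
    scal[ti] <- sum(a); alpha[ti, ] <- a / scal[ti]
  }
  beta <- matrix(0, n, 2); beta[n, ] <- 1
  if (n > 1) for (ti in (n - 1):1)
    beta[ti, ] <- (A %*% (B[ti + 1, ] * beta[ti + 1, ])) / scal[ti + 1]
  g <- alpha * beta
  (g / rowSums(g))[, 2]
}

#' Decode transcribed intervals from fitted HMM parameters
#'
#' Posterior decoding: bins with P(transcribed) > 0.5 are merged into
#' maximal runs and reported as genomic intervals at bin resolution.
#'
#' @param fit `hmm_fit`.
#' @param seqs named list of matrices as passed to [fit_hmm()]; names must
#'   be "chrom:strand" (e.g. "chr1:+").
#' @param bin_size bin width in bp.
#' @param genome named chromosome lengths (intervals are clipped).
#' @param threshold posterior threshold (default 0.5).
#' @return GRanges of transcribed intervals.
#' @export
decode_transcribed <- function(fit, seqs, bin_size = 200L, genome = NULL,
                               threshold = 0.5) {
  out <- list()
  for (nm in names(seqs)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    chrom <- parts[1]; str <- parts[2]
    p <- hmm_posterior(fit, seqs[[nm]])
    r <- rle(p > threshold)
    ends <- cumsum(r$lengths); starts <- c(0L, head(ends, -1L))
    keep <- r$values
    if (!any(keep)) next
    st <- starts[keep] * bin_size + 1L
    en <- ends[keep] * bin_size
    if (!is.null(genome)) en <- pmin(en, genome[[chrom]])
    out[[nm]] <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en),
                                        strand = str)
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  sort(do.call(c, unname(out)), ignore.strand = TRUE)
}
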