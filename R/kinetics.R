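## Spike-in calibration and first-order kinetic estimation of RNA
## synthesis and degradation rates.
##
## Observation model for feature i in sample j:
##   E[k_ij] = L_i * (sigma_j * alpha_ij + epsilon_j * beta_ij)
## where alpha is the labeled and beta the unlabeled RNA amount, sigma_j
## the sequencing depth and epsilon_j the cross-contamination rate of the
## sample.  Labeled spike-ins have (alpha, beta) = (1, 0), unlabeled ones
## (0, 1).  Under first-order kinetics with labeling duration t,
##   lambda_i = -(1/t) * log(beta_i / (alpha_i + beta_i))
##   mu_i     = (alpha_i + beta_i) * lambda_i
## and the half-life is ln(2) / lambda_i.

#' Spike-in table constructor
#'
#' @param id spike-in identifiers.
#' @param length_bp lengths.
#' @param labeled logical or 0/1 flags.
#' @param counts matrix spike-ins x samples.
#' @param samples sample metadata (sample_id, assay).
#' @return data-frame-backed list of class `spikein_table`.
#' @export
spikein_table <- function(id, length_bp, labeled, counts, samples) {
  stopifnot(length(id) == length(length_bp),
            length(id) == nrow(counts))
  structure(list(id = id, length_bp = length_bp,
                 labeled = as.logical(labeled),
                 counts = counts, samples = samples),
            class = "spikein_table")
}

#' Write/read a spike-in table as TSV
#' @param sp `spikein_table`.
#' @param path file path.
#' @export
write_spikeins <- function(sp, path) {
  df <- data.frame(id = sp$id, length_bp = sp$length_bp,
                   labeled = as.integer(sp$labeled), sp$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sp$samples, paste0(path, ".samples"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikeins
#' @param samples optional metadata; defaults to the side-car file.
#' @export
read_spikeins <- function(path, samples = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (is.null(samples))
    samples <- read.table(paste0(path, ".samples"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  spikein_table(df$id, df$length_bp, df$labeled,
                as.matrix(df[, -(1:3), drop = FALSE]), samples)
}

#' Calibrate per-sample depth and cross-contamination from spike-ins
#'
#' sigma_j is the median over labeled spike-ins of k_ij / L_i, epsilon_j
#' the median over unlabeled spike-ins.  Total RNA-seq samples are
#' rescaled so that epsilon_j = 1 (sigma_j divided by the same factor),
#' which fixes the amount unit to "RNA-seq equivalents".
#'
#' The rescale is a consistent renormalization: the factor is kept in a
#' per-sample `scale` column, and fitting divides that sample's counts by
#' the same factor, so amount estimates stay in absolute spike-in units.
#'
#' @param sp `spikein_table`; `sp$samples$assay` must be "TT" or "RNA".
#' @return data.frame sample_id, assay, sigma, epsilon, scale.
#' @export
calibrate <- function(sp) {
  if (!any(sp$labeled) || !any(!sp$labeled))
    stop("calibration requires both labeled and unlabeled spike-ins")
  dens <- sp$counts / sp$length_bp
  sigma <- apply(dens[sp$labeled, , drop = FALSE], 2, median)
  eps <- apply(dens[!sp$labeled, , drop = FALSE], 2, median)
  cal <- data.frame(sample_id = sp$samples$sample_id,
                    assay = sp$samples$assay,
                    sigma = sigma, epsilon = eps, scale = 1,
                    row.names = NULL)
  rna <- cal$assay == "RNA"
  cal$scale[rna] <- cal$epsilon[rna]
  cal$sigma[rna] <- cal$sigma[rna] / cal$epsilon[rna]
  cal$epsilon[rna] <- 1
  if (any(cal$sigma <= 0)) stop("non-positive calibrated depth")
  cal
}

#' Fit labeled/unlabeled RNA amounts for a TT/RNA sample pair
#'
#' With one TT-seq and one RNA-seq observation the Poisson MLE is the
#' exact solution of the linear system
#'   k_TT / L = sigma_T * alpha + eps_T * beta
#'   k_RNA / L = sigma_R * alpha + eps_R * beta.
#' Negative solutions are clamped to zero and flagged.
#'
#' @param k_tt,k_rna counts (vectors over features).
#' @param L feature lengths.
#' @param cal_tt,cal_rna single-row calibration (sigma, epsilon).
#' @return data.frame alpha, beta, clamped.
#' @export
fit_amounts <- function(k_tt, k_rna, L, cal_tt, cal_rna) {
  sT <- cal_tt$sigma; eT <- cal_tt$epsilon
  sR <- cal_rna$sigma; eR <- cal_rna$epsilon
  scT <- cal_tt$scale %||% 1; scR <- cal_rna$scale %||% 1
  det <- sT * eR - sR * eT
  if (abs(det) < 1e-12)
    stop("calibration matrix is singular; amounts not identifiable")
  yT <- k_tt / (L * scT); yR <- k_rna / (L * scR)
  alpha <- (yT * eR - yR * eT) / det
  beta <- (sT * yR - sR * yT) / det
  clamped <- alpha < 0 | beta < 0
  data.frame(alpha = pmax(alpha, 0), beta = pmax(beta, 0),
             clamped = clamped)
}

#' Poisson maximum-likelihood amounts with replicate samples
#'
#' Non-negative ML fit of (alpha, beta) for one feature across any number
#' of TT/RNA samples; reduces to [fit_amounts()] for one pair at zero
#' noise.
#'
#' @param k counts across samples (one feature).
#' @param L feature length.
#' @param cal calibration data.frame rows matching `k`.
#' @return list(alpha, beta, converged).
#' @export
fit_amounts_ml <- function(k, L, cal) {
  sc <- cal$scale %||% rep(1, nrow(cal))
  nll <- function(p) {
    mu <- L * sc * (cal$sigma * p[1] + cal$epsilon * p[2])
    mu <- pmax(mu, 1e-12)
    -sum(k * log(mu) - mu)
  }
  ## moment start from per-assay means
  start <- tryCatch({
    tt <- cal$assay == "TT"
    fa <- fit_amounts(mean(k[tt]), mean(k[!tt]), L,
                      data.frame(sigma = mean(cal$sigma[tt]),
                                 epsilon = mean(cal$epsilon[tt])),
                      data.frame(sigma = mean(cal$sigma[!tt]),
                                 epsilon = mean(cal$epsilon[!tt])))
    pmax(c(fa$alpha, fa$beta), 1e-6)
  }, error = function(e) c(1e-3, 1e-3))
  op <- optim(start, nll, method = "L-BFGS-B", lower = c(0, 0))
  list(alpha = op$par[1], beta = op$par[2], converged = op$convergence == 0)
}

#' First-order synthesis/degradation rates from amounts
#'
#' @param alpha labeled amounts.
#' @param beta unlabeled amounts.
#' @param t labeling duration (min).
#' @return data.frame lambda_per_min, mu_per_min, half_life_min, flag.
#' @export
kinetic_rates <- function(alpha, beta, t) {
  if (t <= 0) stop("labeling duration t must be positive")
  n <- length(alpha)
  stopifnot(length(beta) == n)
  lambda <- mu <- half <- rep(NA_real_, n)
  flag <- rep("", n)
  tot <- alpha + beta
  if (any(tot == 0)) {
    flag[tot == 0] <- "undefined"
  }
  ok <- tot > 0 & alpha > 0 & beta > 0
  lambda[ok] <- -(1 / t) * log(beta[ok] / tot[ok])
  mu[ok] <- tot[ok] * lambda[ok]
  half[ok] <- log(2) / lambda[ok]
  b0 <- tot > 0 & beta == 0   # fully labeled: degradation unresolvable
  lambda[b0] <- Inf
  mu[b0] <- alpha[b0] / t
  half[b0] <- 0
  flag[b0] <- "no_unlabeled"
  a0 <- tot > 0 & alpha == 0  # no labeling observed
  lambda[a0] <- 0
  mu[a0] <- 0
  half[a0] <- Inf
  flag[a0] <- "no_labeled"
  data.frame(lambda_per_min = lambda, mu_per_min = mu,
             half_life_min = half, flag = flag,
             stringsAsFactors = FALSE)
}

#' Full kinetic estimation for a count matrix
#'
#' Pairs TT and RNA samples by time point and replicate, fits amounts per
#' feature and time point, and converts them to rates.
#'
#' @param cm `count_matrix` with sample metadata (assay, time, replicate).
#' @param cal calibration from [calibrate()] (rows matching `cm$samples`).
#' @param t labeling duration (min).
#' @param time optional single time point to restrict to.
#' @return data.frame feature_id, time, alpha, beta, rates and flags.
#' @export
estimate_kinetics <- function(cm, cal, t = 5, time = NULL) {
  meta <- cm$samples
  times <- sort(unique(meta$time))
  if (!is.null(time)) times <- time
  out <- list()
  for (tp in times) {
    tt_idx <- which(meta$assay == "TT" & meta$time == tp)
    rna_idx <- which(meta$assay == "RNA" & meta$time == tp)
    if (!length(tt_idx) || !length(rna_idx)) next
    ## replicate-mean scale-normalized counts give the pooled pair fit
    sc <- cal$scale %||% rep(1, nrow(cal))
    k_tt <- rowMeans(sweep(cm$counts[, tt_idx, drop = FALSE], 2,
                           sc[tt_idx], "/"))
    k_rna <- rowMeans(sweep(cm$counts[, rna_idx, drop = FALSE], 2,
                            sc[rna_idx], "/"))
    ## replicate means of scale-normalized counts keep linearity exact
    cal_tt <- data.frame(sigma = mean(cal$sigma[tt_idx]),
                         epsilon = mean(cal$epsilon[tt_idx]), scale = 1)
    cal_rna <- data.frame(sigma = mean(cal$sigma[rna_idx]),
                          epsilon = mean(cal$epsilon[rna_idx]), scale = 1)
    am <- fit_amounts(k_tt, k_rna, cm$lengths, cal_tt, cal_rna)
    rt <- kinetic_rates(am$alpha, am$beta, t)
    out[[as.character(tp)]] <- data.frame(
      feature_id = rownames(cm$counts), time = tp,
      alpha = am$alpha, beta = am$beta, clamped = am$clamped, rt,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
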