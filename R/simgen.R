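## Synthetic world generator: toy genome, transcript annotation with
## kinetic ground truth, enhancer states, insulated neighborhoods with
## co-regulated enhancer-promoter pairs, and the corresponding synthetic
## observations (coverage tracks, count matrices, spike-ins, promoter
## sequences).  Everything is deterministic given (config, seed).

#' Default simulation configuration
#'
#' The defaults describe a desk-scale world: 2 chromosomes of 5 Mb,
#' roughly 300 transcripts, 40 insulated neighborhoods of 100-400 kb, a
#' 4-time-point (0/5/10/15 min) x 2-replicate design with 5-min labeling,
#' per-class half-life distributions with enhancer RNAs substantially
#' shorter-lived than mRNAs, an antisense bleed of 5%, and 8 labeled plus
#' 8 unlabeled spike-ins.
#'
#' @param ... overrides for any default field.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
    n_mrna = 120, n_lincrna = 10, n_ncrna = 60, n_erna = 80,
    n_pairs = 40,
    mrna_len = c(2000, 20000), lincrna_len = c(2000, 10000),
    ncrna_len = c(600, 4000), erna_len = c(600, 3000),
    min_gap = 1500,
    n_neighborhoods = 40, nb_size = c(1e5, 4e5),
    nb_gap = c(2e4, 8e4),
    n_decoy_states = 15,
    time_points = c(0, 5, 10, 15), replicates = 2, t_label = 5,
    ## kinetic truth (half-lives in minutes, amounts arbitrary units)
    half_life_meanlog = c(mRNA = log(60), lincRNA = log(40),
                          ncRNA = log(15), eRNA = log(6)),
    half_life_sdlog = c(mRNA = 0.6, lincRNA = 0.6, ncRNA = 0.5,
                        eRNA = 0.5),
    amount_meanlog = log(5), amount_sdlog = 0.5,
    frac_responsive = 0.3,
    response_log2_range = c(1, 3),
    response_ramp = c(0, 0.5, 0.8, 1),
    pair_rho = 0.8, pair_traj_sd = 1, pair_up_frac = 0.7,
    distance_decay_bp = 1e5,
    ## observation model
    antisense_c = 0.05,
    sigma_tt = 0.25, eps_tt = 0.005, depth_rna = 0.05,
    sample_depth_jitter = 0.2,
    bg_per_bin = 0.1, bin_size = 200,
    n_spike_labeled = 8, n_spike_unlabeled = 8,
    spike_len = c(1000, 4000))
  ov <- list(...)
  cfg[names(ov)] <- ov
  structure(cfg, class = "sim_config")
}

runif_range <- function(n, r) runif(n, r[1], r[2])

#' Configuration for the co-regulation benchmark world
#'
#' A larger world tailored to benchmarking the enhancer-promoter
#' permutation test: 200 true co-regulated pairs (per-time-point
#' log fold changes correlated at about r = 0.8, no distance decay) plus
#' 500 unpaired transcripts, under the standard 4 x 2 design.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return `sim_config`.
#' @export
coregulated_sim_config <- function(...) {
  sim_config(chrom_lengths = c(chr1 = 6e6, chr2 = 6e6),
             n_mrna = 350, n_lincrna = 50, n_ncrna = 150, n_erna = 350,
             n_pairs = 200, n_neighborhoods = 60,
             distance_decay_bp = Inf, n_decoy_states = 10, ...)
}

## place lengths into [1, L] with at least min_gap between consecutive
## features; deterministic given the RNG state
place_intervals <- function(lens, L, min_gap) {
  n <- length(lens)
  need <- sum(lens) + (n + 1) * min_gap
  if (need > L)
    stop(sprintf(
      "capacity error: %d features (total %.0f bp + gaps) exceed chromosome of %.0f bp",
      n, sum(lens), L))
  slack <- L - sum(lens) - (n + 1) * min_gap
  cuts <- sort(runif(n + 1))
  extra <- diff(c(0, cuts)) / cuts[n + 1] * slack
  gaps <- min_gap + extra[seq_len(n)]
  starts <- round(cumsum(gaps) + cumsum(c(0, lens[-n])))
  data.frame(start = starts, end = starts + round(lens) - 1)
}

#' Simulate a synthetic genomic world with known ground truth
#'
#' Plants non-overlapping transcripts of four classes (mRNA, lincRNA,
#' ncRNA, eRNA) on a toy genome, assigns first-order kinetic parameters
#' (synthesis amount, degradation rate) and per-time-point synthesis fold
#' changes, tiles insulated neighborhoods, selects co-regulated
#' enhancer-promoter pairs whose TSSs share a neighborhood, and places
#' enhancer-state intervals over every planted eRNA plus unconnected
#' decoys.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the world is deterministic given
#'   (config, seed).
#' @return object of class `sim_world`.
#' @export
simulate_world <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  genome <- genome_info(config$chrom_lengths)
  classes <- c(rep("mRNA", config$n_mrna),
               rep("lincRNA", config$n_lincrna),
               rep("ncRNA", config$n_ncrna),
               rep("eRNA", config$n_erna))
  lens <- c(exp(runif(config$n_mrna, log(config$mrna_len[1]),
                      log(config$mrna_len[2]))),
            exp(runif(config$n_lincrna, log(config$lincrna_len[1]),
                      log(config$lincrna_len[2]))),
            exp(runif(config$n_ncrna, log(config$ncrna_len[1]),
                      log(config$ncrna_len[2]))),
            exp(runif(config$n_erna, log(config$erna_len[1]),
                      log(config$erna_len[2]))))
  n <- length(classes)
  ids <- character(n)
  for (cl in unique(classes)) {
    w <- which(classes == cl)
    ids[w] <- sprintf("%s_%03d", cl, seq_along(w))
  }
  ## assign features to chromosomes proportionally to length
  perm <- sample.int(n)
  classes <- classes[perm]; lens <- lens[perm]; ids <- ids[perm]
  chrom_of <- sample(names(genome), n, replace = TRUE,
                     prob = genome / sum(genome))
  rows <- list()
  for (chrom in names(genome)) {
    w <- which(chrom_of == chrom)
    if (!length(w)) next
    pl <- place_intervals(lens[w], genome[[chrom]], config$min_gap)
    rows[[chrom]] <- data.frame(chrom = chrom, start = pl$start,
                                end = pl$end, id = ids[w],
                                class = classes[w],
                                strand = sample(c("+", "-"), length(w),
                                                replace = TRUE))
  }
  df <- do.call(rbind, rows)
  features <- GenomicRanges::GRanges(df$chrom,
                IRanges::IRanges(df$start, df$end), strand = df$strand,
                feature_id = df$id, class = df$class)
  seqlengths(features) <- genome[seqlevels(features)]

  ## insulated neighborhoods: random non-overlapping tiling per chromosome
  nbs <- list()
  for (chrom in names(genome)) {
    pos <- round(runif_range(1, config$nb_gap))
    while (length(nbs) < config$n_neighborhoods) {
      w <- round(runif_range(1, config$nb_size))
      if (pos + w > genome[[chrom]]) break
      nbs[[length(nbs) + 1]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(pos, pos + w - 1))
      pos <- pos + w + round(runif_range(1, config$nb_gap))
    }
  }
  neighborhoods <- suppressWarnings(do.call(c, unname(nbs)))
  mcols(neighborhoods)$name <- sprintf("NB%03d", seq_along(neighborhoods))

  ## kinetic truth
  cls <- mcols(features)$class
  hl <- rlnorm(n, config$half_life_meanlog[cls], config$half_life_sdlog[cls])
  lambda <- log(2) / hl
  A0 <- rlnorm(n, config$amount_meanlog, config$amount_sdlog)
  mu0 <- A0 * lambda

  ## co-regulated pairs: eRNA and mRNA TSSs sharing a neighborhood
  fid <- mcols(features)$feature_id
  tssp <- tss_position(features)
  tss_gr <- GenomicRanges::GRanges(seqnames(features),
                                   IRanges::IRanges(tssp, width = 1))
  nb_hit <- findOverlaps(tss_gr, neighborhoods, ignore.strand = TRUE)
  nb_of <- rep(NA_integer_, n)
  nb_of[queryHits(nb_hit)] <- subjectHits(nb_hit)
  cand <- expand.grid(e = which(cls == "eRNA"), m = which(cls == "mRNA"))
  cand <- cand[!is.na(nb_of[cand$e]) & !is.na(nb_of[cand$m]) &
                 nb_of[cand$e] == nb_of[cand$m], ]
  cand <- cand[abs(tssp[cand$e] - tssp[cand$m]) > 1000, ]
  cand <- cand[sample.int(nrow(cand)), ]
  pairs <- list(); used_e <- used_m <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(pairs) >= config$n_pairs) break
    if (cand$e[i] %in% used_e || cand$m[i] %in% used_m) next
    pairs[[length(pairs) + 1]] <- cand[i, ]
    used_e <- c(used_e, cand$e[i]); used_m <- c(used_m, cand$m[i])
  }
  if (config$n_pairs > 0 && length(pairs) < config$n_pairs)
    warning(sprintf("only %d of %d requested pairs could be planted",
                    length(pairs), config$n_pairs))
  pair_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(e = integer(0), m = integer(0))

  ## per-time-point synthesis fold changes
  tp <- config$time_points
  f <- matrix(1, n, length(tp), dimnames = list(fid, tp))
  ramp <- config$response_ramp
  resp <- rep(FALSE, n)
  unpaired <- setdiff(seq_len(n), c(pair_df$e, pair_df$m))
  is_resp <- unpaired[runif(length(unpaired)) < config$frac_responsive]
  amp <- runif(length(is_resp), config$response_log2_range[1],
               config$response_log2_range[2]) *
    sample(c(1, -1), length(is_resp), replace = TRUE)
  for (j in seq_along(is_resp))
    f[is_resp[j], ] <- 2^(amp[j] * ramp)
  resp[is_resp] <- TRUE

  pair_rows <- list()
  if (nrow(pair_df)) {
    for (j in seq_len(nrow(pair_df))) {
      e <- pair_df$e[j]; m <- pair_df$m[j]
      d <- abs(tssp[e] - tssp[m])
      rho <- config$pair_rho
      if (!is.null(config$distance_decay_bp) &&
          is.finite(config$distance_decay_bp))
        rho <- rho * exp(-d / config$distance_decay_bp)
      Mamp <- runif(1, config$response_log2_range[1],
                    config$response_log2_range[2]) *
        (if (runif(1) < config$pair_up_frac) 1 else -1)
      nt <- length(tp) - 1
      u <- rnorm(nt, 0, config$pair_traj_sd)
      ze <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(nt, 0, config$pair_traj_sd)
      zm <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(nt, 0, config$pair_traj_sd)
      f[e, -1] <- 2^(Mamp * ramp[-1] + ze)
      f[m, -1] <- 2^(Mamp * ramp[-1] + zm)
      resp[c(e, m)] <- TRUE
      pair_rows[[j]] <- data.frame(
        pair_id = sprintf("PAIR%03d", j), erna_id = fid[e],
        mrna_id = fid[m],
        neighborhood_id = mcols(neighborhoods)$name[nb_of[e]],
        tss_distance_bp = d, rho = rho, direction = ifelse(Mamp > 0, "up", "down"))
    }
  }
  truth_pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(pair_id = character(0), erna_id = character(0),
               mrna_id = character(0), neighborhood_id = character(0),
               tss_distance_bp = numeric(0), rho = numeric(0),
               direction = character(0))

  ## enhancer states: one per planted eRNA (covering TSS +/- flank) plus
  ## decoys placed away from any ncRNA/eRNA
  er <- features[cls == "eRNA"]
  er_tss <- tss_position(er)
  states <- GenomicRanges::GRanges(seqnames(er),
              IRanges::IRanges(pmax(er_tss - 800L, 1L), er_tss + 200L))
  nc_all <- features[cls %in% c("ncRNA", "eRNA")]
  avoid <- suppressWarnings(trim(resize(nc_all, width(nc_all) + 6000,
                                        fix = "center")))
  decoys <- list()
  tries <- 0
  while (length(decoys) < config$n_decoy_states && tries < 2000) {
    tries <- tries + 1
    chrom <- sample(names(genome), 1)
    st <- round(runif(1, 1, genome[[chrom]] - 1000))
    g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, st + 999))
    if (!any(suppressWarnings(overlapsAny(g, avoid, ignore.strand = TRUE))))
      decoys[[length(decoys) + 1]] <- g
  }
  if (length(decoys))
    states <- suppressWarnings(c(states, do.call(c, unname(decoys))))
  states <- sort(states, ignore.strand = TRUE)
  mcols(states)$name <- sprintf("ES%03d", seq_along(states))
  strand(states) <- "*"

  ## reference annotation from planted mRNA/lincRNA (single-isoform,
  ## single-exon genes)
  ann_genes <- features[cls %in% c("mRNA", "lincRNA")]
  genes <- GenomicRanges::GRanges(seqnames(ann_genes),
             IRanges::IRanges(start(ann_genes), end(ann_genes)),
             strand = strand(ann_genes))
  mcols(genes)$gene_id <- mcols(ann_genes)$feature_id
  mcols(genes)$gene_biotype <- ifelse(mcols(ann_genes)$class == "mRNA",
                                      "protein_coding", "lincRNA")
  exons <- genes
  mcols(exons)$transcript_id <- paste0(mcols(genes)$gene_id, ".1")
  mcols(exons)$gene_biotype <- NULL
  annotation <- tx_annotation(genes, exons)

  design <- list(time_points = tp, replicates = config$replicates,
                 t_label = config$t_label)
  truth <- list(
    kinetics = data.frame(feature_id = fid, class = cls,
                          half_life_min = hl, lambda_per_min = lambda,
                          amount0 = A0, mu0_per_min = mu0,
                          responsive = resp, stringsAsFactors = FALSE),
    f = f, pairs = truth_pairs, antisense_c = config$antisense_c)
  structure(list(genome = genome, features = features,
                 annotation = annotation, enhancer_states = states,
                 neighborhoods = neighborhoods, truth = truth,
                 design = design, config = config, seed = seed),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat(sprintf(
    "sim_world: %d chrom (%.1f Mb), %d transcripts (%s), %d neighborhoods, %d pairs\n",
    length(x$genome), sum(x$genome) / 1e6, length(x$features),
    paste(names(table(mcols(x$features)$class)),
          table(mcols(x$features)$class), collapse = " ", sep = ":"),
    length(x$neighborhoods), nrow(x$truth$pairs)))
  invisible(x)
}

## labeled/unlabeled amounts per feature and time point under first-order
## kinetics with piecewise-constant synthesis per labeling interval
true_amounts <- function(world) {
  tp <- world$design$time_points
  tl <- world$design$t_label
  kin <- world$truth$kinetics
  f <- world$truth$f
  n <- nrow(kin)
  alpha <- beta <- matrix(0, n, length(tp),
                          dimnames = list(kin$feature_id, tp))
  A <- kin$amount0
  for (k in seq_along(tp)) {
    mu_k <- kin$mu0_per_min * f[, k]
    if (k > 1) {
      dt <- tp[k] - tp[k - 1]
      A <- mu_k / kin$lambda_per_min +
        (A - mu_k / kin$lambda_per_min) * exp(-kin$lambda_per_min * dt)
    }
    alpha[, k] <- mu_k / kin$lambda_per_min *
      (1 - exp(-kin$lambda_per_min * tl))
    beta[, k] <- pmax(A - alpha[, k], 0)
  }
  list(alpha = alpha, beta = beta)
}

#' Simulate observations (tracks, counts, spike-ins) for a world
#'
#' Expected feature count in sample j is L_i * (sigma_j * alpha_ij +
#' epsilon_j * beta_ij); counts are drawn Poisson (or taken as the exact
#' expectation with `noise = "none"`), spread uniformly over the
#' feature's bins to build strand-specific coverage tracks, background
#' noise is added per bin, and the antisense bleed mixes the two strands
#' of the observed tracks with rate c.  The returned count matrix holds
#' the feature-attributed (bleed-free, background-free) counts, i.e. what
#' a perfect antisense correction would recover.
#'
#' @param world `sim_world`.
#' @param seed RNG seed.
#' @param noise "poisson" or "none".
#' @param tracks_for assays for which coverage tracks are materialized.
#' @return list(tracks, counts (`count_matrix`), spikeins
#'   (`spikein_table`), calibration_truth, samples).
#' @export
simulate_counts <- function(world, seed = 1L, noise = c("poisson", "none"),
                            tracks_for = "TT") {
  noise <- match.arg(noise)
  cfg <- world$config
  if (world$design$t_label <= 0) stop("labeling duration must be positive")
  set.seed(seed + 1000L)
  tp <- world$design$time_points
  reps <- world$design$replicates
  samples <- expand.grid(replicate = seq_len(reps), time = tp,
                         assay = c("TT", "RNA"), stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_t%02d_r%d", samples$assay,
                               samples$time, samples$replicate)
  ns <- nrow(samples)
  jit <- function(base) base * exp(runif(ns, -cfg$sample_depth_jitter,
                                         cfg$sample_depth_jitter))
  sigma <- ifelse(samples$assay == "TT", jit(cfg$sigma_tt),
                  jit(cfg$depth_rna))
  eps <- ifelse(samples$assay == "TT", jit(cfg$eps_tt), sigma)
  cal_truth <- data.frame(samples, sigma = sigma, epsilon = eps)

  am <- true_amounts(world)
  feats <- world$features
  L <- width(feats)
  n <- length(feats)
  expected <- matrix(0, n, ns,
                     dimnames = list(mcols(feats)$feature_id,
                                     samples$sample_id))
  for (j in seq_len(ns)) {
    k <- match(samples$time[j], tp)
    expected[, j] <- L * (sigma[j] * am$alpha[, k] + eps[j] * am$beta[, k])
  }
  counts <- if (noise == "poisson")
    matrix(rpois(n * ns, expected), n, ns, dimnames = dimnames(expected))
  else expected

  ## spike-ins
  nsp <- cfg$n_spike_labeled + cfg$n_spike_unlabeled
  sp_len <- round(runif_range(nsp, cfg$spike_len))
  sp_lab <- rep(c(TRUE, FALSE), c(cfg$n_spike_labeled,
                                  cfg$n_spike_unlabeled))
  sp_expected <- matrix(0, nsp, ns)
  for (j in seq_len(ns))
    sp_expected[, j] <- sp_len * ifelse(sp_lab, sigma[j], eps[j])
  sp_counts <- if (noise == "poisson")
    matrix(rpois(nsp * ns, sp_expected), nsp, ns) else sp_expected
  colnames(sp_counts) <- samples$sample_id
  spikeins <- spikein_table(sprintf("spike_%s_%02d",
                                    ifelse(sp_lab, "L", "U"), seq_len(nsp)),
                            sp_len, sp_lab, sp_counts, samples)

  ## coverage tracks for the requested assays
  bs <- cfg$bin_size
  chr <- as.character(seqnames(feats))
  str <- as.character(strand(feats))
  track_idx <- which(samples$assay %in% tracks_for)
  tracks <- list()
  for (j in track_idx) {
    tr <- coverage_track(world$genome, bs, samples$sample_id[j])
    for (i in seq_len(n)) {
      v <- tr$bins[[chr[i]]][[str[i]]]
      b0 <- (start(feats)[i] - 1L) %/% bs
      b1 <- (end(feats)[i] - 1L) %/% bs
      bins <- (b0:b1) + 1L
      ov <- pmin(end(feats)[i], (b0:b1 + 1) * bs) -
        pmax(start(feats)[i] - 1L, (b0:b1) * bs)
      if (noise == "poisson") {
        ## spread the realized count multinomially by overlap width
        if (counts[i, j] > 0)
          v[bins] <- v[bins] +
            as.numeric(rmultinom(1, counts[i, j], ov / sum(ov)))
      } else {
        v[bins] <- v[bins] + expected[i, j] * ov / sum(ov)
      }
      tr$bins[[chr[i]]][[str[i]]] <- v
    }
    if (cfg$bg_per_bin > 0 && noise == "poisson") {
      for (chrom in names(tr$bins)) for (s in c("+", "-")) {
        nb <- length(tr$bins[[chrom]][[s]])
        tr$bins[[chrom]][[s]] <- tr$bins[[chrom]][[s]] +
          rpois(nb, cfg$bg_per_bin)
      }
    }
    ## antisense bleed: obs_s = real_s + c * real_a
    c_bleed <- world$truth$antisense_c
    if (c_bleed > 0) {
      for (chrom in names(tr$bins)) {
        p <- tr$bins[[chrom]][["+"]]; m <- tr$bins[[chrom]][["-"]]
        tr$bins[[chrom]][["+"]] <- p + c_bleed * m
        tr$bins[[chrom]][["-"]] <- m + c_bleed * p
      }
    }
    tracks[[samples$sample_id[j]]] <- tr
  }

  cm <- count_matrix(counts, L, samples)
  list(tracks = tracks, counts = cm, spikeins = spikeins,
       calibration_truth = cal_truth, samples = samples,
       expected = expected, amounts = am)
}

#' Simulate promoter-window sequences with planted motifs
#'
#' Generates uniform-background sequences for the positive set (planted
#' eRNA upstream windows) and negative set (other ncRNA upstream
#' windows); with probability `plant_rate_pos` (resp. `_neg`) a sequence
#' receives one exact consensus occurrence of the motif at a random
#' offset.  A uniform background can still contain chance hits
#' (probability about len * (1/4)^w per strand).
#'
#' @param world `sim_world`.
#' @param pwm_obj a [pwm()]; its consensus string is planted.
#' @param plant_rate_pos,plant_rate_neg planting probabilities in [0, 1].
#' @param seed RNG seed.
#' @param seq_len window length (bp), must be >= motif width.
#' @return list(pos, neg): named character vectors; attribute `planted`
#'   holds the per-sequence planting truth.
#' @export
simulate_sequences <- function(world, pwm_obj, plant_rate_pos = 0.4,
                               plant_rate_neg = 0.05, seed = 1L,
                               seq_len = 250L) {
  if (plant_rate_pos < 0 || plant_rate_pos > 1 ||
      plant_rate_neg < 0 || plant_rate_neg > 1)
    stop("plant rates must lie in [0, 1]")
  w <- pwm_obj$width
  if (seq_len < w) stop("sequence window shorter than the motif")
  set.seed(seed + 2000L)
  cls <- mcols(world$features)$class
  fid <- mcols(world$features)$feature_id
  gen <- function(ids, rate) {
    planted <- runif(length(ids)) < rate
    seqs <- vapply(seq_along(ids), function(i) {
      s <- paste(sample(BASES, seq_len, replace = TRUE), collapse = "")
      if (planted[i]) {
        at <- sample.int(seq_len - w + 1L, 1)
        substr(s, at, at + w - 1L) <- pwm_obj$consensus
      }
      s
    }, character(1))
    names(seqs) <- ids
    attr(seqs, "planted") <- planted
    seqs
  }
  list(pos = gen(fid[cls == "eRNA"], plant_rate_pos),
       neg = gen(fid[cls == "ncRNA"], plant_rate_neg))
}
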