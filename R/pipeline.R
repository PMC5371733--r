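## End-to-end orchestration: simulate -> correct -> segment -> kinetics ->
## diffexpr -> pair -> motifs, with stage outputs written to a run
## directory and a machine-readable summary.

#' Default pipeline configuration
#'
#' @param out_dir run directory.
#' @param seed master seed.
#' @param ... overrides; `sim` may hold [sim_config()] overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("ttseqr_run_"), seed = 1L,
                            ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed, simulate = TRUE,
    bin_size = 200, pseudo_count = 1, min_sense = 100,
    rpk_candidates = c(0.5, 1, 2, 4, 8, 16, 32, 64),
    t_label = 5, fc_cutoff = 2, padj_cutoff = 0.05,
    exclusion = 1000, proximal = 10000, mrna_prefix = 2200,
    n_perm = 1000, motif_frac = 0.8,
    max_iter = 15,
    sim = list())
  ov <- list(...)
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

#' Parse a key = value pipeline config file
#'
#' Lines of the form `key = value`; values are parsed as numbers when
#' possible, comma-separated values become vectors, `true`/`false`
#' become logicals.  Keys prefixed `sim.` populate the simulation
#' sub-config.
#'
#' @param path config file path.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  cfg <- pipeline_config()
  for (l in lines) {
    kv <- strsplit(l, "\\s*=\\s*")[[1]]
    key <- kv[1]; raw <- kv[2]
    parts <- trimws(strsplit(raw, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    val <- if (!any(is.na(num))) num
           else if (all(tolower(parts) %in% c("true", "false")))
             tolower(parts) == "true"
           else parts
    if (startsWith(key, "sim.")) cfg$sim[[sub("^sim\\.", "", key)]] <- val
    else cfg[[key]] <- val
  }
  cfg
}

#' Run the pipeline end-to-end on a synthetic world
#'
#' Executes simulate, antisense correction, segmentation/classification,
#' kinetics, differential testing, enhancer-promoter pairing and motif
#' enrichment; writes per-stage TSV/BED outputs plus a summary JSON to
#' the run directory.  Identical config and seed give identical outputs.
#'
#' @param config `pipeline_config`.
#' @param until last stage to execute; earlier stages always run since
#'   later ones consume their in-memory outputs.
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         until = c("motifs", "simulate", "correct",
                                   "segment", "kinetics", "diffexpr",
                                   "pair")) {
  until <- match.arg(until)
  chain <- c("simulate", "correct", "segment", "kinetics", "diffexpr",
             "pair", "motifs")
  last <- match(until, chain)
  enabled <- function(stage) match(stage, chain) <= last
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(name)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  cfg_digest <- paste0("cfg", sum(utf8ToInt(paste(
    deparse(config[order(names(config))]), collapse = ""))))

  log_stage("simulate")
  world <- do.call(sim_config, config$sim)
  world <- simulate_world(world, seed = config$seed)
  obs <- simulate_counts(world, seed = config$seed)
  write_gtf(world$annotation, file.path(config$out_dir, "reference.gtf"))
  write_bed(world$enhancer_states,
            file.path(config$out_dir, "enhancer_states.bed"))
  write_bed(world$neighborhoods,
            file.path(config$out_dir, "neighborhoods.bed"))
  write_count_matrix(obs$counts, file.path(config$out_dir, "counts.tsv"))
  write_spikeins(obs$spikeins, file.path(config$out_dir, "spikeins.tsv"))
  for (sid in names(obs$tracks)) {
    write_bedgraph(obs$tracks[[sid]], "+",
                   file.path(config$out_dir, paste0(sid, ".plus.bedgraph")))
    write_bedgraph(obs$tracks[[sid]], "-",
                   file.path(config$out_dir, paste0(sid, ".minus.bedgraph")))
  }
  jsonlite::write_json(world$truth$pairs,
                       file.path(config$out_dir, "truth_pairs.json"))
  if (until == "simulate")
    return(invisible(list(world = world, obs = obs)))

  log_stage("correct")
  c_hat <- vapply(obs$tracks, function(tr)
    estimate_antisense_bias(tr, world$annotation,
                            min_sense = config$min_sense)$c, numeric(1))
  corrected <- mapply(correct_track, obs$tracks, c_hat, SIMPLIFY = FALSE)
  write.table(data.frame(sample_id = names(c_hat), c_hat = c_hat),
              file.path(config$out_dir, "antisense_bias.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (until == "correct")
    return(invisible(list(world = world, obs = obs, c_hat = c_hat,
                          corrected = corrected)))

  log_stage("segment")
  seg <- segment_genome(corrected, pseudo_count = config$pseudo_count,
                        rpk_candidates = config$rpk_candidates,
                        reference = world$annotation$genes,
                        max_iter = config$max_iter)
  tus <- classify_tus(seg$tus, world$annotation)
  tus <- classify_ernas(tus, world$enhancer_states)
  tu_df <- data.frame(tu_id = mcols(tus)$tu_id,
                      chrom = as.character(seqnames(tus)),
                      start = start(tus) - 1L, end = end(tus),
                      strand = as.character(strand(tus)),
                      class = mcols(tus)$class,
                      gene_id = mcols(tus)$gene_id,
                      rpk = mcols(tus)$rpk,
                      readthrough = mcols(tus)$readthrough)
  write.table(tu_df, file.path(config$out_dir, "transcription_units.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (until == "segment")
    return(invisible(list(world = world, obs = obs, c_hat = c_hat,
                          segmentation = seg, tus = tus)))

  log_stage("kinetics")
  cal <- calibrate(obs$spikeins)
  kin <- estimate_kinetics(obs$counts, cal, t = config$t_label)
  write.table(kin, file.path(config$out_dir, "kinetics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (until == "kinetics")
    return(invisible(list(world = world, obs = obs, kinetics = kin)))

  log_stage("diffexpr")
  pc_ids <- mcols(world$annotation$genes)$gene_id[
    mcols(world$annotation$genes)$gene_biotype == "protein_coding"]
  tt <- obs$counts$samples$assay == "TT"
  sf_all <- rep(NA_real_, nrow(obs$counts$samples))
  sf_all[tt] <- size_factors(
    count_matrix(obs$counts$counts[, tt, drop = FALSE],
                 obs$counts$lengths,
                 obs$counts$samples[tt, ]), pc_ids)
  de <- test_differential(obs$counts, ifelse(is.na(sf_all), 1, sf_all))
  de <- classify_changes(de, config$fc_cutoff, config$padj_cutoff)
  write.table(de, file.path(config$out_dir, "differential.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (until == "diffexpr")
    return(invisible(list(world = world, obs = obs, de = de)))

  log_stage("pair")
  feats <- world$features
  mcols(feats)$tu_id <- mcols(feats)$feature_id
  ernas <- feats[mcols(feats)$class == "eRNA"]
  mrnas <- feats[mcols(feats)$class == "mRNA"]
  pairs <- pair_within_neighborhoods(ernas, mrnas, world$neighborhoods,
                                     exclusion = config$exclusion,
                                     proximal_cut = config$proximal)
  cm_tt <- count_matrix(obs$counts$counts[, tt, drop = FALSE],
                        obs$counts$lengths, obs$counts$samples[tt, ])
  prof <- timepoint_profile(cm_tt, sf_all[tt])
  pairs <- pair_correlations(pairs, prof)
  perm <- permutation_test(pairs, prof,
                           erna_pool = mcols(ernas)$tu_id,
                           mrna_pool = mcols(mrnas)$tu_id,
                           n_perm = config$n_perm, seed = config$seed)
  write.table(pairs, file.path(config$out_dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (until == "pair")
    return(invisible(list(world = world, obs = obs, pairs = pairs,
                          perm = perm)))

  log_stage("motifs")
  ap1 <- pwm_from_consensus("TGACTCA", id = "AP1")
  seqs <- simulate_sequences(world, ap1, seed = config$seed)
  enr <- motif_enrichment(list(AP1 = ap1), seqs$pos, seqs$neg,
                          frac = config$motif_frac)
  write.table(enr, file.path(config$out_dir, "motif_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    config_digest = cfg_digest, seed = config$seed,
    n_features = length(world$features),
    antisense_c_hat = as.list(c_hat),
    rpk_threshold = seg$threshold,
    n_tus = length(tus),
    n_pairs = nrow(pairs),
    permutation_p = perm$p_value,
    motif_or = enr$odds_ratio[1],
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(world = world, obs = obs, c_hat = c_hat,
                 corrected = corrected, segmentation = seg, tus = tus,
                 kinetics = kin, de = de, pairs = pairs, perm = perm,
                 enrichment = enr, summary = summary))
}
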