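## File readers/writers for the plain-text interchange formats used across
## the pipeline.  Coordinates: GTF is 1-based closed, BED/bedGraph 0-based
## half-open; everything is converted to GRanges (1-based closed) on read.

#' Build a genome description
#'
#' @param lengths named integer vector, chromosome name -> length in bp.
#' @return named integer vector (validated).
#' @export
genome_info <- function(lengths) {
  if (is.null(names(lengths)) || any(names(lengths) == ""))
    stop("genome lengths must be named by chromosome")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  storage.mode(lengths) <- "integer"
  lengths
}

#' Read a BED6 file as GRanges
#'
#' @param path file path.
#' @param genome optional named lengths vector for validation.
#' @return GRanges with `name` and `score` columns when present.
#' @export
read_bed <- function(path, genome = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand")[seq_len(max(3, ncol(read.table(path, sep = "\t", nrows = 1))))],
                   stringsAsFactors = FALSE)
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = strand)
  if ("name" %in% names(df)) mcols(gr)$name <- df$name
  if ("score" %in% names(df)) mcols(gr)$score <- df$score
  if (!is.null(genome)) seqlengths(gr) <- genome[seqlevels(gr)]
  gr
}

#' Write GRanges to BED6
#'
#' @param gr GRanges; the `name` column is used when present.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    if (!is.null(names(gr)) && length(names(gr))) names(gr) else
      paste0("feature_", seq_along(gr))
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr), name = nm,
                   score = sc, strand = as.character(strand(gr)))
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a strand of a coverage track as bedGraph
#'
#' Zero-run compression: consecutive equal-valued bins are merged.
#'
#' @param track a `coverage_track`.
#' @param strand "+" or "-".
#' @param path output path.
#' @export
write_bedgraph <- function(track, strand, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (chrom in names(track$bins)) {
    v <- track$bins[[chrom]][[strand]]
    n <- length(v)
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0L, head(ends_bin, -1L))
    keep <- r$values != 0
    if (!any(keep)) next
    starts <- starts_bin[keep] * bs
    ends <- pmin(ends_bin[keep] * bs, track$genome[[chrom]])
    writeLines(paste(chrom, starts, ends, r$values[keep], sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track strand
#'
#' @param path bedGraph path.
#' @param genome named chromosome lengths.
#' @param bin_size bin width used to produce the file.
#' @return list chrom -> numeric bin vector.
#' @export
read_bedgraph <- function(path, genome, bin_size = 200L) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  out <- lapply(names(genome), function(chrom) {
    nb <- ceiling(genome[[chrom]] / bin_size)
    v <- numeric(nb)
    d <- df[df$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      b0 <- d$start[i] %/% bin_size
      b1 <- (d$end[i] - 1L) %/% bin_size
      v[(b0 + 1L):(b1 + 1L)] <- d$value[i]
    }
    v
  })
  setNames(out, names(genome))
}

#' Reference annotation container
#'
#' @param genes GRanges with `gene_id` and `gene_biotype` metadata columns.
#' @param exons GRanges with `gene_id` and `transcript_id` columns.
#' @return object of class `tx_annotation`.
#' @export
tx_annotation <- function(genes, exons) {
  stopifnot(!is.null(mcols(genes)$gene_id),
            !is.null(mcols(genes)$gene_biotype),
            !is.null(mcols(exons)$gene_id),
            !is.null(mcols(exons)$transcript_id))
  structure(list(genes = genes, exons = exons), class = "tx_annotation")
}

#' Read a GTF with gene and exon records into a tx_annotation
#'
#' Minimal GTF reader for the subset this pipeline writes and consumes:
#' `gene` and `exon` features with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes.
#'
#' @param path GTF path.
#' @return `tx_annotation`.
#' @export
read_gtf <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   quote = "", stringsAsFactors = FALSE,
                   col.names = c("chrom", "source", "feature", "start",
                                 "end", "score", "strand", "frame", "attr"))
  attr_val <- function(attr, key) {
    pat <- paste0(key, ' "([^"]*)"')
    m <- regexpr(pat, attr)
    out <- rep(NA_character_, length(attr))
    out[m > 0] <- sub(pat, "\\1", regmatches(attr, m))
    out
  }
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  mcols(gr)$gene_id <- attr_val(df$attr, "gene_id")
  mcols(gr)$gene_biotype <- attr_val(df$attr, "gene_biotype")
  mcols(gr)$transcript_id <- attr_val(df$attr, "transcript_id")
  genes <- gr[df$feature == "gene"]
  exons <- gr[df$feature == "exon"]
  mcols(genes)$transcript_id <- NULL
  tx_annotation(genes, exons)
}

#' Write a tx_annotation as GTF
#'
#' @param ann `tx_annotation`.
#' @param path output path.
#' @export
write_gtf <- function(ann, path) {
  fmt <- function(gr, feature, attrs) {
    paste(as.character(seqnames(gr)), "ttseqr", feature, start(gr), end(gr),
          ".", as.character(strand(gr)), ".", attrs, sep = "\t")
  }
  g <- ann$genes
  ga <- sprintf('gene_id "%s"; gene_biotype "%s";',
                mcols(g)$gene_id, mcols(g)$gene_biotype)
  e <- ann$exons
  bt <- mcols(g)$gene_biotype[match(mcols(e)$gene_id, mcols(g)$gene_id)]
  ea <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                mcols(e)$gene_id, mcols(e)$transcript_id, bt)
  writeLines(c(fmt(g, "gene", ga), fmt(e, "exon", ea)), path)
  invisible(path)
}

#' Read a JASPAR-style PFM file
#'
#' Accepts the 4-line raw count format, with or without the
#' `A [ ... ]` bracket decoration, one or more motifs per file, each
#' introduced by a `>id name` header line.
#'
#' @param path PFM text path.
#' @return named list of PWM objects (see [pwm()]).
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) { hdr <- 0; lines <- c(">motif", lines) ; hdr <- 1 }
  bounds <- c(hdr, length(lines) + 1L)
  out <- list()
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    id <- strsplit(sub("^>\\s*", "", lines[bounds[i]]), "\\s+")[[1]][1]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[id]] <- pwm(counts, id = id)
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or DNAStringSet.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read FASTA sequences as a named character vector
#'
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read/write TSV count matrices
#'
#' Layout: feature_id, length_bp, then one column per sample.
#' @param cm a `count_matrix`.
#' @param path output path.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts),
                   length_bp = cm$lengths, cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- paste0(path, ".samples")
  write.table(cm$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @param samples optional sample metadata data.frame; if missing, the
#'   side-car `<path>.samples` file is read.
#' @export
read_count_matrix <- function(path, samples = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$feature_id
  if (is.null(samples)) {
    sp <- paste0(path, ".samples")
    if (file.exists(sp))
      samples <- read.table(sp, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  }
  count_matrix(counts, df$length_bp, samples)
}
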