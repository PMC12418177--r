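# File formats. Coordinates are 1-based inclusive SNP positions (ASCAT-style
# segment convention). All writers emit deterministic bytes for fixed input:
# numbers are formatted to 6 significant digits.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Read a per-SNP observation track
#'
#' Accepts a TSV with header and columns `chrom`, `pos` plus either `reads`
#' (and optionally `baf`, `logr`) or allele counts `ref_count`/`alt_count`,
#' from which `reads = ref_count + alt_count` and
#' `baf = alt_count / reads` (`NA` when `reads = 0`) are derived. Rows must
#' be sorted with strictly increasing positions within each chromosome.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"reads"` or `"counts"`.
#' @return An observation track data.frame (`chrom`, `pos`, `reads`, `baf`,
#'   optionally `logr`).
#' @export
read_snp_track <- function(path, dialect = c("auto", "reads", "counts")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos")
  if (!all(need %in% names(df)))
    stop("SNP track must have 'chrom' and 'pos' columns")
  has_counts <- all(c("ref_count", "alt_count") %in% names(df))
  if (dialect == "auto") dialect <- if (has_counts) "counts" else "reads"
  if (dialect == "counts") {
    if (!has_counts) stop("counts dialect requires ref_count/alt_count")
    bad <- which(df$ref_count < 0 | df$alt_count < 0)
    if (length(bad))
      stop(sprintf("negative allele count at line %d", bad[1] + 1L))
    reads <- df$ref_count + df$alt_count
    baf <- ifelse(reads > 0, df$alt_count / reads, NA_real_)
    df$reads <- reads
    df$baf <- baf
  } else {
    if (is.null(df$reads)) stop("reads dialect requires a 'reads' column")
    bad <- which(df$reads < 0)
    if (length(bad)) stop(sprintf("negative reads at line %d", bad[1] + 1L))
    if (is.null(df$baf)) df$baf <- NA_real_
  }
  bad <- which(!is.na(df$baf) & (df$baf < 0 | df$baf > 1))
  if (length(bad))
    stop(sprintf("BAF outside [0, 1] at line %d", bad[1] + 1L))
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0)) {
      off <- which(df$chrom == ch)[which(diff(p) <= 0)[1] + 1L]
      stop(sprintf("positions not strictly increasing at line %d", off + 1L))
    }
  }
  keep <- c("chrom", "pos", "reads", "baf",
            intersect("logr", names(df)))
  df[, keep]
}

#' Write a per-SNP observation track
#'
#' @param obs Observation track data.frame.
#' @param path Output TSV path.
#' @export
write_snp_track <- function(obs, path) {
  out <- obs
  out$reads <- fmt_num(out$reads)
  out$baf <- fmt_num(out$baf)
  if (!is.null(out$logr)) out$logr <- fmt_num(out$logr)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write call outputs: segments, per-locus calls and summary
#'
#' Emits `<prefix>.segments.tsv` (chrom, start_pos, end_pos, n_loci,
#' major_cn, minor_cn, total_cn), `<prefix>.calls.tsv` (chrom, pos,
#' major_cn, minor_cn, p_max) and `<prefix>.summary.json` (purity,
#' tumour_ploidy, sample_ploidy, rd_estimate, wgd, lambda_t,
#' model_checkpoint_id, format_version).
#'
#' @param result A `call_result`.
#' @param obs The observation track the call was made on.
#' @param prefix Output path prefix.
#' @param checkpoint_id Identifier recorded in the summary.
#' @return Invisibly, the three file paths.
#' @export
write_outputs <- function(result, obs, prefix, checkpoint_id = "unknown") {
  stopifnot(inherits(result, "call_result"))
  seg_path <- paste0(prefix, ".segments.tsv")
  call_path <- paste0(prefix, ".calls.tsv")
  sum_path <- paste0(prefix, ".summary.json")
  write.table(result$segments, seg_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cal <- data.frame(
    chrom = obs$chrom, pos = obs$pos,
    major_cn = result$catalog$profiles$a_major[result$states],
    minor_cn = result$catalog$profiles$a_minor[result$states],
    p_max = fmt_num(apply(result$class_probs, 1L, max))
  )
  write.table(cal, call_path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    purity = signif(result$purity, 6),
    tumour_ploidy = signif(result$ploidy, 6),
    sample_ploidy = signif(result$sample_ploidy, 6),
    rd_estimate = if (is.na(result$rd_estimate)) NULL else
      signif(result$rd_estimate, 6),
    wgd = result$wgd,
    lambda_t = result$lambda_t,
    model_checkpoint_id = checkpoint_id,
    format_version = 1L
  )
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(segments = seg_path, calls = call_path, summary = sum_path))
}

#' Read a segment file
#'
#' @param path Segment TSV path.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start_pos", "end_pos", "major_cn", "minor_cn")
  if (!all(need %in% names(df))) stop("malformed segment file")
  if (!is.null(df$total_cn) &&
      any(df$total_cn != df$major_cn + df$minor_cn))
    stop("total_cn must equal major_cn + minor_cn")
  df
}

#' Save a model checkpoint
#'
#' A single serialised file holding the format version, configuration,
#' catalogue ordering, mode and parameters; round-trips bit-identically.
#'
#' @param model An `aracna_model`.
#' @param path Output path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "aracna_model"))
  saveRDS(list(format_version = 1L, config = model$config,
               catalog = model$catalog, mode = model$mode,
               par = model$par), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path from [save_checkpoint()].
#' @return An `aracna_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  x <- readRDS(path)
  if (!is.list(x) || is.null(x$format_version) || x$format_version != 1L)
    stop("invalid checkpoint: unknown format version")
  structure(list(config = x$config, catalog = x$catalog, par = x$par,
                 mode = x$mode),
            class = "aracna_model")
}

#' Write simulated genome files
#'
#' Writes the observation TSV, ground-truth TSV and parameter JSON for a
#' simulated genome.
#'
#' @param genome A `simulated_genome`.
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths.
#' @export
write_genome_files <- function(genome, prefix) {
  obs_path <- paste0(prefix, ".obs.tsv")
  truth_path <- paste0(prefix, ".truth.tsv")
  par_path <- paste0(prefix, ".params.json")
  write_snp_track(genome$observations, obs_path)
  truth <- cbind(genome$observations[, c("chrom", "pos")], genome$truth)
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  par <- list(rho = signif(genome$params$rho, 6),
              r_d = signif(genome$params$r_d, 6),
              r_d_normal = if (is.null(genome$params$r_d_normal)) NULL else
                signif(genome$params$r_d_normal, 6),
              n_segments = nrow(genome$segments),
              n_ibd_regions = nrow(genome$ibd_regions),
              seed = genome$config$seed)
  jsonlite::write_json(par, par_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(obs = obs_path, truth = truth_path, params = par_path))
}
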