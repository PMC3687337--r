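# Synthetic-experiment generator with known ground truth. Emulates the
# structure the pipeline assumes: two peak catalogs whose common peaks share
# a latent linear M-on-A scaling with additive log2 noise, a differential
# subset with shifted M placed in promoter/distal windows of designated
# target genes, reads consistent with the per-region counts, a signature
# enriched for KO-target genes, and replicate log2 expression upregulated at
# KO-target genes. Everything is deterministic under the seed.

#' Simulation parameters
#'
#' Defaults describe the reference synthetic scenario used throughout the
#' package's validation: 1000 genes on a 50 Mb chromosome, 2000 common peaks
#' plus 200 KO- and 200 wt-differential peaks following the scaling law
#' `M = c0 + c1 * A` (c0 = 0.4, c1 = 0.1) with log2 noise sd 0.3 and a
#' differential shift of +/- 2.5 log2 units; a 150-gene signature drawn with
#' 8-fold odds for KO-target genes; expression with 4 replicates per
#' condition, +1 log2 effect at KO-target genes and residual sd 0.3.
#'
#' @param seed Integer master seed.
#' @param n_genes,chrom_length Annotation size; needs
#'   `n_genes * 30000 <= chrom_length`.
#' @param n_common,n_diff_ko,n_diff_wt Peak counts.
#' @param c0,c1 True intercept/slope of the latent M-on-A scaling.
#' @param noise_sd Log2 noise sd on raw M.
#' @param delta_m Differential shift (log2) applied to the KO side.
#' @param signature_size,rho Signature size and odds multiplier for drawing
#'   KO-target genes.
#' @param beta Log2 upregulation of KO-target genes in expression.
#' @param n_reps Replicates per condition.
#' @param expr_sd Residual expression sd (log2).
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(seed = 20130618L, n_genes = 1000L,
                       chrom_length = 5e7, n_common = 2000L,
                       n_diff_ko = 200L, n_diff_wt = 200L, c0 = 0.4,
                       c1 = 0.1, noise_sd = 0.3, delta_m = 2.5,
                       signature_size = 150L, rho = 8, beta = 1.0,
                       n_reps = 4L, expr_sd = 0.3) {
  p <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
            chrom_length = chrom_length, n_common = as.integer(n_common),
            n_diff_ko = as.integer(n_diff_ko),
            n_diff_wt = as.integer(n_diff_wt), c0 = c0, c1 = c1,
            noise_sd = noise_sd, delta_m = delta_m,
            signature_size = as.integer(signature_size), rho = rho,
            beta = beta, n_reps = as.integer(n_reps), expr_sd = expr_sd)
  counts <- c(p$n_genes, p$n_common, p$n_diff_ko, p$n_diff_wt,
              p$signature_size, p$n_reps)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (p$noise_sd < 0 || p$expr_sd < 0) stop("noise sds must be >= 0")
  if (p$delta_m == 0) stop("delta_m must be non-zero")
  if (p$rho < 1) stop("rho must be >= 1")
  if (p$n_genes * 30000 > p$chrom_length) {
    stop("infeasible gene spacing: need n_genes * 30 kb <= chrom_length")
  }
  if (p$n_diff_ko + p$n_diff_wt > p$n_genes) {
    stop("more differential peaks than genes to target")
  }
  if (p$signature_size > p$n_genes) stop("signature_size > n_genes")
  class(p) <- "sim_params"
  p
}

#' Generate a toy gene annotation
#'
#' `n_genes` non-overlapping genes with random strand and 2-5 exons, one per
#' uniformly spaced slot along a single chromosome, placed so that each
#' gene's full promoter footprint (10 kb upstream of the TSS) stays inside
#' its slot. Symbols are `G0001`, `G0002`, ...
#'
#' @param params A [sim_params()] list.
#' @param seed Optional seed (defaults to the params seed).
#' @return A [gene_annotation()].
#' @export
generate_annotation <- function(params = sim_params(), seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_genes
  slot <- floor(params$chrom_length / n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  body_len <- sample(5000:15000, n, replace = TRUE)
  slot_start <- (seq_len(n) - 1) * slot
  # 11 kb margin on the upstream side of the TSS keeps the distal window
  # inside the slot
  tx_start <- ifelse(strand == "+", slot_start + 11000,
                     slot_start + slot - 11000 - body_len)
  tx_end <- tx_start + body_len
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(2:5, 1L)
    # 2k-2 interior breakpoints -> alternating exon/intron segments that
    # start and end with an exon
    bp <- sort(sample(seq(tx_start[i] + 1, tx_end[i] - 1), 2L * k - 2L))
    bounds <- c(tx_start[i], bp, tx_end[i])
    exon_starts[[i]] <- bounds[seq(1L, 2L * k - 1L, by = 2L)]
    exon_ends[[i]] <- bounds[seq(2L, 2L * k, by = 2L)]
  }
  gene_annotation(name = sprintf("G%04d", seq_len(n)), chrom = "chrS",
                  strand = strand, tx_start = tx_start, tx_end = tx_end,
                  exon_starts = exon_starts, exon_ends = exon_ends)
}

#' Generate a paired peak experiment with known scaling and truth labels
#'
#' Common peaks: `A ~ Uniform(4, 12)`, wt log2 density
#' `A - (c0 + c1 A)/2 - eps/2` and KO log2 density `A + (c0 + c1 A)/2 +
#' eps/2` with `eps ~ Normal(0, noise_sd)`, so the raw M follows
#' `c0 + c1 A + eps` while A is noise-free. Differential peaks additionally
#' shift the KO side by `+delta_m` (KO-specific, present only in the KO
#' catalog) or `-delta_m` (wt-specific, wt catalog only) and are placed in
#' the proximal-promoter or distal-promoter window of a designated target
#' gene. Counts are `round(density * length / 1000)` per region for both
#' samples.
#'
#' @param params A [sim_params()] list.
#' @param annotation A [gene_annotation()] from [generate_annotation()].
#' @param seed Optional seed (defaults to the params seed).
#' @return List: `ko`/`wt` ([peak_set()] catalogs), `counts` (per union
#'   region: chrom, start, end, count_ko, count_wt), `truth` (list with
#'   `region` data frame carrying labels and latent values, and gene-label
#'   vectors `ko_targets`, `wt_targets`).
#' @export
generate_peak_experiment <- function(params = sim_params(), annotation,
                                     seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_ko <- params$n_diff_ko; n_wt <- params$n_diff_wt
  n_common <- params$n_common
  # designated target genes, disjoint between conditions
  targets <- sample.int(params$n_genes, n_ko + n_wt)
  ko_idx <- targets[seq_len(n_ko)]
  wt_idx <- targets[n_ko + seq_len(n_wt)]

  place_diff <- function(gene_rows) {
    n <- length(gene_rows)
    promoter <- seq_len(n) %% 2L == 1L  # alternate promoter/distal placement
    off <- ifelse(promoter,
                  round(runif(n, -3500, 1500)),
                  round(runif(n, -9500, -4500)))
    tss <- annotation$tss[gene_rows]
    anchor <- ifelse(annotation$strand[gene_rows] == "+", tss + off,
                     tss - off)
    width <- sample(500:1500, n, replace = TRUE)
    data.frame(start = pmax(anchor - floor(width / 2), 0),
               width = width, anchor = anchor, promoter = promoter,
               gene = annotation$symbol[gene_rows])
  }
  ann_rows_ko <- match(sprintf("G%04d", ko_idx), annotation$name)
  ann_rows_wt <- match(sprintf("G%04d", wt_idx), annotation$name)
  dko <- place_diff(ann_rows_ko)
  dwt <- place_diff(ann_rows_wt)

  # common peaks: evenly spaced centers with jitter, then swept left to
  # right so that every common peak is disjoint from other common peaks and
  # from every differential gene's promoter footprint (truth labels and
  # one-to-one pairing stay clean by construction)
  spacing <- params$chrom_length / n_common
  center <- round((seq_len(n_common) - 0.5) * spacing +
                    runif(n_common, -0.35, 0.35) * spacing)
  width_c <- sample(500:2000, n_common, replace = TRUE)
  excl_tss <- sort(annotation$tss[c(ann_rows_ko, ann_rows_wt)])
  zs <- excl_tss - 11000; ze <- excl_tss + 11000
  start_c <- numeric(n_common)
  last_end <- 0
  for (i in order(center)) {
    s <- max(center[i] - floor(width_c[i] / 2), last_end + 100, 0)
    repeat {
      hit <- which(zs < s + width_c[i] & s < ze)
      if (!length(hit)) break
      s <- max(ze[hit]) + 100
    }
    start_c[i] <- s
    last_end <- s + width_c[i]
  }
  # promoter footprints of genes in the last slot may extend a little past
  # chrom_length; only a material overrun indicates infeasible packing
  if (last_end > params$chrom_length + 25000) {
    stop("chromosome too short to place ", n_common,
         " non-overlapping common peaks")
  }
  center <- start_c + floor(width_c / 2)

  region <- data.frame(
    chrom = "chrS",
    start = c(start_c, dko$start, dwt$start),
    end = c(start_c + width_c, dko$start + dko$width,
            dwt$start + dwt$width),
    summit = c(center, dko$anchor, dwt$anchor),
    truth = c(rep("null_common", n_common),
              rep("true_ko_specific", n_ko),
              rep("true_wt_specific", n_wt)),
    gene = c(rep(NA_character_, n_common), dko$gene, dwt$gene),
    promoter_placed = c(rep(NA, n_common), dko$promoter, dwt$promoter),
    stringsAsFactors = FALSE
  )
  n_total <- nrow(region)
  a <- runif(n_total, 4, 12)
  eps <- rnorm(n_total, 0, params$noise_sd)
  half <- (params$c0 + params$c1 * a) / 2
  log_wt <- a - half - eps / 2
  log_ko <- a + half + eps / 2
  shift <- ifelse(region$truth == "true_ko_specific", params$delta_m,
                  ifelse(region$truth == "true_wt_specific",
                         -params$delta_m, 0))
  log_ko <- log_ko + shift
  len <- region$end - region$start
  region$a_true <- a
  region$m_true <- params$c0 + params$c1 * a + eps + shift
  region$count_ko <- pmax(round(2^log_ko * len / 1000), 0)
  region$count_wt <- pmax(round(2^log_wt * len / 1000), 0)

  mk_set <- function(rows, label) {
    peak_set(region$chrom[rows], region$start[rows], region$end[rows],
             summit = region$summit[rows],
             read_count = if (label == "ko") region$count_ko[rows] else
               region$count_wt[rows],
             name = sprintf("%s_%05d", label, seq_along(rows)),
             sample_label = label)
  }
  ko_rows <- which(region$truth != "true_wt_specific")
  wt_rows <- which(region$truth != "true_ko_specific")
  list(
    ko = mk_set(ko_rows, "ko"),
    wt = mk_set(wt_rows, "wt"),
    counts = region[, c("chrom", "start", "end", "count_ko", "count_wt")],
    truth = list(region = region,
                 ko_targets = sort(unique(dko$gene)),
                 wt_targets = sort(unique(dwt$gene))),
    params = params
  )
}

#' Generate read placements consistent with per-region counts
#'
#' For every region, exactly `count` reads of length `read_length` with
#' midpoints uniform in `[start, end)` and random strand, so that
#' [count_reads_in_regions()] with shift 0 recovers the counts exactly
#' (regions must not overlap).
#'
#' @param counts Data frame with chrom, start, end and a count column.
#' @param count_col Name of the count column (e.g. `"count_ko"`).
#' @param read_length Read length in bp.
#' @param seed Optional seed.
#' @return Data frame of reads: chrom, start, end, strand.
#' @export
generate_reads <- function(counts, count_col, read_length = 36L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- counts[[count_col]]
  total <- sum(n)
  if (total == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character()))
  }
  chrom <- rep(counts$chrom, n)
  lo <- rep(counts$start, n)
  hi <- rep(counts$end, n)
  mid <- lo + floor(runif(total) * (hi - lo))
  half <- floor(read_length / 2)
  data.frame(chrom = chrom, start = mid - half,
             end = mid - half + read_length,
             strand = sample(c("+", "-"), total, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Generate a gene signature enriched for KO-target genes
#'
#' Draws `signature_size` genes without replacement with sampling odds `rho`
#' for KO-target genes versus all other genes (`rho = 1` gives a uniform
#' null signature).
#'
#' @param truth Truth component of [generate_peak_experiment()] output.
#' @param annotation The [gene_annotation()] used for the experiment.
#' @param params A [sim_params()] list.
#' @param seed Optional seed.
#' @param rho Odds override (defaults to `params$rho`).
#' @param name Signature name.
#' @return A [gene_set()].
#' @export
generate_signature <- function(truth, annotation, params = sim_params(),
                               seed = params$seed, rho = params$rho,
                               name = "SYNTH_KO_SIGNATURE") {
  if (!is.null(seed)) set.seed(seed)
  symbols <- annotation$symbol
  if (params$signature_size > length(symbols)) {
    stop("signature_size exceeds the number of genes")
  }
  w <- ifelse(symbols %in% truth$ko_targets, rho, 1)
  gene_set(name, sample(symbols, params$signature_size, prob = w))
}

#' Generate replicate log2 expression with upregulated KO targets
#'
#' Baseline per gene `~ Normal(7, 1)` log2 units; KO replicates add `beta`
#' at KO-target genes; every cell gets residual `Normal(0, expr_sd)` noise.
#'
#' @inheritParams generate_signature
#' @return An [expression_matrix()] with `n_reps` wt and `n_reps` ko columns.
#' @export
generate_expression <- function(truth, annotation, params = sim_params(),
                                seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  symbols <- annotation$symbol
  n <- length(symbols)
  r <- params$n_reps
  baseline <- rnorm(n, 7, 1)
  effect <- ifelse(symbols %in% truth$ko_targets, params$beta, 0)
  vals <- matrix(rnorm(n * 2L * r, 0, params$expr_sd), nrow = n)
  vals <- vals + baseline
  vals[, r + seq_len(r)] <- vals[, r + seq_len(r)] + effect
  dimnames(vals) <- list(symbols,
                         c(paste0("wt_", seq_len(r)),
                           paste0("ko_", seq_len(r))))
  expression_matrix(vals, rep(c("wt", "ko"), each = r))
}

#' Simulate a complete experiment
#'
#' Runs all generators with per-stage seeds derived deterministically from
#' the master seed, so identical params give byte-identical outputs.
#'
#' @param params A [sim_params()] list.
#' @return List: `annotation`, `experiment` (see
#'   [generate_peak_experiment()]), `signatures` (enriched KO signature and
#'   a uniform control signature), `expression`, `params`.
#' @export
simulate_experiment <- function(params = sim_params()) {
  set.seed(params$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 5L)
  annotation <- generate_annotation(params, seed = sub_seeds[1])
  experiment <- generate_peak_experiment(params, annotation,
                                         seed = sub_seeds[2])
  sig_ko <- generate_signature(experiment$truth, annotation, params,
                               seed = sub_seeds[3])
  sig_ctrl <- generate_signature(experiment$truth, annotation, params,
                                 seed = sub_seeds[4], rho = 1,
                                 name = "SYNTH_CONTROL_SIGNATURE")
  expr <- generate_expression(experiment$truth, annotation, params,
                              seed = sub_seeds[5])
  list(annotation = annotation, experiment = experiment,
       signatures = list(SYNTH_KO_SIGNATURE = sig_ko,
                         SYNTH_CONTROL_SIGNATURE = sig_ctrl),
       expression = expr, params = params)
}

#' Write a simulated experiment to disk
#'
#' Emits the same plain-text formats the package readers consume:
#' annotation (refFlat-like TSV), peak catalogs (BED), per-region counts
#' (TSV), optional read placements (BED), signatures (GMT), expression
#' (TSV) and a region truth table (TSV).
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if missing).
#' @param include_reads Also write per-sample read BED files (can be large).
#' @param read_seed Seed for read placement.
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir, include_reads = TRUE,
                             read_seed = sim$params$seed + 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.refflat.tsv"),
    peaks_ko = file.path(dir, "peaks_ko.bed"),
    peaks_wt = file.path(dir, "peaks_wt.bed"),
    counts = file.path(dir, "counts.tsv"),
    signatures = file.path(dir, "signatures.gmt"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_gene_annotation(sim$annotation, paths["annotation"])
  write_peaks(sim$experiment$ko, paths["peaks_ko"])
  write_peaks(sim$experiment$wt, paths["peaks_wt"])
  write_tsv_commented(sim$experiment$counts, paths["counts"],
                      comments = sprintf("seed=%d", sim$params$seed))
  write_gmt(sim$signatures, paths["signatures"])
  expr_df <- data.frame(gene = rownames(sim$expression),
                        as.data.frame(unclass(sim$expression)),
                        check.names = FALSE)
  write_tsv_commented(expr_df, paths["expression"],
                      comments = paste("groups:",
                                       paste(attr(sim$expression, "group"),
                                             collapse = ",")))
  write_tsv_commented(sim$experiment$truth$region, paths["truth"],
                      comments = "per-region ground truth")
  if (include_reads) {
    for (side in c("ko", "wt")) {
      p <- file.path(dir, sprintf("reads_%s.bed", side))
      reads <- generate_reads(sim$experiment$counts,
                              paste0("count_", side),
                              seed = read_seed + (side == "wt"))
      writeLines(paste(reads$chrom, reads$start, reads$end, ".", 0,
                       reads$strand, sep = "\t"), p)
      paths[paste0("reads_", side)] <- p
    }
  }
  message("simulated experiment written to ", dir, " (", length(paths),
          " files)")
  invisible(paths)
}
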