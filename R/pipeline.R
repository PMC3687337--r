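# End-to-end orchestration: validated configuration, the full
# pair -> normalize -> classify -> annotate -> group -> enrich ->
# expression-integration pipeline, and a deterministic JSON summary.

#' Build and validate a pipeline configuration
#'
#' @param peaks_ko,peaks_wt Paths to the two peak BED files.
#' @param annotation Path to the refFlat-like gene annotation.
#' @param counts Optional path to a per-region counts TSV (columns chrom,
#'   start, end, count_ko, count_wt).
#' @param reads_ko,reads_wt Optional paths to read BED files (used when
#'   `counts` is absent).
#' @param signatures Optional path to a GMT file.
#' @param expression Optional path to a log2 expression TSV.
#' @param expression_groups Optional named sample-to-condition map; by
#'   default sample names starting with `wt`/`ko` are mapped to those
#'   conditions.
#' @param outdir Output directory.
#' @param seed Seed driving all stochastic stages (GSEA permutations).
#' @param min_overlap_bp,pseudocount,density,method,threshold Passed to
#'   [manorm()].
#' @param distal_promoter_window,proximal_promoter_window Passed to
#'   [compartment_config()].
#' @param fold_cutoff,p_cutoff Passed to [differential_genes()].
#' @param n_perm GSEA permutations (0 disables GSEA).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(peaks_ko, peaks_wt, annotation, counts = NULL,
                            reads_ko = NULL, reads_wt = NULL,
                            signatures = NULL, expression = NULL,
                            expression_groups = NULL,
                            outdir = tempfile("peaknorm_run_"),
                            seed = 1L, min_overlap_bp = 1L,
                            pseudocount = 1, density = "per_kb",
                            method = "huber", threshold = 1,
                            distal_promoter_window = c(-10000, -4000),
                            proximal_promoter_window = c(-4000, 2000),
                            fold_cutoff = 1.5, p_cutoff = 0.05,
                            n_perm = 1000L) {
  cfg <- list(peaks_ko = peaks_ko, peaks_wt = peaks_wt,
              annotation = annotation, counts = counts,
              reads_ko = reads_ko, reads_wt = reads_wt,
              signatures = signatures, expression = expression,
              expression_groups = expression_groups, outdir = outdir,
              seed = as.integer(seed), min_overlap_bp = min_overlap_bp,
              pseudocount = pseudocount, density = density,
              method = method, threshold = threshold,
              distal_promoter_window = distal_promoter_window,
              proximal_promoter_window = proximal_promoter_window,
              fold_cutoff = fold_cutoff, p_cutoff = p_cutoff,
              n_perm = as.integer(n_perm))
  for (field in c("peaks_ko", "peaks_wt", "annotation", "counts",
                  "reads_ko", "reads_wt", "signatures", "expression")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config: ", field, " path does not exist: ", p)
    }
  }
  if (is.null(cfg$counts) && (is.null(cfg$reads_ko) ||
                              is.null(cfg$reads_wt))) {
    stop("config: either a counts table or both read files are required")
  }
  if (cfg$threshold <= 0 || cfg$pseudocount < 0 || cfg$min_overlap_bp < 1) {
    stop("config: tunable out of range")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

read_counts_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count_ko", "count_wt")
  if (!all(need %in% colnames(tab))) {
    stop("counts table must have columns ", paste(need, collapse = ", "))
  }
  tab
}

# infer wt/ko condition labels from sample-name prefixes
default_groups <- function(samples) {
  g <- ifelse(grepl("^wt", samples, ignore.case = TRUE), "wt",
              ifelse(grepl("^ko", samples, ignore.case = TRUE), "ko", NA))
  if (anyNA(g)) {
    stop("cannot infer wt/ko condition from sample name(s): ",
         paste(samples[is.na(g)], collapse = ", "),
         "; supply expression_groups")
  }
  setNames(g, samples)
}

#' Run the full comparison pipeline
#'
#' Executes pairing, M-A normalization and specific-peak classification,
#' compartment annotation and nearest-gene target assignment, target
#' grouping by binding location, signature overlap enrichment (and GSEA
#' when expression data and signatures are both present), differential
#' expression and expression-ratio summaries, then writes result tables and
#' a deterministic JSON summary to the output directory. Reruns with the
#' same configuration and inputs produce byte-identical summaries.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly; also written as `summary.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be built with pipeline_config()")
  }
  written <- character()
  stage_name <- "setup"
  stage <- function(name) stage_name <<- name
  on_fail <- function(e) {
    unlink(written)  # remove partial outputs
    stop("pipeline stage '", stage_name, "' failed: ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    cc <- compartment_config(config$distal_promoter_window,
                             config$proximal_promoter_window)

    stage("load inputs")
    ko <- read_peaks(config$peaks_ko, "ko")
    wt <- read_peaks(config$peaks_wt, "wt")
    ann <- read_gene_annotation(config$annotation)
    counts <- if (!is.null(config$counts)) read_counts_table(config$counts)
    reads_ko <- if (is.null(counts)) read_bed_intervals(config$reads_ko)
    reads_wt <- if (is.null(counts)) read_bed_intervals(config$reads_wt)
    sigs <- if (!is.null(config$signatures)) read_gmt(config$signatures)
    expr <- if (!is.null(config$expression)) {
      header <- strsplit(grep("^#", readLines(config$expression, n = 50L),
                              invert = TRUE, value = TRUE)[1], "\t")[[1]]
      gm <- config$expression_groups
      if (is.null(gm)) gm <- default_groups(header[-1])
      read_expression(config$expression, gm)
    }

    stage("normalize")
    fit <- manorm(ko, wt, counts = counts, reads_ko = reads_ko,
                  reads_wt = reads_wt,
                  min_overlap_bp = config$min_overlap_bp,
                  pseudocount = config$pseudocount,
                  density = config$density, method = config$method,
                  threshold = config$threshold)
    tab <- fit$table
    p_manorm <- file.path(config$outdir, "comparison.tsv")
    write_manorm(fit, p_manorm); written <- c(written, p_manorm)
    p_model <- file.path(config$outdir, "model.json")
    jsonlite::write_json(
      list(intercept = fit$model$intercept, slope = fit$model$slope,
           n_fit = fit$model$n_fit, excluded_n = fit$model$excluded_n,
           method = fit$model$method, pseudocount = config$pseudocount),
      p_model, auto_unbox = TRUE, digits = NA)
    written <- c(written, p_model)

    stage("annotate")
    union_ps <- peak_set(tab$chrom, tab$start, tab$end,
                         sample_label = "union")
    annotated <- annotate_peaks(union_ps, ann, cc)
    annotated$label <- tab$label
    annotated$m_normalized <- tab$m_normalized
    p_ann <- file.path(config$outdir, "annotated_peaks.tsv")
    write_tsv_commented(annotated, p_ann,
                        comments = sprintf(
                          "windows: distal=[%g,%g) proximal=[%g,%g)",
                          cc$distal_promoter_window[1],
                          cc$distal_promoter_window[2],
                          cc$proximal_promoter_window[1],
                          cc$proximal_promoter_window[2]))
    written <- c(written, p_ann)
    comp <- compartment_distribution(union_ps, ann, cc)

    stage("target assignment")
    targets <- list(
      ko_specific = sort(unique(annotated$nearest_gene[
        annotated$label == "ko_specific" &
          annotated$nearest_gene != "unassigned"])),
      wt_specific = sort(unique(annotated$nearest_gene[
        annotated$label == "wt_specific" &
          annotated$nearest_gene != "unassigned"])),
      common = sort(unique(annotated$nearest_gene[
        annotated$label == "common" &
          annotated$nearest_gene != "unassigned"]))
    )
    groups_loc <- group_targets_by_location(union_ps, ann, cc)

    stage("enrichment")
    enrich <- NULL
    if (!is.null(sigs) && length(sigs)) {
      universe <- unique(ann$symbol)
      rows <- list()
      for (sig in sigs) {
        for (lab in names(targets)) {
          if (!length(targets[[lab]])) next
          er <- overlap_enrichment(targets[[lab]], sig, universe)
          rows[[length(rows) + 1L]] <- data.frame(
            signature = sig$name, target_group = lab, es = er$es, p = er$p,
            n_target = er$n_target, n_signature = er$n_signature,
            n_overlap = er$n_overlap, n_universe = er$n_universe,
            stringsAsFactors = FALSE)
        }
      }
      enrich <- do.call(rbind, rows)
      p_enr <- file.path(config$outdir, "enrichment.tsv")
      write_tsv_commented(enrich, p_enr,
                          comments = "overlap enrichment, one-sided Fisher")
      written <- c(written, p_enr)
    }

    stage("expression integration")
    diff <- NULL; frac <- NULL; ratios <- NULL; gsea_res <- NULL
    if (!is.null(expr)) {
      diff <- differential_genes(expr, config$fold_cutoff, config$p_cutoff)
      p_diff <- file.path(config$outdir, "differential.tsv")
      write_tsv_commented(diff, p_diff,
                          comments = sprintf(
                            "filter: >=%g-fold, p<=%g (Welch two-tailed t)",
                            config$fold_cutoff, config$p_cutoff))
      written <- c(written, p_diff)
      up <- diff$gene[diff$passes & diff$log2fc > 0]
      all_targets <- sort(unique(unlist(targets)))
      if (length(up) && length(all_targets)) {
        frac <- fraction_bound(up, all_targets)
      }
      grp <- attr(expr, "group")
      ratios <- suppressWarnings(ratio_by_group(
        expr[, grp == "ko", drop = FALSE],
        expr[, grp == "wt", drop = FALSE], targets))
      if (!is.null(sigs) && length(sigs) && config$n_perm > 0L) {
        gsea_res <- gsea(expr, sigs, n_perm = config$n_perm,
                         seed = config$seed)
        p_gsea <- file.path(config$outdir, "gsea.tsv")
        write_tsv_commented(as.data.frame(gsea_res), p_gsea,
                            comments = sprintf(
                              "gene-set permutation, n_perm=%d, seed=%d",
                              config$n_perm, config$seed))
        written <- c(written, p_gsea)
      }
    }

    stage("summarize")
    summary <- list(
      config = config[setdiff(names(config), "expression_groups")],
      model = list(intercept = fit$model$intercept,
                   slope = fit$model$slope, n_fit = fit$model$n_fit,
                   method = fit$model$method),
      n_regions = nrow(tab),
      origin_counts = as.list(table(tab$origin)),
      label_counts = as.list(table(tab$label)),
      compartment_fractions = as.list(round(
        as.numeric(comp$fractions), 10L) |>
          setNames(names(comp$fractions))),
      n_target_genes = lapply(targets, length),
      target_location_groups = lapply(groups_loc, length),
      enrichment = if (!is.null(enrich)) enrich,
      differential = if (!is.null(diff)) {
        list(n_tested = nrow(diff), n_pass = sum(diff$passes),
             n_up = sum(diff$passes & diff$log2fc > 0),
             n_down = sum(diff$passes & diff$log2fc < 0))
      },
      fraction_up_bound = if (!is.null(frac)) frac,
      ratio_by_group = if (!is.null(ratios)) ratios,
      gsea = if (!is.null(gsea_res)) as.data.frame(gsea_res)
    )
    summary <- summary[!vapply(summary, is.null, logical(1))]
    p_sum <- file.path(config$outdir, "summary.json")
    jsonlite::write_json(summary, p_sum, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, p_sum)
    invisible(summary)
  }, error = on_fail)
}
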