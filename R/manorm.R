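# Quantitative between-sample normalization of peak read densities.
#
# The model: at every region, M = log2(density_ko / density_wt) and
# A = 0.5 * log2(density_ko * density_wt). Under the assumption that the true
# intensities of most common peaks are identical between the samples, the
# global dependence of M on A over common peaks reflects only the scaling
# relationship of the two libraries. A robust linear fit M = b0 + b1 * A over
# common peaks is therefore used as the reference and extrapolated to all
# peaks; the residual (normalized M) is the quantitative measure of
# differential binding.

#' Compute M-A statistics from a pair of read densities
#'
#' `m = log2(ko / wt)`, `a = 0.5 * log2(ko * wt)`. Inverse-consistent:
#' densities are recoverable as `2^(a + m/2)` and `2^(a - m/2)`.
#'
#' @param density_ko,density_wt Positive read densities (vectorized).
#' @return Data frame with columns `m` and `a`.
#' @export
compute_ma <- function(density_ko, density_wt) {
  if (any(density_ko <= 0) || any(density_wt <= 0)) {
    stop("read densities must be positive; enable a pseudocount for ",
         "zero-count regions")
  }
  data.frame(m = log2(density_ko / density_wt),
             a = 0.5 * log2(density_ko * density_wt))
}

# Huber / bisquare IRLS for a straight-line fit of m on a. The scale is
# re-estimated each iteration as the MAD (about zero) of the residuals.
irls_line <- function(a, m, method = c("huber", "bisquare"),
                      k_huber = 1.345, k_bisquare = 4.685,
                      max_iter = 50L, tol = 1e-8) {
  method <- match.arg(method)
  X <- cbind(1, a)
  beta <- stats::lm.fit(X, m)$coefficients
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- m - X %*% beta
    s <- mad(r, center = 0)
    if (s < 1e-12) { converged <- TRUE; break }  # (near-)exact fit
    u <- abs(r) / s
    w <- if (method == "huber") {
      pmin(1, k_huber / u)
    } else {
      ifelse(u < k_bisquare, (1 - (u / k_bisquare)^2)^2, 0)
    }
    beta_new <- lm.wfit(X, m, as.numeric(w))$coefficients
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       iterations = iter, converged = converged, method = method)
}

#' Fit the robust M-on-A normalization reference
#'
#' Iteratively reweighted least squares with Huber weights (tuning constant
#' 1.345; Tukey bisquare offered as an option), at most 50 iterations,
#' convergence when the coefficient change falls below 1e-8.
#'
#' @param ma Data frame with columns `m` and `a` for the common peaks used
#'   for fitting (after any mask exclusion).
#' @param excluded_n Number of common peaks removed by an exclusion mask
#'   (bookkeeping only).
#' @param method `"huber"` (default) or `"bisquare"`.
#' @param min_n Minimum number of points required for a fit.
#' @return A `normalization_model`: intercept, slope, `n_fit`, `excluded_n`,
#'   `method`, `iterations`, `converged`.
#' @export
fit_normalization <- function(ma, excluded_n = 0L, method = "huber",
                              min_n = 10L) {
  if (nrow(ma) < min_n) {
    stop("insufficient common peaks for normalization fit (", nrow(ma),
         " < ", min_n, ")")
  }
  fit <- irls_line(ma$a, ma$m, method = method)
  structure(c(fit[c("intercept", "slope")],
              list(n_fit = nrow(ma), excluded_n = excluded_n,
                   method = fit$method, iterations = fit$iterations,
                   converged = fit$converged)),
            class = "normalization_model")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat("M-A normalization reference (", x$method, " IRLS): M = ",
      format(x$intercept, digits = 6), " + ", format(x$slope, digits = 6),
      " * A\n  fitted on ", x$n_fit, " common peaks (", x$excluded_n,
      " excluded by mask), ", x$iterations, " iteration(s)\n", sep = "")
  invisible(x)
}

#' @method coef normalization_model
#' @export
coef.normalization_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Normalize M values against a fitted reference
#'
#' `m_normalized = m - (intercept + slope * a)`, applied to every peak
#' (common and sample-unique alike).
#'
#' @param ma Data frame with columns `m` and `a`.
#' @param model A `normalization_model` (see [fit_normalization()]).
#' @return Numeric vector of normalized M values.
#' @export
normalize_m <- function(ma, model) {
  ma$m - (model$intercept + model$slope * ma$a)
}

#' Classify peaks from normalized M values
#'
#' `m > threshold` is condition-specific for the numerator sample
#' (`ko_specific`), `m < -threshold` for the denominator (`wt_specific`);
#' boundary values are `common` (strict inequalities: a specific call
#' requires *more* than `2^threshold`-fold normalized difference).
#'
#' @param m_normalized Numeric vector.
#' @param threshold Positive fold-change threshold in log2 units (default 1,
#'   i.e. twofold).
#' @return Factor with levels ko_specific, wt_specific, common.
#' @export
classify_peaks <- function(m_normalized, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  lab <- rep("common", length(m_normalized))
  lab[m_normalized > threshold] <- "ko_specific"
  lab[m_normalized < -threshold] <- "wt_specific"
  factor(lab, levels = c("ko_specific", "wt_specific", "common"))
}

# Build the union catalog from a pairing: one row per common pair (spanning
# interval of the two mates) plus one row per sample-unique peak.
union_catalog <- function(pairing) {
  a <- pairing$a; b <- pairing$b; cp <- pairing$common_pairs
  common <- data.frame(
    chrom = a$chrom[cp$idx_a],
    start = pmin(a$start[cp$idx_a], b$start[cp$idx_b]),
    end = pmax(a$end[cp$idx_a], b$end[cp$idx_b]),
    summit = a$summit[cp$idx_a],
    origin = rep("common", nrow(cp)),
    idx_a = cp$idx_a, idx_b = cp$idx_b,
    stringsAsFactors = FALSE
  )
  ua <- data.frame(chrom = a$chrom[pairing$unique_a],
                   start = a$start[pairing$unique_a],
                   end = a$end[pairing$unique_a],
                   summit = a$summit[pairing$unique_a],
                   origin = rep("unique_ko", length(pairing$unique_a)),
                   idx_a = pairing$unique_a,
                   idx_b = rep(NA_integer_, length(pairing$unique_a)),
                   stringsAsFactors = FALSE)
  ub <- data.frame(chrom = b$chrom[pairing$unique_b],
                   start = b$start[pairing$unique_b],
                   end = b$end[pairing$unique_b],
                   summit = b$summit[pairing$unique_b],
                   origin = rep("unique_wt", length(pairing$unique_b)),
                   idx_a = rep(NA_integer_, length(pairing$unique_b)),
                   idx_b = pairing$unique_b, stringsAsFactors = FALSE)
  cat_df <- rbind(common, ua, ub)
  ord <- order(cat_df$chrom, cat_df$start, cat_df$end)
  cat_df <- cat_df[ord, , drop = FALSE]
  rownames(cat_df) <- NULL
  cat_df
}

# Resolve per-region read counts for both samples over the union catalog.
resolve_counts <- function(catalog, pairing, counts = NULL,
                           reads_ko = NULL, reads_wt = NULL) {
  if (!is.null(counts)) {
    key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")
    idx <- match(key(catalog$chrom, catalog$start, catalog$end),
                 key(counts$chrom, counts$start, counts$end))
    if (anyNA(idx)) {
      stop("counts table is missing ", sum(is.na(idx)),
           " union-catalog region(s)")
    }
    return(list(ko = counts$count_ko[idx], wt = counts$count_wt[idx]))
  }
  if (!is.null(reads_ko) && !is.null(reads_wt)) {
    return(list(ko = count_reads_in_regions(reads_ko, catalog),
                wt = count_reads_in_regions(reads_wt, catalog)))
  }
  # fall back on the catalogs' own read_count columns; only possible when
  # every region was scored in both samples (i.e. no unique peaks)
  ko <- ifelse(is.na(catalog$idx_a), NA_real_,
               pairing$a$read_count[catalog$idx_a])
  wt <- ifelse(is.na(catalog$idx_b), NA_real_,
               pairing$b$read_count[catalog$idx_b])
  if (anyNA(ko) || anyNA(wt)) {
    stop("cross-sample read counts unavailable for sample-unique peaks; ",
         "supply a counts table or read placements")
  }
  list(ko = ko, wt = wt)
}

#' Quantitative comparison of two peak catalogs (M-A robust normalization)
#'
#' The fitting function of the package. Pairs the two catalogs, obtains read
#' counts for every union-catalog region in both samples, converts counts to
#' densities (reads per kb after a pseudocount), computes M-A values, fits
#' the robust M-on-A reference on common peaks (optionally excluding peaks
#' overlapping `mask`), extrapolates it to all peaks and classifies
#' condition-specific binding at `threshold`.
#'
#' Counts are resolved in this order: an explicit `counts` table (columns
#' chrom, start, end, count_ko, count_wt covering every union region), read
#' placements (`reads_ko`/`reads_wt`, counted by shifted midpoint), or the
#' catalogs' own `read_count` columns (possible only when there are no
#' sample-unique peaks).
#'
#' @param ko,wt [peak_set()] catalogs for the numerator (e.g. knockout) and
#'   denominator (e.g. wild-type) samples.
#' @param counts Optional per-region counts table (see Details).
#' @param reads_ko,reads_wt Optional read placements (see
#'   [read_bed_intervals()]).
#' @param mask Optional [peak_set()]; common peaks overlapping it by >= 1 bp
#'   are excluded from the reference fit (but still normalized).
#' @param min_overlap_bp Overlap required for two peaks to pair.
#' @param pseudocount Reads added to every region count before computing
#'   densities (default 1; 0 disables and errors on zero counts).
#' @param density `"per_kb"` (count / length * 1000, default) or `"raw"`.
#' @param method Robust fit: `"huber"` (default) or `"bisquare"`.
#' @param threshold Specific-peak threshold on |normalized M| (default 1).
#' @param shift_bp Read midpoint shift used when counting from reads.
#' @return A `manorm` object; see [summary.manorm()]. The per-region table is
#'   available via `as.data.frame()` with columns chrom, start, end, origin,
#'   count_ko, count_wt, density_ko, density_wt, m_raw, a, m_normalized,
#'   used_in_fit, label.
#' @export
manorm <- function(ko, wt, counts = NULL, reads_ko = NULL, reads_wt = NULL,
                   mask = NULL, min_overlap_bp = 1L, pseudocount = 1,
                   density = c("per_kb", "raw"), method = "huber",
                   threshold = 1, shift_bp = 0L) {
  density <- match.arg(density)
  pairing <- pair_peaks(ko, wt, min_overlap_bp)
  catalog <- union_catalog(pairing)
  cnt <- resolve_counts(catalog, pairing, counts, reads_ko, reads_wt)
  if (pseudocount == 0 && (any(cnt$ko == 0) || any(cnt$wt == 0))) {
    stop("zero read counts with pseudocount disabled")
  }
  len <- catalog$end - catalog$start
  dens_ko <- cnt$ko + pseudocount
  dens_wt <- cnt$wt + pseudocount
  if (density == "per_kb") {
    dens_ko <- dens_ko / len * 1000
    dens_wt <- dens_wt / len * 1000
  }
  if (all(cnt$ko == 0) || all(cnt$wt == 0)) {
    warning("all-zero read counts in one sample; results are driven by the ",
            "pseudocount alone")
  }
  ma <- compute_ma(dens_ko, dens_wt)
  is_common <- catalog$origin == "common"
  in_fit <- is_common
  excluded_n <- 0L
  if (!is.null(mask) && any(is_common)) {
    masked <- overlap_pairs(catalog, mask, 1L)
    hit <- logical(nrow(catalog))
    hit[unique(masked$idx_a)] <- TRUE
    excluded_n <- sum(is_common & hit)
    in_fit <- is_common & !hit
  }
  model <- fit_normalization(ma[in_fit, , drop = FALSE],
                             excluded_n = excluded_n, method = method)
  m_norm <- normalize_m(ma, model)
  label <- classify_peaks(m_norm, threshold)
  table <- data.frame(
    chrom = catalog$chrom, start = catalog$start, end = catalog$end,
    origin = catalog$origin, count_ko = cnt$ko, count_wt = cnt$wt,
    density_ko = dens_ko, density_wt = dens_wt,
    m_raw = ma$m, a = ma$a, m_normalized = m_norm,
    used_in_fit = in_fit, label = label,
    stringsAsFactors = FALSE
  )
  structure(list(table = table, model = model, pairing = pairing,
                 options = list(min_overlap_bp = min_overlap_bp,
                                pseudocount = pseudocount, density = density,
                                method = method, threshold = threshold,
                                shift_bp = shift_bp),
                 call = match.call()),
            class = "manorm")
}

#' @export
print.manorm <- function(x, ...) {
  tab <- table(x$table$label)
  cat("Quantitative peak comparison (", nrow(x$table), " union regions)\n",
      sep = "")
  print(x$model)
  cat("  labels: ", paste(names(tab), as.integer(tab), sep = "=",
                          collapse = ", "),
      " at |normalized M| > ", x$options$threshold, "\n", sep = "")
  invisible(x)
}

#' Summarize a quantitative peak comparison
#'
#' @param object A `manorm` fit.
#' @param ... Unused.
#' @return A `summary.manorm` list: model coefficients, region counts by
#'   origin and label, and the options used.
#' @method summary manorm
#' @export
summary.manorm <- function(object, ...) {
  structure(list(
    coefficients = coef(object),
    n_regions = nrow(object$table),
    origin = table(object$table$origin),
    label = table(object$table$label),
    mean_m_normalized_fit = mean(
      object$table$m_normalized[object$table$used_in_fit]),
    model = object$model,
    options = object$options
  ), class = "summary.manorm")
}

#' @export
print.summary.manorm <- function(x, ...) {
  cat("Quantitative peak comparison summary\n")
  cat("  regions: ", x$n_regions, " (",
      paste(names(x$origin), as.integer(x$origin), sep = "=",
            collapse = ", "), ")\n", sep = "")
  cat("  reference: M = ", format(x$coefficients[1], digits = 6), " + ",
      format(x$coefficients[2], digits = 6), " * A  [", x$model$method,
      ", n_fit = ", x$model$n_fit, "]\n", sep = "")
  cat("  mean normalized M over fitted peaks: ",
      format(x$mean_m_normalized_fit, digits = 4), "\n", sep = "")
  cat("  labels: ", paste(names(x$label), as.integer(x$label), sep = "=",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method coef manorm
#' @export
coef.manorm <- function(object, ...) coef(object$model)

#' Reference M value predicted at given A
#'
#' @param object A `manorm` fit.
#' @param a Numeric A values (defaults to the fitted regions' A).
#' @param ... Unused.
#' @return `intercept + slope * a`.
#' @export
predict.manorm <- function(object, a = object$table$a, ...) {
  object$model$intercept + object$model$slope * a
}

#' @export
fitted.manorm <- function(object, ...) predict(object)

#' Normalized M values (residuals from the reference line)
#' @param object A `manorm` fit.
#' @param ... Unused.
#' @method residuals manorm
#' @export
residuals.manorm <- function(object, ...) object$table$m_normalized

#' @method as.data.frame manorm
#' @export
as.data.frame.manorm <- function(x, ...) x$table

#' MA plots before and after normalization
#'
#' Two-panel base-graphics plot: raw M vs A with the fitted reference line,
#' and normalized M vs A with the classification threshold; specific peaks
#' are highlighted.
#'
#' @param x A `manorm` fit.
#' @param ... Passed to [plot()].
#' @method plot manorm
#' @export
plot.manorm <- function(x, ...) {
  tab <- x$table
  col <- c(ko_specific = "#d62728", wt_specific = "#1f77b4",
           common = "#00000055")[as.character(tab$label)]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(tab$a, tab$m_raw, col = col, pch = 20, cex = 0.5,
       xlab = "A (average log2 density)", ylab = "M (raw)",
       main = "Before normalization", ...)
  graphics::abline(coef(x)[1], coef(x)[2], col = "red", lwd = 2)
  plot(tab$a, tab$m_normalized, col = col, pch = 20, cex = 0.5,
       xlab = "A (average log2 density)", ylab = "M (normalized)",
       main = "After normalization", ...)
  graphics::abline(h = c(-1, 0, 1) * x$options$threshold,
                   col = c("blue", "grey40", "red"), lty = c(2, 1, 2))
  invisible(x)
}

#' Simulate new comparisons from a fitted reference
#'
#' Draws `nsim` replicate tables in which the raw M of every fitted region is
#' the model reference at its A plus Gaussian noise matched to the residual
#' spread (MAD) of the fit — the "no differential binding" null for the
#' fitted scaling.
#'
#' @param object A `manorm` fit.
#' @param nsim Number of simulated tables.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return List of data frames with columns `a` and `m_raw`.
#' @export
simulate.manorm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fit_rows <- object$table[object$table$used_in_fit, , drop = FALSE]
  s <- mad(fit_rows$m_normalized, center = 0)
  lapply(seq_len(nsim), function(i) {
    data.frame(a = fit_rows$a,
               m_raw = predict(object, fit_rows$a) +
                 rnorm(nrow(fit_rows), 0, s))
  })
}

#' Write the per-region comparison table to TSV
#'
#' @param x A `manorm` fit.
#' @param path Output path; parameters are recorded as `#` comment lines.
#' @export
write_manorm <- function(x, path) {
  o <- x$options
  write_tsv_commented(
    x$table, path,
    comments = c(
      sprintf("normalization: M = %.6g + %.6g * A (%s IRLS, n_fit = %d)",
              x$model$intercept, x$model$slope, x$model$method,
              x$model$n_fit),
      sprintf("options: min_overlap_bp=%d pseudocount=%g density=%s threshold=%g",
              o$min_overlap_bp, o$pseudocount, o$density, o$threshold)
    ))
}
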