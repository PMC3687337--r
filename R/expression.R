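# Differential-expression filtering, expression-ratio summaries over peak
# target groups, fraction-of-genes-bound statistics, and delta-delta-Ct
# relative expression.

#' Differential genes by fold-change and t-test filter
#'
#' Per gene, `log2fc = mean_ko - mean_wt` on the log2 values and a two-tailed
#' t-test between the condition replicates (Welch by default; pooled-variance
#' classic form by flag). A gene passes iff `|log2fc| >= log2(fold_cutoff)`
#' and `p <= p_cutoff` (no multiple-testing correction), with `direction`
#' restricting the sign.
#'
#' @param expr An [expression_matrix()] (log2 scale).
#' @param fold_cutoff Linear fold-change cutoff (default 1.5).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param direction `"both"` (default), `"up"` (ko > wt) or `"down"`.
#' @param var_equal Use the pooled-variance t instead of Welch.
#' @param ko,wt Condition labels to contrast.
#' @return Data frame: gene, log2fc, t, df, p, passes.
#' @export
differential_genes <- function(expr, fold_cutoff = 1.5, p_cutoff = 0.05,
                               direction = c("both", "up", "down"),
                               var_equal = FALSE, ko = "ko", wt = "wt") {
  direction <- match.arg(direction)
  grp <- attr(expr, "group")
  iko <- which(grp == ko); iwt <- which(grp == wt)
  n1 <- length(iko); n2 <- length(iwt)
  if (n1 < 2L || n2 < 2L) {
    stop("each condition needs >= 2 replicates for the t-test")
  }
  m1 <- rowMeans(expr[, iko, drop = FALSE])
  m2 <- rowMeans(expr[, iwt, drop = FALSE])
  v1 <- apply(expr[, iko, drop = FALSE], 1L, stats::var)
  v2 <- apply(expr[, iwt, drop = FALSE], 1L, stats::var)
  fc <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(fc))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- fc / se
  p <- 2 * pt(-abs(t_stat), df)
  # zero pooled variance: identical replicates; p = 1 when means agree,
  # else the difference is exact
  degenerate <- se == 0
  p[degenerate] <- ifelse(fc[degenerate] == 0, 1, 0)
  passes <- abs(fc) >= log2(fold_cutoff) & p <= p_cutoff
  if (direction == "up") passes <- passes & fc > 0
  if (direction == "down") passes <- passes & fc < 0
  data.frame(gene = rownames(expr), log2fc = unname(fc),
             t = unname(t_stat), df = unname(df), p = unname(p),
             passes = unname(passes), stringsAsFactors = FALSE)
}

#' Fraction of upregulated genes bound by the factor
#'
#' @param up_genes Character vector of (e.g. upregulated) gene symbols;
#'   must be non-empty.
#' @param target_genes Character vector of peak target gene symbols.
#' @return List: `fraction` = |up intersect targets| / |up|, `n_up`,
#'   `n_bound`.
#' @export
fraction_bound <- function(up_genes, target_genes) {
  up <- unique(toupper(as.character(up_genes)))
  if (!length(up)) stop("empty upregulated gene set")
  tg <- unique(toupper(as.character(target_genes)))
  k <- length(intersect(up, tg))
  list(fraction = k / length(up), n_up = length(up), n_bound = k)
}

#' Expression-ratio distribution per target-gene group
#'
#' Per gene present in both matrices, the ratio is the mean log2 intensity in
#' `expr_ko` minus that in `expr_wt`. Per named group, the five-number
#' summary of the ratios over its member genes is returned; groups with no
#' matched gene are skipped with a warning.
#'
#' @param expr_ko,expr_wt Matrices of log2 intensities (replicate columns),
#'   rownames = gene symbols.
#' @param groups Named list of character vectors (gene symbol groups).
#' @return Data frame: group, n, min, q1, median, q3, max.
#' @export
ratio_by_group <- function(expr_ko, expr_wt, groups) {
  rk <- rowMeans(as.matrix(expr_ko))
  rw <- rowMeans(as.matrix(expr_wt))
  names(rk) <- toupper(rownames(as.matrix(expr_ko)))
  names(rw) <- toupper(rownames(as.matrix(expr_wt)))
  shared <- intersect(names(rk), names(rw))
  ratio <- rk[shared] - rw[shared]
  rows <- lapply(names(groups), function(g) {
    members <- intersect(unique(toupper(groups[[g]])), shared)
    if (!length(members)) {
      warning("group '", g, "' has no gene matched in both matrices; skipped")
      return(NULL)
    }
    q <- quantile(ratio[members], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(group = g, n = length(members), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(group = character(), n = integer(), min = numeric(),
                      q1 = numeric(), median = numeric(), q3 = numeric(),
                      max = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddct = (ct_target_treated - ct_ref_treated) -
#' (ct_target_control - ct_ref_control)`; relative expression = `2^-ddct`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   qPCR cycle-threshold values (vectorized, finite).
#' @return Relative expression of the target in treated vs control,
#'   normalized to the reference gene.
#' @export
delta_delta_ct <- function(ct_target_treated, ct_ref_treated,
                           ct_target_control, ct_ref_control) {
  ct <- c(ct_target_treated, ct_ref_treated, ct_target_control,
          ct_ref_control)
  if (any(!is.finite(ct))) stop("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
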