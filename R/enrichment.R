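# Signature statistics: observed/expected overlap enrichment with Fisher's
# exact test, and a GSEA-style running enrichment score with a gene-set
# permutation null.

#' Observed/expected overlap enrichment of a target set in a signature
#'
#' The enrichment score is the ratio of the observed overlap between target
#' and signature genes to the overlap expected at random given the set sizes
#' and the gene universe: `es = k / (|T| * |S| / |U|)`. The p-value is the
#' one-sided (enrichment) Fisher's exact probability of the 2x2 table
#' `[[k, |T|-k], [|S|-k, |U|-|T|-|S|+k]]`, i.e. the hypergeometric upper
#' tail; a two-sided test is available.
#'
#' @param target A [gene_set()] or character vector of target gene symbols.
#' @param signature A [gene_set()] or character vector of signature symbols.
#' @param universe Character vector of all gene symbols considered; symbols
#'   of `target`/`signature` outside the universe are dropped with a warning.
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`.
#' @return An `enrichment_result` list: `es`, `p`, `n_target`,
#'   `n_signature`, `n_overlap`, `n_universe`.
#' @export
overlap_enrichment <- function(target, signature, universe,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  as_genes <- function(x) if (inherits(x, "gene_set")) x$genes else
    unique(toupper(as.character(x)))
  universe <- unique(toupper(as.character(universe)))
  if (!length(universe)) stop("empty universe")
  tg <- as_genes(target)
  sg <- as_genes(signature)
  t_out <- setdiff(tg, universe); s_out <- setdiff(sg, universe)
  if (length(t_out) || length(s_out)) {
    warning(length(t_out), " target and ", length(s_out),
            " signature symbol(s) outside the universe dropped")
  }
  tg <- intersect(tg, universe)
  sg <- intersect(sg, universe)
  nu <- length(universe); nt <- length(tg); ns <- length(sg)
  if (nt == 0L || ns == 0L) {
    stop("expected overlap is zero (empty target or signature in universe)")
  }
  k <- length(intersect(tg, sg))
  es <- k / (nt * ns / nu)
  p <- if (alternative == "greater") {
    fisher_exact_greater(k, nt, ns, nu)
  } else {
    fisher.test(matrix(c(k, nt - k, ns - k, nu - nt - ns + k), 2L),
                alternative = "two.sided")$p.value
  }
  structure(list(es = es, p = p, n_target = nt, n_signature = ns,
                 n_overlap = k, n_universe = nu,
                 alternative = alternative),
            class = "enrichment_result")
}

#' One-sided (enrichment) Fisher's exact p-value for a 2x2 overlap table
#'
#' The probability of observing an overlap of at least `k` between a target
#' of size `n_target` and a signature of size `n_signature` drawn from a
#' universe of `n_universe` genes: the hypergeometric upper tail, identical
#' to Fisher's exact test with alternative "greater". Vectorized.
#'
#' @param k Observed overlap count(s).
#' @param n_target,n_signature,n_universe Set and universe sizes.
#' @return p-value(s).
#' @export
fisher_exact_greater <- function(k, n_target, n_signature, n_universe) {
  phyper(k - 1, n_signature, n_universe - n_signature, n_target,
         lower.tail = FALSE)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Overlap enrichment: ES = ", format(x$es, digits = 4), ", p = ",
      format(x$p, digits = 4), " (", x$alternative, ")\n  overlap ",
      x$n_overlap, " of target ", x$n_target, " x signature ",
      x$n_signature, " in universe ", x$n_universe, "\n", sep = "")
  invisible(x)
}

#' Rank genes by signal-to-noise ratio between conditions
#'
#' Score per gene: `(mean_ko - mean_wt) / (sd_ko + sd_wt)` with each
#' standard deviation floored at `max(0.2 * |mean|, 0.2)` of its own group
#' mean before use (the usual variance stabilization for small replicate
#' numbers). Genes are returned in descending score order, ties broken by
#' symbol.
#'
#' @param expr An [expression_matrix()] with condition labels `"wt"` and
#'   `"ko"` (at least 2 replicates each).
#' @param ko,wt Condition labels to contrast (numerator first).
#' @return Data frame with columns `symbol` and `score`, sorted.
#' @export
rank_genes <- function(expr, ko = "ko", wt = "wt") {
  grp <- attr(expr, "group")
  iko <- which(grp == ko); iwt <- which(grp == wt)
  if (length(iko) < 2L || length(iwt) < 2L) {
    stop("each condition needs >= 2 replicates for ranking")
  }
  mk <- rowMeans(expr[, iko, drop = FALSE])
  mw <- rowMeans(expr[, iwt, drop = FALSE])
  sk <- apply(expr[, iko, drop = FALSE], 1L, sd)
  sw <- apply(expr[, iwt, drop = FALSE], 1L, sd)
  floor_sd <- function(s, m) pmax(s, pmax(0.2 * abs(m), 0.2))
  score <- (mk - mw) / (floor_sd(sk, mk) + floor_sd(sw, mw))
  out <- data.frame(symbol = rownames(expr), score = unname(score),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$symbol), , drop = FALSE]
}

#' Running enrichment score of a gene set in a ranked list
#'
#' Walking down the ranked list, hitting a set member increments the running
#' sum proportionally to `|score|^weight_p` (normalized so hit increments sum
#' to 1) and a miss decrements it by `1/(N - Nh)`. The enrichment score is
#' the signed extremum of the running sum; the sum returns to 0 at the end
#' of the list.
#'
#' @param ranked Data frame from [rank_genes()] (columns `symbol`, `score`),
#'   or a named numeric vector of scores sorted in ranking order.
#' @param set A [gene_set()] or character vector of member symbols.
#' @param weight_p Hit-weight exponent (0 = classic Kolmogorov-Smirnov
#'   weighting, 1 = score-weighted; default 1).
#' @return List: `es`, `running` (length-N profile), `hits` (logical per
#'   rank), `n_hits`.
#' @export
running_es <- function(ranked, set, weight_p = 1) {
  if (is.numeric(ranked)) {
    ranked <- data.frame(symbol = names(ranked), score = unname(ranked),
                         stringsAsFactors = FALSE)
  }
  members <- if (inherits(set, "gene_set")) set$genes else
    unique(toupper(as.character(set)))
  hits <- toupper(ranked$symbol) %in% members
  running_es_hits(ranked$score, hits, weight_p)
}

# core running-sum computation on a precomputed hit indicator; shared with
# the permutation loop in gsea()
running_es_hits <- function(score, hits, weight_p = 1) {
  n <- length(hits)
  nh <- sum(hits)
  if (nh == 0L) stop("no gene-set member present in the ranked list")
  if (nh == n) stop("gene set covers the whole ranked list")
  w <- abs(score[hits])^weight_p
  if (sum(w) == 0) w <- rep(1, nh)  # degenerate all-zero scores
  step <- numeric(n)
  step[hits] <- w / sum(w)
  step[!hits] <- -1 / (n - nh)
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hits = hits, n_hits = nh)
}

#' GSEA-style gene-set enrichment with gene-set permutation
#'
#' Ranks genes by signal-to-noise ratio (or uses a supplied pre-ranked
#' list), computes each set's running enrichment score, and builds a
#' gene-set permutation null: each permutation draws a random gene set of
#' identical size from the ranked genes. `nes` is the observed ES divided by
#' the mean |ES| of same-sign permutations, `p_nominal` the fraction of
#' same-sign permutation ES at least as extreme, and `fdr` a ratio-of-tails
#' q-value over the set collection using the pooled permuted |NES|
#' distribution (clipped to [0, 1]).
#'
#' @param expr An [expression_matrix()]; ignored when `ranked` is given.
#' @param sets List of [gene_set()] objects.
#' @param n_perm Number of gene-set permutations (default 1000; < 100 warns).
#' @param seed Optional RNG seed; fixed seed gives bit-reproducible results.
#' @param weight_p Hit-weight exponent, see [running_es()].
#' @param ranked Optional pre-ranked data frame (columns `symbol`, `score`).
#' @return A `gsea_result` data frame: name, size, es, nes, p_nominal, fdr.
#' @export
gsea <- function(expr = NULL, sets, n_perm = 1000L, seed = NULL,
                 weight_p = 1, ranked = NULL) {
  if (n_perm < 100L) warning("n_perm < 100 gives unstable permutation p-values")
  if (is.null(ranked)) ranked <- rank_genes(expr)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ranked)
  symbols <- toupper(ranked$symbol)
  obs <- lapply(sets, function(s) {
    members <- intersect(if (inherits(s, "gene_set")) s$genes else
      toupper(s), symbols)
    if (!length(members)) return(NULL)
    r <- running_es_hits(ranked$score, symbols %in% members, weight_p)
    list(name = if (inherits(s, "gene_set")) s$name else "set",
         size = length(members), es = r$es)
  })
  keep <- !vapply(obs, is.null, logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " gene set(s) with no ranked member skipped")
  }
  obs <- obs[keep]
  sizes <- unique(vapply(obs, `[[`, numeric(1), "size"))
  # permutation ES per distinct set size (sets of equal size share a null)
  perm_by_size <- lapply(sizes, function(sz) {
    vapply(seq_len(n_perm), function(i) {
      hits <- logical(n)
      hits[sample.int(n, sz)] <- TRUE
      running_es_hits(ranked$score, hits, weight_p)$es
    }, numeric(1))
  })
  names(perm_by_size) <- as.character(sizes)
  res <- lapply(obs, function(o) {
    perm <- perm_by_size[[as.character(o$size)]]
    same <- perm[sign(perm) == sign(o$es)]
    if (length(same)) {
      nes <- o$es / mean(abs(same))
      p <- sum(abs(same) >= abs(o$es)) / length(same)
    } else {
      nes <- o$es / mean(abs(perm))
      p <- 1 / n_perm  # reported bound: no same-sign permutation observed
    }
    data.frame(name = o$name, size = o$size, es = o$es, nes = nes,
               p_nominal = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  # ratio-of-tails FDR over the collection: pooled sign-normalized permuted
  # |NES| vs observed |NES|
  norm_perm <- function(perm) {
    mpos <- mean(perm[perm > 0]); mneg <- mean(abs(perm[perm < 0]))
    ifelse(perm > 0, perm / mpos, ifelse(perm < 0, perm / mneg, 0))
  }
  pooled <- abs(unlist(lapply(
    perm_by_size[as.character(vapply(obs, `[[`, numeric(1), "size"))],
    norm_perm)))
  out$fdr <- vapply(out$nes, function(nes) {
    num <- mean(pooled >= abs(nes))
    den <- mean(abs(out$nes) >= abs(nes))
    min(1, max(0, num / den))
  }, numeric(1))
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  attr(out, "n_perm") <- n_perm
  out
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("GSEA (gene-set permutation, n_perm = ", attr(x, "n_perm"), ")\n",
      sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
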