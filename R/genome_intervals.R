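# Interval arithmetic over peak sets: pairing between samples, read counting,
# genomic compartment classification, nearest-TSS gene assignment, Venn-style
# multi-set overlap, and grouping of target genes by binding location.
# Overlap detection is delegated to IRanges; the matching and classification
# logic on top is specific to this pipeline.

#' Compartment window configuration
#'
#' Promoter windows are expressed as half-open offset ranges `[lo, hi)`
#' relative to the TSS in the direction of transcription (negative =
#' upstream). Defaults: distal promoter -10 kb to -4 kb, proximal promoter
#' -4 kb to +2 kb.
#'
#' @param distal_promoter_window,proximal_promoter_window Length-2 numeric
#'   offset ranges.
#' @return A `compartment_config` list.
#' @export
compartment_config <- function(distal_promoter_window = c(-10000, -4000),
                               proximal_promoter_window = c(-4000, 2000)) {
  stopifnot(length(distal_promoter_window) == 2L,
            length(proximal_promoter_window) == 2L,
            distal_promoter_window[1] < distal_promoter_window[2],
            proximal_promoter_window[1] < proximal_promoter_window[2])
  structure(list(distal_promoter_window = as.numeric(distal_promoter_window),
                 proximal_promoter_window = as.numeric(proximal_promoter_window)),
            class = "compartment_config")
}

COMPARTMENT_LEVELS <- c("proximal_promoter", "distal_promoter", "exon",
                        "intron", "intergenic")

# anchor position of each peak: summit when present, else interval midpoint
peak_anchor <- function(peaks) {
  ifelse(is.na(peaks$summit), floor((peaks$start + peaks$end) / 2),
         peaks$summit)
}

# all overlapping index pairs between two interval frames, with overlap width
overlap_pairs <- function(a, b, min_overlap_bp = 1L) {
  res <- list()
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    hits <- IRanges::findOverlaps(ra, rb, minoverlap = min_overlap_bp)
    if (!length(hits)) next
    qa <- ia[S4Vectors::queryHits(hits)]
    qb <- ib[S4Vectors::subjectHits(hits)]
    ov <- pmin(a$end[qa], b$end[qb]) - pmax(a$start[qa], b$start[qb])
    res[[chr]] <- data.frame(idx_a = qa, idx_b = qb, overlap_bp = ov)
  }
  if (!length(res)) {
    return(data.frame(idx_a = integer(), idx_b = integer(),
                      overlap_bp = numeric()))
  }
  do.call(rbind, unname(res))
}

#' Pair peaks between two samples
#'
#' A peak pair is *common* iff the intervals overlap by at least
#' `min_overlap_bp`. Each peak of `a` is matched one-to-one to the unmatched
#' peak of `b` with maximal overlap (ties: leftmost `b` peak); peaks left
#' unmatched are sample-unique.
#'
#' @param a,b [peak_set()] objects.
#' @param min_overlap_bp Minimum overlap in bp (>= 1).
#' @return A `peak_pairing` list: `common_pairs` (data frame `idx_a`,
#'   `idx_b`, `overlap_bp`), `unique_a`, `unique_b` (row indices), plus the
#'   two input sets.
#' @export
pair_peaks <- function(a, b, min_overlap_bp = 1L) {
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  cand <- overlap_pairs(a, b, min_overlap_bp)
  # greedy one-to-one: A peaks in catalog order; per A peak prefer maximal
  # overlap, then leftmost B
  ord <- order(cand$idx_a, -cand$overlap_bp, b$start[cand$idx_b],
               cand$idx_b)
  cand <- cand[ord, , drop = FALSE]
  matched_b <- logical(nrow(b))
  pair_a <- integer(); pair_b <- integer(); pair_ov <- numeric()
  if (nrow(cand)) {
    by_a <- split(seq_len(nrow(cand)), cand$idx_a)
    for (rows in by_a) {
      for (r in rows) {
        jb <- cand$idx_b[r]
        if (!matched_b[jb]) {
          matched_b[jb] <- TRUE
          pair_a <- c(pair_a, cand$idx_a[r])
          pair_b <- c(pair_b, jb)
          pair_ov <- c(pair_ov, cand$overlap_bp[r])
          break
        }
      }
    }
  }
  structure(list(
    common_pairs = data.frame(idx_a = pair_a, idx_b = pair_b,
                              overlap_bp = pair_ov),
    unique_a = setdiff(seq_len(nrow(a)), pair_a),
    unique_b = which(!matched_b),
    a = a, b = b, min_overlap_bp = min_overlap_bp
  ), class = "peak_pairing")
}

#' @export
print.peak_pairing <- function(x, ...) {
  cat("Peak pairing: ", nrow(x$common_pairs), " common pairs, ",
      length(x$unique_a), " unique to A, ", length(x$unique_b),
      " unique to B (min overlap ", x$min_overlap_bp, " bp)\n", sep = "")
  invisible(x)
}

#' Count reads in regions by shifted midpoint
#'
#' A read is assigned to a region iff its strand-shifted midpoint (midpoint
#' `+ shift_bp` on the + strand, `- shift_bp` on the - strand) lies within
#' `[start, end)` of the region.
#'
#' @param reads Data frame with columns chrom, start, end, strand (see
#'   [read_bed_intervals()]).
#' @param regions A [peak_set()] or interval data frame.
#' @param shift_bp Non-negative shift toward the fragment center.
#' @return Integer vector of counts aligned to `regions` rows.
#' @export
count_reads_in_regions <- function(reads, regions, shift_bp = 0L) {
  if (shift_bp < 0L) stop("shift_bp must be >= 0")
  counts <- integer(nrow(regions))
  if (!nrow(reads)) return(counts)
  mid <- floor((reads$start + reads$end) / 2)
  pos <- ifelse(reads$strand == "-", mid - shift_bp, mid + shift_bp)
  for (chr in intersect(unique(regions$chrom), unique(reads$chrom))) {
    ir <- which(regions$chrom == chr)
    ip <- pos[reads$chrom == chr]
    rr <- IRanges::IRanges(start = regions$start[ir] + 1L,
                           end = regions$end[ir])
    rp <- IRanges::IRanges(start = ip + 1L, width = 1L)
    counts[ir] <- counts[ir] + IRanges::countOverlaps(rr, rp)
  }
  counts
}

# per-gene promoter window in genomic half-open coordinates [start, end)
promoter_windows <- function(annotation, window) {
  lo <- window[1]; hi <- window[2]
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss + lo, annotation$tss - hi + 1)
  end <- ifelse(plus, annotation$tss + hi, annotation$tss - lo + 1)
  data.frame(chrom = annotation$chrom, start = pmax(start, 0), end = end)
}

# which anchors (chrom/pos) fall in any of the given half-open windows
anchor_in_windows <- function(chrom, pos, windows) {
  hit <- logical(length(pos))
  for (chr in intersect(unique(chrom), unique(windows$chrom))) {
    ia <- which(chrom == chr)
    iw <- which(windows$chrom == chr)
    ra <- IRanges::IRanges(start = pos[ia] + 1L, width = 1L)
    rw <- IRanges::IRanges(start = windows$start[iw] + 1L,
                           end = windows$end[iw])
    hit[ia] <- hit[ia] | IRanges::overlapsAny(ra, rw)
  }
  hit
}

#' Classify peaks by genomic compartment
#'
#' Each peak is represented by its anchor (summit if present, else midpoint)
#' and assigned exactly one label with precedence proximal_promoter >
#' distal_promoter > exon > intron > intergenic. Promoter windows are
#' strand-oriented (negative offsets = upstream of the TSS in the direction
#' of transcription); intergenic is everything outside the defined regions.
#'
#' @param peaks A [peak_set()].
#' @param annotation A [gene_annotation()].
#' @param config A [compartment_config()].
#' @return Factor of compartment labels aligned to `peaks` rows.
#' @export
classify_compartment <- function(peaks, annotation,
                                 config = compartment_config()) {
  anchor <- peak_anchor(peaks)
  prox <- anchor_in_windows(peaks$chrom, anchor,
                            promoter_windows(annotation,
                                             config$proximal_promoter_window))
  dist <- anchor_in_windows(peaks$chrom, anchor,
                            promoter_windows(annotation,
                                             config$distal_promoter_window))
  exons <- data.frame(
    chrom = rep(annotation$chrom, lengths(annotation$exon_starts)),
    start = unlist(annotation$exon_starts),
    end = unlist(annotation$exon_ends)
  )
  in_exon <- anchor_in_windows(peaks$chrom, anchor, exons)
  bodies <- data.frame(chrom = annotation$chrom, start = annotation$tx_start,
                       end = annotation$tx_end)
  in_body <- anchor_in_windows(peaks$chrom, anchor, bodies)
  lab <- rep("intergenic", nrow(peaks))
  lab[in_body] <- "intron"
  lab[in_exon] <- "exon"
  lab[dist] <- "distal_promoter"
  lab[prox] <- "proximal_promoter"
  factor(lab, levels = COMPARTMENT_LEVELS)
}

#' Genome-wide compartment distribution of a peak set
#'
#' @inheritParams classify_compartment
#' @return List with `counts` and `fractions` (named by compartment;
#'   fractions sum to 1).
#' @export
compartment_distribution <- function(peaks, annotation,
                                     config = compartment_config()) {
  if (!nrow(peaks)) stop("empty peak set")
  lab <- classify_compartment(peaks, annotation, config)
  counts <- table(lab)
  list(counts = counts, fractions = counts / sum(counts))
}

#' Nearest gene by TSS distance
#'
#' Returns, per peak, the symbol of the gene whose TSS is closest to the
#' peak anchor; ties go to the lexicographically smaller symbol. Peaks on a
#' chromosome with no annotated gene receive the sentinel `"unassigned"`.
#'
#' @inheritParams classify_compartment
#' @return List with `symbol` (character per peak) and `distance` (absolute
#'   anchor-to-TSS distance, `NA` when unassigned).
#' @export
nearest_gene <- function(peaks, annotation) {
  anchor <- peak_anchor(peaks)
  symbol <- rep("unassigned", nrow(peaks))
  distance <- rep(NA_real_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    ip <- which(peaks$chrom == chr)
    ig <- which(annotation$chrom == chr)
    if (!length(ig)) next
    tss <- annotation$tss[ig]
    syms <- annotation$symbol[ig]
    # exhaustive per-chromosome scan; annotations here are small enough
    for (i in ip) {
      d <- abs(anchor[i] - tss)
      dmin <- min(d)
      cand <- syms[d == dmin]
      symbol[i] <- min(cand)
      distance[i] <- dmin
    }
  }
  n_un <- sum(symbol == "unassigned")
  if (n_un) message(n_un, " peak(s) on chromosomes without genes: unassigned")
  list(symbol = symbol, distance = distance)
}

#' Map peaks to their target genes
#'
#' The target set of a peak catalog: the union of nearest-TSS genes over all
#' peaks, excluding unassigned peaks.
#'
#' @inheritParams classify_compartment
#' @return Character vector of unique gene symbols (upper case).
#' @export
map_peaks_to_targets <- function(peaks, annotation) {
  if (!nrow(peaks)) return(character())
  ng <- nearest_gene(peaks, annotation)
  sort(unique(ng$symbol[ng$symbol != "unassigned"]))
}

#' Venn-style overlap partition of 2-3 peak sets
#'
#' For every peak of every set, membership records which *other* sets it
#' overlaps by at least `min_overlap_bp`. Counts are reported per set and
#' per membership combination, so each set's counts sum to its size (a peak
#' can overlap several peaks of another set but is counted once).
#'
#' @param sets Named list of 2 or 3 [peak_set()] objects.
#' @param min_overlap_bp Minimum overlap in bp.
#' @return A `venn_overlap` object: named list (per set) of named count
#'   vectors, combination labels like `"A"`, `"A&B"`.
#' @export
venn_overlap <- function(sets, min_overlap_bp = 1L) {
  if (length(sets) < 2L || length(sets) > 3L) stop("need 2 or 3 peak sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  nm <- names(sets)
  out <- list()
  for (i in seq_along(sets)) {
    member <- matrix(FALSE, nrow(sets[[i]]), length(sets))
    member[, i] <- TRUE
    for (j in seq_along(sets)) {
      if (j == i) next
      op <- overlap_pairs(sets[[i]], sets[[j]], min_overlap_bp)
      member[unique(op$idx_a), j] <- TRUE
    }
    combo <- apply(member, 1L, function(m) paste(nm[m], collapse = "&"))
    out[[nm[i]]] <- table(factor(combo, levels = unique(c(
      nm[i], sort(unique(combo))))))
  }
  structure(out, class = "venn_overlap", min_overlap_bp = min_overlap_bp)
}

#' @export
print.venn_overlap <- function(x, ...) {
  cat("Venn overlap partition (min overlap ", attr(x, "min_overlap_bp"),
      " bp)\n", sep = "")
  for (nm in names(x)) {
    cat("  set ", nm, " (n=", sum(x[[nm]]), "): ",
        paste(names(x[[nm]]), as.integer(x[[nm]]), sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Group target genes by binding location
#'
#' Each peak is assigned to its nearest-TSS gene; relative to that gene the
#' peak is a *promoter* peak if its anchor lies in the gene's proximal
#' promoter window and a *distal* peak otherwise. Target genes are then
#' partitioned into three disjoint groups: bound at both distal and promoter
#' positions, distal only, promoter only.
#'
#' @inheritParams classify_compartment
#' @return A `target_groups` list with character vectors
#'   `distal_and_promoter`, `distal_only`, `promoter_only`.
#' @export
group_targets_by_location <- function(peaks, annotation,
                                      config = compartment_config()) {
  empty <- structure(list(distal_and_promoter = character(),
                          distal_only = character(),
                          promoter_only = character()),
                     class = "target_groups")
  if (!nrow(peaks)) return(empty)
  ng <- nearest_gene(peaks, annotation)
  keep <- ng$symbol != "unassigned"
  if (!any(keep)) return(empty)
  anchor <- peak_anchor(peaks)[keep]
  sym <- ng$symbol[keep]
  gi <- match(sym, annotation$symbol)
  # signed offset of the anchor from the gene's TSS, in transcription
  # direction
  off <- ifelse(annotation$strand[gi] == "+",
                anchor - annotation$tss[gi],
                annotation$tss[gi] - anchor)
  w <- config$proximal_promoter_window
  is_prom <- off >= w[1] & off < w[2]
  has_prom <- tapply(is_prom, sym, any)
  has_dist <- tapply(!is_prom, sym, any)
  genes <- names(has_prom)
  structure(list(
    distal_and_promoter = sort(genes[has_prom & has_dist]),
    distal_only = sort(genes[!has_prom & has_dist]),
    promoter_only = sort(genes[has_prom & !has_dist])
  ), class = "target_groups")
}

#' @export
print.target_groups <- function(x, ...) {
  cat("Target genes by binding location:\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", length(x[[nm]]), " genes\n", sep = "")
  }
  invisible(x)
}

#' Annotated-peak table
#'
#' Convenience export: per peak, its anchor, compartment, nearest gene and
#' TSS distance.
#'
#' @inheritParams classify_compartment
#' @return Data frame with columns chrom, start, end, anchor, compartment,
#'   nearest_gene, distance_to_tss.
#' @export
annotate_peaks <- function(peaks, annotation, config = compartment_config()) {
  ng <- nearest_gene(peaks, annotation)
  data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             anchor = peak_anchor(peaks),
             compartment = classify_compartment(peaks, annotation, config),
             nearest_gene = ng$symbol, distance_to_tss = ng$distance,
             stringsAsFactors = FALSE)
}
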