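test_that("pair_peaks applies the overlap criterion and one-to-one matching", {
  a <- peak_set("chr1", 100, 200, sample_label = "a")
  b <- peak_set("chr1", 150, 250, sample_label = "b")
  pp <- pair_peaks(a, b)
  expect_equal(nrow(pp$common_pairs), 1L)
  expect_length(pp$unique_a, 0L)

  # half-open intervals: touching peaks do not overlap
  b2 <- peak_set("chr1", 200, 300)
  pp2 <- pair_peaks(a, b2)
  expect_equal(nrow(pp2$common_pairs), 0L)
  expect_equal(pp2$unique_a, 1L)
  expect_equal(pp2$unique_b, 1L)

  # maximal-overlap choice: [0,100) overlaps [10,40) by 30 and [50,90) by 40
  a3 <- peak_set("chr1", 0, 100)
  b3 <- peak_set("chr1", c(10, 50), c(40, 90))
  pp3 <- pair_peaks(a3, b3)
  expect_equal(pp3$common_pairs$idx_b, which(b3$start == 50))
  expect_equal(pp3$common_pairs$overlap_bp, 40)
  expect_equal(b3$start[pp3$unique_b], 10)

  expect_error(pair_peaks(a, b, min_overlap_bp = 0), "min_overlap_bp")
})

test_that("pairing matches the quadratic oracle and partitions both sets", {
  set.seed(71)
  for (rep in 1:25) {
    a <- random_peaks(sample(5:80, 1))
    b <- random_peaks(sample(5:80, 1))
    mo <- sample(c(1L, 20L), 1)
    pp <- pair_peaks(a, b, mo)
    or <- oracle_pair(a, b, mo)
    if (is.null(or$pairs)) {
      expect_equal(nrow(pp$common_pairs), 0L)
    } else {
      expect_equal(pp$common_pairs[order(pp$common_pairs$idx_a), ],
                   or$pairs[order(or$pairs$idx_a), ],
                   ignore_attr = TRUE)
    }
    expect_setequal(pp$unique_a, or$unique_a)
    expect_setequal(pp$unique_b, or$unique_b)
    # partition invariant
    expect_equal(nrow(pp$common_pairs) + length(pp$unique_a), nrow(a))
    expect_equal(nrow(pp$common_pairs) + length(pp$unique_b), nrow(b))
  }
})

test_that("count_reads_in_regions counts strand-shifted midpoints", {
  regions <- peak_set("chr1", 100, 200)
  mk_reads <- function(mid, strand = "+") {
    data.frame(chrom = "chr1", start = mid - 18, end = mid + 18,
               strand = strand)
  }
  expect_equal(count_reads_in_regions(mk_reads(c(100, 120, 150, 180, 199)),
                                      regions), 5L)
  # half-open: a midpoint exactly at end is outside
  expect_equal(count_reads_in_regions(mk_reads(200), regions), 0L)
  # shift moves the + strand midpoint downstream into the region
  expect_equal(count_reads_in_regions(mk_reads(150),
                                      peak_set("chr1", 200, 300),
                                      shift_bp = 100), 1L)
  # - strand shifts upstream
  expect_equal(count_reads_in_regions(mk_reads(250, "-"),
                                      peak_set("chr1", 100, 200),
                                      shift_bp = 100), 1L)
  expect_equal(count_reads_in_regions(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character()), regions), 0L)
  expect_error(count_reads_in_regions(mk_reads(150), regions, -1), "shift")
})

test_that("compartment classification is strand-oriented with precedence", {
  ann <- tiny_annotation()  # + strand TSS 100000; - strand TSS 311999
  at <- function(pos) peak_set("chr1", pos - 50, pos + 50, summit = pos)
  cls <- function(pos) as.character(classify_compartment(at(pos), ann))

  expect_equal(cls(97000), "proximal_promoter")   # offset -3000, + strand
  expect_equal(cls(91000), "distal_promoter")     # offset -9000, + strand
  expect_equal(cls(311999 + 3000), "proximal_promoter")  # - strand upstream
  expect_equal(cls(311999 + 9000), "distal_promoter")
  expect_equal(cls(104500), "exon")  # beyond the +2 kb promoter edge
  expect_equal(cls(103000), "intron")
  expect_equal(cls(2000000), "intergenic")
  # proximal wins over the - strand gene's exon at the TSS itself
  expect_equal(cls(311000), "proximal_promoter")
})

test_that("every anchor near a gene is labeled and labels are exclusive", {
  ann <- tiny_annotation()
  pos <- seq(90000, 110000 - 1, by = 97)
  labs <- classify_compartment(
    peak_set("chr1", pos - 10, pos + 10, summit = pos), ann)
  expect_false(anyNA(labs))
  expect_false(any(labs == "intergenic"))  # all within [TSS-10kb, tx_end)
})

test_that("compartment_distribution returns fractions summing to one", {
  ann <- tiny_annotation()
  pos <- c(97000, 91000, 104500, 103000, 2000000, 3000000)
  ps <- peak_set("chr1", pos - 50, pos + 50, summit = pos)
  cd <- compartment_distribution(ps, ann)
  expect_equal(sum(cd$fractions), 1, tolerance = 1e-9)
  expect_equal(as.numeric(cd$counts[c("intergenic", "exon")]), c(2, 1))
  expect_error(compartment_distribution(ps[0, ], ann), "empty")
})

test_that("nearest_gene minimizes TSS distance with lexicographic ties", {
  ann <- gene_annotation(name = c("gB", "gA"), chrom = "chr1",
                         strand = c("+", "+"), tx_start = c(1000, 7000),
                         tx_end = c(2000, 9000))
  at <- function(pos) peak_set("chr1", pos, pos + 1)
  expect_equal(nearest_gene(at(3000), ann)$symbol, "GB")   # 2000 < 4000
  expect_equal(nearest_gene(at(4000), ann)$symbol, "GA")   # tie at 3000
  ps_other <- peak_set("chrX", 5, 10)
  expect_message(ng <- nearest_gene(ps_other, ann), "unassigned")
  expect_equal(ng$symbol, "unassigned")
  expect_true(is.na(ng$distance))
})

test_that("nearest_gene distance is minimal against an exhaustive scan", {
  set.seed(5)
  ann <- generate_annotation(sim_params(n_genes = 80L, chrom_length = 80 * 30000,
                                        n_diff_ko = 10L, n_diff_wt = 10L,
                                        signature_size = 20L), seed = 5)
  ps <- random_peaks(60, max_pos = 80 * 30000 - 400, chroms = "chrS")
  ng <- nearest_gene(ps, ann)
  anchor <- floor((ps$start + ps$end) / 2)
  for (i in seq_len(nrow(ps))) {
    expect_equal(ng$distance[i], min(abs(anchor[i] - ann$tss)))
  }
})

test_that("map_peaks_to_targets unions nearest genes", {
  ann <- tiny_annotation()
  ps <- peak_set("chr1", c(99000, 101000, 105000), c(99100, 101100, 105100))
  expect_equal(map_peaks_to_targets(ps, ann), "APLUS")
  expect_equal(map_peaks_to_targets(ps[0, ], ann), character())
})

test_that("differential peaks in the simulator map to their truth targets", {
  sim <- small_sim()
  tr <- sim$experiment$truth
  diff_ko <- tr$region[tr$region$truth == "true_ko_specific", ]
  ps <- peak_set(diff_ko$chrom, diff_ko$start, diff_ko$end,
                 summit = diff_ko$summit)
  expect_setequal(map_peaks_to_targets(ps, sim$annotation), tr$ko_targets)
})

test_that("venn_overlap counts match the quadratic membership oracle", {
  A <- peak_set("chr1", 0, 100)
  B <- peak_set("chr1", 50, 150)
  vo <- venn_overlap(list(A = A, B = B))
  expect_equal(as.integer(vo$A["A&B"]), 1L)
  expect_equal(sum(vo$A), 1L)

  D <- peak_set("chr1", 1000, 1100)
  vo2 <- venn_overlap(list(A = A, D = D))
  expect_equal(as.integer(vo2$A["A"]), 1L)
  expect_equal(as.integer(vo2$D["D"]), 1L)

  expect_error(venn_overlap(list(A)), "2 or 3")

  set.seed(31)
  for (rep in 1:10) {
    sets <- list(A = random_peaks(40), B = random_peaks(40),
                 C = random_peaks(40))
    vo <- venn_overlap(sets)
    om <- oracle_venn_membership(sets)
    for (i in seq_along(sets)) {
      otab <- table(om[[i]])
      expect_equal(sum(vo[[i]]), nrow(sets[[i]]))
      for (combo in names(otab)) {
        expect_equal(as.integer(vo[[i]][combo]),
                     as.integer(otab[combo]), label = combo)
      }
    }
  }
})

test_that("target genes partition into distal/promoter binding groups", {
  ann <- tiny_annotation()
  # APLUS: one proximal-promoter peak (offset -3000) and one distal peak
  # 50 kb upstream but still nearest to APLUS; BMINUS: promoter peak only
  ps <- peak_set("chr1", c(96950, 49950, 314950), c(97050, 50050, 315050),
                 summit = c(97000, 50000, 315000))
  tg <- group_targets_by_location(ps, ann)
  expect_equal(tg$distal_and_promoter, "APLUS")
  expect_equal(tg$promoter_only, "BMINUS")
  expect_length(tg$distal_only, 0L)
  # disjoint partition covering all targets
  all_targets <- map_peaks_to_targets(ps, ann)
  expect_setequal(unlist(tg), all_targets)
  expect_equal(anyDuplicated(unlist(tg)), 0L)
})
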