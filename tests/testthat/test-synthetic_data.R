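test_that("sim_params validates its stated world", {
  p <- sim_params()
  expect_equal(p$n_common, 2000L)
  expect_equal(c(p$c0, p$c1, p$noise_sd, p$delta_m), c(0.4, 0.1, 0.3, 2.5))
  expect_error(sim_params(n_genes = 1000, chrom_length = 1e6),
               "infeasible")
  expect_error(sim_params(rho = 0.5), "rho")
  expect_error(sim_params(delta_m = 0), "delta_m")
  expect_error(sim_params(signature_size = 5000), "signature_size")
})

test_that("generate_annotation builds a deterministic, well-formed annotation", {
  p <- sim_params(n_genes = 100L, chrom_length = 1e7, n_diff_ko = 10L,
                  n_diff_wt = 10L, signature_size = 30L)
  a1 <- generate_annotation(p, seed = 4)
  a2 <- generate_annotation(p, seed = 4)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 100L)
  expect_equal(a1$name, sprintf("G%04d", 1:100))
  expect_true(all(a1$strand %in% c("+", "-")))
  # non-overlapping bodies, exons inside the transcript, TSS convention
  expect_true(all(head(a1$tx_end, -1) <= tail(a1$tx_start, -1)))
  for (i in seq_len(nrow(a1))) {
    expect_gte(a1$exon_starts[[i]][1], a1$tx_start[i])
    expect_lte(max(a1$exon_ends[[i]]), a1$tx_end[i])
    expect_true(length(a1$exon_starts[[i]]) %in% 2:5)
  }
  expect_equal(a1$tss,
               ifelse(a1$strand == "+", a1$tx_start, a1$tx_end - 1))
  # the full promoter footprint of every gene stays on the chromosome
  expect_true(all(a1$tss - 10000 >= 0 | a1$strand == "-"))
})

test_that("the peak experiment realizes the latent M-on-A law", {
  p <- sim_params(n_genes = 150L, chrom_length = 150 * 30000,
                  n_common = 200L, n_diff_ko = 20L, n_diff_wt = 20L,
                  noise_sd = 0, signature_size = 30L)
  ann <- generate_annotation(p, seed = 8)
  ex <- generate_peak_experiment(p, ann, seed = 8)
  reg <- ex$truth$region

  # construction-level: with zero noise the latent raw M of null-common
  # regions lies exactly on c0 + c1 * A
  null_rows <- reg$truth == "null_common"
  expect_equal(reg$m_true[null_rows],
               p$c0 + p$c1 * reg$a_true[null_rows], tolerance = 1e-12)
  # differential regions are shifted by exactly +/- delta_m
  expect_equal(reg$m_true[reg$truth == "true_ko_specific"],
               p$c0 + p$c1 * reg$a_true[reg$truth == "true_ko_specific"] +
                 p$delta_m, tolerance = 1e-12)
  # label consistency at zero noise: KO density exceeds wt at KO-specific
  # regions
  expect_true(all(reg$count_ko[reg$truth == "true_ko_specific"] >
                    reg$count_wt[reg$truth == "true_ko_specific"]))
  # catalogs: KO carries common + KO-differential, wt the mirror
  expect_equal(nrow(ex$ko), p$n_common + p$n_diff_ko)
  expect_equal(nrow(ex$wt), p$n_common + p$n_diff_wt)
  # determinism
  ex2 <- generate_peak_experiment(p, ann, seed = 8)
  expect_identical(ex$counts, ex2$counts)
  # regions are mutually disjoint, so counting and pairing stay exact
  reg_sorted <- reg[order(reg$start), ]
  expect_true(all(head(reg_sorted$end, -1) <= tail(reg_sorted$start, -1)))
})

test_that("generate_reads round-trips region counts exactly", {
  counts <- data.frame(chrom = "chrS", start = c(1000, 5000, 9000),
                       end = c(2000, 6200, 9600),
                       count_ko = c(7L, 0L, 13L))
  reads <- generate_reads(counts, "count_ko", seed = 12)
  expect_equal(nrow(reads), 20L)
  got <- count_reads_in_regions(reads, counts)
  expect_equal(got, counts$count_ko)
  empty <- generate_reads(transform(counts, count_ko = 0L), "count_ko")
  expect_equal(nrow(empty), 0L)
})

test_that("signatures are enriched for KO targets in proportion to rho", {
  sim <- small_sim()
  sig <- sim$signatures$SYNTH_KO_SIGNATURE
  ctrl <- sim$signatures$SYNTH_CONTROL_SIGNATURE
  targets <- sim$experiment$truth$ko_targets
  frac_sig <- mean(sig$genes %in% targets)
  frac_ctrl <- mean(ctrl$genes %in% targets)
  expect_gt(frac_sig, 2 * frac_ctrl)
  expect_length(sig$genes, sim$params$signature_size)
  # determinism under an explicit seed
  s1 <- generate_signature(sim$experiment$truth, sim$annotation,
                           sim$params, seed = 77)
  s2 <- generate_signature(sim$experiment$truth, sim$annotation,
                           sim$params, seed = 77)
  expect_identical(s1, s2)
})

test_that("expression carries the KO-target effect with seeded determinism", {
  sim <- small_sim()
  expr <- sim$expression
  p <- sim$params
  expect_equal(dim(expr), c(p$n_genes, 2L * p$n_reps))
  expect_equal(attr(expr, "group"), rep(c("wt", "ko"), each = p$n_reps))
  grp <- attr(expr, "group")
  ratio <- rowMeans(unclass(expr)[, grp == "ko"]) -
    rowMeans(unclass(expr)[, grp == "wt"])
  is_target <- rownames(expr) %in% sim$experiment$truth$ko_targets
  expect_equal(mean(ratio[is_target]), p$beta, tolerance = 0.15)
  expect_equal(mean(ratio[!is_target]), 0, tolerance = 0.1)

  e1 <- generate_expression(sim$experiment$truth, sim$annotation,
                            sim$params, seed = 5)
  e2 <- generate_expression(sim$experiment$truth, sim$annotation,
                            sim$params, seed = 5)
  expect_identical(e1, e2)
})

test_that("simulate_experiment is fully deterministic under its master seed", {
  p <- sim_params(n_genes = 60L, chrom_length = 60 * 30000, n_common = 80L,
                  n_diff_ko = 10L, n_diff_wt = 10L, signature_size = 20L,
                  seed = 314L)
  s1 <- simulate_experiment(p)
  s2 <- simulate_experiment(p)
  expect_identical(s1, s2)
})
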