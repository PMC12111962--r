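make_rankings <- function(G, n_tools = 3, seed = 1, identical_order = FALSE) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(G))
  shared <- rnorm(G)
  lapply(seq_len(n_tools), function(t)
    ranking_table(paste0("tool", t), genes,
                  if (identical_order) shared else rnorm(G)))
}

test_that("top decile uses the ceiling and breaks ties lexicographically", {
  r100 <- make_rankings(100)[[1]]
  expect_length(top_decile(r100), 10)
  r25 <- make_rankings(25)[[1]]
  expect_length(top_decile(r25), 3)     # ceiling(2.5)
  ## two genes tied at the cutoff score: lexicographically smaller included
  r <- ranking_table("t", c("B", "A", "C"), c(1, 0.5, 0.5))
  expect_equal(top_decile(r, 2 / 3), c("B", "A"))
  expect_error(top_decile(r, 0), "fraction")
})

test_that("joint detection enumerates membership counts", {
  s <- c("a", "b", "c")
  expect_equal(joint_detection(list(s, s, s), 2), s)
  expect_equal(joint_detection(list(c("a"), c("b"), c("c")), 2), character(0))
  expect_equal(joint_detection(list(c("a", "b"), c("b", "c"), c("c", "d")), 2),
               c("b", "c"))
  expect_error(joint_detection(list(s), 2), "min_tools")
})

test_that("coincidence test: concordant rankings give the floor p-value", {
  rk <- make_rankings(200, identical_order = TRUE)
  res <- multi_tool_coincidence_test(rk, B = 999, seed = 4)
  expect_equal(res$observed_stat, 20)
  ## no random resample of three 20-gene sets from 200 reaches 20 joint genes
  expect_lt(max(res$null_stats), 20)
  expect_equal(res$p_empirical, 1 / 1000)
})

test_that("coincidence test: disjoint deciles give p = 1", {
  genes <- sprintf("G%04d", 1:300)
  rk <- lapply(1:3, function(t) {
    score <- numeric(300)
    score[((t - 1) * 100 + 1):(t * 100)] <- 10   # each tool favors its own block
    ranking_table(paste0("tool", t), genes, score + seq(0.001, 0.3, length.out = 300))
  })
  res <- multi_tool_coincidence_test(rk, B = 200, seed = 2)
  expect_equal(res$observed_stat, 0)
  expect_equal(res$p_empirical, 1)
})

test_that("resampling nulls are reproducible under a fixed seed", {
  rk <- make_rankings(150, seed = 9)
  r1 <- multi_tool_coincidence_test(rk, B = 300, seed = 77)
  r2 <- multi_tool_coincidence_test(rk, B = 300, seed = 77)
  expect_identical(r1$null_stats, r2$null_stats)
  u <- sprintf("G%03d", 1:50)
  o1 <- cross_cohort_overlap_test(u[1:8], u[5:16], u, B = 300, seed = 5)
  o2 <- cross_cohort_overlap_test(u[1:8], u[5:16], u, B = 300, seed = 5)
  expect_identical(o1$null_stats, o2$null_stats)
})

test_that("overlap test matches its analytic expectation and bounds", {
  u <- sprintf("G%03d", 1:630)
  res <- cross_cohort_overlap_test(u[1:63], u[100:162], u, B = 500, seed = 1)
  expect_equal(res$expected_null, 63 * 63 / 630)
  ## A = B: observed = |A|, no null resample can exceed it in a universe >> |A|
  res2 <- cross_cohort_overlap_test(u[1:20], u[1:20], u, B = 999, seed = 3)
  expect_equal(res2$observed_overlap, 20)
  expect_equal(res2$p_empirical, 1 / 1000)
  ## disjoint sets covering the universe: observed 0, p = 1
  u10 <- u[1:10]
  res3 <- cross_cohort_overlap_test(u10[1:4], u10[5:10], u10, B = 200, seed = 2)
  expect_equal(res3$observed_overlap, 0)
  expect_equal(res3$p_empirical, 1)
  expect_error(cross_cohort_overlap_test(c("ZZZ"), u10[1:2], u10, B = 10),
               "subsets")
})

test_that("enlarging the true overlap never increases the empirical p", {
  u <- sprintf("G%03d", 1:100)
  p_at <- function(k) {
    A <- u[1:20]
    B <- c(u[seq_len(k)], u[50:(69 - k)])
    cross_cohort_overlap_test(A, B, u, B = 500, seed = 11)$p_empirical
  }
  ps <- vapply(c(0, 5, 10, 15, 20), p_at, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("Poisson recurrence ranker scores by upper-tail probability", {
  ## gene A: 10 nonsilent mutations at expectation 1 (rate 0.01/b * 100 b)
  somatic <- rbind(
    do.call(rbind, lapply(1:10, function(i)
      somatic_row(patient_id = sprintf("P%02d", i), gene = "A"))),
    somatic_row(patient_id = "P01", gene = "B", variant_class = "silent"))
  lens <- c(A = 100, B = 900)
  r <- recurrence_ranker(somatic, lens)
  expect_equal(r$score[r$gene == "A"], pois_tail_oracle(10, 1),
               tolerance = 1e-10)
  expect_equal(r$rank[r$gene == "A"], 1L)
  ## silent mutations do not count toward recurrence
  expect_equal(r$score[r$gene == "B"], 1)

  ## identical counts and lengths rank lexicographically
  somatic2 <- rbind(somatic_row(gene = "ZZ"), somatic_row(gene = "AA"))
  r2 <- recurrence_ranker(somatic2, c(ZZ = 100, AA = 100))
  expect_equal(r2$gene[order(r2$rank)], c("AA", "ZZ"))

  expect_error(recurrence_ranker(somatic_row(gene = "X"), c(Y = 10)),
               "missing a length")
})

test_that("planted drivers surface in the recurrence top decile", {
  for (s in 1:5) {
    cfg <- sim_config(n_patients = 200, n_genes = 300, mutation_rate = 100,
                      driver_genes = 10, driver_multiplier = 10, seed = s)
    co <- generate_cohort(cfg)
    r <- recurrence_ranker(co$somatic, co$truth$gene_lengths)
    expect_true(all(co$truth$drivers %in% top_decile(r)),
                info = paste("seed", s))
  }
})

test_that("subsample bias test resamples deterministically and validates m", {
  cfg <- sim_config(n_patients = 40, n_genes = 200, mutation_rate = 100,
                    driver_genes = 10, seed = 2)
  co <- generate_cohort(cfg)
  ref_list <- top_decile(recurrence_ranker(co$somatic, co$truth$gene_lengths))
  res <- subsample_bias_test(co$somatic, ref_list, co$truth$gene_lengths,
                             m = 10, B = 15, seed = 3,
                             observed_nonref = 0.5)
  expect_length(res$intersections, 15)
  expect_true(all(res$intersections <= length(ref_list)))
  expect_true(all(res$proportion_nonreference >= 0 &
                    res$proportion_nonreference <= 1))
  expect_equal(res$observed_quantile, mean(res$proportion_nonreference < 0.5))
  res2 <- subsample_bias_test(co$somatic, ref_list, co$truth$gene_lengths,
                              m = 10, B = 15, seed = 3)
  expect_identical(res$intersections, res2$intersections)
  expect_error(subsample_bias_test(co$somatic, ref_list,
                                   co$truth$gene_lengths, m = 40, B = 5),
               "smaller than the reference cohort")
})

test_that("ranking TSV IO validates the permutation property", {
  rk <- make_rankings(30, seed = 6)
  path <- tempfile(fileext = ".tsv")
  write_rankings_tsv(rk, path)
  back <- read_rankings_tsv(path)
  expect_length(back, 3)
  expect_equal(back[["tool1"]]$gene, rk[[1]]$gene)
  expect_equal(back[["tool2"]]$rank, rk[[2]]$rank)
  broken <- do.call(rbind, rk)
  broken$rank[1] <- 999L
  write.table(broken, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_rankings_tsv(path), "permutation")
})
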