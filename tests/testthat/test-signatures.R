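syn5 <- synthetic_signature_catalog(5)

test_that("synthetic catalog is a valid probability profile set", {
  expect_equal(dim(syn5), c(96L, 5L))
  expect_true(all(syn5 > 0))
  expect_equal(unname(colSums(syn5)), rep(1, 5))
  ## deterministic construction
  expect_identical(syn5, synthetic_signature_catalog(5))
})

test_that("COSMIC-format catalog IO round-trips, including the bundled file", {
  path <- tempfile(fileext = ".tsv")
  write_signature_catalog(syn5, path)
  expect_equal(read_signature_catalog(path), syn5, tolerance = 1e-12)
  bundled <- system.file("extdata", "synthetic_sbs96_catalog.tsv",
                         package = "oncocohort")
  expect_equal(read_signature_catalog(bundled), syn5, tolerance = 1e-12)
  ## malformed catalogs are rejected
  bad <- syn5; bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(write_signature_catalog(bad, path), "sum to 1")
})

test_that("NNLS refit recovers trivial and separable mixtures exactly", {
  ## K = 1: everything attributed to the single signature
  m <- matrix(rpois(96, 5), 1, dimnames = list("P001", sbs96_channels()))
  ex1 <- refit_exposures(m, syn5[, 1, drop = FALSE])
  expect_equal(unname(ex1$proportions[1, 1]), 1)

  ## two signatures with disjoint support, counts = 700 from sig1 + 300
  ## from sig2 -> proportions recovered exactly
  sigs <- matrix(0, 96, 2, dimnames = list(sbs96_channels(), c("s1", "s2")))
  sigs[1:10, 1] <- 1 / 10
  sigs[51:60, 2] <- 1 / 10
  counts <- matrix(0, 1, 96, dimnames = list("P001", sbs96_channels()))
  counts[1, 1:10] <- 70
  counts[1, 51:60] <- 30
  ex2 <- refit_exposures(counts, sigs)
  expect_equal(unname(ex2$exposures[1, ]), c(700, 300), tolerance = 1e-9)
  expect_equal(unname(ex2$proportions[1, ]), c(0.7, 0.3), tolerance = 1e-12)
})

test_that("all-zero patients get zero exposures and undefined proportions", {
  m <- matrix(0, 2, 96, dimnames = list(c("P001", "P002"), sbs96_channels()))
  m[2, 5] <- 10
  ex <- refit_exposures(m, syn5)
  expect_equal(ex$defined, c(P001 = FALSE, P002 = TRUE))
  expect_true(all(is.na(ex$proportions[1, ])))
  expect_equal(sum(ex$proportions[2, ]), 1, tolerance = 1e-9)
})

test_that("adding a signature column never increases the residual norm", {
  set.seed(5)
  m <- matrix(rpois(96, 20), 1, dimnames = list("P001", sbs96_channels()))
  resid_norm <- function(sigs) {
    ex <- refit_exposures(m, sigs)
    sqrt(sum((as.numeric(m) - as.numeric(sigs %*% ex$exposures[1, ]))^2))
  }
  r3 <- resid_norm(syn5[, 1:3])
  r4 <- resid_norm(syn5[, 1:4])
  r5 <- resid_norm(syn5)
  expect_lte(r4, r3 + 1e-9)
  expect_lte(r5, r4 + 1e-9)
})

test_that("refit error shrinks as per-patient mutation load grows", {
  err_at <- function(rate) {
    e <- numeric(3)
    for (s in 1:3) {
      cfg <- sim_config(n_patients = 10, n_genes = 100, mutation_rate = rate,
                        seed = s)
      co <- generate_cohort(cfg, syn5)
      ex <- refit_exposures(build_catalog(co$somatic,
                                          co$patients$patient_id), syn5)
      e[s] <- mean(rowSums(abs(ex$proportions - co$truth$exposures)))
    }
    mean(e)
  }
  e300 <- err_at(300); e3000 <- err_at(3000); e30000 <- err_at(30000)
  expect_lt(e3000, e300)
  expect_lt(e30000, e3000)
})

test_that("cohort summary averages proportions over defined patients", {
  pr <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("P001", "P002"), c("s1", "s2")))
  ex <- structure(list(exposures = pr * 10, proportions = pr,
                       defined = c(P001 = TRUE, P002 = TRUE)),
                  class = "exposure_table")
  expect_equal(cohort_signature_summary(ex), c(s1 = 0.5, s2 = 0.5))

  ## single patient: the summary is that patient's proportions
  ex1 <- structure(list(exposures = pr[1, , drop = FALSE] * 10,
                        proportions = pr[1, , drop = FALSE],
                        defined = c(P001 = TRUE)), class = "exposure_table")
  expect_equal(cohort_signature_summary(ex1), c(s1 = 1, s2 = 0))

  ## a zero-SNV patient is excluded: result identical to dropping them
  m <- matrix(0, 3, 96, dimnames = list(c("P001", "P002", "P003"),
                                        sbs96_channels()))
  m[1, 1:10] <- 5; m[2, 40:60] <- 7
  full <- cohort_signature_summary(refit_exposures(m, syn5))
  dropped <- cohort_signature_summary(refit_exposures(m[1:2, ], syn5))
  expect_equal(full, dropped)
  expect_equal(sum(full), 1, tolerance = 1e-8)
})

test_that("summary is invariant to scaling one patient's total burden", {
  set.seed(9)
  props <- matrix(runif(96), 1)
  props <- props / sum(props)
  m <- matrix(0, 2, 96, dimnames = list(c("P001", "P002"), sbs96_channels()))
  m[1, ] <- round(props * 1000)
  m[2, ] <- m[1, ] * 7          # same channel proportions, 7x the burden
  ex <- refit_exposures(m, syn5)
  expect_equal(unname(ex$proportions[1, ]), unname(ex$proportions[2, ]),
               tolerance = 1e-8)
})

test_that("cohort signature contrast follows rank-sum and Bonferroni rules", {
  ## identical cohorts: all ranks tied, p = 1 by convention
  expect_equal(compare_signature_between_cohorts(rep(0.3, 5),
                                                 rep(0.3, 8))$p_raw, 1)
  ## Bonferroni arithmetic
  expect_equal(bonferroni_adjust(0.001, 36), 0.036)
  expect_equal(bonferroni_adjust(0.2, 36), 1)
  ## complete separation at nA = nB = 10 equals exact enumeration
  a <- seq(0.6, 0.9, length.out = 10)
  b <- seq(0.1, 0.4, length.out = 10)
  cmp <- compare_signature_between_cohorts(a, b, m_tests = 1)
  expect_equal(cmp$p_raw, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(cmp$p_raw, mwu_enum_oracle(a, b), tolerance = 1e-12)
})

test_that("presence test delegates to the shared Fisher routine", {
  expect_equal(signature_presence_test(0, 10, 0, 10), 1)
  expect_equal(signature_presence_test(0, 10, 10, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  ## presence threshold semantics: a proportion of 0.005 flips presence
  pr <- matrix(c(0.005, 0.995), 1, dimnames = list("P001", c("s1", "s2")))
  ex <- structure(list(exposures = pr * 200, proportions = pr,
                       defined = c(P001 = TRUE)), class = "exposure_table")
  expect_equal(unname(signature_presence(ex, 0)$present["s1"]), 1)
  expect_equal(unname(signature_presence(ex, 0.01)$present["s1"]), 0)
})
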