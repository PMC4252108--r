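toy_assignments <- function(n1, n2) {
  data.frame(sample_id = sprintf("S%02d", seq_len(n1 + n2)),
             subtype = rep(c("ST1", "ST2"), c(n1, n2)))
}

test_that("percentile-shift normalization matches hand arithmetic", {
  raw <- matrix(c(0.5, 2, 8, 16,
                  4, 4, 4, 4,
                  1, 8, 64, 128), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  norm <- normalize_expression(raw)
  ## by hand: floor at 1, log2, subtract per-sample 75th percentile
  ## (linear interpolation of order statistics)
  logd <- log2(pmax(raw, 1))
  for (j in 1:4) {
    q <- stats::quantile(logd[, j], 0.75, names = FALSE)
    expect_equal(norm[, j], logd[, j] - q, tolerance = 1e-12)
  }
  ## a constant sample normalizes to all zeros
  const <- matrix(8, 5, 2, dimnames = list(paste0("p", 1:5), c("a", "b")))
  expect_true(all(normalize_expression(const) == 0))
  expect_error(normalize_expression(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("normalization is scale-invariant and the shift is idempotent", {
  set.seed(4)
  raw <- matrix(2^runif(60, 2, 10), 10, 6,
                dimnames = list(paste0("p", 1:10), paste0("s", 1:6)))
  scaled <- sweep(raw, 2, c(10, 0.5, 3, 1, 7, 2), `*`)
  expect_equal(normalize_expression(raw), normalize_expression(scaled),
               tolerance = 1e-12)
  once <- normalize_expression(raw)
  expect_equal(p53pathtype:::percentile_shift(once), once, tolerance = 1e-12)
  ## the linear-scale division variant agrees on the shift-invariance too
  expect_equal(normalize_expression(raw, percentile_scale = TRUE),
               normalize_expression(scaled, percentile_scale = TRUE),
               tolerance = 1e-12)
})

test_that("probe t-tests match the direct Welch formula", {
  mat <- matrix(c(1.2, 2.1, 1.8, 5.5, 4.9, 6.2,
                  3.3, 3.1, 3.2, 3.4, 3.0, 3.2), nrow = 2, byrow = TRUE,
                dimnames = list(c("pA", "pB"), sprintf("S%02d", 1:6)))
  res <- differential_expression(mat, toy_assignments(3, 3))
  x <- mat["pA", 1:3]; y <- mat["pA", 4:6]
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  row <- res[res$probe_id == "pA", ]
  expect_equal(row$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(row$p, p_hand, tolerance = 1e-10)
  expect_equal(row$direction, "lower_in_ST1")
  expect_error(differential_expression(mat, toy_assignments(1, 5)), "at least two")
})

test_that("constant probes are flagged and never significant", {
  set.seed(5)
  mat <- rbind(matrix(rnorm(80), 10, 8), 0)
  rownames(mat) <- c(paste0("p", 1:10), "flat")
  colnames(mat) <- sprintf("S%02d", 1:8)
  res <- differential_expression(mat, toy_assignments(4, 4))
  flat <- res[res$probe_id == "flat", ]
  expect_true(flat$constant)
  expect_equal(flat$p, 1)
  expect_false(flat$significant)
})

test_that("significance membership is invariant to probe order", {
  set.seed(6)
  mat <- matrix(rnorm(400), 50, 8,
                dimnames = list(paste0("p", 1:50), sprintf("S%02d", 1:8)))
  mat[1:5, 1:4] <- mat[1:5, 1:4] + 3
  a <- differential_expression(mat, toy_assignments(4, 4))
  b <- differential_expression(mat[sample(50), ], toy_assignments(4, 4))
  expect_setequal(a$probe_id[a$significant], b$probe_id[b$significant])
})

test_that("gene collapsing keeps the best probe and flags discordance", {
  rec <- data.frame(
    probe_id = paste0("p", 1:5),
    gene = c("GA", "GA", NA, "GB", "GB"),
    mean_st1 = 1, mean_st2 = 0, t_statistic = 2,
    p = c(0.001, 0.01, 0.5, 0.002, 0.003),
    q = c(0.01, 0.05, 0.6, 0.02, 0.03),
    direction = c("higher_in_ST1", "higher_in_ST1", "lower_in_ST1",
                  "higher_in_ST1", "lower_in_ST1"),
    constant = FALSE,
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  genes <- collapse_to_genes(rec)
  ga <- genes[!is.na(genes$gene) & genes$gene == "GA", ]
  expect_equal(ga$probe_id, "p1")   # minimum-q probe represents the gene
  expect_equal(ga$n_probes, 2L)
  expect_false(ga$discordant)
  gb <- genes[!is.na(genes$gene) & genes$gene == "GB", ]
  expect_true(gb$discordant)        # significant probes disagree in direction
  unmapped <- genes[is.na(genes$gene), ]
  expect_equal(unmapped$probe_id, "p3")  # carried through under the probe id
})

test_that("planted subtype shifts are recovered on generator output", {
  co <- make_test_cohort(seed = 27, n_samples = 14L, fraction_st1 = 4 / 14,
                         n_expr_probes = 400L, n_shifted_probes = 30L,
                         n_shifted_genes = 22L)
  norm <- normalize_expression(co$expression$matrix)
  truth <- co$truth$samples[, c("sample_id", "subtype")]
  res <- differential_expression(norm, truth, probe_map = co$expression$probe_map)
  sig <- res$probe_id[res$significant]
  expect_gte(mean(co$truth$shifted_probes %in% sig), 0.8)
  ## realized false-discovery proportion consistent with the nominal level
  expect_gte(mean(sig %in% co$truth$shifted_probes), 0.8)
})
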