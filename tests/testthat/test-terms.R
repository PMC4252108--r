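test_that("EASE p-values follow the overlap-minus-one rule", {
  uni <- sprintf("g%03d", 1:100)
  query <- uni[1:10]
  expect_equal(ease_p(uni[50:59], query, uni), 1)        # no overlap
  expect_equal(ease_p(c(uni[1], uni[50:58]), query, uni), 1)  # single gene
  ## overlap 4 between a 10-gene term and a 10-gene query in 100:
  ## adjusted one-tailed Fisher on [[3, 7], [7, 83]]
  term <- c(uni[1:4], uni[40:45])
  expect_equal(ease_p(term, query, uni),
               hyper_enum_ge(3, 10, 10, 100), tolerance = 1e-12)
  expect_error(ease_p(term, c(query, "missing"), uni), "universe")
})

test_that("kappa agreement matches hand arithmetic and its symmetries", {
  uni <- letters[1:10]
  terms <- list(T1 = c("a", "b", "c", "d"),
                T2 = c("a", "b", "e", "f"),
                T3 = c("a", "b", "c", "d"),
                T4 = letters[1:5],
                T5 = letters[6:10])            # complement of T4, equal sizes
  km <- kappa_matrix(terms, uni)
  ## po = 0.6, pe = 0.52 -> kappa = 0.08 / 0.48
  expect_equal(km$kappa["T1", "T2"], 0.08 / 0.48, tolerance = 1e-12)
  expect_equal(km$kappa["T1", "T3"], 1)          # identical sets
  expect_equal(km$kappa["T4", "T5"], -1)         # perfect disagreement
  expect_equal(km$kappa, t(km$kappa))
  expect_true(all(diag(km$kappa) == 1))
  expect_equal(km$overlap["T1", "T2"], 2)
  expect_error(kappa_matrix(terms["T1"], uni), "two terms")
  expect_error(kappa_matrix(terms, character(0)), "non-empty")
})

test_that("degenerate term pairs get kappa 0 with a flag", {
  uni <- letters[1:6]
  km <- kappa_matrix(list(A = uni, B = uni, C = letters[1:2]), uni)
  expect_true(km$degenerate["A", "B"])
  expect_equal(km$kappa["A", "B"], 0)
  expect_false(km$degenerate["A", "C"])
})

test_that("fuzzy clustering seeds, filters, and merges to a fixed point", {
  uni <- sprintf("g%02d", 1:40)
  identical3 <- list(T1 = uni[1:8], T2 = uni[1:8], T3 = uni[1:8])
  km <- kappa_matrix(identical3, uni)
  cl <- fuzzy_cluster(km, kappa_threshold = 0.35, overlap_min = 3,
                      membership_min = 3, linkage_threshold = 0.5)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]], c("T1", "T2", "T3"))

  ## two families with no cross-similarity stay apart
  two <- list(A1 = uni[1:8], A2 = uni[1:8], A3 = uni[1:8],
              B1 = uni[20:28], B2 = uni[20:28], B3 = uni[20:28])
  cl2 <- fuzzy_cluster(kappa_matrix(two, uni))
  expect_length(cl2, 2L)
  expect_setequal(cl2[[1]], c("A1", "A2", "A3"))
  expect_setequal(cl2[[2]], c("B1", "B2", "B3"))

  ## a chain A~B, B~C merges into one cluster at linkage 0.5
  chain <- list(A = uni[1:6], B = uni[c(1:4, 7, 8)], C = uni[c(3, 4, 7:10)],
                D = uni[30:35], E = uni[30:35], F = uni[30:35])
  kmc <- kappa_matrix(chain, uni)
  cl3 <- fuzzy_cluster(kmc, kappa_threshold = 0.3, overlap_min = 3,
                       membership_min = 2, linkage_threshold = 0.5)
  abc <- Filter(function(g) "A" %in% g, cl3)
  expect_length(abc, 1L)
  expect_setequal(abc[[1]], c("A", "B", "C"))

  ## input order of the terms does not change the result
  cl4 <- fuzzy_cluster(kappa_matrix(chain[sample(6)], uni),
                       kappa_threshold = 0.3, overlap_min = 3,
                       membership_min = 2, linkage_threshold = 0.5)
  expect_identical(cl3, cl4)
})

test_that("enrichment score is the mean of -log10 p", {
  ps <- c(A = 0.05, B = 0.05, C = 0.05)
  expect_equal(enrichment_score(c("A", "B", "C"), ps), -log10(0.05),
               tolerance = 1e-12)
  expect_equal(enrichment_score("A", c(A = 0.1)), 1, tolerance = 1e-12)
  expect_equal(enrichment_score(c("A", "B"), c(A = 0.01, B = 0.1)), 1.5,
               tolerance = 1e-12)
  set.seed(8)
  ps2 <- stats::setNames(runif(6, 1e-6, 1), paste0("T", 1:6))
  expect_equal(enrichment_score(names(ps2), ps2), mean(-log10(ps2)),
               tolerance = 1e-12)
  expect_warning(z <- enrichment_score("A", c(A = 0)), "clamped")
  expect_true(is.finite(z))
  expect_error(enrichment_score(c("A", "Z"), c(A = 0.5)), "missing")
})

test_that("planted terms co-cluster and outscore random terms", {
  wins <- 0L
  for (s in 1:5) {
    co <- make_test_cohort(seed = 300 + s)
    res <- cluster_terms(co$truth$shifted_genes, co$terms, co$gene_map$gene)
    cl <- res$clusters
    planted_cl <- grepl("PLANTED", cl$member_terms)
    if (any(planted_cl)) {
      top <- cl[planted_cl, ][1, ]
      members <- strsplit(top$member_terms, ",")[[1]]
      ok_cocluster <- sum(grepl("PLANTED", members)) >= 2L
      best_random <- if (any(!planted_cl)) max(cl$enrichment_score[!planted_cl]) else -Inf
      if (ok_cocluster && top$enrichment_score > best_random) wins <- wins + 1L
    }
  }
  expect_gte(wins, 4L)
})
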