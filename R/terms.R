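#' EASE-adjusted one-tailed enrichment p-value for one term
#'
#' The conservative DAVID-style variant of the one-tailed Fisher enrichment
#' test: the term/query overlap is reduced by one gene (floored at 0, keeping
#' all margins), which penalizes enrichment carried by very few genes. An
#' overlap of 0 or 1 therefore yields p = 1.
#'
#' @param term_genes genes annotated to the term.
#' @param query query gene list (must be a subset of the universe).
#' @param universe background gene universe.
#' @return one-tailed enrichment p-value.
#' @export
ease_p <- function(term_genes, query, universe) {
  if (!length(query) || !length(universe)) stopf("query and universe must be non-empty")
  if (length(setdiff(query, universe)))
    stopf("query contains genes outside the universe: %s",
          paste(utils::head(setdiff(query, universe), 3), collapse = ", "))
  term_genes <- intersect(term_genes, universe)
  k <- length(intersect(term_genes, query))
  if (k == 0L) return(1)
  k_adj <- max(k - 1L, 0L)
  ## P(overlap >= k_adj) with margins |term|, |query|, |universe|
  stats::phyper(k_adj - 1L, length(term_genes),
                length(universe) - length(term_genes), length(query),
                lower.tail = FALSE)
}

#' Pairwise kappa agreement between annotation terms
#'
#' Treats each term as a binary gene-membership vector over the universe and
#' computes Cohen's kappa, `(po - pe) / (1 - pe)`, for every pair, along with
#' the gene overlap count. Degenerate pairs with chance agreement pe = 1 are
#' set to kappa 0 and flagged.
#'
#' @param terms named list of gene sets.
#' @param universe background gene universe.
#' @return list with symmetric matrices `kappa` and `overlap`, and a logical
#'   matrix `degenerate`.
#' @export
kappa_matrix <- function(terms, universe) {
  if (length(terms) < 2L) stopf("at least two terms are required")
  if (!length(universe)) stopf("universe must be non-empty")
  n <- length(universe)
  m <- vapply(terms, function(g) universe %in% g, logical(n))
  sizes <- colSums(m)
  a <- crossprod(m)                      # both-member counts
  d <- n - outer(sizes, sizes, `+`) + a  # both-absent counts
  po <- (a + d) / n
  pe <- (outer(sizes, sizes) + outer(n - sizes, n - sizes)) / n^2
  degenerate <- abs(1 - pe) < 1e-12
  kappa <- matrix(0, length(terms), length(terms),
                  dimnames = dimnames(a))
  kappa[!degenerate] <- ((po - pe) / (1 - pe))[!degenerate]
  list(kappa = kappa, overlap = a, degenerate = degenerate)
}

#' Fuzzy multiple-linkage clustering of annotation terms
#'
#' DAVID-style heuristic grouping. Seed groups are formed around each term
#' from its neighbors with kappa at or above `kappa_threshold` and pairwise
#' gene overlap at least `overlap_min`; seeds with fewer than `membership_min`
#' members are discarded. Groups sharing at least a `linkage_threshold`
#' fraction of the smaller group's members are merged iteratively until a
#' fixed point; a term may belong to several clusters. Merge order is by
#' descending group size with ties broken by sorted term id, so the result is
#' invariant to the input order of terms.
#'
#' @param similarities result of [kappa_matrix()].
#' @param kappa_threshold minimum kappa for seed membership (default 0.35).
#' @param overlap_min minimum pairwise gene overlap (default 3).
#' @param membership_min minimum seed size (default 3).
#' @param linkage_threshold member-sharing fraction that triggers a merge
#'   (default 0.5).
#' @return list of character vectors of member terms (sorted), itself sorted
#'   by decreasing size then first member.
#' @export
fuzzy_cluster <- function(similarities, kappa_threshold = 0.35, overlap_min = 3L,
                          membership_min = 3L, linkage_threshold = 0.5) {
  assert_proportion(linkage_threshold, "linkage_threshold", 0, 1)
  if (kappa_threshold < -1 || kappa_threshold > 1)
    stopf("'kappa_threshold' must be within [-1, 1]")
  kappa <- similarities$kappa
  overlap <- similarities$overlap
  ids <- sort(rownames(kappa))
  kappa <- kappa[ids, ids]
  overlap <- overlap[ids, ids]
  seeds <- lapply(ids, function(t) {
    nb <- ids[kappa[t, ] >= kappa_threshold & overlap[t, ] >= overlap_min & ids != t]
    sort(unique(c(t, nb)))
  })
  seeds <- seeds[vapply(seeds, length, 0L) >= membership_min]
  seeds <- unique(seeds)
  if (!length(seeds)) return(list())
  order_groups <- function(gs)
    gs[order(-vapply(gs, length, 0L), vapply(gs, `[[`, "", 1L))]
  groups <- order_groups(seeds)
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        share <- length(intersect(groups[[i]], groups[[j]])) /
          min(length(groups[[i]]), length(groups[[j]]))
        if (share >= linkage_threshold) {
          groups[[i]] <- sort(union(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          groups <- order_groups(groups)
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  order_groups(unique(groups))
}

#' Enrichment score of a term cluster
#'
#' Minus log10 of the geometric mean of the member terms' EASE p-values,
#' equivalently the arithmetic mean of -log10(p). A score above 1.3
#' (geometric mean p below 0.05) is conventionally called significant.
#'
#' @param member_terms character vector of term ids.
#' @param ease_ps named numeric vector of EASE p-values covering the members.
#' @return the enrichment score (non-negative real).
#' @export
enrichment_score <- function(member_terms, ease_ps) {
  p <- ease_ps[member_terms]
  if (any(is.na(p))) stopf("missing EASE p-value for: %s",
                           paste(member_terms[is.na(p)], collapse = ", "))
  if (any(p == 0)) {
    warning("EASE p-value of 0 clamped to 1e-300")
    p[p == 0] <- 1e-300
  }
  mean(-log10(p))
}

#' Functional annotation clustering of a query gene list
#'
#' End-to-end wrapper: per-term EASE enrichment p-values, pairwise kappa
#' similarity, fuzzy multiple-linkage grouping, and group enrichment scores.
#'
#' @param query query gene list.
#' @param terms named list of term gene sets (e.g. from [read_gmt()]).
#' @param universe background gene universe.
#' @param min_query_hits drop terms with fewer query hits than this before
#'   clustering (default 1, mirroring annotation charts that only display
#'   terms hit by the query).
#' @param es_significant score threshold for the `significant` flag
#'   (default 1.3).
#' @inheritParams fuzzy_cluster
#' @return list with `clusters` (data frame: cluster, enrichment_score,
#'   significant, n_terms, member_terms, member_genes) and `term_stats`
#'   (per-term EASE p and query overlap).
#' @export
cluster_terms <- function(query, terms, universe,
                          kappa_threshold = 0.35, overlap_min = 3L,
                          membership_min = 3L, linkage_threshold = 0.5,
                          min_query_hits = 1L, es_significant = 1.3) {
  ps <- vapply(terms, ease_p, 0, query = query, universe = universe)
  hits <- vapply(terms, function(g) length(intersect(g, query)), 0L)
  term_stats <- data.frame(term = names(terms), n_genes = lengths(terms),
                           query_hits = hits, ease_p = ps,
                           row.names = NULL, stringsAsFactors = FALSE)
  keep <- names(terms)[hits >= min_query_hits]
  if (length(keep) < 2L)
    return(list(clusters = data.frame(cluster = integer(0),
                                      enrichment_score = numeric(0),
                                      significant = logical(0),
                                      n_terms = integer(0),
                                      member_terms = character(0),
                                      member_genes = character(0)),
                term_stats = term_stats))
  sims <- kappa_matrix(terms[keep], universe)
  groups <- fuzzy_cluster(sims, kappa_threshold, overlap_min,
                          membership_min, linkage_threshold)
  scores <- vapply(groups, enrichment_score, 0, ease_ps = ps)
  ord <- order(-scores)
  clusters <- data.frame(
    cluster = seq_along(groups),
    enrichment_score = scores[ord],
    significant = scores[ord] > es_significant,
    n_terms = vapply(groups, length, 0L)[ord],
    member_terms = vapply(groups, paste, "", collapse = ",")[ord],
    member_genes = vapply(groups, function(g)
      paste(sort(unique(unlist(terms[g]))), collapse = ","), "")[ord],
    stringsAsFactors = FALSE, row.names = NULL)
  list(clusters = clusters, term_stats = term_stats)
}
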