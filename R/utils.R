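#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Nonsynonymous + splice consequence classes counted throughout the package.
NONSYN_CLASSES <- c("missense", "nonsense", "splice_site", "frameshift_indel")
CONSEQUENCE_LEVELS <- c(NONSYN_CLASSES, "synonymous", "other")
AUTOSOMES <- as.character(1:22)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) stopf("'%s' must be a %s integer", name, if (positive) "positive" else "non-negative")
  as.integer(x)
}

assert_proportion <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("'%s' must be a proportion in [%g, %g]", name, lo, hi)
  as.numeric(x)
}

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("'%s' is missing required column(s): %s", name, paste(miss, collapse = ", "))
  invisible(df)
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' Splits one master seed into independent integer seeds keyed by a stage
#' label, so that toggling one pipeline stage does not perturb the random
#' stream of another. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

## Half-open interval overlap on one chromosome.
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

## Two-sided Fisher's exact p on 2x2 tables given as parallel count vectors,
## with caching over repeated tables (frequent in per-probe scans).
fisher_p2 <- function(a, b, c, d, alternative = "two.sided") {
  key <- paste(a, b, c, d, alternative, sep = ":")
  out <- numeric(length(a))
  uk <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    cache[[key[i]]] <- stats::fisher.test(
      matrix(c(a[i], b[i], c[i], d[i]), nrow = 2, byrow = TRUE),
      alternative = alternative)$p.value
  }
  for (i in seq_along(a)) out[i] <- cache[[key[i]]]
  out
}
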