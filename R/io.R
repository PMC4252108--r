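#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set exchange format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return a named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("'sets' must be a named list")
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED interval file (0-based half-open)
#'
#' @param path file path.
#' @return data frame with columns chrom, start, end and, when present, name.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  df$chrom <- as.character(df$chrom)
  df
}

#' Write a BED interval file (0-based half-open)
#'
#' @param df data frame with chrom, start, end and optionally name columns.
#' @param path file path.
#' @export
write_bed <- function(df, path) {
  assert_columns(df, c("chrom", "start", "end"), "df")
  cols <- intersect(c("chrom", "start", "end", "name"), names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tab-separated table with an optional comment header
#'
#' All pipeline outputs share this writer so that every table carries the
#' package version and configuration hash in `#`-prefixed comment lines.
#'
#' @param df data frame.
#' @param path file path.
#' @param header character vector of comment lines (without the leading `#`).
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write copy-number segments in SEG layout
#'
#' One row per segment: sample, chrom, start, end, number of probes, and the
#' segment value (here the decoded integer copy-number state alongside the
#' observed mean log R ratio).
#'
#' @param segments segment data frame from [segment_cnv()].
#' @param path file path.
#' @param header optional comment header lines.
#' @export
write_seg <- function(segments, path, header = NULL) {
  assert_columns(segments,
                 c("sample_id", "chrom", "start", "end", "n_probes", "cn_state", "mean_lrr"),
                 "segments")
  write_tsv(segments[, c("sample_id", "chrom", "start", "end",
                         "n_probes", "cn_state", "mean_lrr")], path, header)
}

#' Export somatic calls as a minimal VCF
#'
#' One record per call; paired allele depths are carried in AD-style
#' per-sample FORMAT fields (tumor and normal columns).
#'
#' @param calls somatic call data frame from [call_somatic()].
#' @param path file path.
#' @export
write_vcf <- function(calls, path) {
  assert_columns(calls, c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
                          "tumor_ref_count", "tumor_alt_count",
                          "normal_ref_count", "normal_alt_count", "fisher_p"), "calls")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample of origin\">",
    "##INFO=<ID=FPV,Number=1,Type=Float,Description=\"Fisher exact p value\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL"), con)
  if (nrow(calls)) {
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSAMPLE=%s;FPV=%.3g\tAD\t%d,%d\t%d,%d",
                    calls$chrom, calls$pos + 1L, calls$ref_allele, calls$alt_allele,
                    calls$sample_id, calls$fisher_p,
                    calls$tumor_ref_count, calls$tumor_alt_count,
                    calls$normal_ref_count, calls$normal_alt_count)
    writeLines(rows, con)
  }
  invisible(path)
}
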