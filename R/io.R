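#' Read / write the SNV table format
#'
#' Tab-separated with columns `chrom`, `pos` (1-based), `ref_count`,
#' `alt_count`, `major_cn`, `minor_cn`. Internally positions stay 1-based in
#' SNV tables; segment tables use 0-based half-open starts.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_snv_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref_count", "alt_count", "major_cn", "minor_cn")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("SNV table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_snv_tsv
#' @param snvs `data.frame` as produced by [simulate_reads()] (or with the
#'   canonical columns already present).
#' @export
write_snv_tsv <- function(snvs, path) {
  out <- data.frame(
    chrom = snvs$chrom, pos = snvs$pos,
    ref_count = if (!is.null(snvs$ref_count)) snvs$ref_count
      else snvs$total_count - snvs$alt_count,
    alt_count = snvs$alt_count,
    major_cn = snvs$major_cn, minor_cn = snvs$minor_cn)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write the subclonal-structure clustering table
#'
#' Tab-separated with columns `cluster`, `n_ssms`, `proportion` (cellular
#' prevalence or CCF of the cluster, per the `scale` argument).
#'
#' @param path File path.
#' @param scale Location scale of the `proportion` column.
#' @return A [clustering()].
#' @export
read_clustering_tsv <- function(path, scale = c("CCF", "CP")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("cluster", "n_ssms", "proportion")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("clustering table missing column(s): ",
                         paste(miss, collapse = ", "))
  clustering(df$n_ssms / sum(df$n_ssms), df$proportion, scale = scale,
             n_snvs_total = sum(df$n_ssms))
}

#' @rdname read_clustering_tsv
#' @param cl A [clustering()].
#' @export
write_clustering_tsv <- function(cl, path) {
  n <- if (is.na(cl$n_snvs_total)) 1000 else cl$n_snvs_total
  out <- data.frame(cluster = seq_along(cl$locations),
                    n_ssms = round(cl$proportions * n),
                    proportion = cl$locations)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write segment tables (BED-like)
#'
#' Tab-separated with columns `chrom`, `start` (0-based), `end`, `major_cn`,
#' `minor_cn` and optional `clonal_frac`, `level`, `stars`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_segments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "major_cn", "minor_cn")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("segment table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_segments_tsv
#' @param segments `data.frame` with the canonical columns.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a run manifest (key = value text)
#'
#' Every stochastic run records its seed and parameters so results can be
#' regenerated exactly.
#'
#' @param manifest Named list of scalar values.
#' @param path File path.
#' @return The path (write) or named character list (read).
#' @export
write_manifest <- function(manifest, path) {
  lines <- vapply(names(manifest), function(k)
    paste0(k, "=", as.character(manifest[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) paste(x[-1], collapse = "="))
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}
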