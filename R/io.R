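#' Write a count matrix as TSV
#'
#' Sites as rows, time points as columns; library sizes stored in a
#' `#library_sizes:` header comment so the file round-trips.
#'
#' @param cm [count_matrix()]
#' @param path output file
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "cc_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#tag: %s", cm$tag),
    sprintf("#times: %s", paste(cm$times, collapse = "\t")),
    sprintf("#library_sizes: %s", paste(cm$library_sizes, collapse = "\t"))
  ), con)
  df <- data.frame(site_id = cm$site_ids, cm$counts, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path TSV file
#' @return [count_matrix()]
#' @export
read_count_matrix <- function(path) {
  hdr <- readLines(path, n = 3)
  parse_field <- function(line, prefix) {
    strsplit(sub(prefix, "", line), "\t", fixed = TRUE)[[1]]
  }
  tag <- trimws(sub("#tag: ", "", hdr[1]))
  times <- as.numeric(parse_field(hdr[2], "#times: "))
  libs <- as.numeric(parse_field(hdr[3], "#library_sizes: "))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 3,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  count_matrix(m, times, tag = tag, library_sizes = libs,
               site_ids = df$site_id)
}

#' Write regions as BED6
#'
#' 0-based half-open coordinates; score 0, strand ".".
#'
#' @param regions data frame with `chrom`, `start`, `end` and optionally
#'   `site_id`
#' @param path output file
#' @export
write_bed6 <- function(regions, path) {
  name <- if (is.null(regions$site_id)) {
    sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  } else {
    regions$site_id
  }
  bed <- data.frame(regions$chrom, regions$start, regions$end, name,
                    0L, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BED6 (or BED3+) region file
#'
#' @param path BED file
#' @return data frame with `chrom`, `start`, `end`, `site_id`
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                    stringsAsFactors = FALSE)
  out$site_id <- if (ncol(df) >= 4) df[[4]] else
    sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Read a western-blot ratio series from TSV
#'
#' Expects columns `time`, `replicate`, `ratio`.
#'
#' @param path TSV file
#' @return data frame suitable for [fit_induction()]
#' @export
read_western_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("time", "ratio") %in% names(df)))
  df
}

#' Write a data frame as TSV
#'
#' Thin wrapper with the package's conventions (tab separator, no quotes,
#' no row names).
#'
#' @param df data frame
#' @param path output file
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
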