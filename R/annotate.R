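#' Merge peak regions
#'
#' Merges overlapping or bookended intervals per chromosome, matching
#' `bedtools merge` default semantics (0-based half-open input; intervals
#' that touch are merged). Output is sorted and non-overlapping, with
#' `site_id` set to `chrom:start-end`.
#'
#' @param regions data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open; `0 <= start < end`)
#' @return data frame with `chrom`, `start`, `end`, `site_id`
#' @examples
#' merge_regions(data.frame(chrom = "chrI", start = c(10, 15, 20),
#'                          end = c(20, 30, 40)))
#' @export
merge_regions <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start < 0) || any(regions$start >= regions$end)) {
    stop("malformed intervals: need 0 <= start < end")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out$site_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Assign peak regions to genes by TSS proximity
#'
#' Each region is assigned to the gene with the nearest TSS on the same
#' chromosome, by signed strand-aware distance from the region midpoint
#' (negative = upstream of the TSS on the gene's strand). Assignments
#' outside the closed window `[-250, +100]` bp are dropped, regions at
#' tRNA genes are removed, and when several regions land on one gene only
#' the closest (smallest absolute distance) is kept. Equidistant-TSS ties
#' go to the lexicographically smaller `gene_id`.
#'
#' @param regions data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `site_id`
#' @param genes data frame with `gene_id`, `chrom`, `tss`, `strand`
#'   (`+`/`-`) and optionally `biotype`
#' @param window signed window around the TSS, bp (closed interval)
#' @return data frame with `site_id`, `gene_id`, `signed_distance`
#' @export
assign_regions <- function(regions, genes, window = c(-250, 100)) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (!is.data.frame(genes) || nrow(genes) == 0) {
    stop("`genes` must be a non-empty data frame")
  }
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)),
            all(genes$strand %in% c("+", "-")))
  if (is.null(regions$site_id)) {
    regions$site_id <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                               regions$end)
  }
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"

  mid <- (regions$start + regions$end) / 2
  n <- nrow(regions)
  gene_hit <- character(n)
  signed <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == regions$chrom[i], ]
    if (nrow(g) == 0) next
    d_abs <- abs(mid[i] - g$tss)
    best <- which(d_abs == min(d_abs))
    if (length(best) > 1L) best <- best[order(g$gene_id[best])][1L]
    gene_hit[i] <- g$gene_id[best]
    signed[i] <- if (g$strand[best] == "+") mid[i] - g$tss[best]
                 else g$tss[best] - mid[i]
  }
  res <- data.frame(site_id = regions$site_id, gene_id = gene_hit,
                    signed_distance = signed, stringsAsFactors = FALSE)
  res <- res[gene_hit != "" & is.finite(signed), ]
  res <- res[res$signed_distance >= window[1] &
             res$signed_distance <= window[2], ]
  trna <- genes$gene_id[genes$biotype == "tRNA"]
  res <- res[!(res$gene_id %in% trna), ]
  if (nrow(res) == 0) return(res)
  # per gene keep only the closest region (stable order breaks |d| ties)
  res <- res[order(res$gene_id, abs(res$signed_distance)), ]
  res <- res[!duplicated(res$gene_id), ]
  rownames(res) <- NULL
  res
}
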