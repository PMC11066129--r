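test_that("overlapping and bookended intervals merge", {
  m <- merge_regions(data.frame(chrom = "chrI", start = c(10, 15),
                                end = c(20, 30)))
  expect_equal(m[, c("start", "end")], data.frame(start = 10, end = 30))
  m2 <- merge_regions(data.frame(chrom = "chrI", start = c(10, 20),
                                 end = c(20, 30)))
  expect_equal(m2[, c("start", "end")], data.frame(start = 10, end = 30))
  m3 <- merge_regions(data.frame(chrom = c("chrI", "chrII"),
                                 start = c(10, 10), end = c(20, 20)))
  expect_equal(nrow(m3), 2L)
  expect_error(merge_regions(data.frame(chrom = "chrI", start = 5, end = 5)),
               "malformed")
})

test_that("merge matches a brute-force sweep-line oracle on random sets", {
  set.seed(77)
  n <- 1000
  start <- sample.int(5e4, n, replace = TRUE)
  regions <- data.frame(chrom = sample(c("chrI", "chrII", "chrIII"), n,
                                       replace = TRUE),
                        start = start,
                        end = start + sample.int(300, n, replace = TRUE))
  got <- merge_regions(regions)
  want <- sweep_merge(regions)
  expect_equal(got[, c("chrom", "start", "end")], want, ignore_attr = TRUE)
})

test_that("TSS-window assignment follows the signed distance rules", {
  genes <- data.frame(gene_id = c("geneA", "geneB", "geneC"),
                      chrom = "chrI", tss = c(1000, 6000, 11000),
                      strand = c("+", "-", "+"),
                      biotype = c("protein_coding", "protein_coding", "tRNA"))
  mk <- function(mid) data.frame(chrom = "chrI", start = mid - 25,
                                 end = mid + 25)
  # midpoint 50 bp downstream of a + strand TSS: kept at +50
  r1 <- assign_regions(mk(1050), genes)
  expect_identical(r1$gene_id, "geneA")
  expect_equal(r1$signed_distance, 50)
  # 300 bp upstream: outside the window, dropped
  expect_equal(nrow(assign_regions(mk(700), genes)), 0L)
  # minus strand: upstream is to the right of the TSS
  r2 <- assign_regions(mk(6100), genes)
  expect_identical(r2$gene_id, "geneB")
  expect_equal(r2$signed_distance, -100)
  # tRNA assignment removed
  expect_equal(nrow(assign_regions(mk(11020), genes)), 0L)
  # closed window boundaries kept
  expect_equal(assign_regions(mk(1000 - 250), genes)$signed_distance, -250)
  expect_equal(assign_regions(mk(1000 + 100), genes)$signed_distance, 100)
  expect_error(assign_regions(mk(1000), genes[0, ]), "non-empty")
})

test_that("only the closest region per gene is kept", {
  genes <- data.frame(gene_id = "geneA", chrom = "chrI", tss = 5000,
                      strand = "+", biotype = "protein_coding")
  regions <- data.frame(chrom = "chrI",
                        start = c(5000 - 30 - 25, 5000 - 120 - 25),
                        end = c(5000 - 30 + 25, 5000 - 120 + 25),
                        site_id = c("near", "far"))
  asg <- assign_regions(regions, genes)
  expect_identical(asg$site_id, "near")
  expect_equal(asg$signed_distance, -30)
})

test_that("equidistant TSS ties resolve to the smaller gene id", {
  genes <- data.frame(gene_id = c("geneB", "geneA"), chrom = "chrI",
                      tss = c(1100, 900), strand = "+",
                      biotype = "protein_coding")
  r <- assign_regions(data.frame(chrom = "chrI", start = 975, end = 1025),
                      genes)
  expect_identical(r$gene_id, "geneA")
})
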