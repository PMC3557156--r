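test_that("haplotype_panel sorts markers and validates entries", {
  mat <- matrix(c(0, 1, 1, 0,
                  1, 0, 0, 1,
                  0, 0, 1, 1), nrow = 4)
  markers <- data.frame(chrom = c("2", "1", "1"), pos = c(100, 500, 200),
                        id = c("a", "b", "c"),
                        ref_allele = "A", alt_allele = "G")
  p <- haplotype_panel(mat, markers)
  expect_equal(p$markers$chrom, c("1", "1", "2"))
  expect_equal(p$markers$pos, c(200, 500, 100))
  # columns permuted with the markers
  expect_equal(p$haplotypes[, 1], c(0, 0, 1, 1))
  expect_equal(dim(p), c(4L, 3L))
})

test_that("panel construction rejects bad input", {
  mat <- matrix(0:1, nrow = 4, ncol = 2)
  markers <- data.frame(chrom = "1", pos = c(100, 100), id = c("a", "b"),
                        ref_allele = "A", alt_allele = "G")
  expect_error(haplotype_panel(mat, markers), "pos")
  mat2 <- matrix(c(0, 1, 2, 0, 1, 0, 1, 0), nrow = 4)
  markers2 <- data.frame(chrom = "1", pos = c(100, 200), id = c("a", "b"),
                         ref_allele = "A", alt_allele = "G")
  expect_error(haplotype_panel(mat2, markers2), "0 or 1")
  expect_error(
    haplotype_panel(matrix(0L, nrow = 3, ncol = 2), markers2),
    "4"
  )
})

test_that("chromosome labels sort numerically when possible", {
  mat <- matrix(rep(c(0, 1), 12), nrow = 4)
  markers <- data.frame(chrom = c("10", "2", "1", "X", "2", "1"),
                        pos = c(10, 10, 20, 10, 30, 10),
                        id = letters[1:6], ref_allele = "A",
                        alt_allele = "G")
  p <- haplotype_panel(mat, markers)
  expect_equal(p$markers$chrom, c("1", "1", "2", "2", "10", "X"))
  expect_equal(p$markers$pos, c(10, 20, 10, 30, 10, 10))
})

test_that("allele_frequencies and filter_markers report disjoint removals", {
  mat <- cbind(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),   # monomorphic
               c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0),   # maf 0.10
               c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),   # maf 0.10 unplaced chrom
               c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),   # maf 0.50
               c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0))   # maf 0.10
  markers <- data.frame(chrom = c("1", "1", "un", "1", "1"),
                        pos = c(100, 200, 300, 400, 500),
                        id = paste0("m", 1:5), ref_allele = "A",
                        alt_allele = "G")
  p <- haplotype_panel(mat, markers)
  st <- allele_frequencies(p)
  expect_equal(sort(st$maf), c(0, 0.1, 0.1, 0.1, 0.5))
  expect_equal(sum(st$is_monomorphic), 1)
  expect_equal(sum(!st$has_position), 1)

  fl <- filter_markers(p, min_maf = 0.2)
  expect_equal(fl$report$n_input, 5)
  expect_equal(fl$report$n_removed_unplaced, 1)
  expect_equal(fl$report$n_removed_monomorphic, 1)
  expect_equal(fl$report$n_removed_maf, 2)
  expect_equal(fl$report$n_retained, 1)
  expect_equal(
    fl$report$n_input,
    fl$report$n_removed_unplaced + fl$report$n_removed_monomorphic +
      fl$report$n_removed_maf + fl$report$n_retained
  )
  expect_equal(nrow(fl$panel$markers), 1)
  expect_error(filter_markers(p, min_maf = 0.6), "removed")
})

test_that("phased VCF round-trips into a panel", {
  panel <- block_panel()
  tmp <- tempfile(fileext = ".vcf")
  write_toy_vcf(tmp, panel)
  got <- read_phased_vcf(tmp)
  expect_equal(got$haplotypes, panel$haplotypes, ignore_attr = TRUE)
  expect_equal(got$markers$pos, panel$markers$pos)
  expect_equal(got$markers$chrom, panel$markers$chrom)
  expect_equal(nrow(got$haplotypes), 48)
  expect_match(got$sample_ids[1], "_1$")
})

test_that("unphased and missing genotypes are hard errors", {
  panel <- block_panel()
  tmp <- tempfile(fileext = ".vcf")
  write_toy_vcf(tmp, panel)
  txt <- readLines(tmp)
  bad <- sub("0\\|0", "0/0", txt[4])  # first data row starts "0|0"
  writeLines(c(txt[1:3], bad, txt[-(1:4)]), tmp)
  expect_error(read_phased_vcf(tmp), "unphased")

  write_toy_vcf(tmp, panel)
  txt <- readLines(tmp)
  bad <- sub("0\\|0", ".|.", txt[4])
  writeLines(c(txt[1:3], bad, txt[-(1:4)]), tmp)
  expect_error(read_phased_vcf(tmp), "missing|unphased")
})

test_that("hap/legend round-trip is exact", {
  panel <- block_panel()
  prefix <- tempfile()
  write_panel(panel, prefix)
  got <- read_hap_legend(paste0(prefix, ".hap"), paste0(prefix, ".legend"),
                         paste0(prefix, ".samples"))
  expect_equal(got$haplotypes, panel$haplotypes, ignore_attr = TRUE)
  expect_equal(got$markers$pos, panel$markers$pos)
  expect_equal(got$markers$id, panel$markers$id)
  expect_equal(got$sample_ids, panel$sample_ids)
})

test_that("hap/legend row mismatch and non-binary alleles error", {
  panel <- block_panel()
  prefix <- tempfile()
  write_panel(panel, prefix)
  hap <- readLines(paste0(prefix, ".hap"))
  writeLines(hap[-1], paste0(prefix, ".hap"))
  expect_error(
    read_hap_legend(paste0(prefix, ".hap"), paste0(prefix, ".legend")),
    "mismatch|rows"
  )
  write_panel(panel, prefix)
  hap <- readLines(paste0(prefix, ".hap"))
  hap[1] <- sub("0", "7", hap[1])
  writeLines(hap, paste0(prefix, ".hap"))
  expect_error(
    read_hap_legend(paste0(prefix, ".hap"), paste0(prefix, ".legend")),
    "0/1|allele"
  )
})
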