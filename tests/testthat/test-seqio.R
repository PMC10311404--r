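# VCF and FASTA parsing, polarization, and the site filters.

write_vcf_fixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.vcf")
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">")
  writeLines(c(header, lines), path)
  path
}

vcf_cols <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT"

test_that("phased diploid genotypes expand to haplotype rows", {
  skip_if_not_installed("vcfR")
  path <- write_vcf_fixture(c(
    paste0(vcf_cols, "\tS1"),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1"))
  m <- parse_vcf(path, ancestral = "ref")
  expect_equal(dim(m$states), c(2, 1))
  expect_equal(m$states[, 1], c(0L, 1L))
  expect_equal(m$positions_bp, 100)
  expect_equal(m$sample_ids, c("S1_1", "S1_2"))
  expect_equal(nrow(parse_vcf(path, sample_subset = "S1")$states), 2)
  expect_error(parse_vcf(path, sample_subset = "nope"), "not in VCF")
})

test_that("missing genotypes become OTHER and AA polarization flips
          alleles", {
  skip_if_not_installed("vcfR")
  path <- write_vcf_fixture(c(
    paste0(vcf_cols, "\tS1\tS2"),
    "1\t100\t.\tA\tG\t.\tPASS\tAA=G\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t.|.\t0|1",
    "1\t300\t.\tC\tT\t.\tPASS\tAA=C\tGT\t0|0\t0|1"))
  m <- parse_vcf(path, ancestral = "aa")
  # site 1: AA=ALT, so REF carriers are derived
  expect_equal(m$states[, 1], c(1L, 0L, 0L, 0L))
  # site 2: no AA -> REF ancestral; missing genotypes are OTHER
  expect_equal(m$states[, 2], c(2L, 2L, 0L, 1L))
  # site 3: AA=REF agrees with the default
  expect_equal(m$states[, 3], c(0L, 0L, 0L, 1L))
})

test_that("unphased input errors by default but can be accepted as
          haplotypes", {
  skip_if_not_installed("vcfR")
  path <- write_vcf_fixture(c(
    paste0(vcf_cols, "\tS1"),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"))
  expect_error(parse_vcf(path), "unphased")
  expect_warning(m <- parse_vcf(path, unphased = "haplotype"), "unphased")
  expect_equal(sort(m$states[, 1]), c(0L, 1L))
})

test_that("an empty VCF body gives a zero-site matrix", {
  skip_if_not_installed("vcfR")
  path <- write_vcf_fixture(paste0(vcf_cols, "\tS1"))
  m <- suppressWarnings(parse_vcf(path))
  expect_equal(ncol(m$states), 0)
})

test_that("filter_sites removes monomorphic and multi-allelic columns,
          idempotently", {
  states <- cbind(c(0L, 0L, 0L),     # monomorphic ancestral
                  c(0L, 1L, 1L),     # good
                  c(0L, 1L, 2L),     # flagged multi-allelic source
                  c(2L, 2L, 2L),     # all missing
                  c(1L, 0L, 1L))     # good
  m <- snp_matrix(states, c(10, 20, 30, 40, 50), 100)
  attr(m, "multiallelic") <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  f <- filter_sites(m)
  rep <- attr(f, "filter_report")
  expect_equal(f$positions_bp, c(20, 50))
  expect_equal(rep$n_monomorphic, 2)
  expect_equal(rep$n_multiallelic, 1)
  expect_equal(rep$n_kept, 2)
  # idempotence
  f2 <- filter_sites(f)
  expect_equal(f2$states, f$states)
  expect_equal(attr(f2, "filter_report")$n_kept, 2)
  # an already clean matrix passes through unchanged
  clean <- snp_matrix(cbind(c(0L, 1L), c(1L, 0L)), c(1, 2), 10)
  expect_equal(filter_sites(clean)$states, clean$states)
})

test_that("VCF multi-allelic ALT records are dropped by the filter", {
  skip_if_not_installed("vcfR")
  path <- write_vcf_fixture(c(
    paste0(vcf_cols, "\tS1\tS2"),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
    "1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0|1\t0|2"))
  m <- parse_vcf(path, ancestral = "ref")
  f <- filter_sites(m)
  expect_equal(f$positions_bp, 100)
  expect_equal(attr(f, "filter_report")$n_multiallelic, 1)
})

test_that("FASTA parsing extracts polymorphic columns with gap handling and
          outgroup polarization", {
  skip_if_not_installed("Biostrings")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "aln.fasta")
  writeLines(c(">s1", "ACGTA", ">s2", "ACGAA", ">s3", "AGG-A",
               ">anc", "ACGTA"), path)
  # outgroup polarization, outgroup excluded from the sample rows
  m <- parse_fasta(path, outgroup = "anc")
  expect_equal(nrow(m$states), 3)
  expect_equal(m$positions_bp, c(2, 4))
  expect_equal(m$states[, 1], c(0L, 0L, 1L))   # G derived vs outgroup C
  expect_equal(m$states[, 2], c(0L, 1L, 2L))   # A derived, gap -> OTHER
  # without an outgroup the majority allele is ancestral
  m2 <- parse_fasta(path)
  expect_equal(ncol(m2$states), 2)
  # ragged alignments are rejected
  writeLines(c(">a", "ACGT", ">b", "ACG"), path)
  expect_error(parse_fasta(path), "ragged")
})
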