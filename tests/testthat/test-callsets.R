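test_that("variant classification follows allele lengths", {
  expect_equal(classify_variant("A", "G"), "SNV")
  expect_equal(classify_variant("AG", "TC"), "MNV")
  expect_equal(classify_variant("A", "AAG"), "INDEL")
  expect_equal(classify_variant(c("A", "ACGT", "GT"), c("T", "A", "CA")),
               c("SNV", "INDEL", "MNV"))
})

test_that("multiallelic split plus trimming yields the forced representations", {
  # ref=AT alt=AG,A at pos 100: the AG allele trims to an SNV at 101 (T>G),
  # the A allele stays an AT>A deletion anchored at 100
  t1 <- trim_alleles(100L, "AT", "AG")
  expect_equal(t1, list(pos = 101L, ref = "T", alt = "G"))
  t2 <- trim_alleles(100L, "AT", "A")
  expect_equal(t2, list(pos = 100L, ref = "AT", alt = "A"))
  # shared suffix is removed before the prefix
  t3 <- trim_alleles(50L, "CAG", "CTG")
  expect_equal(t3, list(pos = 51L, ref = "A", alt = "T"))
})

test_that("normalization trims redundant representations and is idempotent", {
  raw <- make_calls("chr1", c(100, 100, 200, 300),
                    ref = c("AT", "AT", "c", "GGG"),
                    alt = c("AG", "A", "t", "GGA"),
                    vaf = c(0.03, 0.04, 0.5, 0.2))
  norm <- normalize_calls(raw)
  expect_setequal(variant_key(norm),
                  c("chr1:101:T:G", "chr1:100:AT:A", "chr1:200:C:T",
                    "chr1:302:G:A"))
  expect_identical(normalize_calls(norm), norm)

  # duplicate keys collapse; non-ACGT alleles are skipped with a message
  dup <- make_calls("chr1", c(10, 10, 20), alt = c("G", "G", "<DEL>"),
                    vaf = c(0.1, 0.3, 0.2))
  expect_message(out <- normalize_calls(dup), "1 record")
  expect_equal(nrow(out), 1L)
  expect_equal(out$vaf, 0.3)
})

test_that("read_vcf splits multiallelics and honors the VAF source priority", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tAT\tAG,A\t.\tPASS\tAF=0.05,0.12",
    "chr1\t200\t.\tC\tT\t.\tPASS\tAF=0.034",
    "chr1\t300\t.\tG\t<DUP>\t.\tPASS\tAF=0.5"
  ), vcf)
  cs <- suppressMessages(
    read_vcf(vcf, panel = "P", lab = "L1", sample = "A", replicate = 2)
  )
  expect_equal(nrow(cs), 3L)
  expect_setequal(variant_key(cs),
                  c("chr1:101:T:G", "chr1:100:AT:A", "chr1:200:C:T"))
  expect_equal(cs$vaf[variant_key(cs) == "chr1:200:C:T"], 0.034)
  expect_equal(cs$vaf[variant_key(cs) == "chr1:101:T:G"], 0.05)
  expect_true(all(cs$replicate == 2L))
})

test_that("read_vcf derives VAF from FORMAT/AD when INFO/AF is absent", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tAD\t95,5",
    "chr1\t200\t.\tG\tA,C\t.\tPASS\t.\tAD\t80,12,8"
  ), vcf)
  cs <- read_vcf(vcf)
  expect_equal(cs$vaf[variant_key(cs) == "chr1:100:C:T"], 0.05)
  expect_equal(cs$vaf[variant_key(cs) == "chr1:200:G:A"], 0.12)
  expect_equal(cs$vaf[variant_key(cs) == "chr1:200:G:C"], 0.08)
})

test_that("read_vcf errors on records with no usable VAF source", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tC\tT\t.\tPASS\t."
  ), vcf)
  expect_error(read_vcf(vcf), "no VAF obtainable.*record 1")
})

test_that("truth matching equals the quadratic oracle on random sets", {
  set.seed(5)
  for (rep in 1:3) {
    truth <- make_calls("chrT", sample.int(500, 60),
                        ref = sample(c("A", "C"), 60, TRUE),
                        alt = sample(c("G", "T"), 60, TRUE))
    calls <- make_calls("chrT", sample.int(500, 80),
                        ref = sample(c("A", "C"), 80, TRUE),
                        alt = sample(c("G", "T"), 80, TRUE),
                        vaf = runif(80))
    m <- match_truth(calls, truth)
    expect_equal(m$truth$detected, match_oracle(calls, truth))
    # shared-key computation is symmetric under relabeling
    m2 <- match_truth(truth, calls)
    expect_equal(sum(m$truth$detected & !duplicated(variant_key(truth))),
                 length(intersect(unique(variant_key(truth)),
                                  unique(variant_key(calls)))))
    expect_equal(length(intersect(unique(variant_key(calls)),
                                  unique(variant_key(truth)))),
                 sum(m2$truth$detected & !duplicated(variant_key(calls))))
  }
})

test_that("calls are labeled KP / KN / unknown against the catalogs", {
  truth <- make_calls("chr1", 100)
  kn <- tibble::tibble(chrom = "chr1", pos = 200L)
  calls <- make_calls("chr1", c(100, 200, 300), vaf = c(0.1, 0.02, 0.3))
  m <- match_truth(calls, truth, kn = kn)
  expect_equal(m$calls$status, c("KP", "KN", "unknown"))
})

test_that("region restriction matches the per-call membership oracle", {
  set.seed(9)
  region <- random_intervals(40, 5000, max_w = 100)
  calls <- make_calls("chrT", sample.int(5000, 300, replace = TRUE),
                      vaf = runif(300))
  got <- restrict_calls(calls, region)
  want <- restrict_oracle(calls, region, "chrT", 5000)
  expect_equal(got$pos, want$pos)
  # empty region and full containment
  expect_equal(nrow(restrict_calls(calls, GenomicRanges::GRanges())), 0L)
  all_in <- region_set("chrT", 0, 5000)
  expect_equal(nrow(restrict_calls(calls, all_in)), nrow(calls))
  # union decomposition over disjoint regions
  r1 <- region_set("chrT", 0, 2000)
  r2 <- region_set("chrT", 3000, 5000)
  expect_equal(
    sort(restrict_calls(calls, region_union(r1, r2))$pos),
    sort(c(restrict_calls(calls, r1)$pos, restrict_calls(calls, r2)$pos))
  )
})

test_that("sample C negatives are the KN positions minus B variant loci", {
  kn <- tibble::tibble(chrom = "chr1", pos = 1:100)
  b <- make_calls("chr1", c(5, 50, 200))
  got <- derive_sample_c_negatives(kn, b)
  expect_equal(got$pos, setdiff(1:100, c(5, 50)))
  expect_equal(derive_sample_c_negatives(kn, b[0, ]), kn)
  expect_equal(nrow(derive_sample_c_negatives(kn[kn$pos %in% c(5, 50), ], b)),
               0L)
})

test_that("truth_for_sample applies the mixture arithmetic", {
  kp <- make_calls("chr1", c(10, 20, 30))[, c("chrom", "pos", "ref", "alt")]
  kp$vaf_a <- c(0.10, 0.30, 0.08)
  kp$provenance <- "cellline"
  b <- make_calls("chr1", 20)  # same key as the second KP
  a <- truth_for_sample(kp, "A")
  expect_equal(a$expected_vaf, kp$vaf_a)
  cc <- truth_for_sample(kp, "C", b_variants = b)
  expect_equal(nrow(cc), 2L)  # B-overlapping KP excluded
  expect_equal(cc$expected_vaf, c(0.05, 0.04))
  sp <- make_calls("chr1", 40)[, c("chrom", "pos", "ref", "alt")]
  s <- truth_for_sample(kp, "SPIKEIN", spike = sp)
  expect_equal(s$expected_vaf, 0.05)
})
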