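test_that("KP VAF spectrum follows the configured stratum weights", {
  cfg <- generator_config(n_kp = 10000, n_kn = 1000, n_b_germline = 50,
                          n_spike = 10)
  truth <- generate_truth(cfg, seed = 3)
  sp <- cfg$vaf_spectrum
  counts <- vapply(seq_len(nrow(sp)), function(i) {
    inside <- truth$kp$vaf_a > sp$low[i] & truth$kp$vaf_a <= sp$high[i]
    if (i == 1) inside <- inside | truth$kp$vaf_a == sp$low[i]
    sum(inside)
  }, numeric(1))
  expect_equal(sum(counts), cfg$n_kp)
  for (i in seq_len(nrow(sp))) {
    se <- sqrt(cfg$n_kp * sp$weight[i] * (1 - sp$weight[i]))
    expect_lt(abs(counts[i] - cfg$n_kp * sp$weight[i]), 3 * se)
  }
  # a one-stratum spectrum concentrates all VAFs there
  cfg1 <- generator_config(n_kp = 200, n_kn = 100, n_b_germline = 20,
                           n_spike = 5,
                           vaf_spectrum = tibble::tibble(
                             low = 0.05, high = 0.10, weight = 1))
  t1 <- generate_truth(cfg1, seed = 4)
  expect_true(all(t1$kp$vaf_a > 0.05 & t1$kp$vaf_a <= 0.10))
})

test_that("truth sets respect their structural invariants", {
  b <- small_bundle()
  # KN and KP positions are disjoint by construction
  expect_equal(length(intersect(position_key(b$kn), position_key(b$kp))), 0L)
  # truth lives inside the CTR
  expect_equal(nrow(restrict_calls(b$kp, b$regions$ctr)), nrow(b$kp))
  expect_equal(nrow(restrict_calls(b$kn, b$regions$ctr)), nrow(b$kn))
  # region nesting: CTR inside HC_CR, CTR inside the panel target
  expect_equal(region_size(region_subtract(b$regions$ctr, b$regions$hccr)), 0)
  expect_equal(region_size(region_subtract(b$regions$ctr, b$regions$panel)), 0)
  # B germline VAFs are diploid
  expect_true(all(b$b_germline$vaf_b %in% c(0.5, 1.0)))
  # the configured overlap fraction of B variants sits on KP loci
  n_ov <- sum(variant_key(b$b_germline) %in% variant_key(b$kp))
  expect_equal(n_ov, round(b$config$b_overlap_frac * b$config$n_b_germline))
})

test_that("identical seeds give identical bundles", {
  cfg <- generator_config(n_kp = 100, n_kn = 500, n_b_germline = 30,
                          n_spike = 10, n_labs = 2, samples = c("A", "B"))
  b1 <- generate_study(cfg, seed = 99)
  b2 <- generate_study(cfg, seed = 99)
  expect_identical(b1$kp, b2$kp)
  expect_identical(b1$calls, b2$calls)
  b3 <- generate_study(cfg, seed = 100)
  expect_false(identical(b3$calls, b1$calls))
})

test_that("sample C carries half the expected VAF of sample A KPs", {
  b <- small_bundle()
  cc <- b$calls[b$calls$sample == "C" & b$calls$origin == "kp", ]
  joined <- dplyr::inner_join(cc, b$kp[, c("chrom", "pos", "ref", "alt",
                                           "vaf_a")],
                              by = c("chrom", "pos", "ref", "alt"))
  # use KPs detected with certainty (well above threshold) so that the
  # reporting cutoff introduces no selection bias in the observed VAFs, and
  # drop KP loci shared with a B germline variant (their sample-C VAF is the
  # sum of both contributions, checked separately below)
  joined <- joined[joined$vaf_a > 0.2 &
                     !(variant_key(joined) %in% variant_key(b$b_germline)), ]
  ratio <- joined$vaf / (joined$vaf_a / 2)
  expect_lt(abs(mean(ratio) - 1), 0.02)
  # sample A shows the full VAF
  ca <- b$calls[b$calls$sample == "A" & b$calls$origin == "kp", ]
  ja <- dplyr::inner_join(ca, b$kp[, c("chrom", "pos", "ref", "alt", "vaf_a")],
                          by = c("chrom", "pos", "ref", "alt"))
  ja <- ja[ja$vaf_a > 0.2, ]
  expect_lt(abs(mean(ja$vaf / ja$vaf_a) - 1), 0.02)
  # KP loci shared with a B germline variant carry both halves in sample C
  shared <- dplyr::inner_join(
    cc, dplyr::inner_join(b$kp[, c("chrom", "pos", "ref", "alt", "vaf_a")],
                          b$b_germline,
                          by = c("chrom", "pos", "ref", "alt")),
    by = c("chrom", "pos", "ref", "alt"))
  expect_gt(nrow(shared), 0)
  exp_vaf <- pmin(1, shared$vaf_a / 2 + shared$vaf_b / 2)
  expect_lt(abs(mean(shared$vaf / exp_vaf) - 1), 0.05)
})

test_that("the noiseless limit detects everything and nothing spurious", {
  cfg <- generator_config(n_kp = 300, n_kn = 500, n_b_germline = 40,
                          n_spike = 10, n_labs = 2, samples = "A",
                          depth = 20000, depth_size = Inf,
                          vaf_threshold = 0, min_alt = 0,
                          fp_rate_in_ctr = 0, fp_rate_out_ctr = 0)
  b <- generate_study(cfg, seed = 12)
  res <- estimate_sensitivity(b$calls, truth_for_sample(b$kp, "A"),
                              strata = vaf_strata(c(0.01, 1)), n_boot = 0)
  expect_equal(res$sensitivity, 1)
  expect_true(all(b$calls$origin != "fp"))
})

test_that("per-library detection frequency matches the analytic probability", {
  cfg <- generator_config(n_kp = 2000, n_kn = 100, n_b_germline = 10,
                          n_spike = 5, n_labs = 3, samples = "A",
                          vaf_spectrum = tibble::tibble(
                            low = 0.03, high = 0.045, weight = 1))
  b <- generate_study(cfg, seed = 21)
  truth <- truth_for_sample(b$kp, "A")
  det <- detection_matrix(b$calls, truth)
  p <- detection_probability(truth$vaf_a, cfg$depth, cfg$vaf_threshold,
                             cfg$min_alt, cfg$depth_size)
  n <- length(det)
  se <- sqrt(sum(p * (1 - p)) * ncol(det)) / n
  expect_lt(abs(mean(det) - mean(p)), 3 * se)
})

test_that("a study directory round-trips through the readers", {
  cfg <- generator_config(n_kp = 120, n_kn = 300, n_b_germline = 30,
                          n_spike = 10, n_labs = 2, n_reps = 2)
  b <- generate_study(cfg, seed = 77)
  dir <- withr::local_tempdir()
  write_study(b, dir)
  back <- read_study(dir)
  # regions and truth survive
  expect_equal(region_size(back$regions$ctr), region_size(b$regions$ctr))
  expect_setequal(variant_key(back$kp), variant_key(b$kp))
  expect_setequal(position_key(back$kn), position_key(b$kn))
  # calls: same keys per library, VAFs to write precision
  for (l in unique(paste(b$calls$lab, b$calls$sample, b$calls$replicate))) {
    sel <- paste(b$calls$lab, b$calls$sample, b$calls$replicate) == l
    sel2 <- paste(back$calls$lab, back$calls$sample, back$calls$replicate) == l
    expect_setequal(variant_key(back$calls[sel2, ]),
                    variant_key(b$calls[sel, ]))
  }
  ord <- function(df) df[order(df$lab, df$sample, df$replicate, df$chrom,
                               df$pos, df$alt), ]
  expect_equal(ord(back$calls)$vaf, ord(b$calls)$vaf, tolerance = 1e-5)
})

test_that("TMB catalog counts honor range, size and dispersion settings", {
  cat0 <- generate_tmb_catalog(0)
  expect_equal(nrow(cat0$mutations), 0L)
  cat <- generate_tmb_catalog(50, tmb_range = c(5, 40), seed = 6)
  expect_true(all(cat$tmb$tmb >= 4.9 & cat$tmb$tmb <= 40.1))
  expect_true(all(cat$mutations$pos >= 1))
  # pair probability solves the dispersion target
  c2 <- generate_tmb_catalog(5, overdispersion = 1.31, seed = 7)
  p <- c2$params$p_pair
  expect_equal((1 + 3 * p) / (1 + p), 1.31)
  expect_error(generate_tmb_catalog(5, overdispersion = 3.2))
})
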