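test_that("KP eligibility filtering and banding follow the VAF rules", {
  b <- small_bundle()
  kps <- prepare_tmb_kps(b$kp, b$b_germline, b$regions$ctr)
  expect_true(all(kps$vaf_a >= 0.05 & kps$vaf_a <= 0.40))
  expect_false(any(variant_key(kps) %in% variant_key(b$b_germline)))
  expect_equal(kps$band, ifelse(kps$vaf_a > 0.10, "high", "mid"))
})

test_that("thinning retains the banded fractions within binomial error", {
  kps <- tibble::tibble(chrom = "chr1", pos = 1:10000, ref = "A", alt = "G",
                        vaf_a = runif(10000, 0.05, 0.40))
  kps$band <- ifelse(kps$vaf_a > 0.10, "high", "mid")
  set.seed(8)
  ret <- sample_base_region(kps, k = 10)
  for (band in c("high", "mid")) {
    p <- if (band == "high") 0.10 else 0.05
    n <- sum(kps$band == band)
    got <- sum(ret[kps$band == band])
    expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)))
  }
  # k = 100 keeps every high-band KP
  expect_true(all(sample_base_region(kps, 100)[kps$band == "high"]))
  expect_error(sample_base_region(kps, 0))
})

test_that("technical CV arithmetic on constant counts", {
  ctr <- region_set("chr1", 0, 1e6)
  empty_kp <- tibble::tibble(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             vaf_a = numeric())
  no_b <- empty_kp
  # two libraries with fixed distinct counts: 90 and 110 non-KP calls
  calls <- dplyr::bind_rows(
    make_calls("chr1", 1:90, vaf = 0.3, sample = "C", replicate = 1),
    make_calls("chr1", 101:210, vaf = 0.3, sample = "C", replicate = 2)
  )
  res <- suppressWarnings(
    technical_cv(calls, empty_kp, ctr, no_b, k = 5, cutoffs = 0.025,
                 n_rounds = 10, seed = 1)
  )
  expect_equal(res$mean_count, 100)
  expect_equal(res$variance, 200)  # var(c(90, 110))
  expect_equal(res$cv, sqrt(200) / 100)
  expect_equal(res$mean_tmb, 100 / 1)
  # identical libraries give zero CV
  same <- dplyr::bind_rows(
    make_calls("chr1", 1:50, vaf = 0.3, sample = "C", replicate = 1),
    make_calls("chr1", 1:50, vaf = 0.3, sample = "C", replicate = 2)
  )
  res0 <- suppressWarnings(
    technical_cv(same, empty_kp, ctr, no_b, k = 5, cutoffs = 0.025,
                 n_rounds = 5)
  )
  expect_equal(res0$cv, 0)
  expect_error(
    suppressWarnings(
      technical_cv(same[same$replicate == 1, ], empty_kp, ctr, no_b, k = 5)
    ),
    "at least 2"
  )
})

test_that("projection reproduces the reference TMB on the full region", {
  cat <- generate_tmb_catalog(40, seed = 5)
  proj <- project_tmb(cat, cat$shared_region, panel = "full")
  expect_equal(proj$tmb_panel, cat$tmb$tmb)
  expect_error(project_tmb(cat, region_set("cds1", 0, 1e5)), "below")
  # a sample with no mutations projects to zero
  cat2 <- cat
  keep <- cat2$mutations$sample != cat2$tmb$sample[1]
  cat2$mutations <- cat2$mutations[keep, ]
  proj2 <- project_tmb(cat2, cat$shared_region, panel = "full")
  expect_equal(proj2$tmb_panel[1], 0)
})

test_that("projection counts match a brute-force membership oracle", {
  set.seed(17)
  shared <- region_set("cds1", 0, 4e5)
  cat <- generate_tmb_catalog(15, shared_region = shared)
  cov <- random_subregion(shared, 3e5)
  proj <- project_tmb(cat, cov, panel = "p")
  mask <- region_mask(cov, "cds1", 4e5)
  for (i in seq_len(nrow(proj))) {
    mu <- cat$mutations[cat$mutations$sample == proj$sample[i], ]
    expect_equal(proj$n_mut[i], sum(mask[mu$pos]))
  }
})

test_that("MSD arithmetic and decomposition identities hold", {
  # five hand-written (reference, panel) TMB pairs
  t <- c(6, 7, 8, 9, 10)
  p <- c(5, 8, 7, 11, 9)
  cat <- list(tmb = tibble::tibble(sample = sprintf("S%d", 1:5), tmb = t))
  proj <- tibble::tibble(panel = "P", sample = sprintf("S%d", 1:5),
                         n_mut = NA_integer_, tmb_panel = p)
  res <- msd_decompose(proj, cat, group_size = 5, tmb_range = c(0, 100))
  expect_equal(res$msd, mean((t - p)^2))
  expect_equal(res$msd_prime, mean((mean(t) - p)^2))
  expect_equal(res$bias2, (mean(t) - mean(p))^2)
  pvar <- function(x) mean((x - mean(x))^2)
  expect_equal(res$adj_variance, pvar(p) - pvar(t))
  # exact identity with population variances
  expect_equal(res$msd_prime, pvar(p) + res$bias2)
  # perfect projection decomposes to zeros
  res0 <- msd_decompose(proj |> dplyr::mutate(tmb_panel = t), cat,
                        group_size = 5, tmb_range = c(0, 100))
  expect_equal(res0$msd, 0)
  expect_equal(res0$bias2, 0)
  expect_equal(res0$adj_variance, 0)
  expect_error(msd_decompose(proj, cat, group_size = 2), "at least 3")
})

test_that("msd approaches msd_prime - var(ref) as group spread shrinks", {
  set.seed(23)
  for (spread in c(2, 0.5, 0.1)) {
    t <- 20 + runif(60, -spread, spread)
    p <- t + rnorm(60, 0, 1)
    cat <- list(tmb = tibble::tibble(sample = sprintf("S%d", 1:60), tmb = t))
    proj <- tibble::tibble(panel = "P", sample = sprintf("S%d", 1:60),
                           n_mut = NA_integer_, tmb_panel = p)
    res <- msd_decompose(proj, cat, group_size = 60, tmb_range = c(0, 100))
    pvar <- function(x) mean((x - mean(x))^2)
    gap <- abs(res$msd - (res$msd_prime - pvar(t)))
    # the residual is twice the centered cross-covariance of t and p
    expect_equal(gap, abs(2 * mean((t - mean(t)) * (p - mean(p))) -
                            2 * pvar(t)),
                 tolerance = 1e-8)
  }
})

test_that("a Poisson-sampled catalog yields a near-unit dispersion slope", {
  cat <- generate_tmb_catalog(600, overdispersion = 1, seed = 29)
  sizes <- c(PA = 3e5, PB = 6e5)
  msd <- dplyr::bind_rows(lapply(names(sizes), function(p) {
    cov <- random_subregion(cat$shared_region, sizes[[p]])
    msd_decompose(project_tmb(cat, cov, panel = p), cat, group_size = 100)
  }))
  m <- fit_intrinsic_model(msd, sizes / 1e6)
  expect_lt(abs(m$coef - 1), 0.08)
  expect_gt(m$r2, 0.8)
})

test_that("intrinsic and overall CV formulas are exact", {
  expect_equal(intrinsic_cv(21, coef = 1.15), 1.15 / sqrt(21))
  expect_equal(intrinsic_cv(c(10, 40), coef = 1), c(1 / sqrt(10), 1 / sqrt(40)))
  expect_equal(overall_cv(0, 0.25), 0.25)
  expect_equal(overall_cv(0.1, 0.1), 0.1 * sqrt(2))
  expect_true(all(overall_cv(0.07, 0.11) >= pmax(0.07, 0.11)))
  # invalid fits are rejected
  msd <- tibble::tibble(panel = "P", mean_panel = c(1, 2),
                        adj_variance = c(-1, -2))
  expect_error(fit_intrinsic_model(msd, c(P = 1)), "non-positive")
})
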