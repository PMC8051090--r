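#' Configuration for the synthetic study generator
#'
#' Defines the statistical structure of a simulated multi-laboratory
#' oncopanel study: a toy genome with nested HC_CR / CTR regions and a panel
#' target spanning all three sub-regions; a known-positive catalog whose VAF
#' spectrum follows the reference admixture sample (about 7% of KPs in
#' 1–2.5%, 18% in 2.5–5%, 25% in 5–10% and 18% in 10–20%, remainder above
#' 20%); a dense known-negative list covering about half of the CTR; a
#' diploid normal germline catalog; a 5%-VAF spike-in catalog; and per-library
#' read sampling with a reporting threshold. Sample C is a 1:1 mixture of A
#' and B and is sequenced twice as deep.
#'
#' @param chrom_sizes Named integer vector of toy chromosome sizes.
#' @param n_kp Number of known positives placed uniformly in the CTR.
#' @param vaf_spectrum Tibble (`low`, `high`, `weight`) of VAF strata for
#'   sample-A KP VAFs; draws are uniform within a stratum.
#' @param indel_fraction Fraction of KPs that are non-SNV (small indels and
#'   MNVs combined).
#' @param n_kn Number of known-negative positions (non-KP CTR loci).
#' @param n_b_germline Sample-B germline variant count; `b_overlap_frac` of
#'   them coincide with KP loci (same variant), exercising the exclusion
#'   rules.
#' @param b_overlap_frac See `n_b_germline`.
#' @param n_spike Spike-in variant count, all at `spike_vaf`.
#' @param spike_vaf Expected spike-in VAF (default 0.05).
#' @param n_labs,n_reps Laboratories and library replicates per sample.
#' @param samples Which reference samples to sequence.
#' @param depth Mean per-variant read depth for samples A, B and the
#'   spike-in; sample C uses `depth * c_depth_factor`.
#' @param c_depth_factor Depth multiplier for sample C (default 2).
#' @param depth_size Negative-binomial size parameter of the per-variant
#'   depth draw (`Inf` gives fixed depth). The consortium's per-panel depth
#'   targets are vendor-specific; this is a documented stand-in for coverage
#'   variability.
#' @param min_alt Minimum alt-read count for a call to be emitted.
#' @param vaf_threshold Panel VAF reporting threshold: a call is emitted iff
#'   its observed VAF (alt reads / depth) reaches it.
#' @param panel Panel label.
#' @param fp_rate_in_ctr,fp_rate_out_ctr Injected per-base per-library
#'   error-call rates inside the CTR and outside it (both other
#'   sub-regions).
#' @param fp_vaf_min,fp_vaf_scale Injected FP VAFs follow
#'   `fp_vaf_min + Exponential(scale)`: most mass below 5% and essentially
#'   none above 10%, so the closed-form tail
#'   `P(vaf >= c) = exp(-(c - fp_vaf_min)/scale)` is available to oracle
#'   tests (see [fp_tail_prob()]).
#' @param batch_effect Optional numeric vector (length `n_labs`) of per-lab
#'   depth multipliers; `NULL` means no batch effect.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    chrom_sizes = c(chr1 = 10e6, chr2 = 10e6, chr3 = 10e6),
    n_kp = 4000,
    vaf_spectrum = tibble::tibble(
      low = c(0.01, 0.025, 0.05, 0.10, 0.20),
      high = c(0.025, 0.05, 0.10, 0.20, 1.00),
      weight = c(0.07, 0.18, 0.25, 0.18, 0.32)
    ),
    indel_fraction = 0.012,
    n_kn = 1e6,
    n_b_germline = 1000,
    b_overlap_frac = 0.05,
    n_spike = 300,
    spike_vaf = 0.05,
    n_labs = 3,
    n_reps = 4,
    samples = c("A", "B", "C", "SPIKEIN"),
    depth = 1000,
    c_depth_factor = 2,
    depth_size = 60,
    min_alt = 3,
    vaf_threshold = 0.01,
    panel = "PANEL1",
    fp_rate_in_ctr = 5e-6,
    fp_rate_out_ctr = 2e-5,
    fp_vaf_min = 0.01,
    fp_vaf_scale = 0.015,
    batch_effect = NULL) {
  stopifnot(all(vaf_spectrum$weight >= 0), sum(vaf_spectrum$weight) > 0,
            depth > 0, n_reps >= 2, n_labs >= 1,
            indel_fraction >= 0, indel_fraction < 1)
  cfg <- as.list(environment())
  cfg$vaf_spectrum$weight <- vaf_spectrum$weight / sum(vaf_spectrum$weight)
  if (is.null(cfg$batch_effect)) cfg$batch_effect <- rep(1, n_labs)
  stopifnot(length(cfg$batch_effect) == n_labs)
  class(cfg) <- "generator_config"
  cfg
}

#' Toy genome region structure for the generator
#'
#' Builds nested regions on the configured chromosomes: per chromosome, ten
#' 100-kb HC_CR blocks; a CTR sub-block inside each; and a panel target made
#' of the whole CTR, a slice of HC_CR outside the CTR, and a slice outside
#' the HC_CR. Defaults give roughly CTR 2.0 Mb, HC_CR 3.0 Mb, panel 3.1 Mb.
#'
#' @param chrom_sizes Named vector of chromosome sizes.
#' @return A list of `GRanges`: `panel`, `ctr`, `hccr`.
#' @export
default_regions <- function(chrom_sizes = c(chr1 = 10e6, chr2 = 10e6,
                                            chr3 = 10e6)) {
  chroms <- names(chrom_sizes)
  blocks <- expand.grid(chrom = chroms, j = 0:9, stringsAsFactors = FALSE)
  b0 <- blocks$j * 1e6 + 1e5
  hccr <- region_set(blocks$chrom, b0, b0 + 1e5, name = "HC_CR")
  ctr <- region_set(blocks$chrom, b0 + 2e4, b0 + 86667, name = "CTR")
  panel <- normalize_region(c(
    ctr,
    region_set(blocks$chrom, b0, b0 + 2e4),
    region_set(blocks$chrom, b0 + 2e5, b0 + 216667)
  ), name = "panel")
  list(panel = panel, ctr = ctr, hccr = hccr)
}

# Uniformly sample positions (1-based) from a region set, without
# replacement by default. Returns a tibble (chrom, pos).
sample_region_positions <- function(region, n, replace = FALSE) {
  w <- as.numeric(GenomicRanges::width(region))
  total <- sum(w)
  if (!replace && n > total) {
    stop("cannot place ", n, " distinct positions in ", total, " bases")
  }
  idx <- if (replace) ceiling(runif(n) * total) else sample.int(total, n)
  offs <- cumsum(c(0, w))
  int <- findInterval(idx - 0.5, offs)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(region))[int],
    pos = as.integer(GenomicRanges::start(region)[int] + (idx - offs[int] - 1))
  )
}

BASES <- c("A", "C", "G", "T")

random_snv_alleles <- function(n) {
  ref <- sample(BASES, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- BASES[(match(ref, BASES) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

random_seq <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

random_indel_alleles <- function(n) {
  ref <- character(n)
  alt <- character(n)
  ins <- runif(n) < 0.5
  for (i in seq_len(n)) {
    anchor <- sample(BASES, 1L)
    tail_len <- sample.int(3L, 1L)
    if (ins[i]) {
      ref[i] <- anchor
      alt[i] <- paste0(anchor, random_seq(tail_len))
    } else {
      ref[i] <- paste0(anchor, random_seq(tail_len))
      alt[i] <- anchor
    }
  }
  list(ref = ref, alt = alt)
}

random_mnv_alleles <- function(n) {
  a <- random_snv_alleles(n)
  b <- random_snv_alleles(n)
  list(ref = paste0(a$ref, b$ref), alt = paste0(a$alt, b$alt))
}

#' Generate the truth sets and regions of a synthetic study
#'
#' Places known positives uniformly in the CTR with sample-A VAFs drawn from
#' the configured spectrum, known negatives at non-KP CTR positions, a
#' diploid sample-B germline catalog (VAF 50% or 100%, a configured fraction
#' coinciding with KP loci), and a spike-in catalog at a fixed VAF. KN and
#' KP positions are disjoint by construction.
#'
#' @param cfg A [generator_config()].
#' @param seed Optional integer seed (set it here only when calling this
#'   function stand-alone; [generate_study()] seeds once for the bundle).
#' @return A list: `regions` (panel/ctr/hccr), `kp`, `kn`, `b_germline`,
#'   `spike`.
#' @export
generate_truth <- function(cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- default_regions(cfg$chrom_sizes)
  n_b_new <- cfg$n_b_germline - round(cfg$b_overlap_frac * cfg$n_b_germline)
  n_total <- cfg$n_kp + cfg$n_kn + n_b_new + cfg$n_spike
  pool <- sample_region_positions(regions$ctr, n_total)
  take <- function(n) {
    out <- pool[seq_len(n), , drop = FALSE]
    pool <<- pool[-seq_len(n), , drop = FALSE]
    out
  }

  # known positives: VAF spectrum, small non-SNV share
  kp <- take(cfg$n_kp)
  sp <- cfg$vaf_spectrum
  stratum <- sample.int(nrow(sp), cfg$n_kp, replace = TRUE, prob = sp$weight)
  kp$vaf_a <- runif(cfg$n_kp, sp$low[stratum], sp$high[stratum])
  n_nonsnv <- round(cfg$indel_fraction * cfg$n_kp)
  n_mnv <- round(n_nonsnv / 3)
  n_indel <- n_nonsnv - n_mnv
  kind <- rep("SNV", cfg$n_kp)
  kind[sample.int(cfg$n_kp, n_nonsnv)] <- rep(c("INDEL", "MNV"),
                                              c(n_indel, n_mnv))
  kp$ref <- kp$alt <- NA_character_
  for (k in c("SNV", "INDEL", "MNV")) {
    i <- which(kind == k)
    if (length(i) == 0L) next
    al <- switch(k,
                 SNV = random_snv_alleles(length(i)),
                 INDEL = random_indel_alleles(length(i)),
                 MNV = random_mnv_alleles(length(i)))
    kp$ref[i] <- al$ref
    kp$alt[i] <- al$alt
  }
  kp$vtype <- classify_variant(kp$ref, kp$alt)
  kp$provenance <- "cellline"
  kp <- kp[, c("chrom", "pos", "ref", "alt", "vtype", "vaf_a", "provenance")]

  kn <- take(cfg$n_kn)

  # sample-B germline: mostly fresh loci, some coinciding with KPs
  n_ov <- cfg$n_b_germline - n_b_new
  b_new <- take(n_b_new)
  al <- random_snv_alleles(n_b_new)
  b_new$ref <- al$ref
  b_new$alt <- al$alt
  b_ov <- kp[sample.int(nrow(kp), n_ov), c("chrom", "pos", "ref", "alt")]
  b <- dplyr::bind_rows(b_new[, c("chrom", "pos", "ref", "alt")], b_ov)
  b$vaf_b <- sample(c(0.5, 1.0), nrow(b), replace = TRUE, prob = c(2, 1) / 3)

  spike <- take(cfg$n_spike)
  al <- random_snv_alleles(cfg$n_spike)
  spike$ref <- al$ref
  spike$alt <- al$alt
  spike$vtype <- "SNV"
  spike$vaf_a <- NA_real_
  spike$provenance <- "spikein"

  list(regions = regions, kp = kp, kn = kn, b_germline = b, spike = spike)
}

# Expected variant content (key, expected VAF, origin) of one reference
# sample. Sample C halves both contributions and sums them at shared loci.
expected_variants <- function(truth, sample, cfg) {
  kp <- truth$kp[, c("chrom", "pos", "ref", "alt")]
  kp$evaf <- truth$kp$vaf_a
  kp$origin <- "kp"
  b <- truth$b_germline[, c("chrom", "pos", "ref", "alt")]
  b$evaf <- truth$b_germline$vaf_b
  b$origin <- "germline"
  if (sample == "A") return(kp)
  if (sample == "B") return(b)
  if (sample == "C") {
    kp$evaf <- kp$evaf / 2
    b$evaf <- b$evaf / 2
    df <- dplyr::bind_rows(kp, b)
    key <- variant_key(df)
    tot <- tapply(df$evaf, key, sum)
    df <- df[!duplicated(key), , drop = FALSE]
    df$evaf <- pmin(1, unname(tot[variant_key(df)]))
    return(df)
  }
  if (sample == "SPIKEIN") {
    s <- truth$spike[, c("chrom", "pos", "ref", "alt")]
    s$evaf <- cfg$spike_vaf
    s$origin <- "spike"
    return(dplyr::bind_rows(b, s))
  }
  stop("unknown sample '", sample, "'")
}

#' Generate the multi-laboratory replicate call sets of a synthetic study
#'
#' Per library, each expected variant's alt-read count is drawn from
#' `Binomial(depth, expected VAF)` with a per-variant depth draw, and a call
#' is emitted iff the observed VAF reaches the panel's reporting threshold
#' and the alt count reaches the minimum. False-positive calls are injected
#' as a Poisson process over each panel sub-region at the configured error
#' rates, with VAFs from the decaying low-VAF distribution. Every call
#' carries an `origin` column (`"kp"`, `"germline"`, `"spike"`, `"fp"`)
#' recording its generative source.
#'
#' @param truth Output of [generate_truth()].
#' @param cfg The same [generator_config()].
#' @param seed Optional integer seed (see [generate_truth()]).
#' @return A normalized call set tibble covering all labs, samples and
#'   replicates.
#' @export
generate_callsets <- function(truth, cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- truth$regions
  compartments <- list(
    list(region = region_intersect(regions$panel, regions$ctr),
         rate = cfg$fp_rate_in_ctr),
    list(region = region_subtract(region_intersect(regions$panel,
                                                   regions$hccr),
                                  regions$ctr),
         rate = cfg$fp_rate_out_ctr),
    list(region = region_subtract(regions$panel, regions$hccr),
         rate = cfg$fp_rate_out_ctr)
  )
  labs <- sprintf("LAB%d", seq_len(cfg$n_labs))
  out <- list()
  for (li in seq_len(cfg$n_labs)) {
    for (smp in cfg$samples) {
      exp_v <- expected_variants(truth, smp, cfg)
      d_mean <- cfg$depth * cfg$batch_effect[li] *
        if (smp == "C") cfg$c_depth_factor else 1
      for (r in seq_len(cfg$n_reps)) {
        n <- nrow(exp_v)
        d <- if (is.finite(cfg$depth_size)) {
          pmax(1L, rnbinom(n, mu = d_mean, size = cfg$depth_size))
        } else {
          rep(round(d_mean), n)
        }
        alt_reads <- rbinom(n, d, exp_v$evaf)
        obs <- alt_reads / d
        keep <- obs >= cfg$vaf_threshold & alt_reads >= cfg$min_alt
        det <- exp_v[keep, , drop = FALSE]
        det$vaf <- obs[keep]
        fps <- lapply(compartments, function(cp) {
          size <- region_size(cp$region)
          n_fp <- rpois(1L, cp$rate * size)
          if (n_fp == 0L) return(NULL)
          fp <- sample_region_positions(cp$region, n_fp, replace = TRUE)
          al <- random_snv_alleles(n_fp)
          fp$ref <- al$ref
          fp$alt <- al$alt
          fp$evaf <- NA_real_
          fp$origin <- "fp"
          fp$vaf <- pmin(0.999, cfg$fp_vaf_min + rexp(n_fp, 1 / cfg$fp_vaf_scale))
          fp[fp$vaf >= cfg$vaf_threshold, , drop = FALSE]
        })
        lib <- dplyr::bind_rows(c(list(det), fps))
        if (nrow(lib) == 0L) next
        lib$panel <- cfg$panel
        lib$lab <- labs[li]
        lib$sample <- smp
        lib$replicate <- r
        out[[length(out) + 1L]] <-
          lib[, c("panel", "lab", "sample", "replicate", "chrom", "pos",
                  "ref", "alt", "vaf", "origin")]
      }
    }
  }
  calls <- dplyr::bind_rows(out)
  calls$vtype <- classify_variant(calls$ref, calls$alt)
  normalize_calls(calls)
}

#' Generate a complete synthetic study bundle
#'
#' Seeds the generator once and produces truth sets, regions and call sets,
#' together with the exact configuration used (the generative truth for
#' parameter-recovery tests). Identical seeds give identical bundles.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @return A list of class `study_bundle`: `config`, `regions`, `kp`, `kn`,
#'   `b_germline`, `spike`, `calls`.
#' @export
generate_study <- function(cfg = generator_config(), seed = 1) {
  set.seed(seed)
  truth <- generate_truth(cfg)
  calls <- generate_callsets(truth, cfg)
  structure(
    list(config = cfg, regions = truth$regions, kp = truth$kp, kn = truth$kn,
         b_germline = truth$b_germline, spike = truth$spike, calls = calls,
         seed = seed),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Synthetic oncopanel study bundle\n")
  cat(sprintf("  panel %s: %d labs x %d replicates, samples %s\n",
              x$config$panel, x$config$n_labs, x$config$n_reps,
              paste(x$config$samples, collapse = "/")))
  cat(sprintf("  truth: %d KPs, %d KNs, %d B-germline, %d spike-in\n",
              nrow(x$kp), nrow(x$kn), nrow(x$b_germline), nrow(x$spike)))
  cat(sprintf("  calls: %d across %d libraries\n", nrow(x$calls),
              length(unique(paste(x$calls$lab, x$calls$sample,
                                  x$calls$replicate)))))
  invisible(x)
}

#' Analytic per-library detection probability
#'
#' Probability that a variant with a given expected VAF is called by one
#' library: the binomial upper tail of the alt-read count clearing both the
#' VAF reporting threshold and the minimum alt-read count, integrated over
#' the depth distribution when depth is negative-binomial. This is the
#' boundary-effect mechanism in closed form and serves as the independent
#' oracle for the generator's detection model.
#'
#' @param vaf Numeric vector of expected VAFs.
#' @param depth Mean depth.
#' @param threshold VAF reporting threshold.
#' @param min_alt Minimum alt-read count.
#' @param depth_size Negative-binomial size (`Inf` = fixed depth).
#' @return Vector of detection probabilities.
#' @export
detection_probability <- function(vaf, depth, threshold = 0, min_alt = 0,
                                  depth_size = Inf) {
  tail_at <- function(d) {
    need <- pmax(ceiling(d * threshold), min_alt)
    1 - pbinom(need - 1, d, vaf)
  }
  if (!is.finite(depth_size)) {
    return(tail_at(round(depth)))
  }
  ds <- qnbinom(1e-7, mu = depth, size = depth_size):
    qnbinom(1 - 1e-7, mu = depth, size = depth_size)
  ds <- pmax(ds, 1L)
  w <- dnbinom(ds, mu = depth, size = depth_size)
  w <- w / sum(w)
  out <- numeric(length(vaf))
  for (i in seq_along(ds)) out <- out + w[i] * tail_at(ds[i])
  out
}

#' Tail probability of the injected false-positive VAF distribution
#'
#' @param cutoff VAF cutoff.
#' @param vaf_min,scale Parameters of the shifted-exponential FP VAF model
#'   (see [generator_config()]).
#' @return `P(FP VAF >= cutoff)`.
#' @export
fp_tail_prob <- function(cutoff, vaf_min = 0.01, scale = 0.015) {
  exp(-(pmax(cutoff, vaf_min) - vaf_min) / scale)
}

#' Generate a TCGA-like per-sample mutation catalog
#'
#' Each sample's exome-level TMB is uniform over `tmb_range`; its mutations
#' are placed on a coding-sequence-like shared region. Overdispersion beyond
#' Poisson in panel-projected counts is injected by placing a fraction of
#' mutations as adjacent pairs: with pair probability
#' `p = (overdispersion - 1) / (3 - overdispersion)` the index of dispersion
#' of a small-fraction projection equals `overdispersion`.
#'
#' @param n_samples Number of catalog samples.
#' @param tmb_range Reference TMB range in mutations/Mb (default 5–40).
#' @param overdispersion Target count-level index of dispersion in
#'   `[1, 3)`.
#' @param shared_region `GRanges` of the shared CDS/CTR region; default a
#'   single 20-Mb toy coding region.
#' @param seed Optional integer seed.
#' @return A list of class `tmb_catalog`: `mutations` (`sample`, `chrom`,
#'   `pos`), `tmb` (`sample`, `tmb` recomputed exactly as in-region count
#'   over size), `shared_region`, `params`.
#' @export
generate_tmb_catalog <- function(n_samples, tmb_range = c(5, 40),
                                 overdispersion = 1,
                                 shared_region = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(overdispersion >= 1, overdispersion < 3)
  if (is.null(shared_region)) {
    shared_region <- region_set("cds1", 0, 20e6, name = "CDS_CTR")
  }
  size_mb <- region_size(shared_region) / 1e6
  p_pair <- (overdispersion - 1) / (3 - overdispersion)
  samples <- sprintf("S%05d", seq_len(n_samples))
  muts <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    n_i <- round(runif(1, tmb_range[1L], tmb_range[2L]) * size_mb)
    sizes <- 1L + rbinom(n_i, 1L, p_pair)
    cum <- cumsum(sizes)
    j <- which(cum >= n_i)[1L]
    sizes <- sizes[seq_len(j)]
    sizes[j] <- sizes[j] - (cum[j] - n_i)
    sizes <- sizes[sizes > 0L]
    starts <- sample_region_positions(shared_region, length(sizes),
                                      replace = TRUE)
    two <- sizes == 2L
    pos <- c(starts$pos, starts$pos[two] + 1L)
    chrom <- c(starts$chrom, starts$chrom[two])
    muts[[i]] <- tibble::tibble(sample = samples[i], chrom = chrom, pos = pos)
  }
  mutations <- dplyr::bind_rows(c(
    list(tibble::tibble(sample = character(), chrom = character(),
                        pos = integer())),
    muts
  ))
  in_region <- restrict_calls(mutations, shared_region)
  counts <- table(factor(in_region$sample, levels = samples))
  structure(
    list(
      mutations = mutations,
      tmb = tibble::tibble(sample = samples,
                           tmb = as.integer(counts) / size_mb),
      shared_region = shared_region,
      params = list(overdispersion = overdispersion, p_pair = p_pair,
                    tmb_range = tmb_range)
    ),
    class = "tmb_catalog"
  )
}

#' Draw a random sub-region of a given total size
#'
#' Takes a contiguous block of the region's cumulative coordinate space, so
#' the result respects interval boundaries and has exactly the requested
#' size. Used to carve panel covered regions out of a shared region.
#'
#' @param region A normalized `GRanges`.
#' @param size Target size in bases.
#' @param seed Optional integer seed.
#' @return A normalized `GRanges` of total width `size`.
#' @export
random_subregion <- function(region, size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- as.numeric(GenomicRanges::width(region))
  total <- sum(w)
  stopifnot(size > 0, size <= total)
  u <- floor(runif(1, 0, total - size + 1))
  offs <- cumsum(c(0, w))
  chroms <- as.character(GenomicRanges::seqnames(region))
  starts <- GenomicRanges::start(region)
  pieces <- list()
  for (i in seq_along(w)) {
    a <- max(u, offs[i])
    b <- min(u + size, offs[i + 1L])
    if (b > a) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = chroms[i],
        start0 = starts[i] - 1 + (a - offs[i]),
        end = starts[i] - 1 + (b - offs[i])
      )
    }
  }
  df <- do.call(rbind, pieces)
  region_set(df$chrom, df$start0, df$end)
}
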