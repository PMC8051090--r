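#' Reference intrinsic-CV coefficient
#'
#' Coefficient of the intrinsic-CV relation `cv = coef / sqrt(mean count)`
#' as fitted on a large pan-cancer whole-exome mutation catalog projected
#' onto panel-sized regions. Provided as a named constant for replication;
#' the estimators themselves always use a coefficient fitted on the supplied
#' catalog (see [fit_intrinsic_model()]).
#'
#' @export
reference_intrinsic_coef <- 1.15

#' Eligible known positives for the TMB thinning simulation
#'
#' Prepares the KP list the run-to-run simulation thins: sample-B germline
#' variants are removed (they are not somatic signal), KPs with sample-A VAF
#' below 5% or above 40% are removed (so that, in the 1:1 mixture sample C,
#' remaining expected VAFs lie in 2.5–20%), and the list is restricted to
#' the CTR. Each KP is banded by its sample-A VAF: `"high"` for (10%, 40%],
#' `"mid"` for 5–10% inclusive below.
#'
#' @param kp Known-positive tibble with `vaf_a`.
#' @param b_variants Sample-B germline tibble.
#' @param ctr `GRanges` of the consensus targeted region.
#' @return The eligible KP tibble with a `band` column.
#' @export
prepare_tmb_kps <- function(kp, b_variants, ctr) {
  kp <- kp[!(variant_key(kp) %in% variant_key(b_variants)), , drop = FALSE]
  kp <- kp[kp$vaf_a >= 0.05 & kp$vaf_a <= 0.40, , drop = FALSE]
  kp <- restrict_calls(kp, ctr)
  kp$band <- ifelse(kp$vaf_a > 0.10, "high", "mid")
  kp
}

#' Draw one thinned KP retention defining a base-report-region
#'
#' Retains each eligible KP independently: with probability `k`% for the
#' high VAF band (10–40% in sample A) and `0.5 * k`% for the mid band
#' (5–10%), emulating samples with tumor-like mutation prevalence. The
#' positions of the non-retained KPs are excluded from the report region, so
#' any call at an excluded locus (FPs and uncharacterized variants included)
#' is dropped from the simulated reports.
#'
#' @param kps Eligible KP tibble from [prepare_tmb_kps()].
#' @param k Retention percent (0 < k <= 100).
#' @return Logical retention vector along the rows of `kps`. A band with no
#'   KPs triggers a warning; an empty retention is possible at small `k`.
#' @export
sample_base_region <- function(kps, k) {
  stopifnot(k > 0, k <= 100)
  for (b in c("high", "mid")) {
    if (!any(kps$band == b)) warning("no eligible KPs in the ", b, " VAF band")
  }
  p <- ifelse(kps$band == "high", k / 100, k / 200)
  runif(nrow(kps)) < p
}

#' Technical run-to-run CV of panel TMB via KP thinning
#'
#' For each retention percent `k` and VAF cutoff, repeatedly (i) thins the
#' eligible KPs to a tumor-like prevalence, (ii) counts each sample-C
#' library's reported calls above the cutoff within the base-report-region
#' (CTR minus the excluded KP loci), and (iii) takes the mean and variance
#' of the counts across library replicates. The technical CV is
#' `sqrt(overall average variance) / overall average mean count`, and the
#' mean TMB is the overall average count divided by the report-region size
#' in Mb.
#'
#' @param calls Sample-C call set tibble for one panel (all libraries; the
#'   replicates of the run-to-run comparison). Sample-B germline calls and
#'   calls matching ineligible KPs (sample-A VAF below 5% or above 40%) are
#'   removed before counting, mirroring their removal from the KP list.
#' @param kp Full known-positive catalog (with `vaf_a`); eligibility and
#'   banding are derived internally via [prepare_tmb_kps()].
#' @param ctr `GRanges` of the CTR.
#' @param b_variants Sample-B germline tibble excluded from the call sets.
#' @param k Vector of retention percents (k = 0 is excluded from CV
#'   estimation: its counts are essentially the FP floor).
#' @param cutoffs VAF cutoffs applied to reported calls.
#' @param n_rounds Simulation rounds per (k, cutoff).
#' @param seed Optional integer seed.
#' @param detail If `TRUE`, attach per-round means and variances as the
#'   `"rounds"` attribute (one tibble per k x cutoff).
#' @return A tibble per (k, cutoff): `mean_count`, `variance`, `cv`,
#'   `report_mb`, `mean_tmb`, `n_libraries`, `n_rounds`.
#' @export
technical_cv <- function(calls, kp, ctr, b_variants,
                         k = c(1, 2, 5, 10, 20),
                         cutoffs = c(0.025, 0.05),
                         n_rounds = 5000, seed = NULL, detail = FALSE) {
  stopifnot(all(k > 0), n_rounds >= 1)
  if (!is.null(seed)) set.seed(seed)
  kps <- prepare_tmb_kps(kp, b_variants, ctr)
  calls <- restrict_calls(calls, ctr)
  drop_keys <- c(variant_key(b_variants),
                 setdiff(variant_key(kp), variant_key(kps)))
  calls <- calls[!(variant_key(calls) %in% drop_keys), , drop = FALSE]
  libs <- unique(lib_id(calls))
  if (length(libs) < 2L) {
    stop("technical_cv requires at least 2 library replicates")
  }
  ctr_size <- region_size(ctr)
  kp_pos <- position_key(kps)
  n_kp <- nrow(kps)
  rounds_out <- list()
  rows <- list()
  for (kk in k) {
    # retention matrix: one column per simulation round
    p <- ifelse(kps$band == "high", kk / 100, kk / 200)
    ret <- matrix(runif(n_kp * n_rounds) < p, nrow = n_kp, ncol = n_rounds)
    n_excluded <- n_kp - colSums(ret)
    report_mb <- (ctr_size - mean(n_excluded)) / 1e6
    for (ct in cutoffs) {
      counts <- matrix(0, nrow = length(libs), ncol = n_rounds)
      for (i in seq_along(libs)) {
        df <- calls[lib_id(calls) == libs[i] & calls$vaf >= ct, ,
                    drop = FALSE]
        at_kp <- match(position_key(df), kp_pos)
        n_other <- sum(is.na(at_kp))
        hit <- at_kp[!is.na(at_kp)]
        counts[i, ] <- n_other + if (length(hit) > 0L) {
          colSums(ret[hit, , drop = FALSE])
        } else 0
      }
      m <- colMeans(counts)
      v <- apply(counts, 2L, var)
      mean_count <- mean(m)
      variance <- mean(v)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        k = kk, cutoff = ct, mean_count = mean_count, variance = variance,
        cv = sqrt(variance) / mean_count, report_mb = report_mb,
        mean_tmb = mean_count / report_mb,
        n_libraries = length(libs), n_rounds = n_rounds
      )
      if (detail) {
        rounds_out[[sprintf("k%g_cutoff%g", kk, ct)]] <-
          tibble::tibble(round = seq_len(n_rounds), mean = m, variance = v)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (detail) attr(out, "rounds") <- rounds_out
  out
}

#' Project exome-level mutation catalogs onto a panel region
#'
#' The panel-measured TMB of each catalog sample is the number of its
#' mutations falling in the panel's covered region (panel target
#' intersected with the CTR and the coding sequence) divided by that
#' region's size in Mb. Panels covering less than `min_size` bases are
#' rejected: their sampling variability makes the projection meaningless.
#'
#' @param catalog A TMB catalog (see [generate_tmb_catalog()]): a list with
#'   `mutations` (`sample`, `chrom`, `pos`), `tmb` (`sample`, `tmb`) and
#'   `shared_region`.
#' @param panel_cov `GRanges` of the panel's covered region.
#' @param panel Panel label attached to the result.
#' @param min_size Minimum covered size in bases (default 250 kb).
#' @return A tibble per catalog sample: `panel`, `sample`, `n_mut`,
#'   `tmb_panel`; the covered size in Mb is the `"size_mb"` attribute.
#' @export
project_tmb <- function(catalog, panel_cov, panel = "panel",
                        min_size = 250e3) {
  size <- region_size(panel_cov)
  if (size < min_size) {
    stop("panel '", panel, "' covers ", size,
         " bases, below the ", min_size, " minimum for TMB projection")
  }
  mut <- restrict_calls(catalog$mutations, panel_cov)
  counts <- table(factor(mut$sample, levels = catalog$tmb$sample))
  out <- tibble::tibble(
    panel = panel,
    sample = catalog$tmb$sample,
    n_mut = as.integer(counts),
    tmb_panel = as.integer(counts) / (size / 1e6)
  )
  attr(out, "size_mb") <- size / 1e6
  out
}

#' Mean-squared-deviation decomposition of panel TMB error
#'
#' Samples are filtered to the reference TMB range, sorted by reference TMB
#' and cut into consecutive groups. Per group, the deviation of the
#' panel-projected TMB from the reference TMB is decomposed: `msd` is the
#' mean squared deviation; `msd_prime` replaces each sample's reference TMB
#' by the group mean; `bias2` is the squared difference of group means; and
#' `adj_variance = var(panel TMB) - var(reference TMB)` is the variance
#' component attributable to the panel sampling a genomic subset. Variances
#' are population (1/N) variances, making
#' `msd_prime = var(panel TMB) + bias2` an exact identity and
#' `msd = msd_prime - var(reference TMB)` exact up to the within-group
#' covariance of reference and panel TMB.
#'
#' Samples whose deviation sits more than `outlier_sd` group standard
#' deviations from the group mean deviation are excluded with a message.
#'
#' @param proj Projection tibble from [project_tmb()].
#' @param catalog The TMB catalog the projection came from.
#' @param group_size Consecutive samples per group (>= 3); a trailing
#'   partial group is dropped.
#' @param tmb_range Reference TMB range retained (default 5–40).
#' @param outlier_sd Outlier threshold in group standard deviations.
#' @return A tibble per group: `panel`, `group`, `n`, `mean_ref`,
#'   `mean_panel`, `msd`, `msd_prime`, `bias2`, `adj_variance`.
#' @export
msd_decompose <- function(proj, catalog, group_size = 100,
                          tmb_range = c(5, 40), outlier_sd = 5) {
  if (group_size < 3) stop("group_size must be at least 3")
  df <- dplyr::inner_join(proj, catalog$tmb, by = "sample")
  df <- df[df$tmb >= tmb_range[1L] & df$tmb <= tmb_range[2L], , drop = FALSE]
  df <- df[order(df$tmb), , drop = FALSE]
  n_groups <- nrow(df) %/% group_size
  if (n_groups < 1L) stop("fewer samples than one full group")
  rows <- lapply(seq_len(n_groups), function(g) {
    idx <- ((g - 1L) * group_size + 1L):(g * group_size)
    t <- df$tmb[idx]
    p <- df$tmb_panel[idx]
    dev <- t - p
    out_flag <- abs(dev - mean(dev)) > outlier_sd * sd(dev)
    if (any(out_flag)) {
      message("msd_decompose: excluded ", sum(out_flag),
              " outlier sample(s) in group ", g)
      t <- t[!out_flag]
      p <- p[!out_flag]
    }
    n <- length(t)
    pvar <- function(x) mean((x - mean(x))^2)
    tibble::tibble(
      panel = proj$panel[1L], group = g, n = n,
      mean_ref = mean(t), mean_panel = mean(p),
      msd = mean((t - p)^2),
      msd_prime = mean((mean(t) - p)^2),
      bias2 = (mean(t) - mean(p))^2,
      adj_variance = pvar(p) - pvar(t)
    )
  })
  dplyr::bind_rows(rows)
}

#' Fit the intrinsic-CV model across panels
#'
#' Converts each group's adjusted panel TMB variance to the mutation-count
#' scale (multiplying by the squared panel size in Mb) and regresses it
#' against the group's mean panel mutation count (mean panel TMB times panel
#' size). The through-origin least-squares slope is the count-level index of
#' dispersion; its square root is the coefficient of the intrinsic-CV
#' relation `cv(c) = coef / sqrt(c)`. A free-intercept fit is reported as a
#' diagnostic.
#'
#' @param msd_results MSD tibbles (rows for one or more panels, from
#'   [msd_decompose()]), stacked.
#' @param panel_sizes Named numeric vector of covered panel sizes in Mb.
#' @return An object of class `intrinsic_model`: `slope`, `slope_se`,
#'   `coef`, `r2`, `free_intercept`, `free_slope`, `n_points`.
#' @export
fit_intrinsic_model <- function(msd_results, panel_sizes) {
  sz <- panel_sizes[msd_results$panel]
  if (any(is.na(sz))) stop("panel_sizes is missing entries for some panels")
  x <- msd_results$mean_panel * sz
  y <- msd_results$adj_variance * sz^2
  fit0 <- lm(y ~ 0 + x)
  slope <- unname(coef(fit0)[["x"]])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive fitted slope: intrinsic model invalid for this input")
  }
  free <- lm(y ~ x)
  out <- list(
    slope = slope,
    slope_se = unname(sqrt(diag(vcov(fit0)))[1L]),
    coef = sqrt(slope),
    r2 = summary(fit0)$r.squared,
    free_intercept = unname(coef(free)[1L]),
    free_slope = unname(coef(free)[2L]),
    n_points = length(x)
  )
  class(out) <- "intrinsic_model"
  out
}

#' @export
print.intrinsic_model <- function(x, ...) {
  cat("Intrinsic TMB CV model: cv(count) = coef / sqrt(count)\n")
  cat(sprintf("  slope (count-level dispersion): %.4f (se %.4f)\n",
              x$slope, x$slope_se))
  cat(sprintf("  coef = sqrt(slope):             %.4f\n", x$coef))
  cat(sprintf("  through-origin R^2:             %.4f on %d group points\n",
              x$r2, x$n_points))
  cat(sprintf("  free fit (diagnostic):          intercept %.3f, slope %.4f\n",
              x$free_intercept, x$free_slope))
  invisible(x)
}

#' Intrinsic CV at a given mean mutation count
#'
#' @param mean_count Panel TMB mean in mutation count (TMB rate times the
#'   panel's covered size in Mb).
#' @param coef Coefficient, either from a fitted [fit_intrinsic_model()]
#'   (`model$coef`) or the replication constant
#'   [reference_intrinsic_coef].
#' @return `coef / sqrt(mean_count)`, vectorized.
#' @examples
#' intrinsic_cv(21, coef = reference_intrinsic_coef)  # about 0.251
#' @export
intrinsic_cv <- function(mean_count, coef = reference_intrinsic_coef) {
  stopifnot(all(mean_count > 0))
  coef / sqrt(mean_count)
}

#' Overall TMB CV combining technical and intrinsic components
#'
#' The two components arise from independent mechanisms (run-to-run
#' measurement noise vs genomic subsampling), so they combine in
#' quadrature.
#'
#' @param cv_technical,cv_intrinsic Numeric vectors of component CVs.
#' @return `sqrt(cv_technical^2 + cv_intrinsic^2)`.
#' @export
overall_cv <- function(cv_technical, cv_intrinsic) {
  sqrt(cv_technical^2 + cv_intrinsic^2)
}
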