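#' Default VAF strata
#'
#' The four low-VAF ranges used for stratified performance reporting:
#' 1–2.5%, 2.5–5%, 5–10% and 10–20%. Strata are half-open `(low, high]`
#' except the lowest, which is closed below, so consecutive strata partition
#' the VAF axis without double counting.
#'
#' @param bounds Increasing numeric vector of stratum boundaries (fractions).
#' @return A tibble with columns `low`, `high`, `label`.
#' @export
vaf_strata <- function(bounds = c(0.01, 0.025, 0.05, 0.10, 0.20)) {
  stopifnot(length(bounds) >= 2L, all(diff(bounds) > 0))
  tibble::tibble(
    low = bounds[-length(bounds)],
    high = bounds[-1L],
    label = sprintf("%g-%g%%", 100 * bounds[-length(bounds)],
                    100 * bounds[-1L])
  )
}

#' Assign VAF values to strata
#'
#' @param vaf Numeric vector of VAF fractions.
#' @param strata A strata tibble from [vaf_strata()].
#' @return Integer stratum index (row of `strata`), `NA` if outside all.
#' @export
stratum_index <- function(vaf, strata) {
  idx <- rep(NA_integer_, length(vaf))
  for (i in seq_len(nrow(strata))) {
    inside <- vaf > strata$low[i] & vaf <= strata$high[i]
    if (i == 1L) inside <- inside | vaf == strata$low[i]
    idx[inside & is.na(idx)] <- i
  }
  idx
}

#' Clustered bootstrap confidence interval for pooled sensitivity
#'
#' Two-stage percentile bootstrap honoring the dependence of library
#' replicates within a laboratory: labs are resampled with replacement, then
#' libraries within each sampled lab. The statistic is the pooled
#' sensitivity, total detections over total assessed known positives.
#'
#' @param det Logical detection matrix (known positives x libraries), as from
#'   [detection_matrix()].
#' @param labs Character vector of lab labels, one per column of `det`.
#' @param n_boot Number of bootstrap resamples (>= 200 recommended).
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @return Numeric `c(ci_low, ci_high)`. With a single lab containing a
#'   single library the interval is degenerate at the point estimate and a
#'   warning is emitted.
#' @export
bootstrap_ci <- function(det, labs, n_boot = 1000, conf = 0.95, seed = NULL) {
  stopifnot(ncol(det) == length(labs))
  if (!is.null(seed)) set.seed(seed)
  d <- colSums(det)
  n <- rep(nrow(det), ncol(det))
  point <- sum(d) / sum(n)
  lab_u <- unique(labs)
  if (length(lab_u) == 1L && ncol(det) == 1L) {
    warning("single lab with a single library: degenerate interval")
    return(c(ci_low = point, ci_high = point))
  }
  cols_by_lab <- split(seq_along(labs), labs)
  n_lab <- length(lab_u)
  stats <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    picked <- lab_u[sample.int(n_lab, n_lab, replace = TRUE)]
    cols <- unlist(lapply(cols_by_lab[picked], function(j) {
      j[sample.int(length(j), length(j), replace = TRUE)]
    }), use.names = FALSE)
    stats[b] <- sum(d[cols]) / sum(n[cols])
  }
  alpha <- 1 - conf
  ci <- unname(quantile(stats, c(alpha / 2, 1 - alpha / 2), names = FALSE))
  c(ci_low = ci[1L], ci_high = ci[2L])
}

#' VAF-stratified sensitivity with clustered bootstrap intervals
#'
#' Sensitivity is the portion of known positives detected, pooled over
#' libraries: total detections divided by (known positives targeted x
#' libraries). Stratification uses the expected (characterized) VAF of the
#' truth catalog, not the observed VAF of the calls. Strata with no known
#' positive are flagged not assessable (`sensitivity` is `NA`).
#'
#' @param calls A call set tibble (several libraries of one panel/sample).
#' @param truth A truth tibble with an `expected_vaf` column (see
#'   [truth_for_sample()]); `vaf_a` is used if `expected_vaf` is absent.
#' @param strata A strata tibble, default [vaf_strata()].
#' @param region Optional `GRanges`; truth and calls are restricted to it.
#' @param method `"pooled"` (default; sum of detections over all libraries)
#'   or `"average"` (mean of per-library sensitivities).
#' @param n_boot Bootstrap resamples for the 95% interval; `0` skips the
#'   bootstrap (`ci_low`/`ci_high` become `NA`).
#' @param conf Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @param libs Optional character vector of library ids (`lab.replicate`)
#'   making up the denominator; defaults to the libraries present in
#'   `calls`. Pass it when filtering might empty a library entirely.
#' @return A tibble with one row per stratum: counts, sensitivity, interval
#'   bounds and an `assessable` flag.
#' @export
estimate_sensitivity <- function(calls, truth, strata = vaf_strata(),
                                 region = NULL,
                                 method = c("pooled", "average"),
                                 n_boot = 1000, conf = 0.95, seed = NULL,
                                 libs = NULL) {
  method <- match.arg(method)
  if (!"expected_vaf" %in% names(truth)) truth$expected_vaf <- truth$vaf_a
  if (is.null(libs)) libs <- unique(paste(calls$lab, calls$replicate, sep = "."))
  if (!is.null(region)) {
    truth <- restrict_calls(truth, region)
    calls <- restrict_calls(calls, region)
  }
  det <- detection_matrix(calls, truth, libs = libs)
  n_lib <- ncol(det)
  labs <- sub("\\.[^.]*$", "", colnames(det))
  idx <- stratum_index(truth$expected_vaf, strata)
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    in_s <- which(!is.na(idx) & idx == i)
    n_kp <- length(in_s)
    if (n_kp == 0L || n_lib == 0L) {
      return(tibble::tibble(
        stratum = strata$label[i], low = strata$low[i], high = strata$high[i],
        n_kp = n_kp, n_libraries = n_lib, detected = 0L,
        sensitivity = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        assessable = FALSE
      ))
    }
    sub <- det[in_s, , drop = FALSE]
    sens <- if (method == "pooled") {
      sum(sub) / (n_kp * n_lib)
    } else {
      mean(colMeans(sub))
    }
    if (n_boot > 0L) {
      ci <- bootstrap_ci(sub, labs, n_boot = n_boot, conf = conf, seed = seed)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    tibble::tibble(
      stratum = strata$label[i], low = strata$low[i], high = strata$high[i],
      n_kp = n_kp, n_libraries = n_lib, detected = sum(sub),
      sensitivity = sens, ci_low = ci[[1L]], ci_high = ci[[2L]],
      assessable = TRUE
    )
  })
  dplyr::bind_rows(rows)
}

#' Sensitivity under a sweep of artificial VAF cutoffs
#'
#' For each cutoff, calls with observed VAF below the cutoff are removed
#' before matching; sensitivity is then non-increasing in the cutoff. This
#' exposes the boundary effect: a variant whose sampled VAF straddles the
#' reporting threshold is lost in some replicates.
#'
#' @param calls,truth,strata,region,method As in [estimate_sensitivity()].
#' @param cutoffs Numeric vector of VAF cutoffs (fractions), ascending.
#' @param n_boot Bootstrap resamples per cutoff (default 0: no intervals,
#'   sweeps are usually exploratory).
#' @param seed Optional seed.
#' @return A tibble: one row per cutoff x stratum.
#' @export
cutoff_sweep <- function(calls, truth, cutoffs, strata = vaf_strata(),
                         region = NULL, method = c("pooled", "average"),
                         n_boot = 0, seed = NULL) {
  stopifnot(!is.unsorted(cutoffs))
  method <- match.arg(method)
  libs <- unique(paste(calls$lab, calls$replicate, sep = "."))
  rows <- lapply(cutoffs, function(ct) {
    kept <- calls[calls$vaf >= ct, , drop = FALSE]
    res <- estimate_sensitivity(kept, truth, strata = strata, region = region,
                                method = method, n_boot = n_boot, seed = seed,
                                libs = libs)
    res$cutoff <- ct
    res
  })
  out <- dplyr::bind_rows(rows)
  out[, c("cutoff", setdiff(names(out), "cutoff"))]
}
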