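#' Non-symmetric pairwise reproducibility
#'
#' For an ordered pair of library replicates of the same sample, the value
#' is the portion of the first library's calls (optionally restricted to a
#' VAF stratum applied to the first library only) that are also called in
#' the second library, matched by normalized variant key with no restriction
#' on the second library's VAF. The measure is directional:
#' `value(x -> y)` generally differs from `value(y -> x)`.
#'
#' @param libx,liby Call set tibbles for the two libraries.
#' @param stratum Optional one-row stratum (from [vaf_strata()]) or numeric
#'   `c(low, high)`; applied to `libx`'s observed VAFs, half-open
#'   `(low, high]`.
#' @return Fraction in `[0, 1]`, or `NA` (flagged, not 0) when `libx` has no
#'   call in the stratum.
#' @export
pair_reproducibility <- function(libx, liby, stratum = NULL) {
  x <- libx
  if (!is.null(stratum)) {
    lo <- if (is.list(stratum) || is.data.frame(stratum)) stratum$low else stratum[1L]
    hi <- if (is.list(stratum) || is.data.frame(stratum)) stratum$high else stratum[2L]
    x <- x[x$vaf > lo & x$vaf <= hi, , drop = FALSE]
  }
  xk <- unique(variant_key(x))
  if (length(xk) == 0L) return(NA_real_)
  mean(xk %in% variant_key(liby))
}

#' Aggregate intra-lab and cross-lab reproducibility
#'
#' Computes the non-symmetric reproducibility over all ordered pairs of
#' libraries of one panel/sample, stratified by the first library's VAF, and
#' averages per scope: pairs sharing a lab are intra-lab measurements, pairs
#' from different labs cross-lab measurements.
#'
#' @param calls A call set tibble holding all libraries of one panel/sample.
#' @param strata Strata tibble applied to the first library of each pair;
#'   use a single wide stratum (e.g. `vaf_strata(c(0.025, 0.20))`) for an
#'   unstratified summary.
#' @param region Optional `GRanges` restriction applied to both libraries.
#' @param per_pair If `TRUE`, return the per-pair table instead of the
#'   aggregate.
#' @param phred_cap Cap for the Phred transform of a perfect value.
#' @return A tibble per stratum x scope with `n_pairs` (pairs with a defined
#'   value), `mean_repro` and `phred`; or the per-pair table when
#'   `per_pair = TRUE`.
#' @export
reproducibility <- function(calls, strata = vaf_strata(), region = NULL,
                            per_pair = FALSE, phred_cap = 60) {
  if (!is.null(region)) calls <- restrict_calls(calls, region)
  libs <- unique(lib_id(calls))
  if (length(libs) < 2L) stop("reproducibility requires at least 2 libraries")
  lab_of <- vapply(libs, function(l) {
    calls$lab[lib_id(calls) == l][1L]
  }, character(1))
  split_calls <- lapply(libs, function(l) {
    calls[lib_id(calls) == l, , drop = FALSE]
  })
  names(split_calls) <- libs
  pairs <- expand.grid(from = libs, to = libs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    vals <- mapply(function(fx, ty) {
      pair_reproducibility(split_calls[[fx]], split_calls[[ty]],
                           stratum = strata[i, ])
    }, pairs$from, pairs$to)
    tibble::tibble(
      stratum = strata$label[i],
      from_lib = pairs$from, to_lib = pairs$to,
      scope = ifelse(lab_of[pairs$from] == lab_of[pairs$to],
                     "intra", "cross"),
      value = as.numeric(vals)
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (per_pair) return(tab)
  agg <- dplyr::summarise(
    dplyr::group_by(tab, stratum, scope),
    n_pairs = sum(!is.na(value)),
    mean_repro = mean(value, na.rm = TRUE),
    .groups = "drop"
  )
  agg$mean_repro[agg$n_pairs == 0L] <- NA_real_
  agg$phred <- phred(agg$mean_repro, cap = phred_cap)
  agg
}

#' Phred-scaled reproducibility
#'
#' Maps a reproducibility fraction `r` to `-10 * log10(1 - r)`, the standard
#' Phred transform of the miss probability `1 - r`; a perfect value of 1
#' maps to the configured cap.
#'
#' @param r Numeric vector in `[0, 1]` (`NA` passed through).
#' @param cap Value returned for a perfect fraction and the upper bound
#'   overall.
#' @return Numeric vector on the Phred scale.
#' @examples
#' phred(c(0.9, 0.99, 1))  # 10, 20, 60
#' @export
phred <- function(r, cap = 60) {
  stopifnot(all(r >= 0 & r <= 1, na.rm = TRUE))
  out <- -10 * log10(1 - r)
  out[!is.na(r) & r >= 1] <- cap
  pmin(out, cap)
}
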