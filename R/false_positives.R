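#' False-positive rate via known-negative positions
#'
#' A false positive is any call sitting on a known-negative (KN) position.
#' The KN catalog is only defined within the consensus targeted region, so
#' both the calls and the KN list are restricted to the supplied region
#' before counting. The rate is reported as FP calls per million KN
#' positions; multiple alternate alleles at one KN position count as
#' distinct FP calls.
#'
#' @param calls A call set tibble (one or more libraries).
#' @param kn Known-negative tibble (`chrom`, `pos`); must be non-empty.
#' @param cutoff Minimum observed VAF for a call to be counted (fraction).
#' @param region Optional `GRanges` (typically the panel's CTR portion) used
#'   to restrict both calls and KN positions.
#' @return A tibble with one row per library: `method`, `cutoff`, `n_fp`,
#'   `denominator` (KN position count) and `rate` (per million).
#' @export
fp_via_kn <- function(calls, kn, cutoff = 0, region = NULL) {
  if (nrow(kn) == 0L) stop("fp_via_kn requires a non-empty KN position list")
  if (!is.null(region)) {
    kn <- restrict_calls(kn, region)
    calls <- restrict_calls(calls, region)
    if (nrow(kn) == 0L) stop("no KN positions remain inside the region")
  }
  kn_keys <- position_key(kn)
  per_library_fp(calls, function(df) {
    sum(df$vaf >= cutoff & position_key(df) %in% kn_keys)
  }, method = "viaKN", cutoff = cutoff, denominator = nrow(kn))
}

#' False-positive rate from low-VAF calls in the normal sample B
#'
#' Sample B is a pure diploid normal, so true variants sit near 50% or 100%
#' VAF; calls inside the low-VAF window are counted as false positives.
#' A call whose variant is seen with VAF above `sibling_vaf` in any other
#' sample-B replicate at the same laboratory is excluded (it is supported
#' elsewhere, so more likely a real mosaic/germline signal than noise). With
#' fewer than two replicates at a lab the exclusion rule is skipped with a
#' warning. The denominator is the evaluated region size in bases.
#'
#' @param calls Sample-B call set tibble (all replicates of one panel).
#' @param region `GRanges` over which the rate is evaluated.
#' @param cutoff Minimum VAF; the effective window is
#'   `[max(window[1], cutoff), window[2]]`.
#' @param window Inclusive low-VAF window marking FPs (default 1–10%).
#' @param sibling_vaf Sibling-replicate VAF above which a variant is
#'   excluded from the FP count (default 10%).
#' @return A tibble with one row per library (`method = "B_low"`).
#' @export
fp_b_low <- function(calls, region, cutoff = 0, window = c(0.01, 0.10),
                     sibling_vaf = 0.10) {
  if (nrow(calls) > 0L && !all(calls$sample == "B")) {
    stop("fp_b_low expects sample B call sets only")
  }
  calls <- restrict_calls(calls, region)
  lo <- max(window[1L], cutoff)
  hi <- window[2L]
  denom <- region_size(region)
  high_keys_by_lib <- split(
    variant_key(calls)[calls$vaf > sibling_vaf],
    lib_id(calls)[calls$vaf > sibling_vaf]
  )
  per_library_fp(calls, function(df) {
    this_lib <- lib_id(df)[1L]
    this_lab <- df$lab[1L]
    n_reps <- length(unique(lib_id(calls)[calls$lab == this_lab]))
    in_window <- df$vaf >= lo & df$vaf <= hi
    if (n_reps < 2L) {
      warning("lab ", this_lab,
              ": fewer than 2 sample-B replicates, sibling exclusion skipped")
      return(sum(in_window))
    }
    sib_libs <- setdiff(unique(lib_id(calls)[calls$lab == this_lab]), this_lib)
    sib_high <- unique(unlist(high_keys_by_lib[sib_libs], use.names = FALSE))
    sum(in_window & !(variant_key(df) %in% sib_high))
  }, method = "B_low", cutoff = cutoff, denominator = denom)
}

#' False-positive rate from mixture-sample exclusivity
#'
#' Every true variant in sample C (a 1:1 mix of A and B) must come from A or
#' B. A call in a sample-C library is a false positive if its variant is
#' absent from all sample-A libraries (at any VAF) and absent from all
#' sample-B libraries at VAF above `b_vaf` at the same laboratory. Because
#' systematic panel errors are called in all three samples, this method is
#' blind to them. The denominator is the evaluated region size in bases.
#'
#' @param calls_c Sample-C call set tibble.
#' @param calls_a,calls_b Sample-A and sample-B call set tibbles covering the
#'   same laboratories; missing a lab is an error (the method is unavailable
#'   there).
#' @param region `GRanges` over which the rate is evaluated.
#' @param cutoff Minimum observed VAF for a C call to be assessed.
#' @param b_vaf VAF floor for the sample-B lookup (default 10%).
#' @return A tibble with one row per C library (`method = "C_only"`).
#' @export
fp_c_only <- function(calls_c, calls_a, calls_b, region, cutoff = 0,
                      b_vaf = 0.10) {
  if (nrow(calls_c) > 0L && !all(calls_c$sample == "C")) {
    stop("fp_c_only expects sample C call sets in `calls_c`")
  }
  labs <- unique(calls_c$lab)
  missing_a <- setdiff(labs, unique(calls_a$lab))
  missing_b <- setdiff(labs, unique(calls_b$lab))
  if (length(missing_a) > 0L || length(missing_b) > 0L) {
    stop("C_only unavailable: no sample A/B libraries for lab(s) ",
         paste(union(missing_a, missing_b), collapse = ", "))
  }
  calls_c <- restrict_calls(calls_c, region)
  a_keys_by_lab <- split(variant_key(calls_a), calls_a$lab)
  b_high <- calls_b[calls_b$vaf > b_vaf, , drop = FALSE]
  b_keys_by_lab <- split(variant_key(b_high), b_high$lab)
  denom <- region_size(region)
  per_library_fp(calls_c, function(df) {
    lab <- df$lab[1L]
    known <- c(a_keys_by_lab[[lab]], b_keys_by_lab[[lab]])
    sum(df$vaf >= cutoff & !(variant_key(df) %in% known))
  }, method = "C_only", cutoff = cutoff, denominator = denom)
}

# Shared per-library bookkeeping: applies `count_fun` to each library's
# calls and assembles the FPResult rows. Rate is per million units of the
# denominator (KN positions or bases). A library is one (lab, sample,
# replicate): viaKN is routinely applied to samples A and C jointly.
per_library_fp <- function(calls, count_fun, method, cutoff, denominator) {
  full_id <- paste(calls$lab, calls$sample, calls$replicate, sep = ".")
  libs <- if (nrow(calls) > 0L) unique(full_id) else character()
  rows <- lapply(libs, function(l) {
    df <- calls[full_id == l, , drop = FALSE]
    n_fp <- count_fun(df)
    tibble::tibble(
      panel = df$panel[1L], lab = df$lab[1L], sample = df$sample[1L],
      replicate = df$replicate[1L], method = method, cutoff = cutoff,
      n_fp = as.integer(n_fp), denominator = denominator,
      rate = n_fp / (denominator / 1e6)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      panel = character(), lab = character(), sample = character(),
      replicate = integer(), method = character(), cutoff = numeric(),
      n_fp = integer(), denominator = numeric(), rate = numeric()
    )
  }
  out
}

#' False-positive rates by panel sub-region and VAF cutoff
#'
#' Evaluates `B_low` or `C_only` over each of the three panel sub-regions.
#' The known-negative method is only defined within the CTR and is rejected
#' here.
#'
#' @param subregions A [build_subregions()] object.
#' @param method `"B_low"` or `"C_only"`.
#' @param cutoffs Numeric vector of VAF cutoffs.
#' @param ... Arguments forwarded to [fp_b_low()] (`calls`) or
#'   [fp_c_only()] (`calls_c`, `calls_a`, `calls_b`).
#' @return A tibble of per-library results with `part` and `cutoff` columns.
#' @export
fp_by_subregion <- function(subregions, method = c("B_low", "C_only"),
                            cutoffs = c(0.01, 0.025, 0.05), ...) {
  if (identical(method, "viaKN")) {
    stop("viaKN is only defined within the CTR; ",
         "use fp_via_kn() on the in-CTR part directly")
  }
  method <- match.arg(method)
  parts <- c("in_ctr", "in_hccr_out_ctr", "rest")
  rows <- lapply(parts, function(p) {
    reg <- subregions[[p]]
    dplyr::bind_rows(lapply(cutoffs, function(ct) {
      res <- if (method == "B_low") {
        fp_b_low(..., region = reg, cutoff = ct)
      } else {
        fp_c_only(..., region = reg, cutoff = ct)
      }
      res$part <- p
      res
    }))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) out <- out[, c("part", setdiff(names(out), "part"))]
  out
}

#' Recurrence of false-positive calls across library replicates
#'
#' Independent sequencing errors almost never recur at the same variant in
#' two libraries, so recurrent FPs are systematic-error candidates and are
#' listed for inspection.
#'
#' @param fp_calls Tibble of FP calls across libraries (columns `lab`,
#'   `replicate`, `chrom`, `pos`, `ref`, `alt`).
#' @return A list: `recurrence` (fraction of distinct FP variants seen in
#'   two or more libraries; `NA` with a message when there are no FPs),
#'   `n_variants`, and `recurring` (tibble of recurrent variants with their
#'   library counts).
#' @export
fp_reproducibility <- function(fp_calls) {
  if (nrow(fp_calls) == 0L) {
    message("no FP calls: recurrence undefined")
    return(list(recurrence = NA_real_, n_variants = 0L,
                recurring = tibble::tibble(key = character(),
                                           n_libraries = integer())))
  }
  u <- unique(tibble::tibble(key = variant_key(fp_calls),
                             lib = lib_id(fp_calls)))
  counts <- table(u$key)
  rec <- counts[counts >= 2L]
  list(
    recurrence = mean(counts >= 2L),
    n_variants = length(counts),
    recurring = tibble::tibble(key = names(rec),
                               n_libraries = as.integer(rec))
  )
}
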