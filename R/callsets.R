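#' Variant call sets
#'
#' A call set is a tibble with one row per reported variant call and columns
#' `panel`, `lab`, `sample`, `replicate`, `chrom`, `pos` (1-based), `ref`,
#' `alt`, `vtype` and `vaf`. Tibbles from several libraries can be
#' concatenated with `dplyr::bind_rows()`; the estimator functions group by
#' `(panel, lab, sample, replicate)` as needed. Calls are normalized: alleles
#' uppercase over ACGT, multiallelic records split, redundant padding bases
#' trimmed, and the `(chrom, pos, ref, alt)` key unique within a library.
#'
#' @name callset
NULL

#' Variant key
#'
#' The exact-match key `chrom:pos:ref:alt` used throughout for matching calls
#' against truth catalogs and against other libraries.
#'
#' @param x A call set or variant tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return Character vector of keys.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Position key (`chrom:pos`), used for locus-level lookups such as known
#' negatives.
#' @param x A tibble with columns `chrom` and `pos`.
#' @return Character vector of keys.
#' @export
position_key <- function(x) {
  paste(x$chrom, x$pos, sep = ":")
}

lib_id <- function(x) paste(x$lab, x$replicate, sep = ".")

#' Classify a variant by its normalized alleles
#'
#' SNV if both alleles have length 1, MNV if they have equal lengths greater
#' than 1, INDEL otherwise.
#'
#' @param ref,alt Character vectors of normalized alleles.
#' @return Character vector over `"SNV"`, `"MNV"`, `"INDEL"`.
#' @export
classify_variant <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNV", ifelse(lr == la, "MNV", "INDEL"))
}

# Parsimony trimming of one ref/alt pair: shared suffix removed first, then
# shared prefix (advancing pos). Both alleles keep at least one base.
trim_one <- function(pos, ref, alt) {
  r <- strsplit(ref, "", fixed = TRUE)[[1L]]
  a <- strsplit(alt, "", fixed = TRUE)[[1L]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Trim redundant padding bases from variant representations
#'
#' Removes the shared allele suffix, then the shared prefix (advancing the
#' position), leaving a parsimonious representation. Left-alignment through
#' repeat tracts is not attempted: it requires the reference sequence, and
#' exact-key matching is only guaranteed for call sets normalized to the same
#' convention.
#'
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of alleles.
#' @return A list with elements `pos`, `ref`, `alt`.
#' @export
trim_alleles <- function(pos, ref, alt) {
  n <- length(pos)
  needs <- nchar(ref) > 1L | nchar(alt) > 1L
  out_pos <- as.integer(pos)
  out_ref <- ref
  out_alt <- alt
  for (i in which(needs)) {
    t <- trim_one(out_pos[i], ref[i], alt[i])
    out_pos[i] <- t$pos
    out_ref[i] <- t$ref
    out_alt[i] <- t$alt
  }
  list(pos = out_pos, ref = out_ref, alt = out_alt)
}

#' Normalize a call set
#'
#' Uppercases alleles, drops non-ACGT (symbolic/breakend) alleles with a
#' message stating how many were skipped, trims redundant padding, assigns
#' `vtype`, removes records where ref equals alt after trimming, and
#' deduplicates on the variant key (keeping the call with the highest VAF).
#' Idempotent.
#'
#' @param calls A call set tibble.
#' @return The normalized call set, sorted by `(lab, replicate, chrom, pos)`.
#' @export
normalize_calls <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  calls$ref <- toupper(calls$ref)
  calls$alt <- toupper(calls$alt)
  ok <- grepl("^[ACGT]+$", calls$ref) & grepl("^[ACGT]+$", calls$alt)
  if (any(!ok)) {
    message("normalize_calls: skipped ", sum(!ok),
            " record(s) with non-ACGT (symbolic) alleles")
    calls <- calls[ok, , drop = FALSE]
  }
  if (nrow(calls) == 0L) return(calls)
  t <- trim_alleles(calls$pos, calls$ref, calls$alt)
  calls$pos <- t$pos
  calls$ref <- t$ref
  calls$alt <- t$alt
  calls <- calls[calls$ref != calls$alt, , drop = FALSE]
  calls$vtype <- classify_variant(calls$ref, calls$alt)
  calls <- calls[order(-calls$vaf), , drop = FALSE]
  dup <- duplicated(paste(calls$lab, calls$sample, calls$replicate,
                          variant_key(calls)))
  calls <- calls[!dup, , drop = FALSE]
  calls[order(calls$lab, calls$replicate, calls$chrom, calls$pos), ,
        drop = FALSE]
}

# Extract one VAF per alt allele for each VCF record, trying the configured
# sources in order. Returns a list (one numeric vector per record) or stops
# naming the first record with no usable source.
vcf_vafs <- function(vcf, n_alt, sources) {
  n <- length(n_alt)
  out <- vector("list", n)
  fill <- function(vals) {
    for (i in seq_len(n)) {
      if (!is.null(out[[i]])) next
      v <- vals[[i]]
      if (length(v) == 0L || all(is.na(v))) next
      if (length(v) == 1L && n_alt[i] > 1L) v <- rep(v, n_alt[i])
      out[[i]] <<- v[seq_len(n_alt[i])]
    }
  }
  split_num <- function(x) {
    lapply(strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE),
           function(s) suppressWarnings(as.numeric(s)))
  }
  for (src in sources) {
    if (all(!vapply(out, is.null, logical(1)))) break
    if (src == "info_af") {
      af <- tryCatch(vcfR::extract.info(vcf, "AF"), error = function(e) NULL)
      if (!is.null(af)) fill(split_num(af))
    } else if (src == "format_af") {
      af <- tryCatch(vcfR::extract.gt(vcf, "AF"), error = function(e) NULL)
      if (!is.null(af)) fill(split_num(af[, 1L]))
    } else if (src == "format_ad") {
      ad <- tryCatch(vcfR::extract.gt(vcf, "AD"), error = function(e) NULL)
      if (!is.null(ad)) {
        vals <- lapply(split_num(ad[, 1L]), function(d) {
          if (length(d) < 2L || any(is.na(d)) || sum(d) == 0) return(NA_real_)
          d[-1L] / sum(d)
        })
        fill(vals)
      }
    } else {
      stop("unknown VAF source '", src, "'")
    }
  }
  miss <- which(vapply(out, is.null, logical(1)))
  if (length(miss) > 0L) {
    stop("no VAF obtainable from sources [",
         paste(sources, collapse = ", "), "] for record ", miss[1L])
  }
  out
}

#' Read a VCF file into a normalized call set
#'
#' Multiallelic records are split into one call per alternate allele and the
#' per-record VAF is taken from the first available configured source:
#' `INFO/AF`, `FORMAT/AF` of the first sample, or derived from `FORMAT/AD`
#' (alt depth over total depth). Symbolic and breakend alleles are skipped
#' with a message; a record with no usable VAF source is an error naming the
#' record.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param panel,lab,sample,replicate Library identity attached to every call.
#' @param vaf_sources Character vector, tried in order, from
#'   `"info_af"`, `"format_af"`, `"format_ad"`.
#' @return A normalized call set tibble.
#' @export
read_vcf <- function(path, panel = "PANEL", lab = "LAB", sample = "A",
                     replicate = 1L,
                     vaf_sources = c("info_af", "format_af", "format_ad")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  empty <- tibble::tibble(
    panel = character(), lab = character(), sample = character(),
    replicate = integer(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), vtype = character(),
    vaf = numeric()
  )
  if (is.null(fix)) return(empty)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  if (nrow(fix) == 0L) return(empty)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  vafs <- vcf_vafs(v, n_alt, vaf_sources)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  calls <- tibble::tibble(
    panel = panel, lab = lab, sample = sample,
    replicate = as.integer(replicate),
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS)[idx],
    ref = fix$REF[idx],
    alt = unlist(alt_list),
    vtype = NA_character_,
    vaf = unlist(vafs)
  )
  calls <- calls[!is.na(calls$vaf), , drop = FALSE]
  normalize_calls(calls)
}

#' Restrict a call set (or any positioned tibble) to a region
#'
#' Membership is decided by the variant's anchor base: its leftmost (1-based)
#' reference position. Indels or MNVs extending past a region edge are kept
#' if their anchor base is inside.
#'
#' @param calls A tibble with columns `chrom` and `pos`.
#' @param region A normalized `GRanges`.
#' @return The subset of rows whose anchor base falls in `region`.
#' @export
restrict_calls <- function(calls, region) {
  if (nrow(calls) == 0L || length(region) == 0L) {
    return(calls[0L, , drop = FALSE])
  }
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$pos, calls$pos))
  inside <- suppressWarnings(IRanges::overlapsAny(gr, region))
  calls[inside, , drop = FALSE]
}

#' Per-library detection matrix for a truth catalog
#'
#' @param calls A call set tibble (one or more libraries).
#' @param truth A known-variant tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param libs Optional character vector of library ids (`lab.replicate`) to
#'   report columns for; defaults to the libraries present in `calls`.
#'   Supplying it keeps libraries that called nothing in the evaluated
#'   region.
#' @return A logical matrix with one row per truth variant (rownames are
#'   variant keys) and one column per library (`lab.replicate`); `TRUE` where
#'   a call with the identical key exists in that library.
#' @export
detection_matrix <- function(calls, truth, libs = NULL) {
  tk <- variant_key(truth)
  if (is.null(libs)) libs <- unique(lib_id(calls))
  m <- matrix(FALSE, nrow = length(tk), ncol = length(libs),
              dimnames = list(tk, libs))
  if (nrow(calls) > 0L) {
    by_lib <- split(variant_key(calls), lib_id(calls))
    for (l in names(by_lib)) m[, l] <- tk %in% by_lib[[l]]
  }
  m
}

#' Match a call set against truth catalogs
#'
#' A known positive is detected iff a call with the identical
#' `(chrom, pos, ref, alt)` key exists. Each call is labeled `"KP"` (matches
#' a known positive), `"KN"` (sits on a known-negative position) or
#' `"unknown"`.
#'
#' @param calls A call set tibble.
#' @param truth A known-variant tibble.
#' @param kn Optional known-negative tibble with columns `chrom`, `pos`.
#' @return A list with `truth` (input plus logical `detected`, any library)
#'   and `calls` (input plus `status`).
#' @export
match_truth <- function(calls, truth, kn = NULL) {
  tk <- variant_key(truth)
  ck <- variant_key(calls)
  truth$detected <- tk %in% ck
  status <- ifelse(ck %in% tk, "KP", "unknown")
  if (!is.null(kn) && nrow(kn) > 0L) {
    on_kn <- position_key(calls) %in% position_key(kn) & status != "KP"
    status[on_kn] <- "KN"
  }
  calls$status <- status
  list(truth = truth, calls = calls)
}

#' Derive sample C's known-negative positions
#'
#' Sample C is a 1:1 mixture of sample A and the normal sample B, so a
#' position can only be negative in C if it is negative in A and carries no
#' sample-B germline variant.
#'
#' @param kn_a Known-negative tibble for sample A (`chrom`, `pos`).
#' @param b_variants Sample B germline variant tibble (`chrom`, `pos`, ...).
#' @return The subset of `kn_a` not overlapping any B variant position.
#' @export
derive_sample_c_negatives <- function(kn_a, b_variants) {
  if (nrow(kn_a) == 0L || nrow(b_variants) == 0L) return(kn_a)
  kn_a[!(position_key(kn_a) %in% position_key(b_variants)), , drop = FALSE]
}

#' Expected truth catalog for a given reference sample
#'
#' Attaches the `expected_vaf` column used for VAF stratification: sample A
#' keeps its characterized VAF; sample C (a 1:1 dilution with the diploid
#' normal B) halves it and drops known positives overlapping a B germline
#' variant; the spike-in sample carries its variants at a fixed 5% VAF.
#'
#' @param kp Known-positive tibble with `vaf_a` (cell-line provenance).
#' @param sample One of `"A"`, `"C"`, `"SPIKEIN"`.
#' @param b_variants Sample B germline tibble (required for `"C"`).
#' @param spike Spike-in variant tibble (required for `"SPIKEIN"`).
#' @param spike_vaf Expected spike-in VAF (default 0.05).
#' @return The truth tibble with an `expected_vaf` column.
#' @export
truth_for_sample <- function(kp, sample = c("A", "C", "SPIKEIN"),
                             b_variants = NULL, spike = NULL,
                             spike_vaf = 0.05) {
  sample <- match.arg(sample)
  if (sample == "A") {
    kp$expected_vaf <- kp$vaf_a
    return(kp)
  }
  if (sample == "C") {
    if (is.null(b_variants)) {
      stop("sample C truth requires the sample B germline catalog")
    }
    keep <- !(variant_key(kp) %in% variant_key(b_variants))
    kp <- kp[keep, , drop = FALSE]
    kp$expected_vaf <- kp$vaf_a / 2
    return(kp)
  }
  if (is.null(spike)) stop("spike-in truth requires the spike catalog")
  spike$expected_vaf <- spike_vaf
  spike
}
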