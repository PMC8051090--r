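#' Genomic region sets
#'
#' Region sets are plain unstranded [GenomicRanges::GRanges] objects kept in
#' normalized form: sorted, with overlapping and bookended (adjacent)
#' intervals merged, so that the size in bases is unambiguous. BED input and
#' output use the 0-based half-open convention; internally coordinates are
#' the 1-based closed convention native to `GRanges`. The conversion happens
#' exactly once, at the file boundary.
#'
#' @param chrom Character vector of chromosome names (compared as exact
#'   strings; no "chr" aliasing is performed).
#' @param start0 Integer vector of 0-based inclusive start positions.
#' @param end Integer vector of 0-based exclusive end positions.
#' @param name Optional label stored in the object's metadata.
#' @return A normalized `GRanges`.
#' @examples
#' r <- region_set("chr1", c(10, 15), c(20, 30))
#' region_size(r)  # 20: the two overlapping intervals merge into [10, 30)
#' @export
region_set <- function(chrom, start0, end, name = NULL) {
  stopifnot(length(start0) == length(end))
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start0))
  stopifnot(length(chrom) == length(start0))
  if (length(chrom) == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (any(start0 < 0) || any(start0 >= end)) {
    stop("region_set() requires 0 <= start < end for every interval")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end))
  )
  normalize_region(gr, name = name)
}

#' Normalize a region set
#'
#' Sorts intervals and merges overlapping or bookended ones. Idempotent.
#'
#' @param gr A `GRanges`.
#' @param name Optional label stored in metadata.
#' @return A normalized `GRanges`.
#' @export
normalize_region <- function(gr, name = NULL) {
  out <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 1L)
  if (!is.null(name)) S4Vectors::metadata(out)$name <- name
  out
}

#' Read a BED file into a normalized region set
#'
#' Accepts BED3+ (tab-separated `chrom`, `start`, `end`; extra columns and
#' `track`/`browser`/comment lines are ignored). Malformed lines raise an
#' error naming the offending line number.
#'
#' @param path Path to a BED file.
#' @param name Optional label stored in metadata.
#' @return A normalized `GRanges`; an empty file yields an empty region set.
#' @export
read_bed <- function(path, name = NULL) {
  lines <- readLines(path)
  ln <- seq_along(lines)
  drop <- grepl("^(#|track\\b|browser\\b)", lines) | !nzchar(trimws(lines))
  lines <- lines[!drop]
  ln <- ln[!drop]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("malformed BED line ", ln[which(nf < 3L)[1L]], " in '", path,
         "': fewer than 3 tab-separated fields")
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  bad <- is.na(start0) | is.na(end)
  if (any(bad)) {
    stop("malformed BED line ", ln[which(bad)[1L]], " in '", path,
         "': non-integer coordinates")
  }
  bad <- start0 < 0L | start0 >= end
  if (any(bad)) {
    stop("malformed BED line ", ln[which(bad)[1L]], " in '", path,
         "': requires 0 <= start < end")
  }
  region_set(chrom, start0, end, name = name)
}

#' Write a region set to a BED3 file
#'
#' @param region A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(region, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(region)),
    start = GenomicRanges::start(region) - 1L,
    end = GenomicRanges::end(region)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Region set size in bases
#'
#' @param region A `GRanges` (assumed normalized; overlapping intervals would
#'   be double counted).
#' @return Total number of bases covered.
#' @export
region_size <- function(region) {
  sum(as.numeric(GenomicRanges::width(region)))
}

#' Interval algebra on region sets
#'
#' Thin wrappers over the `GenomicRanges` set operations, returning
#' normalized region sets.
#'
#' @param a,b Normalized `GRanges` region sets.
#' @return A normalized `GRanges`.
#' @export
region_intersect <- function(a, b) {
  suppressWarnings(GenomicRanges::intersect(a, b))
}

#' @rdname region_intersect
#' @export
region_subtract <- function(a, b) {
  suppressWarnings(GenomicRanges::setdiff(a, b))
}

#' @rdname region_intersect
#' @export
region_union <- function(a, b) {
  suppressWarnings(GenomicRanges::union(a, b))
}

#' Partition a panel's target region into three evaluation sub-regions
#'
#' Splits the panel target into the part inside the consensus targeted
#' region (CTR), the part inside the high-confidence coding region (HC_CR)
#' but outside the CTR, and the rest. The three parts are pairwise disjoint
#' and their union is the panel target. The CTR must lie entirely within the
#' HC_CR.
#'
#' @param panel,ctr,hccr Normalized `GRanges` region sets.
#' @return An object of class `panel_subregions`: a list with elements
#'   `in_ctr`, `in_hccr_out_ctr` and `rest`.
#' @export
build_subregions <- function(panel, ctr, hccr) {
  if (region_size(region_subtract(ctr, hccr)) > 0) {
    stop("the CTR must lie entirely within the HC_CR")
  }
  out <- list(
    in_ctr = region_intersect(panel, ctr),
    in_hccr_out_ctr = region_subtract(region_intersect(panel, hccr), ctr),
    rest = region_subtract(panel, hccr)
  )
  class(out) <- "panel_subregions"
  out
}

#' Sizes of the three panel sub-regions
#'
#' @param subregions A `panel_subregions` object.
#' @return A tibble with one row per part: `part`, `bases`, `mb`.
#' @export
subregion_sizes <- function(subregions) {
  stopifnot(inherits(subregions, "panel_subregions"))
  bases <- vapply(unclass(subregions), region_size, numeric(1))
  tibble::tibble(part = names(bases), bases = unname(bases),
                 mb = unname(bases) / 1e6)
}

#' @export
print.panel_subregions <- function(x, ...) {
  s <- subregion_sizes(x)
  cat("Panel sub-regions (bases):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-16s %12.0f (%.3f Mb)\n", s$part[i], s$bases[i], s$mb[i]))
  }
  invisible(x)
}
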