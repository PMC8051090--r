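# Brute-force oracles kept deliberately naive: per-base boolean masks for
# interval algebra, quadratic loops for matching. They must stay independent
# of the package's implementation paths.

# Boolean coverage mask of one toy chromosome (1-based positions 1..len).
region_mask <- function(region, chrom, len) {
  m <- logical(len)
  sel <- as.character(GenomicRanges::seqnames(region)) == chrom
  s <- GenomicRanges::start(region)[sel]
  e <- GenomicRanges::end(region)[sel]
  for (i in seq_along(s)) m[s[i]:e[i]] <- TRUE
  m
}

# Random raw (unnormalized) intervals on a single toy chromosome.
random_intervals <- function(n, len, chrom = "chrT", max_w = 50) {
  s <- sample.int(len - max_w, n, replace = TRUE) - 1L  # 0-based starts
  w <- sample.int(max_w, n, replace = TRUE)
  region_set(chrom, s, s + w)
}

# Quadratic truth-matching oracle: for every truth variant scan every call.
match_oracle <- function(calls, truth) {
  detected <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(calls))) {
      if (truth$chrom[i] == calls$chrom[j] && truth$pos[i] == calls$pos[j] &&
          truth$ref[i] == calls$ref[j] && truth$alt[i] == calls$alt[j]) {
        detected[i] <- TRUE
        break
      }
    }
  }
  detected
}

# Per-call region membership oracle via the per-base mask.
restrict_oracle <- function(calls, region, chroms, len) {
  masks <- lapply(chroms, region_mask, region = region, len = len)
  names(masks) <- chroms
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    masks[[calls$chrom[i]]][calls$pos[i]]
  }, logical(1))
  calls[keep, , drop = FALSE]
}

# Minimal call-set tibble constructor for hand-built cases.
make_calls <- function(chrom, pos, ref = "A", alt = "G", vaf = 0.5,
                       lab = "LAB1", replicate = 1L, sample = "A",
                       panel = "P") {
  tibble::tibble(
    panel = panel, lab = lab, sample = sample,
    replicate = as.integer(replicate),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    vtype = classify_variant(ref, alt), vaf = vaf
  )
}
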