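#' Write a call set as a minimal VCF 4.2 file
#'
#' One record per call, VAF carried in `INFO/AF`. Multiallelic records are
#' not recombined; the file round-trips through [read_vcf()].
#'
#' @param calls Call set tibble for a single library.
#' @param path Output path.
#' @param chrom_sizes Named vector used for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, chrom_sizes = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(chrom_sizes)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_sizes),
              as.integer(chrom_sizes))
    },
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6g",
                  calls$chrom, calls$pos, calls$ref, calls$alt, calls$vaf)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a known-variant catalog from a tab-separated file
#'
#' Expected columns: `chrom`, `pos`, `ref`, `alt`, `vaf_a`, `provenance`
#' (header required).
#'
#' @param path Input path.
#' @return A tibble with a `vtype` column added.
#' @export
read_known_variants <- function(path) {
  df <- tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                                     colClasses = c(chrom = "character",
                                                    ref = "character",
                                                    alt = "character")))
  df$vtype <- classify_variant(df$ref, df$alt)
  df
}

#' Read a known-negative position list (two tab-separated columns `chrom`,
#' `pos`, header required).
#'
#' @param path Input path.
#' @return A tibble.
#' @export
read_known_negatives <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               colClasses = c(chrom = "character")))
}

#' Write a synthetic study bundle to a directory
#'
#' Produces the on-disk form of a study: BED files for the panel, CTR and
#' HC_CR; tab-separated truth catalogs; one VCF per library; and a manifest
#' mapping each VCF to its `(panel, lab, sample, replicate)` identity and
#' the panel's VAF reporting threshold. The directory round-trips through
#' [read_study()].
#'
#' @param bundle A [generate_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_bed(bundle$regions$panel, file.path(dir, "panel.bed"))
  write_bed(bundle$regions$ctr, file.path(dir, "ctr.bed"))
  write_bed(bundle$regions$hccr, file.path(dir, "hccr.bed"))
  wt <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(bundle$kp[, c("chrom", "pos", "ref", "alt", "vaf_a", "provenance")],
     "known_variants.tsv")
  wt(bundle$kn, "known_negatives.tsv")
  wt(bundle$b_germline, "b_germline.tsv")
  wt(bundle$spike[, c("chrom", "pos", "ref", "alt")], "spike.tsv")
  calls <- bundle$calls
  groups <- unique(calls[, c("panel", "lab", "sample", "replicate")])
  manifest <- groups
  manifest$path <- sprintf("vcf/%s_%s_%s_%d.vcf", groups$panel, groups$lab,
                           groups$sample, groups$replicate)
  manifest$vaf_threshold <- bundle$config$vaf_threshold
  for (i in seq_len(nrow(manifest))) {
    sel <- calls$panel == groups$panel[i] & calls$lab == groups$lab[i] &
      calls$sample == groups$sample[i] &
      calls$replicate == groups$replicate[i]
    write_vcf(calls[sel, , drop = FALSE], file.path(dir, manifest$path[i]),
              chrom_sizes = bundle$config$chrom_sizes)
  }
  wt(manifest[, c("path", "panel", "lab", "sample", "replicate",
                  "vaf_threshold")], "manifest.tsv")
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory containing `manifest.tsv`.
#' @return A list: `regions`, `kp`, `kn`, `b_germline`, `spike`, `calls`,
#'   `manifest`.
#' @export
read_study <- function(dir) {
  manifest <- tibble::as_tibble(
    read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t",
               colClasses = c(path = "character", panel = "character",
                              lab = "character", sample = "character"))
  )
  calls <- dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
    read_vcf(file.path(dir, manifest$path[i]),
             panel = manifest$panel[i], lab = manifest$lab[i],
             sample = manifest$sample[i],
             replicate = manifest$replicate[i])
  }))
  list(
    regions = list(panel = read_bed(file.path(dir, "panel.bed"), "panel"),
                   ctr = read_bed(file.path(dir, "ctr.bed"), "CTR"),
                   hccr = read_bed(file.path(dir, "hccr.bed"), "HC_CR")),
    kp = read_known_variants(file.path(dir, "known_variants.tsv")),
    kn = read_known_negatives(file.path(dir, "known_negatives.tsv")),
    b_germline = tibble::as_tibble(
      read.table(file.path(dir, "b_germline.tsv"), header = TRUE, sep = "\t",
                 colClasses = c(chrom = "character", ref = "character",
                                alt = "character"))),
    spike = tibble::as_tibble(
      read.table(file.path(dir, "spike.tsv"), header = TRUE, sep = "\t",
                 colClasses = c(chrom = "character", ref = "character",
                                alt = "character"))),
    calls = calls,
    manifest = manifest
  )
}
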