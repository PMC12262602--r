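# VCF ingestion (via vcfR) restricted to the phased biallelic-SNP subset
# used throughout the package, plus a plain-text writer for round-trips.

#' Read phased biallelic SNPs from a VCF
#'
#' Parses a VCF (v4.x) and returns the biallelic-SNP subset as positioned
#' variants plus haplotype and diplotype matrices.  Multiallelic records,
#' indels and records on other contigs are dropped (counts are reported
#' via `message()`).  Haplotypes are populated from phased GT fields only;
#' an unphased genotype among retained records is an error naming the
#' first offending record, unless `require_phased = FALSE`, in which case
#' haplotypes are returned as `NULL` and only diplotypes are built.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param contig Contig to read.  Defaults to the single contig present;
#'   an error lists the options when several are present.
#' @param region Optional length-2 numeric `c(bp_start, bp_end)` filter.
#' @param require_phased Demand phased GT for all retained records.
#' @return A list with elements `variants`, `hap` (a [hapset()] or `NULL`)
#'   and `dip` (a [dipset()]).
#' @export
read_vcf <- function(path, contig = NULL, region = NULL,
                     require_phased = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  if (is.null(contig)) {
    u <- unique(chrom)
    if (length(u) != 1L)
      stop("VCF has several contigs (", paste(u, collapse = ", "),
           "); pass `contig`")
    contig <- u
  }
  if (!any(chrom == contig))
    stop("contig '", contig, "' not present in ", path)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_multi <- sum(chrom == contig & grepl(",", alt, fixed = TRUE))
  n_nonsnp <- sum(chrom == contig & !snp) - n_multi
  keep <- chrom == contig & snp
  pos <- as.integer(fix[, "POS"])
  if (!is.null(region))
    keep <- keep & pos >= region[1] & pos <= region[2]
  if (n_multi > 0L || n_nonsnp > 0L)
    message("read_vcf: dropped ", n_multi, " multiallelic and ",
            max(n_nonsnp, 0L), " non-SNP record(s)")
  if (!any(keep)) stop("no biallelic SNPs retained from ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
  samples <- colnames(gt)

  core <- sub(":.*$", "", gt)          # GT is the first colon field
  core[is.na(core) | core %in% c(".", "./.", ".|.")] <- NA
  hap <- NULL
  unphased <- !is.na(core) & grepl("/", core, fixed = TRUE)
  if (any(unphased)) {
    if (require_phased) {
      i <- which(unphased, arr.ind = TRUE)[1L, ]
      stop("unphased genotype at ", contig, ":", pos[i[1L]],
           " (sample ", samples[i[2L]], "); phased GT ('|') required")
    }
  } else {
    a1 <- suppressWarnings(as.integer(substr(core, 1L, 1L)))
    a2 <- suppressWarnings(as.integer(substr(core, 3L, 3L)))
    H <- matrix(NA_integer_, nrow(gt), 2L * length(samples))
    H[, seq(1L, ncol(H), 2L)] <- a1
    H[, seq(2L, ncol(H), 2L)] <- a2
    hap <- hapset(contig, pos, H, samples, ref, alt)
  }
  G <- if (!is.null(hap)) hap_to_dip(hap)$G else {
    a1 <- suppressWarnings(as.integer(substr(core, 1L, 1L)))
    a2 <- suppressWarnings(as.integer(substr(core, 3L, 3L)))
    matrix(a1 + a2, nrow(gt), length(samples))
  }
  dip <- dipset(contig, pos, G, samples, ref, alt)
  list(variants = variants_of(dip), hap = hap, dip = dip)
}

#' Write a haplotype set as a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with phased GT fields, suitable for
#' round-tripping through [read_vcf()] and for text fixtures.
#'
#' @param hap A [hapset()].
#' @param path Output path (`.vcf`).
#' @param contig_length Optional contig length for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(hap, path, contig_length = NULL) {
  stopifnot(inherits(hap, "hapset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hapscan",
               if (is.null(contig_length))
                 paste0("##contig=<ID=", hap$contig, ">")
               else
                 paste0("##contig=<ID=", hap$contig, ",length=",
                        format(contig_length, scientific = FALSE), ">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", hap$samples),
                     collapse = "\t")), con)
  a1 <- hap$H[, seq(1L, n_haps(hap), 2L), drop = FALSE]
  a2 <- hap$H[, seq(2L, n_haps(hap), 2L), drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), "|",
                      ifelse(is.na(a2), ".", a2)),
               nrow = n_sites(hap))
  lines <- paste(hap$contig, hap$pos, ".", hap$ref, hap$alt, ".", "PASS",
                 ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Scan track containers and exports
# ---------------------------------------------------------------------------

#' Build a scan track
#'
#' A scan track couples an ordered window list with one statistic value per
#' window (H12, delta-H12, pi, Tajima's D, F_ST, ...).
#'
#' @param windows A `snp_windows` data.frame.
#' @param values Numeric vector, one value per window.
#' @param statistic Name of the statistic.
#' @param extra Optional data.frame of additional per-window columns.
#' @return A data.frame of class `scan_track` with attribute `statistic`.
#' @export
scan_track <- function(windows, values, statistic, extra = NULL) {
  if (nrow(windows) != length(values))
    stop("track needs one value per window (", nrow(windows), " windows, ",
         length(values), " values)")
  tr <- cbind(as.data.frame(windows), value = as.numeric(values))
  if (!is.null(extra)) tr <- cbind(tr, extra)
  attr(tr, "statistic") <- statistic
  class(tr) <- c("scan_track", "data.frame")
  tr
}

#' Export a scan track as BED-compatible TSV
#'
#' Writes `contig`, 0-based `start`, `end`, `value` (BED) or the full
#' window table (TSV).
#'
#' @param track A `scan_track`.
#' @param path Output path.
#' @param format `"tsv"` (all columns) or `"bed"` (4-column BED).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- data.frame(chrom = track$contig, start = track$bp_start - 1L,
                      end = track$bp_end, value = track$value)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Export a scan track as JSON
#' @param track A `scan_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_json <- function(track, path) {
  jsonlite::write_json(list(statistic = attr(track, "statistic"),
                            windows = as.data.frame(track)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
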