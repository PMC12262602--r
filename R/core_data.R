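#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rbinom rnorm rpois runif sd setNames
#'   complete.cases as.dist cutree hclust prcomp glm binomial coef pchisq
#'   p.adjust wilcox.test plogis qlogis rbeta var
#' @importFrom utils read.table write.table head tail
NULL

# ---------------------------------------------------------------------------
# Positioned variant sets: one contig, strictly ascending 1-based positions,
# biallelic SNPs only.  Shared backbone of haplotype and diplotype sets.
# ---------------------------------------------------------------------------

new_variants <- function(contig, pos, ref = NULL, alt = NULL) {
  stopifnot(length(contig) == 1L, is.character(contig))
  pos <- as.integer(pos)
  if (anyNA(pos)) stop("variant positions must be non-missing integers")
  if (is.unsorted(pos, strictly = TRUE))
    stop("variant positions must be strictly ascending on contig '",
         contig, "'")
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  stopifnot(length(ref) == n, length(alt) == n)
  structure(list(contig = contig, pos = pos,
                 ref = as.character(ref), alt = as.character(alt)),
            class = "variants")
}

#' Number of sites in a variant-backed object
#'
#' @param x A `variants`, `hapset` or `dipset` object.
#' @return Integer site count.
#' @export
n_sites <- function(x) length(x$pos)

#' @export
print.variants <- function(x, ...) {
  cat("<variants> ", n_sites(x), " biallelic SNPs on ", x$contig,
      " [", x$pos[1L], "-", x$pos[n_sites(x)], " bp]\n", sep = "")
  invisible(x)
}

variants_of <- function(x) new_variants(x$contig, x$pos, x$ref, x$alt)

# ---------------------------------------------------------------------------
# HaplotypeSet: sites x haplotypes binary matrix, two columns per sample.
# ---------------------------------------------------------------------------

#' Construct a haplotype set
#'
#' A haplotype set holds a sites-by-haplotypes binary matrix of phased
#' alternate-allele indicators, with two haplotype columns per sample
#' (named `<sample>_1` and `<sample>_2`).
#'
#' @param contig Contig name (single string).
#' @param pos Integer vector of 1-based bp positions, strictly ascending.
#' @param H Matrix of 0/1 entries (`NA` allowed for missing calls), one row
#'   per site, two columns per sample.
#' @param samples Character vector of sample ids, `ncol(H)/2` long.
#' @param ref,alt Optional allele codes per site.
#' @return An object of class `hapset`.
#' @export
hapset <- function(contig, pos, H, samples, ref = NULL, alt = NULL) {
  v <- new_variants(contig, pos, ref, alt)
  H <- as.matrix(H)
  if (nrow(H) != n_sites(v))
    stop("haplotype matrix has ", nrow(H), " rows but ", n_sites(v), " sites")
  if (ncol(H) != 2L * length(samples))
    stop("haplotype matrix must have two columns per sample")
  bad <- !(H %in% c(0L, 1L, NA))
  if (any(bad)) stop("haplotype entries must be 0, 1 or NA")
  storage.mode(H) <- "integer"
  colnames(H) <- if (length(samples))
    paste0(rep(samples, each = 2L), "_", 1:2) else character(0)
  structure(list(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
                 H = H, samples = as.character(samples)),
            class = "hapset")
}

#' Number of haplotypes in a haplotype set
#' @param x A `hapset`.
#' @return Integer number of haplotype columns.
#' @export
n_haps <- function(x) ncol(x$H)

#' Sample id owning each haplotype column
#' @param x A `hapset`.
#' @return Character vector, one entry per haplotype column.
#' @export
hap_samples <- function(x) rep(x$samples, each = 2L)

#' @export
print.hapset <- function(x, ...) {
  cat("<hapset> ", n_sites(x), " sites x ", n_haps(x), " haplotypes (",
      length(x$samples), " samples) on ", x$contig, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# DiplotypeSet: sites x samples {0,1,2,NA} alternate-allele counts.
# ---------------------------------------------------------------------------

#' Construct a diplotype set
#'
#' A diplotype set holds per-sample alternate-allele counts in \{0, 1, 2\}
#' (`NA` for missing genotypes), one row per site.
#'
#' @inheritParams hapset
#' @param G Matrix of allele counts, one row per site, one column per sample.
#' @return An object of class `dipset`.
#' @export
dipset <- function(contig, pos, G, samples, ref = NULL, alt = NULL) {
  v <- new_variants(contig, pos, ref, alt)
  G <- as.matrix(G)
  if (nrow(G) != n_sites(v))
    stop("genotype matrix has ", nrow(G), " rows but ", n_sites(v), " sites")
  if (ncol(G) != length(samples))
    stop("genotype matrix must have one column per sample")
  if (any(!(G %in% c(0L, 1L, 2L, NA))))
    stop("diplotype entries must be 0, 1, 2 or NA")
  storage.mode(G) <- "integer"
  colnames(G) <- samples
  structure(list(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
                 G = G, samples = as.character(samples)),
            class = "dipset")
}

#' @export
print.dipset <- function(x, ...) {
  cat("<dipset> ", n_sites(x), " sites x ", length(x$samples),
      " samples on ", x$contig, "\n", sep = "")
  invisible(x)
}

#' Collapse a haplotype set to a diplotype set
#'
#' Sums the two phased haplotypes of each sample into alternate-allele
#' counts; a missing haplotype call yields a missing genotype.
#'
#' @param hap A `hapset`.
#' @return A `dipset` over the same sites and samples.
#' @export
hap_to_dip <- function(hap) {
  idx <- seq(1L, n_haps(hap), by = 2L)
  G <- hap$H[, idx, drop = FALSE] + hap$H[, idx + 1L, drop = FALSE]
  dipset(hap$contig, hap$pos, G, hap$samples, hap$ref, hap$alt)
}

# ---------------------------------------------------------------------------
# Site / sample subsetting
# ---------------------------------------------------------------------------

#' Subset sites of a haplotype or diplotype set
#'
#' @param x A `hapset` or `dipset`.
#' @param sites Integer or logical index along the site axis.
#' @return Object of the same class restricted to `sites`, order preserved.
#' @export
subset_sites <- function(x, sites) UseMethod("subset_sites")

#' @export
subset_sites.hapset <- function(x, sites) {
  hapset(x$contig, x$pos[sites], x$H[sites, , drop = FALSE], x$samples,
         x$ref[sites], x$alt[sites])
}

#' @export
subset_sites.dipset <- function(x, sites) {
  dipset(x$contig, x$pos[sites], x$G[sites, , drop = FALSE], x$samples,
         x$ref[sites], x$alt[sites])
}

#' Subset samples of a haplotype or diplotype set
#'
#' For haplotype sets both haplotype columns of each retained sample are
#' kept, in sample order.
#'
#' @param x A `hapset` or `dipset`.
#' @param ids Character vector of sample ids to keep.
#' @return Object of the same class restricted to `ids`.
#' @export
subset_samples <- function(x, ids) UseMethod("subset_samples")

#' @export
subset_samples.hapset <- function(x, ids) {
  miss <- setdiff(ids, x$samples)
  if (length(miss))
    stop("samples not present: ", paste(miss, collapse = ", "))
  cols <- as.vector(rbind(match(ids, x$samples) * 2L - 1L,
                          match(ids, x$samples) * 2L))
  hapset(x$contig, x$pos, x$H[, cols, drop = FALSE], ids, x$ref, x$alt)
}

#' @export
subset_samples.dipset <- function(x, ids) {
  miss <- setdiff(ids, x$samples)
  if (length(miss))
    stop("samples not present: ", paste(miss, collapse = ", "))
  dipset(x$contig, x$pos, x$G[, ids, drop = FALSE], ids, x$ref, x$alt)
}

# ---------------------------------------------------------------------------
# Cohort metadata
# ---------------------------------------------------------------------------

cohort_required_cols <- c("sample_id", "region", "round", "arm",
                          "household", "country", "year")

#' Validate a cohort metadata frame
#'
#' Checks the per-sample trial metadata: required columns present, sample
#' ids unique, and (optionally) one row per genotyped sample.
#'
#' @param frame A data.frame of per-sample metadata.
#' @param samples Optional character vector of genotyped sample ids that
#'   must match the frame exactly (set equality).
#' @return The validated frame, invisibly classed as `cohort_frame`.
#' @export
validate_cohort <- function(frame, samples = NULL) {
  miss <- setdiff(cohort_required_cols, names(frame))
  if (length(miss))
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  dup <- frame$sample_id[duplicated(frame$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in metadata: ",
         paste(unique(dup), collapse = ", "))
  if (!is.null(samples)) {
    only_meta <- setdiff(frame$sample_id, samples)
    only_data <- setdiff(samples, frame$sample_id)
    if (length(only_meta) || length(only_data))
      stop("metadata/genotype sample mismatch; only in metadata: [",
           paste(only_meta, collapse = ", "), "]; only in genotypes: [",
           paste(only_data, collapse = ", "), "]")
  }
  frame$year <- as.integer(frame$year)
  class(frame) <- unique(c("cohort_frame", class(frame)))
  frame
}

#' Read per-sample cohort metadata
#'
#' Reads a delimited text table (TSV by default, CSV for `.csv` paths) with
#' one row per sample and columns `sample_id`, `region`, `round`, `arm`,
#' `household`, `country`, `year`.
#'
#' @param path Path to the metadata file.
#' @param samples Optional sample ids to validate against (see
#'   [validate_cohort()]).
#' @return A validated `cohort_frame` data.frame.
#' @export
read_metadata <- function(path, samples = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  frame <- read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character")
  validate_cohort(frame, samples)
}

#' Write cohort metadata as TSV
#' @param frame A `cohort_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(frame, path) {
  write.table(frame, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select an analysis cohort by metadata predicate
#'
#' Subsets a haplotype or diplotype set to the samples whose metadata rows
#' satisfy a predicate, keeping data and metadata aligned.
#'
#' @param x A `hapset` or `dipset`.
#' @param frame A `cohort_frame` covering the samples of `x`.
#' @param subset An unquoted logical expression over metadata columns,
#'   e.g. `region == "East" & round == "baseline"`.
#' @return A list with elements `data` (subset of `x`) and `frame`
#'   (matching metadata rows).  An empty selection is allowed but warned
#'   about.
#' @export
select_cohort <- function(x, frame, subset) {
  frame <- validate_cohort(as.data.frame(frame), x$samples)
  keep <- eval(substitute(subset), frame, parent.frame())
  if (!is.logical(keep) || length(keep) != nrow(frame))
    stop("cohort predicate must evaluate to one logical per metadata row")
  keep[is.na(keep)] <- FALSE
  ids <- frame$sample_id[keep]
  if (!length(ids)) {
    warning("cohort predicate matched no samples")
    sub <- subset_samples(x, character(0))
  } else {
    sub <- subset_samples(x, ids)
  }
  list(data = sub, frame = frame[keep, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# SNP-count windows
# ---------------------------------------------------------------------------

#' Build SNP-count windows over a site axis
#'
#' Windows contain a fixed number of consecutive SNPs (default 500) and by
#' default tile the site axis without overlap; a smaller `step_snps` gives
#' moving windows.  SNP indices are 1-based inclusive; bp bounds span the
#' first to last contained position.
#'
#' @param x A `hapset`, `dipset` or `variants` object (or a bare integer
#'   vector of positions, in which case `contig` must be given).
#' @param window_snps Number of SNPs per window (>= 2).
#' @param step_snps Step between window starts in SNPs (default: no
#'   overlap).
#' @param keep_partial Keep a trailing window with fewer than `window_snps`
#'   sites?  Default drops it.
#' @param contig Contig name when `x` is a bare position vector.
#' @return A data.frame of class `snp_windows` with columns `contig`,
#'   `snp_first`, `snp_last`, `n_snps`, `bp_start`, `bp_end`.
#' @export
make_windows <- function(x, window_snps = 500L, step_snps = window_snps,
                         keep_partial = FALSE, contig = NULL) {
  if (is.numeric(x)) {
    if (is.null(contig)) stop("contig required for bare positions")
    v <- new_variants(contig, x)
  } else v <- variants_of(x)
  window_snps <- as.integer(window_snps)
  step_snps <- as.integer(step_snps)
  if (window_snps < 2L) stop("window_snps must be >= 2")
  if (step_snps < 1L) stop("step_snps must be >= 1")
  L <- n_sites(v)
  if (L < window_snps) {
    warning("fewer sites (", L, ") than one window (", window_snps, ")")
    starts <- integer(0)
  } else {
    starts <- seq.int(1L, L - window_snps + 1L, by = step_snps)
  }
  ends <- pmin.int(starts + window_snps - 1L, L)
  if (keep_partial) {
    tail_start <- if (length(starts)) max(starts) + step_snps else 1L
    if (tail_start <= L) {
      starts <- c(starts, tail_start)
      ends <- c(ends, L)
    }
  }
  w <- data.frame(contig = rep(v$contig, length(starts)),
                  snp_first = starts, snp_last = ends,
                  n_snps = ends - starts + 1L,
                  bp_start = v$pos[starts], bp_end = v$pos[ends],
                  stringsAsFactors = FALSE)
  class(w) <- c("snp_windows", "data.frame")
  w
}

#' Windows for several contigs at once
#'
#' Applies [make_windows()] per contig and concatenates, keeping a global
#' window order (contigs in list order).
#'
#' @param sets Named list of `hapset`/`dipset`/`variants`, one per contig.
#' @inheritParams make_windows
#' @return A `snp_windows` data.frame with an extra `set` column naming the
#'   originating list element.
#' @export
make_windows_multi <- function(sets, window_snps = 500L,
                               step_snps = window_snps,
                               keep_partial = FALSE) {
  out <- lapply(names(sets), function(nm) {
    w <- make_windows(sets[[nm]], window_snps, step_snps, keep_partial)
    if (nrow(w)) w$set <- nm
    w
  })
  w <- do.call(rbind, out[vapply(out, nrow, 0L) > 0L])
  class(w) <- c("snp_windows", "data.frame")
  w
}

#' Mask of segregating sites within a cohort
#'
#' A site segregates when its alternate-allele count is strictly between 0
#' and the number of non-missing alleles observed in the cohort.
#'
#' @param x A `hapset` or `dipset` (use [subset_samples()] first to
#'   restrict to a cohort).
#' @return Logical vector, one entry per site.
#' @export
segregating_mask <- function(x) {
  m <- if (inherits(x, "hapset")) x$H else x$G
  if (!ncol(m)) stop("cohort is empty")
  ploidy_max <- if (inherits(x, "hapset")) 1L else 2L
  ac <- rowSums(m, na.rm = TRUE)
  an <- rowSums(!is.na(m)) * ploidy_max
  ac > 0L & ac < an
}

#' Extract the sites of a genomic interval
#'
#' Restricts a haplotype/diplotype set to sites with
#' `bp_start <= pos <= bp_end`, e.g. a candidate resistance locus.
#'
#' @param x A `hapset` or `dipset`.
#' @param bp_start,bp_end 1-based inclusive bp bounds.
#' @return Subset object; errors when the interval contains no sites.
#' @export
extract_locus <- function(x, bp_start, bp_end) {
  if (bp_end < bp_start) stop("empty interval: bp_end < bp_start")
  keep <- x$pos >= bp_start & x$pos <= bp_end
  if (!any(keep))
    stop("interval ", x$contig, ":", bp_start, "-", bp_end,
         " contains no sites")
  subset_sites(x, keep)
}
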