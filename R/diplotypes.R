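# Complete-linkage hierarchical clustering of diplotypes over candidate
# loci, heterozygosity profiling, and tag-SNP annotation of clusters.

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with inter-cluster distance equal to the
#' maximum pairwise member distance (full linkage), typically applied to
#' the Manhattan distances of [manhattan_dist()] over a locus extract.
#' Merge heights are non-decreasing by construction.
#'
#' @param D Symmetric distance matrix (no `NA`s) with sample labels.
#' @return A `stats::hclust` object.
#' @export
complete_linkage <- function(D) {
  D <- as.matrix(D)
  if (anyNA(D)) stop("distance matrix contains NA")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  hc <- hclust(as.dist(D), method = "complete")
  stopifnot(!is.unsorted(hc$height))
  hc
}

#' Cut a dendrogram into flat clusters
#'
#' @param linkage A `hclust` object (from [complete_linkage()]).
#' @param k Number of clusters, or
#' @param height Cut height; give exactly one of `k`/`height`.
#' @return Integer cluster assignment named by sample, with stable labels
#'   (clusters numbered by first appearance in leaf order).
#' @export
cut_clusters <- function(linkage, k = NULL, height = NULL) {
  if (is.null(k) == is.null(height))
    stop("give exactly one of k or height")
  if (!is.null(k) && k > length(linkage$labels))
    stop("k exceeds the number of samples")
  cutree(linkage, k = k, h = height)
}

#' Per-sample heterozygosity at a locus
#'
#' Fraction of non-missing sites at which the sample is heterozygous
#' (genotype 1).  A swept (homozygous-core) diplotype cluster shows
#' reduced heterozygosity relative to wild-type clusters.
#'
#' @param dip A [dipset()] (typically a locus extract).
#' @return Numeric vector named by sample; `NA` for all-missing samples.
#' @export
sample_heterozygosity <- function(dip) {
  stopifnot(inherits(dip, "dipset"))
  obs <- colSums(!is.na(dip$G))
  het <- colSums(dip$G == 1L, na.rm = TRUE)
  ifelse(obs > 0L, het / obs, NA_real_)
}

#' Define a tag SNP
#'
#' A tag SNP is a single variant whose alternate allele marks carriage of
#' a swept haplotype (e.g. a `Cyp9k1`-G454A-like marker); the amino-acid
#' style name is metadata only.
#'
#' @param name Label, e.g. `"Cyp9k1-G454A"`.
#' @param contig Contig name.
#' @param pos 1-based bp position.
#' @return A one-row data.frame.
#' @export
tag_snp <- function(name, contig, pos) {
  data.frame(name = name, contig = contig, pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

#' Summarise diplotype clusters
#'
#' Per cluster: size, alternate-allele frequency at each tag SNP, mean
#' heterozygosity, and composition (proportions) by the requested
#' metadata fields.
#'
#' @param assignment Integer cluster assignment named by sample (from
#'   [cut_clusters()]).
#' @param dip The locus [dipset()] that was clustered.
#' @param tags Data.frame of tag SNPs ([tag_snp()] rows); every tag
#'   position must be present in the locus.
#' @param frame A `cohort_frame` covering the samples.
#' @param fields Metadata fields to profile (default country, region,
#'   round, arm).
#' @return A list with `clusters` (one row per cluster: size, mean_het,
#'   one `tag_freq.<name>` column per tag) and `composition` (long
#'   data.frame: cluster, field, level, proportion).
#' @export
annotate_clusters <- function(assignment, dip, tags = NULL, frame = NULL,
                              fields = c("country", "region", "round",
                                         "arm")) {
  stopifnot(inherits(dip, "dipset"))
  ids <- names(assignment)
  if (is.null(ids)) stop("assignment must be named by sample")
  G <- dip$G[, ids, drop = FALSE]
  tag_rows <- integer(0)
  if (!is.null(tags) && nrow(tags)) {
    tag_rows <- match(tags$pos, dip$pos)
    if (anyNA(tag_rows))
      stop("tag SNP(s) absent from locus: ",
           paste(tags$name[is.na(tag_rows)], collapse = ", "))
  }
  het <- sample_heterozygosity(dip)[ids]
  ks <- sort(unique(assignment))
  clusters <- do.call(rbind, lapply(ks, function(k) {
    member <- ids[assignment == k]
    row <- data.frame(cluster = k, size = length(member),
                      mean_het = mean(het[member], na.rm = TRUE))
    for (t in seq_along(tag_rows)) {
      g <- G[tag_rows[t], member]
      row[[paste0("tag_freq.", tags$name[t])]] <-
        mean(g, na.rm = TRUE) / 2
    }
    row
  }))
  composition <- NULL
  if (!is.null(frame)) {
    frame <- as.data.frame(frame)
    rownames(frame) <- frame$sample_id
    composition <- do.call(rbind, lapply(ks, function(k) {
      member <- ids[assignment == k]
      do.call(rbind, lapply(fields, function(f) {
        tab <- table(frame[member, f])
        data.frame(cluster = k, field = f, level = names(tab),
                   proportion = as.numeric(tab) / length(member),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  list(clusters = clusters, composition = composition)
}

#' Export a merge table for a linkage
#'
#' Flat TSV of the merge sequence (cluster indices as in
#' `stats::hclust`: negative = leaf, positive = earlier merge) with
#' heights.
#'
#' @param linkage A `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage <- function(linkage, path) {
  out <- data.frame(merge1 = linkage$merge[, 1L],
                    merge2 = linkage$merge[, 2L],
                    height = linkage$height)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
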