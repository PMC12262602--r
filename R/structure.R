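# Population structure: PCA, Manhattan distances, neighbour-joining trees,
# Hudson/Patterson F_ST (ratio-of-averages), the two-individual resampling
# null, and Mann-Whitney comparison of the null distributions.

#' PCA of a diplotype matrix
#'
#' Sites are mean-centred and, by default, scaled by
#' `sqrt(p (1 - p))` with `p` the alternate-allele frequency (Patterson
#' scaling).  Sites with any missing genotype or with `p (1 - p) = 0` are
#' dropped before decomposition.
#'
#' @param dip A [dipset()].
#' @param n_components Number of leading components to return.
#' @param patterson_scale Apply the `sqrt(p(1-p))` scaling (default) or
#'   centre only.
#' @return A list with `coords` (samples x components), `explained_var`
#'   (proportion of total variance per component) and `n_sites_used`.
#' @export
pca_genotypes <- function(dip, n_components = 10L, patterson_scale = TRUE) {
  stopifnot(inherits(dip, "dipset"))
  G <- dip$G
  if (ncol(G) < 2L) stop("PCA needs >= 2 samples")
  G <- G[!rowSums(is.na(G)), , drop = FALSE]
  p <- rowMeans(G) / 2
  keep <- p > 0 & p < 1
  G <- G[keep, , drop = FALSE]
  p <- p[keep]
  X <- G - 2 * p
  if (patterson_scale) X <- X / sqrt(p * (1 - p))
  s <- svd(t(X))
  rank <- sum(s$d > max(s$d) * 1e-10)
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds matrix rank (", rank,
         ")")
  coords <- s$u[, seq_len(n_components), drop = FALSE] %*%
    diag(s$d[seq_len(n_components)], n_components)
  rownames(coords) <- dip$samples
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coords = coords,
       explained_var = (s$d^2 / sum(s$d^2))[seq_len(n_components)],
       n_sites_used = nrow(G))
}

#' Pairwise Manhattan (city-block) distances between diplotypes
#'
#' `d(i, j) = sum_sites |g_i - g_j|` over the sites non-missing in both
#' members of the pair.  Errors when some pair shares no non-missing site.
#'
#' @param dip A [dipset()] (typically a locus extract).
#' @return Symmetric distance matrix with zero diagonal, labelled by
#'   sample id.
#' @export
manhattan_dist <- function(dip) {
  stopifnot(inherits(dip, "dipset"))
  G <- dip$G
  if (ncol(G) < 2L) stop("need >= 2 samples")
  obs <- !is.na(G)
  shared <- crossprod(obs)
  if (any(shared == 0)) {
    ij <- which(shared == 0, arr.ind = TRUE)[1L, ]
    stop("samples ", dip$samples[ij[1L]], " and ", dip$samples[ij[2L]],
         " share no non-missing site")
  }
  # |a - b| over {0,1,2} decomposes on value-indicator matrices
  ind <- lapply(0:2, function(v) { M <- (G == v); M[!obs] <- FALSE; M })
  D <- matrix(0, ncol(G), ncol(G))
  for (a in 1:3) for (b in 1:3)
    if (a != b) D <- D + abs(a - b) * crossprod(ind[[a]], ind[[b]])
  dimnames(D) <- list(dip$samples, dip$samples)
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]); negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to
#' zero with the negative excess transferred to the sibling branch so
#' that leaf-to-leaf path lengths through the parent are preserved.
#'
#' @param D Symmetric non-negative distance matrix with labels, >= 3 taxa.
#' @param clamp_negative Apply the negative-branch post-pass (default).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D, clamp_negative = TRUE) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbour joining needs >= 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  tree <- ape::nj(as.dist(D))
  if (clamp_negative && any(tree$edge.length < 0)) {
    repeat {
      neg <- which(tree$edge.length < 0)
      if (!length(neg)) break
      e <- neg[1L]
      parent <- tree$edge[e, 1L]
      sibs <- which(tree$edge[, 1L] == parent)
      sibs <- setdiff(sibs, e)
      if (length(sibs))
        tree$edge.length[sibs] <- tree$edge.length[sibs] +
          tree$edge.length[e]
      tree$edge.length[e] <- 0
    }
  }
  tree
}

# per-site alt frequency and allele number from a cohort's haplotype or
# diplotype matrix
ac_freq <- function(x) {
  m <- if (inherits(x, "hapset")) x$H else if (inherits(x, "dipset")) x$G
       else x
  mult <- if (inherits(x, "dipset")) 1L else 1L
  an <- rowSums(!is.na(m)) * if (inherits(x, "dipset")) 2L else 1L
  ac <- rowSums(m, na.rm = TRUE)
  list(p = ifelse(an > 0, ac / an, NA_real_), n = an)
}

fst_per_site <- function(p1, n1, p2, n2, estimator) {
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    h1 <- p1 * (1 - p1) * n1 / (n1 - 1)
    h2 <- p2 * (1 - p2) * n2 / (n2 - 1)
    num <- (p1 - p2)^2 - h1 / n1 - h2 / n2
    den <- num + h1 + h2
  }
  list(num = num, den = den)
}

#' Hudson or Patterson F_ST from two cohorts
#'
#' Per-site moment estimators aggregated as a ratio of averages
#' (`sum(num) / sum(den)`), the standard bias-avoiding aggregation.
#' Hudson: `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' `D = p1(1-p2) + p2(1-p1)`.  Patterson: with unbiased heterozygosity
#' `h = p(1-p) n/(n-1)`, `N = (p1-p2)^2 - h1/n1 - h2/n2`, `D = N + h1 +
#' h2`.  Sites monomorphic in both cohorts (0/0) are excluded from the
#' sums.  Negative estimates are reported as computed.
#'
#' @param a,b Cohort data: [hapset()]/[dipset()] objects restricted to
#'   each population, or lists `list(p =, n =)` of per-site frequencies
#'   and allele numbers.
#' @param estimator `"hudson"` or `"patterson"`.
#' @return List with `fst` (ratio of averages), and per-site `num`,
#'   `den` vectors (`NA` where excluded).
#' @export
fst_estimate <- function(a, b, estimator = c("hudson", "patterson")) {
  estimator <- match.arg(estimator)
  as_pn <- function(x) {
    if (inherits(x, c("hapset", "dipset"))) return(ac_freq(x))
    if (is.list(x) && !is.null(x[["p"]]) && !is.null(x[["n"]])) return(x)
    stop("cohort must be a hapset/dipset or a list(p =, n =)")
  }
  A <- as_pn(a)
  B <- as_pn(b)
  if (length(A$p) != length(B$p)) stop("cohorts cover different site sets")
  ok <- !is.na(A$p) & !is.na(B$p) & A$n >= 2 & B$n >= 2
  ps <- fst_per_site(A$p, A$n, B$p, B$n, estimator)
  ps$num[!ok] <- NA_real_
  ps$den[!ok] <- NA_real_
  zero <- !is.na(ps$den) & ps$den == 0 & ps$num == 0
  ps$num[zero] <- NA_real_
  ps$den[zero] <- NA_real_
  use <- !is.na(ps$den)
  list(fst = sum(ps$num[use]) / sum(ps$den[use]),
       num = ps$num, den = ps$den, n_sites_used = sum(use))
}

#' Windowed F_ST scan between two cohorts
#'
#' @param a,b [hapset()] or [dipset()] objects restricted to the two
#'   cohorts (same site axis).
#' @param windows A `snp_windows` data.frame.
#' @inheritParams fst_estimate
#' @return A [scan_track()] of per-window ratio-of-averages F_ST.
#' @export
fst_scan <- function(a, b, windows, estimator = c("hudson", "patterson")) {
  estimator <- match.arg(estimator)
  A <- ac_freq(a); B <- ac_freq(b)
  ps <- fst_estimate(A, B, estimator)
  vals <- vapply(seq_len(nrow(windows)), function(i) {
    idx <- windows$snp_first[i]:windows$snp_last[i]
    use <- !is.na(ps$den[idx])
    if (!any(use)) return(NA_real_)
    sum(ps$num[idx][use]) / sum(ps$den[idx][use])
  }, 0)
  scan_track(windows, vals, paste0("fst_", estimator))
}

#' Two-individual F_ST resampling null
#'
#' Emulates the within/between-population pairwise F_ST null: each
#' iteration draws two random individuals — both from population A
#' (within-A), both from B (within-B), or one from each (between) — and a
#' fresh random set of `n_snps` sites, then computes pairwise F_ST
#' treating each individual's two haplotypes as a population of two
#' alleles.  Mann-Whitney U tests compare each within distribution to the
#' between distribution.
#'
#' @param dip A [dipset()] covering both populations.
#' @param ids_a,ids_b Sample ids of the two populations (>= 2 each).
#' @param n_snps Sites drawn per iteration (default 1000).
#' @param n_iter Iterations (default 1000).
#' @param estimator F_ST estimator (default Patterson).
#' @param seed Integer seed.
#' @return A list of class `fst_null`: `within_a`, `within_b`, `between`
#'   (numeric vectors of length `n_iter`), `mw_a`, `mw_b` (Mann-Whitney
#'   results from [mann_whitney_u()]), plus the parameters used.
#' @export
fst_resampling_null <- function(dip, ids_a, ids_b, n_snps = 1000L,
                                n_iter = 1000L,
                                estimator = c("patterson", "hudson"),
                                seed = 1L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(dip, "dipset"))
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stop("each population needs >= 2 individuals")
  set.seed(seed)
  G <- dip$G[, c(ids_a, ids_b), drop = FALSE]
  eligible <- which(!rowSums(is.na(G)))
  if (length(eligible) < n_snps)
    stop("only ", length(eligible), " fully observed sites; need ", n_snps)
  pair_fst <- function(g1, g2) {
    r <- fst_estimate(list(p = g1 / 2, n = rep(2L, length(g1))),
                      list(p = g2 / 2, n = rep(2L, length(g2))),
                      estimator)
    r$fst
  }
  draw <- function(pool1, pool2) {
    s1 <- sample(pool1, 1L)
    s2 <- sample(setdiff(pool2, s1), 1L)
    sites <- eligible[sample.int(length(eligible), n_snps)]
    pair_fst(dip$G[sites, s1], dip$G[sites, s2])
  }
  within_a <- replicate(n_iter, draw(ids_a, ids_a))
  within_b <- replicate(n_iter, draw(ids_b, ids_b))
  between <- replicate(n_iter, draw(ids_a, ids_b))
  structure(list(within_a = within_a, within_b = within_b,
                 between = between,
                 mw_a = mann_whitney_u(within_a, between),
                 mw_b = mann_whitney_u(within_b, between),
                 n_snps = n_snps, n_iter = n_iter,
                 estimator = estimator, seed = seed),
            class = "fst_null")
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midrank ties; the p-value is exact (by enumeration)
#' for small tie-free samples and uses the tie-corrected normal
#' approximation otherwise, as implemented by [stats::wilcox.test()].
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}
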