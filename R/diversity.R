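# Windowed diversity statistics: nucleotide diversity (theta-pi),
# Watterson's theta, and Tajima's D on phased haplotype allele counts.

# alt-allele count and non-missing allele number per site for a haplotype
# matrix (sites x haplotypes)
hap_counts <- function(H) {
  list(ac = rowSums(H, na.rm = TRUE), an = rowSums(!is.na(H)))
}

#' Nucleotide diversity of a window
#'
#' Mean number of pairwise differences per site:
#' `pi = sum_sites 2 p (1 - p) n / (n - 1) / L`, with the per-site sum
#' running over all sites of the window (monomorphic sites contribute 0)
#' and `L` the window's site count.  Sites with any missing call in the
#' cohort are excluded from both the sum and `L`.
#'
#' @param H Binary haplotype matrix (sites x haplotypes) for the cohort
#'   window, or a [hapset()].
#' @return Per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(H) {
  if (inherits(H, "hapset")) H <- H$H
  if (ncol(H) < 2L) stop("nucleotide diversity needs >= 2 haplotypes")
  cc <- !rowSums(is.na(H))
  H <- H[cc, , drop = FALSE]
  L <- nrow(H)
  if (!L) return(NA_real_)
  n <- ncol(H)
  p <- rowMeans(H)
  sum(2 * p * (1 - p) * n / (n - 1)) / L
}

#' Watterson's theta per site
#'
#' `theta_W = S / a1 / L` with `a1 = sum_{i=1..n-1} 1/i`.
#'
#' @param S Number of segregating sites.
#' @param n_hap Number of haplotypes (>= 2).
#' @param L Number of sites in the window (>= 1).
#' @return Per-site Watterson estimate.
#' @export
watterson_theta <- function(S, n_hap, L) {
  stopifnot(n_hap >= 2L, L >= 1L)
  S / sum(1 / seq_len(n_hap - 1L)) / L
}

# Tajima (1989) normalising constants for sample size n
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for a window
#'
#' `D = (pi - theta_W) / sqrt(e1 S + e2 S (S - 1))`, with `pi` and
#' `theta_W` on the whole-window scale and the Tajima (1989) constants
#' computed from the haplotype count.  Undefined (`NA`) when no site
#' segregates or when the variance term degenerates to zero (as it does
#' identically for n = 2 haplotypes).
#'
#' @inheritParams nucleotide_diversity
#' @return Tajima's D, or `NA` when `S = 0`.
#' @export
tajimas_d <- function(H) {
  if (inherits(H, "hapset")) H <- H$H
  if (ncol(H) < 2L) stop("Tajima's D needs >= 2 haplotypes")
  cc <- !rowSums(is.na(H))
  H <- H[cc, , drop = FALSE]
  n <- ncol(H)
  p <- rowMeans(H)
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  pi_w <- sum(2 * p * (1 - p) * n / (n - 1))
  k <- tajima_constants(n)
  theta_w <- S / k$a1
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_w - theta_w) / sqrt(v)
}

#' Windowed diversity scan for one cohort
#'
#' Computes nucleotide diversity, Watterson's theta (both per site) and
#' Tajima's D for every window.
#'
#' @param hap A [hapset()] already restricted to the cohort (see
#'   [select_cohort()]).
#' @param windows A `snp_windows` data.frame from [make_windows()].
#' @return A data.frame with one row per window: the window columns plus
#'   `S`, `n_hap`, `pi`, `theta_w`, `tajimas_d`.
#' @export
diversity_scan <- function(hap, windows) {
  stopifnot(inherits(hap, "hapset"))
  if (!n_haps(hap)) stop("cohort is empty")
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    H <- hap$H[windows$snp_first[i]:windows$snp_last[i], , drop = FALSE]
    cc <- !rowSums(is.na(H))
    Hc <- H[cc, , drop = FALSE]
    n <- ncol(Hc)
    p <- rowMeans(Hc)
    S <- sum(p > 0 & p < 1)
    L <- nrow(Hc)
    data.frame(S = S, n_hap = n,
               pi = if (L) sum(2 * p * (1 - p) * n / (n - 1)) / L
                    else NA_real_,
               theta_w = if (L) watterson_theta(S, n, L) else NA_real_,
               tajimas_d = tajimas_d(Hc))
  })
  cbind(as.data.frame(windows), do.call(rbind, rows))
}
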