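# Per-SNP temporal association: allele-frequency change between survey
# rounds tested with a binomial logit model and household-cluster-robust
# (sandwich) variance, followed by Benjamini-Hochberg FDR control.

#' Test one SNP for an allele-frequency change between rounds
#'
#' Per-sample alternate-allele counts (0-2 of 2 trials) are modelled with
#' a binomial logit GLM with round as the only covariate; within-
#' household dependence is absorbed by a cluster-robust sandwich variance
#' over households, and the two-sided Wald p-value uses a t reference
#' whose degrees of freedom are the effective cluster count minus one:
#' the number of households actually carrying the minor allele (capped at
#' the total household count).  The sandwich variance is only informed by
#' clusters where the score varies, so rare variants concentrated in a
#' handful of households get the heavy-tailed reference they warrant —
#' the usual small-cluster-count correction taken at per-site resolution.
#' Under complete separation (the Wald statistic degenerates) the p-value
#' falls back to a likelihood-ratio test and the row is flagged.
#'
#' @param g Integer vector of genotypes in \{0, 1, 2\} (no missing).
#' @param round Factor/character of round labels, two levels, aligned
#'   with `g`.
#' @param household Household ids aligned with `g`.
#' @return One-row data.frame: `freq_pre`, `freq_post`, `effect`
#'   (log-odds of the second round level), `se`, `p_value`, `separation`.
#'   Returns `NULL` for monomorphic input.
#' @export
snp_round_test <- function(g, round, household) {
  if (anyNA(g)) stop("snp_round_test requires complete data")
  round <- factor(round)
  if (nlevels(round) != 2L) stop("round must have exactly two levels")
  if (all(g == 0L) || all(g == 2L)) return(NULL)
  dat <- data.frame(alt = g, ref = 2L - g, round = round,
                    household = household)
  fit <- suppressWarnings(glm(cbind(alt, ref) ~ round, family = binomial(),
                              data = dat))
  beta <- coef(fit)[2L]
  vc <- tryCatch(sandwich::vcovCL(fit, cluster = dat$household,
                                  type = "HC0"),
                 error = function(e) NULL)
  separated <- is.null(vc) || !is.finite(vc[2L, 2L]) ||
    abs(beta) > 15 || sqrt(vc[2L, 2L]) > 1e3
  if (!separated) {
    se <- sqrt(vc[2L, 2L])
    minor <- if (mean(g) / 2 <= 0.5) g > 0L else g < 2L
    df <- max(min(length(unique(dat$household[minor])),
                  length(unique(dat$household))) - 1L, 1L)
    p <- 2 * pt(-abs(beta / se), df = df)
  } else {
    dev0 <- suppressWarnings(
      glm(cbind(alt, ref) ~ 1, family = binomial(), data = dat))$deviance
    p <- pchisq(dev0 - fit$deviance, df = 1L, lower.tail = FALSE)
    se <- NA_real_
  }
  lev <- levels(round)
  data.frame(freq_pre = mean(g[round == lev[1L]]) / 2,
             freq_post = mean(g[round == lev[2L]]) / 2,
             effect = unname(beta), se = se, p_value = p,
             separation = separated)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`adj_(i) = min_{j>=i} p_(j) m / j`, capped at
#' 1), returned in input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")

#' Genome-wide per-SNP round association scan
#'
#' Applies [snp_round_test()] to every fully observed segregating site
#' with both rounds represented, then controls FDR with
#' Benjamini-Hochberg over the full tested set.
#'
#' @param dip A [dipset()].
#' @param frame A `cohort_frame` covering its samples.
#' @param rounds Length-2 character: the pre and post round labels (in
#'   that order).
#' @param fdr Discovery threshold on the adjusted p (default 0.05).
#' @return A data.frame with one row per tested site: `site` (index),
#'   `contig`, `pos`, the [snp_round_test()] columns, `p_adjusted`, and
#'   `discovery` (`p_adjusted < fdr`).
#' @export
gwas_scan <- function(dip, frame, rounds = c("baseline", "round5"),
                      fdr = 0.05) {
  stopifnot(inherits(dip, "dipset"))
  frame <- validate_cohort(as.data.frame(frame), dip$samples)
  keep_s <- frame$sample_id[frame$round %in% rounds]
  sub <- subset_samples(dip, keep_s)
  meta <- frame[match(sub$samples, frame$sample_id), ]
  rnd <- factor(meta$round, levels = rounds)
  complete <- !rowSums(is.na(sub$G))
  seg <- segregating_mask(sub)
  sites <- which(complete & seg)
  rows <- lapply(sites, function(i)
    snp_round_test(sub$G[i, ], rnd, meta$household))
  keep <- !vapply(rows, is.null, TRUE)
  sites <- sites[keep]
  out <- do.call(rbind, rows[keep])
  if (is.null(out) || !nrow(out))
    return(data.frame())
  out <- cbind(data.frame(site = sites, contig = dip$contig,
                          pos = dip$pos[sites]), out)
  out$p_adjusted <- bh_fdr(out$p_value)
  out$discovery <- out$p_adjusted < fdr
  rownames(out) <- NULL
  out
}

#' @importFrom stats pt
NULL
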