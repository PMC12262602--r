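# Garud haplotype-homozygosity statistics (H1, H12, H123, H2/H1), the
# cross-cohort H1X, genome-wide window scans, top-quantile thresholding
# and peak grouping, and the pre/post-intervention delta-H12 contrast with
# a label-permutation significance test.

#' Haplotype frequency spectrum of a window
#'
#' Counts distinct full-window haplotype strings in a cohort and returns
#' their frequencies sorted descending.  Sites with a missing call in the
#' cohort are dropped from the window before counting (haplotype-based
#' statistics use complete sites only).
#'
#' @param H Binary haplotype matrix (window sites x cohort haplotypes) or
#'   a [hapset()].
#' @return A list of class `hap_spectrum`: `freq` (sorted descending),
#'   `count`, `key` (haplotype strings, aligned with `freq`) and `n_hap`.
#' @export
hap_freq_spectrum <- function(H) {
  if (inherits(H, "hapset")) H <- H$H
  if (!nrow(H)) stop("empty window")
  if (ncol(H) < 2L) stop("spectrum needs >= 2 haplotypes")
  H <- H[!rowSums(is.na(H)), , drop = FALSE]
  key <- apply(H, 2L, paste, collapse = "")
  tab <- sort(table(key), decreasing = TRUE)
  structure(list(freq = as.numeric(tab) / ncol(H),
                 count = as.integer(tab),
                 key = names(tab), n_hap = ncol(H)),
            class = "hap_spectrum")
}

#' Garud's haplotype homozygosity statistics
#'
#' From a descending haplotype frequency spectrum `p`:
#' `H1 = sum p_i^2`; `H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2`;
#' `H123 = (p1 + p2 + p3)^2 + sum_{i>=4} p_i^2`;
#' `H2/H1 = (H1 - p1^2) / H1`.  Absent ranks count as frequency 0.  H12
#' pools the top two haplotypes, giving power against both hard and soft
#' sweeps.
#'
#' @param spectrum A `hap_spectrum` or a numeric frequency vector sorted
#'   descending.
#' @return Named numeric vector `c(H1, H12, H123, H2_H1)`.
#' @export
garud_h <- function(spectrum) {
  p <- if (inherits(spectrum, "hap_spectrum")) spectrum$freq else spectrum
  if (any(diff(p) > 1e-12)) stop("spectrum must be sorted descending")
  p1 <- if (length(p) >= 1) p[1] else 0
  p2 <- if (length(p) >= 2) p[2] else 0
  p3 <- if (length(p) >= 3) p[3] else 0
  h1 <- sum(p^2)
  h12 <- (p1 + p2)^2 + sum(p[-(1:2)]^2)
  h123 <- (p1 + p2 + p3)^2 + if (length(p) > 3) sum(p[-(1:3)]^2) else 0
  c(H1 = h1, H12 = h12, H123 = h123,
    H2_H1 = if (h1 > 0) (h1 - p1^2) / h1 else 0)
}

#' Cross-cohort haplotype homozygosity H1X
#'
#' `H1X = sum_h f_A(h) f_B(h)` over haplotypes observed in either cohort,
#' keyed by haplotype identity.  High H1X in a window indicates a sweep
#' shared between the two cohorts.
#'
#' @param spec_a,spec_b `hap_spectrum` objects for the same window sites
#'   in two cohorts.
#' @return H1X value.
#' @export
h1x <- function(spec_a, spec_b) {
  stopifnot(inherits(spec_a, "hap_spectrum"),
            inherits(spec_b, "hap_spectrum"))
  if (length(spec_a$key) && length(spec_b$key) &&
      nchar(spec_a$key[1L]) != nchar(spec_b$key[1L]))
    stop("window site sets differ between cohorts")
  shared <- intersect(spec_a$key, spec_b$key)
  if (!length(shared)) return(0)
  sum(spec_a$freq[match(shared, spec_a$key)] *
      spec_b$freq[match(shared, spec_b$key)])
}

#' Genome-wide H12 scan
#'
#' Computes Garud's statistics per window for one cohort; the track value
#' is H12, with H1, H123 and H2/H1 carried as extra columns.
#'
#' @param hap A [hapset()] restricted to the cohort.
#' @param windows A `snp_windows` data.frame over the same site axis.
#' @return A [scan_track()] (`value` = H12) with columns `h1`, `h123`,
#'   `h2_h1`.
#' @export
h12_scan <- function(hap, windows) {
  stopifnot(inherits(hap, "hapset"))
  if (!n_haps(hap)) stop("cohort is empty")
  gh <- t(vapply(seq_len(nrow(windows)), function(i) {
    garud_h(hap_freq_spectrum(
      hap$H[windows$snp_first[i]:windows$snp_last[i], , drop = FALSE]))
  }, c(H1 = 0, H12 = 0, H123 = 0, H2_H1 = 0)))
  scan_track(windows, gh[, "H12"], "H12",
             extra = data.frame(h1 = gh[, "H1"], h123 = gh[, "H123"],
                                h2_h1 = gh[, "H2_H1"]))
}

#' Genome-wide H1X scan between two cohorts
#'
#' @param hap_a,hap_b [hapset()] objects for the two cohorts over the
#'   same site axis.
#' @param windows A `snp_windows` data.frame.
#' @return A [scan_track()] of per-window H1X.
#' @export
h1x_scan <- function(hap_a, hap_b, windows) {
  vals <- vapply(seq_len(nrow(windows)), function(i) {
    idx <- windows$snp_first[i]:windows$snp_last[i]
    h1x(hap_freq_spectrum(hap_a$H[idx, , drop = FALSE]),
        hap_freq_spectrum(hap_b$H[idx, , drop = FALSE]))
  }, 0)
  scan_track(windows, vals, "H1X")
}

#' Genome-wide top-quantile threshold
#'
#' The `(1 - q)` empirical quantile (linear interpolation) of all window
#' values pooled across contigs; the default `q = 0.01` reproduces a
#' "top 1% genome-wide" rule.
#'
#' @param track A `scan_track` or numeric vector.
#' @param q Upper tail mass (default 0.01); `q = 0` gives the maximum.
#' @return Threshold value.
#' @export
top_quantile_threshold <- function(track, q = 0.01) {
  v <- if (inherits(track, "scan_track")) track$value else track
  if (!length(v)) stop("empty track")
  unname(quantile(v, 1 - q, na.rm = TRUE, type = 7))
}

#' Group above-threshold windows into peaks
#'
#' Maximal runs of windows with `value >= threshold`; runs separated by
#' at most `max_gap_windows` below-threshold windows are merged.  Runs
#' never merge across contigs, nor across a genomic discontinuity (rows
#' whose SNP ranges are neither overlapping nor contiguous, as in a
#' track already reduced to its peak windows) — which makes peak calling
#' idempotent.  The summit is the window with the maximal value (first
#' on ties).
#'
#' @param track A `scan_track`.
#' @param threshold Finite threshold value.
#' @param max_gap_windows Below-threshold gap tolerated inside a peak.
#' @return A data.frame of class `peak_set`: `contig`, `win_first`,
#'   `win_last` (row indices into `track`), `bp_start`, `bp_end`,
#'   `summit_win`, `summit_bp`, `summit_value`; attribute `threshold`.
#' @export
call_peaks <- function(track, threshold, max_gap_windows = 0L) {
  stopifnot(is.finite(threshold))
  above <- !is.na(track$value) & track$value >= threshold
  n <- nrow(track)
  # block id: changes at contig boundaries and genomic discontinuities
  new_block <- c(TRUE, track$contig[-1] != track$contig[-n] |
                   track$snp_first[-1] > track$snp_last[-n] + 1L)
  block <- cumsum(new_block)
  peaks <- list()
  for (blk in unique(block)) {
    rows <- which(block == blk)
    ctg <- track$contig[rows[1L]]
    ab <- above[rows]
    if (!any(ab)) next
    r <- rle(ab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(first = starts[r$values], last = ends[r$values])
    merged <- runs[1L, , drop = FALSE]
    if (nrow(runs) > 1L) for (k in 2L:nrow(runs)) {
      gap <- runs$first[k] - merged$last[nrow(merged)] - 1L
      if (gap <= max_gap_windows)
        merged$last[nrow(merged)] <- runs$last[k]
      else merged <- rbind(merged, runs[k, ])
    }
    for (k in seq_len(nrow(merged))) {
      w <- rows[merged$first[k]:merged$last[k]]
      summit <- w[which.max(track$value[w])]
      peaks[[length(peaks) + 1L]] <- data.frame(
        contig = ctg, win_first = w[1L], win_last = w[length(w)],
        bp_start = track$bp_start[w[1L]],
        bp_end = track$bp_end[w[length(w)]],
        summit_win = summit, summit_bp =
          (track$bp_start[summit] + track$bp_end[summit]) / 2,
        summit_value = track$value[summit], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(contig = character(0), win_first = integer(0),
               win_last = integer(0), bp_start = integer(0),
               bp_end = integer(0), summit_win = integer(0),
               summit_bp = numeric(0), summit_value = numeric(0))
  attr(out, "threshold") <- threshold
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Delta-H12 between two tracks
#'
#' Per-window difference of H12 between a post-intervention and a
#' pre-intervention cohort.  The default convention `post - pre` makes
#' positive values indicate reduced haplotype diversity (a
#' frequency/homozygosity gain) after the intervention;
#' `convention = "pre_minus_post"` flips the sign.
#'
#' @param track_pre,track_post `scan_track`s over identical windows.
#' @param convention `"post_minus_pre"` (default) or `"pre_minus_post"`.
#' @return A [scan_track()] of delta values.
#' @export
delta_h12 <- function(track_pre, track_post,
                      convention = c("post_minus_pre", "pre_minus_post")) {
  convention <- match.arg(convention)
  same <- identical(track_pre$contig, track_post$contig) &&
    identical(track_pre$snp_first, track_post$snp_first) &&
    identical(track_pre$snp_last, track_post$snp_last)
  if (!same) stop("tracks are defined on different window lists")
  d <- track_post$value - track_pre$value
  if (convention == "pre_minus_post") d <- -d
  scan_track(track_pre[, c("contig", "snp_first", "snp_last", "n_snps",
                           "bp_start", "bp_end")],
             d, "delta_H12")
}

#' Peak threshold for a delta-H12 track
#'
#' `threshold = 3 * (P98 - median)` of the genome-wide delta
#' distribution; windows whose delta exceeds the median by more than the
#' threshold are positive peaks, and windows more than the threshold
#' below the median are negative peaks (reported separately).  Centring
#' on the median makes a constant track yield no peaks.
#'
#' @param track A `scan_track` of delta values (or numeric vector).
#' @return List with `threshold`, `peak_pos`, `peak_neg` (logical flags
#'   per window).
#' @export
delta_peak_threshold <- function(track) {
  v <- if (inherits(track, "scan_track")) track$value else track
  if (!length(v)) stop("empty track")
  med <- median(v, na.rm = TRUE)
  thr <- 3 * (unname(quantile(v, 0.98, na.rm = TRUE, type = 7)) - med)
  list(threshold = thr,
       peak_pos = !is.na(v) & v - med > thr,
       peak_neg = !is.na(v) & v - med < -thr)
}

# ---------------------------------------------------------------------------
# Fast windowed H12 machinery used by the permutation test: precompute a
# per-window within-window haplotype class index for every haplotype
# column, then recompute H12 for arbitrary column subsets with tabulation
# and two max.col passes (H12 = H1 + 2 p1 p2).
# ---------------------------------------------------------------------------

window_hap_classes <- function(H, windows) {
  L <- nrow(windows)
  n <- ncol(H)
  IDX <- matrix(0L, L, n)
  nclass <- integer(L)
  for (i in seq_len(L)) {
    key <- apply(H[windows$snp_first[i]:windows$snp_last[i], ,
                   drop = FALSE], 2L, paste, collapse = "")
    u <- unique(key)
    IDX[i, ] <- match(key, u)
    nclass[i] <- length(u)
  }
  k <- max(nclass)
  # global ids: window i, class c -> (i - 1) * k + c
  list(IDX = IDX, k = k, L = L,
       GID = IDX + (seq_len(L) - 1L) * k)
}

h12_from_classes <- function(wc, cols) {
  cnt <- tabulate(wc$GID[, cols, drop = FALSE], nbins = wc$L * wc$k)
  C <- matrix(cnt, wc$L, wc$k, byrow = TRUE)
  nh <- length(cols)
  P <- C / nh
  h1 <- rowSums(P^2)
  m1 <- max.col(P, ties.method = "first")
  v1 <- P[cbind(seq_len(wc$L), m1)]
  P[cbind(seq_len(wc$L), m1)] <- -1
  v2 <- pmax(P[cbind(seq_len(wc$L), max.col(P, ties.method = "first"))], 0)
  h1 + 2 * v1 * v2
}

#' Permutation test for delta-H12
#'
#' Tests, window by window, whether the observed H12 difference between a
#' pre- and a post-intervention cohort exceeds what label exchange
#' explains.  Each permutation reassigns whole individuals (both
#' haplotypes moving together) between the two cohorts, keeping group
#' sizes, and recomputes delta-H12 for every window.  The two-sided
#' p-value uses the add-one estimator
#' `p = (1 + #\{|delta_perm| >= |delta_obs|\}) / (1 + n_perm)`.
#'
#' @param hap A [hapset()] containing both cohorts.
#' @param ids_pre,ids_post Sample ids of the pre- and post-intervention
#'   cohorts.
#' @param windows A `snp_windows` data.frame.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level on the raw permutation p (default
#'   0.01); a `marginal` tier at 0.05 is also flagged.
#' @param convention Delta sign convention (see [delta_h12()]).
#' @return A data.frame of class `delta_result`: window columns plus
#'   `h12_pre`, `h12_post`, `delta`, `p_value`, `peak` / `peak_neg`
#'   (from [delta_peak_threshold()]), `significant` (`p < alpha`) and
#'   `marginal` (`p < 0.05`); attributes `n_perm`, `seed`, `alpha`,
#'   `delta_threshold`.
#' @export
delta_permutation_test <- function(hap, ids_pre, ids_post, windows,
                                   n_perm = 1000L, seed = 1L,
                                   alpha = 0.01,
                                   convention = c("post_minus_pre",
                                                  "pre_minus_post")) {
  convention <- match.arg(convention)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(ids_pre) < 1L || length(ids_post) < 1L)
    stop("both cohorts need samples")
  sgn <- if (convention == "post_minus_pre") 1 else -1
  both <- c(ids_pre, ids_post)
  sub <- subset_samples(hap, both)
  H <- sub$H
  if (anyNA(H))
    stop("missing haplotype calls in the analysis cohorts; drop or ",
         "restrict sites first")
  wc <- window_hap_classes(H, windows)
  samp <- hap_samples(sub)
  cols_of <- function(ids) which(samp %in% ids)
  n_pre <- length(ids_pre)
  obs_pre <- h12_from_classes(wc, cols_of(ids_pre))
  obs_post <- h12_from_classes(wc, cols_of(ids_post))
  delta_obs <- sgn * (obs_post - obs_pre)
  set.seed(seed)
  exceed <- integer(nrow(windows))
  for (b in seq_len(n_perm)) {
    perm <- sample(both)
    d <- sgn * (h12_from_classes(wc, cols_of(perm[-seq_len(n_pre)])) -
                  h12_from_classes(wc, cols_of(perm[seq_len(n_pre)])))
    exceed <- exceed + (abs(d) >= abs(delta_obs))
  }
  p <- (1 + exceed) / (1 + n_perm)
  pk <- delta_peak_threshold(delta_obs)
  out <- cbind(as.data.frame(windows),
               data.frame(h12_pre = obs_pre, h12_post = obs_post,
                          delta = delta_obs, p_value = p,
                          peak = pk$peak_pos, peak_neg = pk$peak_neg,
                          significant = p < alpha, marginal = p < 0.05))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  attr(out, "delta_threshold") <- pk$threshold
  class(out) <- c("delta_result", "data.frame")
  out
}
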