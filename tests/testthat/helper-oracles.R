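# Independent reference implementations used as oracles.  These are
# deliberately written as naive loops / first-principles formulas so they
# share no code path with the package implementations they check.

# quick hapset from a bare matrix
make_hap <- function(H, pos = NULL, contig = "chr") {
  H <- as.matrix(H)
  if (is.null(pos)) pos <- seq_len(nrow(H))
  hapset(contig, pos, H, paste0("s", seq_len(ncol(H) / 2)))
}

rand_window <- function(n_hap, n_site, maf_shape = 1) {
  p <- rbeta(n_site, maf_shape, 3)
  matrix(rbinom(n_site * n_hap, 1L, rep(p, n_hap)), n_site, n_hap)
}

# --- Garud statistics by explicit dictionary counting ---------------------
oracle_garud <- function(H) {
  n <- ncol(H)
  keys <- character(n)
  for (j in seq_len(n)) keys[j] <- paste(H[, j], collapse = ",")
  uniq <- unique(keys)
  cnt <- integer(length(uniq))
  for (u in seq_along(uniq))
    for (j in seq_len(n)) if (keys[j] == uniq[u]) cnt[u] <- cnt[u] + 1L
  p <- sort(cnt / n, decreasing = TRUE)
  # H1 independently as the probability two draws (with replacement) match
  same <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if (keys[i] == keys[j]) same <- same + 1L
  h1_pairs <- same / n^2
  g <- function(k) sum(p[seq_len(min(k, length(p)))])
  list(H1 = sum(p^2),
       H1_pairs = h1_pairs,
       H12 = g(2)^2 + sum(p[-seq_len(min(2, length(p)))]^2),
       H123 = g(3)^2 + sum(p[-seq_len(min(3, length(p)))]^2),
       H2_H1 = (sum(p^2) - p[1]^2) / sum(p^2))
}

# --- nucleotide diversity by all-pairs Hamming counting -------------------
oracle_pi <- function(H) {
  n <- ncol(H)
  L <- nrow(H)
  tot <- 0
  npair <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(H[, i] != H[, j])
    npair <- npair + 1
  }
  tot / npair / L
}

# --- Tajima's D from independently coded 1989 constants -------------------
oracle_tajd <- function(H) {
  n <- ncol(H)
  ac <- rowSums(H)
  seg <- ac > 0 & ac < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # pi on the window scale via pairwise-difference counting
  k_hat <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    k_hat <- k_hat + sum(H[, i] != H[, j])
  k_hat <- k_hat / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- Benjamini-Hochberg by the min-over-tail definition -------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {
    i <- o[r]
    tail_vals <- numeric(0)
    for (r2 in r:m) tail_vals <- c(tail_vals, p[o[r2]] * m / r2)
    adj[i] <- min(1, min(tail_vals))
  }
  adj
}

# --- naive O(n^3) complete-linkage agglomeration --------------------------
# returns merge heights (sorted) and the cophenetic distance matrix
oracle_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- max(D[clusters[[a]], clusters[[b]]])
      if (dd < best_d) { best_d <- dd; best <- c(a, b) }
    }
    heights <- c(heights, best_d)
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, coph = coph)
}

# --- Manhattan distance by direct double loop -----------------------------
oracle_manhattan <- function(G) {
  n <- ncol(G)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(nrow(G)))
      if (!is.na(G[k, i]) && !is.na(G[k, j]))
        s <- s + abs(G[k, i] - G[k, j])
    D[i, j] <- s
  }
  D
}

# small silhouette for a 1-d embedding with two groups
silhouette_1d <- function(x, grp) {
  vals <- vapply(seq_along(x), function(i) {
    own <- abs(x[i] - x[grp == grp[i]])
    a <- sum(own) / (length(own) - 1)
    b <- mean(abs(x[i] - x[grp != grp[i]]))
    (b - a) / max(a, b)
  }, 0)
  mean(vals)
}
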