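# Synthetic cohort generator emulating a two-region, two-round, two-arm
# cluster-randomised LLIN trial: neutral 1/i site-frequency-spectrum
# background in linkage equilibrium, Balding-Nichols regional
# differentiation, household random effects on logit allele frequency, and
# injected hard/soft selective sweeps with distance-dependent erosion.

#' Sample allele frequencies from the standard neutral SFS
#'
#' Draws per-site derived-allele counts `i` with probability proportional
#' to `1/i` for `i = 1 .. 2n-1` (the standard neutral site frequency
#' spectrum) and returns frequencies `i / 2n`, all strictly inside (0, 1).
#'
#' @param n_sites Number of sites to draw.
#' @param n_alleles Total allele count `2n` (>= 4).
#' @param seed Optional integer seed; when given the draw is a pure
#'   function of it.
#' @return Numeric vector of length `n_sites`.
#' @export
sample_neutral_frequencies <- function(n_sites, n_alleles, seed = NULL) {
  if (n_alleles < 4L) stop("need at least 4 alleles (2n >= 4)")
  if (!is.null(seed)) set.seed(seed)
  i <- sample.int(n_alleles - 1L, n_sites, replace = TRUE,
                  prob = 1 / seq_len(n_alleles - 1L))
  i / n_alleles
}

#' Describe an injected selective sweep
#'
#' @param contig Contig carrying the sweep.
#' @param center Sweep center in bp (the tag SNP is the site nearest it).
#' @param half_width Half-width of the swept interval in bp (> 0).
#' @param n_core Number of distinct core haplotypes (1 = hard sweep,
#'   >= 2 = soft sweep).
#' @param freq Swept-haplotype frequency: either a single number applied to
#'   every cohort or a named list/vector keyed `"<round>:<arm>"` (missing
#'   keys fall back to `default`, default 0).
#' @param erosion Per-site reversion probability at the sweep edge; the
#'   probability grows linearly from 0 at the center to `erosion` at
#'   distance `half_width`, eroding core-haplotype identity toward the
#'   flanks so scans see peak-shaped signals.
#' @param default Fallback frequency for cohorts absent from `freq`.
#' @param name Optional locus label (e.g. `"Cyp9k1"`).
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(contig, center, half_width, n_core = 1L,
                         freq = 0.5, erosion = 0, default = 0,
                         name = NULL) {
  stopifnot(half_width > 0, n_core >= 1L, erosion >= 0, erosion <= 1)
  fr <- unlist(freq)
  if (any(fr < 0 | fr > 1)) stop("sweep frequencies must lie in [0, 1]")
  structure(list(contig = contig, center = center, half_width = half_width,
                 n_core = as.integer(n_core), freq = freq,
                 erosion = erosion, default = default,
                 name = if (is.null(name)) paste0(contig, ":", center)
                        else name),
            class = "sweep_config")
}

sweep_freq_for <- function(cfg, round, arm) {
  if (is.numeric(cfg$freq) && is.null(names(cfg$freq)) &&
      length(cfg$freq) == 1L) return(cfg$freq)
  key <- paste(round, arm, sep = ":")
  f <- cfg$freq[[key]]
  if (is.null(f)) cfg$default else f
}

#' Design of a synthetic trial cohort
#'
#' Captures the study conditions the generator emulates: per-cell sample
#' sizes over (region x round x arm), genome layout, household structure,
#' regional differentiation and sweeps.  Defaults give a desk-scale
#' cohort with the trial's qualitative structure: two regions with weak
#' (Balding-Nichols `F = d`) differentiation, two survey rounds, two net
#' arms, Poisson-sized households with a normal random effect on logit
#' allele frequency.
#'
#' @param n_per_cell Samples per (region, round, arm) cell.
#' @param regions,rounds,arms Factor levels of the design.
#' @param n_sites Sites per contig: named integer vector (names =
#'   contigs) or a single number for one contig.
#' @param contig_lengths Named bp lengths, same names as `n_sites`.
#' @param positions Optional named list of explicit position vectors per
#'   contig (overrides uniform placement).
#' @param household_mean_size Mean household size (>= 1); sizes are
#'   `1 + Poisson(mean - 1)`.
#' @param sigma_h Household random-effect SD: per-(site, household)
#'   normal effects on the log carrier weight induce within-household
#'   allele-frequency correlation (0 = none).
#' @param d Regional differentiation parameter: variance of per-(site,
#'   region) normal log-weight perturbations.  `d = 0` is exact
#'   panmixia; small `d` gives weak F_ST of order
#'   `d * mean(p(1-p))`, and the default emulates differentiation on
#'   the `F_ST <= 0.003` scale typical of a single connected
#'   population.
#' @param sweeps List of [sweep_config()] objects.
#' @param years Named vector mapping round to calendar year.
#' @param country Country label written to metadata.
#' @param seed Integer seed fixing the full output.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_per_cell = 25L,
                       regions = c("East", "West"),
                       rounds = c("baseline", "round5"),
                       arms = c("PBO", "nonPBO"),
                       n_sites = c("2RL" = 5000L),
                       contig_lengths = NULL,
                       positions = NULL,
                       household_mean_size = 3,
                       sigma_h = 0.5,
                       d = 0.01,
                       sweeps = list(),
                       years = NULL,
                       country = "Uganda",
                       seed = 1L) {
  if (is.null(names(n_sites))) names(n_sites) <- "2RL"
  if (is.null(contig_lengths))
    contig_lengths <- setNames(pmax(n_sites * 200L, 1e6), names(n_sites))
  if (is.null(years))
    years <- setNames(seq(2017L, by = 2L, length.out = length(rounds)),
                      rounds)
  if (any(n_per_cell <= 0L) || any(n_sites <= 0L))
    stop("all counts must be positive")
  if (d < 0) stop("d must be >= 0")
  if (household_mean_size < 1) stop("household_mean_size must be >= 1")
  structure(list(n_per_cell = as.integer(n_per_cell), regions = regions,
                 rounds = rounds, arms = arms,
                 n_sites = setNames(as.integer(n_sites), names(n_sites)),
                 contig_lengths = contig_lengths, positions = positions,
                 household_mean_size = household_mean_size,
                 sigma_h = sigma_h, d = d, sweeps = sweeps, years = years,
                 country = country, seed = as.integer(seed)),
            class = "sim_design")
}

# assign samples of one (region, arm) block to households (both rounds share
# the household pool, as in a cluster-randomised trial)
assign_households <- function(n, mean_size, prefix) {
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, 1L + rpois(max(8L, n), max(mean_size - 1, 0)))
  hh <- rep(seq_along(sizes), sizes)[seq_len(n)]
  paste0(prefix, sprintf("%03d", hh))
}

#' Simulate a phased trial cohort
#'
#' Generates phased haplotypes for every design cell.  Background sites
#' are in linkage equilibrium with per-site derived-allele counts drawn
#' exactly from the standard neutral `1/i` spectrum; carriers are then
#' assigned by weighted sampling without replacement, with per-(site,
#' region) log-weight perturbations of variance `d` (regional
#' differentiation; `d = 0` reproduces exchangeability exactly) and
#' per-(site, household) perturbations of SD `sigma_h` (household
#' correlation).  Configured sweeps are injected per (round, arm)
#' cohort.  Fully deterministic given `design$seed`.
#'
#' @param design A [sim_design()].
#' @return A list with elements `sets` (named list of [hapset()] per
#'   contig), `frame` (a `cohort_frame`), and `truth` (sweep and design
#'   parameters realised, for parameter-recovery tests).
#' @export
simulate_cohorts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  cells <- expand.grid(region = design$regions, round = design$rounds,
                       arm = design$arms, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  n_total <- design$n_per_cell * nrow(cells)
  frame <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_total)),
    region = rep(cells$region, each = design$n_per_cell),
    round = rep(cells$round, each = design$n_per_cell),
    arm = rep(cells$arm, each = design$n_per_cell),
    household = NA_character_,
    country = design$country,
    year = design$years[rep(cells$round, each = design$n_per_cell)],
    stringsAsFactors = FALSE)
  for (r in design$regions) for (a in design$arms) {
    idx <- which(frame$region == r & frame$arm == a)
    if (!length(idx)) stop("infeasible design: empty (region, arm) block")
    frame$household[idx] <- assign_households(
      length(idx), design$household_mean_size,
      paste0("H", substr(r, 1, 1), substr(a, 1, 1)))
  }
  frame <- validate_cohort(frame)

  n2 <- 2L * n_total
  hh_levels <- sort(unique(frame$household))
  hap_owner <- ceiling(seq_len(n2) / 2)            # sample index per hap
  reg_idx <- match(frame$region, design$regions)[hap_owner]
  hh_idx <- match(frame$household, hh_levels)[hap_owner]
  uniform <- design$d == 0 && design$sigma_h == 0
  sets <- list()
  truth_sweeps <- list()
  for (ctg in names(design$n_sites)) {
    L <- design$n_sites[[ctg]]
    clen <- design$contig_lengths[[ctg]]
    pos <- if (!is.null(design$positions[[ctg]]))
      as.integer(design$positions[[ctg]])
    else sort(sample.int(clen, L))
    # exact neutral SFS: per-site derived-allele count i ~ 1/i, carriers
    # assigned by (weighted) sampling without replacement so that the
    # sample count spectrum is exactly neutral (E[pi | S] = theta_W)
    counts <- sample.int(n2 - 1L, L, replace = TRUE,
                         prob = 1 / seq_len(n2 - 1L))
    delta <- if (design$d > 0)
      matrix(rnorm(L * length(design$regions), sd = sqrt(design$d)), L)
    else NULL
    U <- if (design$sigma_h > 0)
      matrix(rnorm(L * length(hh_levels), sd = design$sigma_h), L)
    else NULL
    H <- matrix(0L, L, n2)
    for (s in seq_len(L)) {
      if (uniform) {
        idx <- sample.int(n2, counts[s])
      } else {
        eta <- numeric(n2)
        if (!is.null(delta)) eta <- eta + delta[s, reg_idx]
        if (!is.null(U)) eta <- eta + U[s, hh_idx]
        idx <- sample.int(n2, counts[s], prob = exp(eta))
      }
      H[s, idx] <- 1L
    }
    hs <- hapset(ctg, pos, H, frame$sample_id)
    for (sw in design$sweeps) {
      if (!identical(sw$contig, ctg)) next
      realized <- list(name = sw$name, contig = ctg, center = sw$center,
                       half_width = sw$half_width, n_core = sw$n_core,
                       erosion = sw$erosion, freq = list())
      # one set of core haplotypes per sweep, shared by every cohort
      sw_sites <- which(pos >= sw$center - sw$half_width &
                        pos <= sw$center + sw$half_width)
      if (!length(sw_sites))
        stop("sweep '", sw$name, "' covers no sites on ", ctg)
      p_bg <- rowMeans(hs$H[sw_sites, , drop = FALSE])
      templates <- vapply(seq_len(sw$n_core),
                          function(k) rbinom(length(sw_sites), 1L, p_bg),
                          integer(length(sw_sites)))
      for (rd in design$rounds) for (a in design$arms) {
        f <- sweep_freq_for(sw, rd, a)
        realized$freq[[paste(rd, a, sep = ":")]] <- f
        if (f <= 0) next
        ids <- frame$sample_id[frame$round == rd & frame$arm == a]
        cols <- which(hap_samples(hs) %in% ids)
        hs <- inject_sweep(hs, cols, sw, freq = f, templates = templates)
      }
      sweep_sites <- which(pos >= sw$center - sw$half_width &
                           pos <= sw$center + sw$half_width)
      realized$tag_pos <- pos[sweep_sites[
        which.min(abs(pos[sweep_sites] - sw$center))]]
      truth_sweeps[[sw$name]] <- realized
    }
    sets[[ctg]] <- hs
  }
  truth <- list(seed = design$seed, d = design$d,
                sigma_h = design$sigma_h,
                n_per_cell = design$n_per_cell,
                regions = design$regions, rounds = design$rounds,
                arms = design$arms, n_sites = as.list(design$n_sites),
                sweeps = truth_sweeps)
  list(sets = sets, frame = frame, truth = truth)
}

#' Inject a selective sweep into a haplotype set
#'
#' Overwrites a fraction `freq` of the given haplotype columns with copies
#' of `n_core` core haplotypes across the swept interval.  Each copied
#' site reverts to the carrier's original allele with probability
#' `erosion * |pos - center| / half_width`, so core-haplotype identity
#' decays toward the flanks; the tag SNP (site nearest the center) is
#' fixed alternate on every core copy regardless of erosion.
#'
#' @param hap A [hapset()].
#' @param cols Integer haplotype column indices forming the cohort.
#' @param config A [sweep_config()].
#' @param freq Swept-haplotype frequency to realise in `cols` (defaults
#'   to the scalar `config$freq`).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @param templates Optional matrix (sweep sites x `n_core`) of core
#'   haplotypes to reuse, so the same sweep identity can be shared
#'   across cohorts; drawn from the background frequencies when `NULL`.
#' @return A new [hapset()] with the sweep applied.
#' @export
inject_sweep <- function(hap, cols, config, freq = NULL, seed = NULL,
                         templates = NULL) {
  stopifnot(inherits(hap, "hapset"), inherits(config, "sweep_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freq)) {
    stopifnot(is.numeric(config$freq), length(config$freq) == 1L)
    freq <- config$freq
  }
  lo <- config$center - config$half_width
  hi <- config$center + config$half_width
  sites <- which(hap$pos >= lo & hap$pos <= hi)
  if (!length(sites))
    stop("sweep window ", hap$contig, ":", lo, "-", hi,
         " contains no sites")
  n_car <- round(freq * length(cols))
  if (n_car == 0L) return(hap)
  if (n_car > length(cols)) stop("infeasible sweep frequency")
  carriers <- sample(cols, n_car)
  core_of <- rep_len(seq_len(config$n_core), n_car)
  tag <- sites[which.min(abs(hap$pos[sites] - config$center))]
  if (is.null(templates)) {
    p_bg <- rowMeans(hap$H[sites, , drop = FALSE], na.rm = TRUE)
    templates <- vapply(seq_len(config$n_core),
                        function(k) rbinom(length(sites), 1L, p_bg),
                        integer(length(sites)))
  } else {
    templates <- as.matrix(templates)
    if (nrow(templates) != length(sites) ||
        ncol(templates) < config$n_core)
      stop("templates must be (sweep sites x n_core)")
  }
  H <- hap$H
  p_rev <- pmin(config$erosion *
                  abs(hap$pos[sites] - config$center) / config$half_width, 1)
  for (k in seq_len(config$n_core)) {
    ck <- carriers[core_of == k]
    if (!length(ck)) next
    block <- matrix(templates[, k], length(sites), length(ck))
    if (config$erosion > 0) {
      keep_orig <- matrix(runif(length(sites) * length(ck)), length(sites)) <
        p_rev
      orig <- H[sites, ck, drop = FALSE]
      block[keep_orig] <- orig[keep_orig]
    }
    H[sites, ck] <- block
    H[tag, ck] <- 1L
  }
  hapset(hap$contig, hap$pos, H, hap$samples, hap$ref, hap$alt)
}

#' Plant per-round allele-frequency shifts at chosen sites
#'
#' Resets the alternate-allele carriers of the given sites within each
#' round's haplotype columns to an exact target frequency (carriers drawn
#' uniformly), creating true temporal frequency changes for association
#' power studies while leaving other sites untouched.
#'
#' @param hap A [hapset()].
#' @param frame A `cohort_frame` for its samples.
#' @param sites Integer site indices to modify.
#' @param freq_by_round Named numeric vector mapping round label to
#'   target alternate-allele frequency.
#' @param seed Optional seed; `NULL` continues the RNG stream.
#' @return A new [hapset()] with the shifts applied.
#' @export
inject_frequency_shift <- function(hap, frame, sites, freq_by_round,
                                   seed = NULL) {
  stopifnot(inherits(hap, "hapset"))
  if (!is.null(seed)) set.seed(seed)
  H <- hap$H
  rnd <- frame$round[match(hap_samples(hap), frame$sample_id)]
  for (r in names(freq_by_round)) {
    cols <- which(rnd == r)
    if (!length(cols)) stop("no samples in round ", r)
    for (s in sites) {
      H[s, cols] <- 0L
      k <- round(freq_by_round[[r]] * length(cols))
      if (k > 0L) H[s, sample(cols, k)] <- 1L
    }
  }
  hapset(hap$contig, hap$pos, H, hap$samples, hap$ref, hap$alt)
}

#' Write a simulated cohort to disk
#'
#' Emits one plain-text VCF per contig, a metadata TSV, and a JSON truth
#' sidecar recording the realised sweep parameters and seed.
#'
#' @param sim Result of [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = character(0))
  for (ctg in names(sim$sets)) {
    p <- file.path(dir, paste0(ctg, ".vcf"))
    write_vcf(sim$sets[[ctg]], p)
    paths$vcf[ctg] <- p
  }
  paths$metadata <- file.path(dir, "metadata.tsv")
  write_metadata(sim$frame, paths$metadata)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
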