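# Pipeline orchestration: YAML/JSON config with field-standard defaults
# (500-SNP windows, 1000 permutations, top 1%, alpha 0.01, 1000 F_ST
# iterations), run logs with seeds and a design hash, and the R-level
# entry points behind the inst/cli/hapscan.R dispatcher.

default_run_config <- function() {
  list(window_snps = 500L, step_snps = NULL, n_perm = 1000L,
       alpha = 0.01, q = 0.01, fst_n_snps = 1000L, fst_n_iter = 1000L,
       seed = 1L, rounds = c("baseline", "round5"),
       arms = c("PBO", "nonPBO"), regions = c("East", "West"))
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) config and fills unset fields with the
#' defaults: 500-SNP windows, 1000 permutations, top-1% threshold,
#' alpha 0.01, 1000 F_ST resampling iterations.
#'
#' @param path Optional path to a YAML/JSON config file.
#' @param overrides Named list applied on top (e.g. CLI flags).
#' @return Named list of run parameters.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                             simplifyVector = TRUE)
            else yaml::read_yaml(path)
    if (!is.list(user)) stop("malformed config: ", path)
    bad <- setdiff(names(user), c(names(cfg), "input", "metadata",
                                  "out", "design"))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  if (is.null(cfg$step_snps)) cfg$step_snps <- cfg$window_snps
  cfg
}

# FNV-1a 32-bit hash of a canonical JSON rendering; identifies a design
# in run manifests without external digest dependencies
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                   digits = NA)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply without losing double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * p) %% 65536 * 65536 + lo * p) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

write_manifest <- function(dir, stage, params) {
  man <- c(list(stage = stage, hash = fnv1a32(params)), params)
  jsonlite::write_json(man, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Simulate a cohort and write it to disk
#'
#' @param design A [sim_design()] (or `NULL` for the default design).
#' @param out Output directory.
#' @param seed Overrides the design seed when given.
#' @return Invisibly, the paths written (see [write_sim()]).
#' @export
run_simulate <- function(design = NULL, out, seed = NULL) {
  if (is.null(design)) design <- sim_design()
  if (!is.null(seed)) design$seed <- as.integer(seed)
  sim <- simulate_cohorts(design)
  paths <- write_sim(sim, out)
  write_manifest(out, "simulate",
                 list(seed = design$seed, n_per_cell = design$n_per_cell,
                      n_sites = as.list(design$n_sites), d = design$d,
                      sigma_h = design$sigma_h,
                      sweeps = lapply(design$sweeps, unclass)))
  invisible(paths)
}

load_inputs <- function(vcf, metadata) {
  vcf <- unlist(vcf)
  sets <- lapply(vcf, function(p) read_vcf(p))
  names(sets) <- vapply(sets, function(s) s$dip$contig, "")
  frame <- read_metadata(metadata, samples = sets[[1L]]$dip$samples)
  list(sets = sets, frame = frame)
}

#' Run per-cohort H12 scans
#'
#' H12 scan per (round, arm) cohort for every contig, written as TSV.
#'
#' @param vcf Character vector of VCF paths (one per contig).
#' @param metadata Metadata TSV path.
#' @param out Output directory.
#' @param config Run configuration ([load_config()] result or `NULL`).
#' @return Invisibly, a named list of `scan_track`s.
#' @export
run_scan <- function(vcf, metadata, out, config = NULL) {
  cfg <- if (is.null(config)) load_config() else config
  inp <- load_inputs(vcf, metadata)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tracks <- list()
  for (ctg in names(inp$sets)) {
    hap <- inp$sets[[ctg]]$hap
    w <- make_windows(hap, cfg$window_snps, cfg$step_snps)
    for (rd in intersect(cfg$rounds, unique(inp$frame$round)))
      for (a in intersect(cfg$arms, unique(inp$frame$arm))) {
        ids <- inp$frame$sample_id[inp$frame$round == rd &
                                     inp$frame$arm == a]
        if (length(ids) < 2L) next
        tr <- h12_scan(subset_samples(hap, ids), w)
        key <- paste(ctg, rd, a, sep = ".")
        write_track(tr, file.path(out, paste0("h12_", key, ".tsv")))
        tracks[[key]] <- tr
      }
  }
  write_manifest(out, "scan", cfg[c("window_snps", "step_snps")])
  invisible(tracks)
}

#' Run the delta-H12 permutation analysis
#'
#' Per arm and contig: delta-H12 between the two configured rounds with
#' the label-permutation test, peak flags, and TSV/BED outputs.
#'
#' @inheritParams run_scan
#' @return Invisibly, a named list of `delta_result`s.
#' @export
run_delta <- function(vcf, metadata, out, config = NULL) {
  cfg <- if (is.null(config)) load_config() else config
  inp <- load_inputs(vcf, metadata)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  for (ctg in names(inp$sets)) {
    hap <- inp$sets[[ctg]]$hap
    w <- make_windows(hap, cfg$window_snps, cfg$step_snps)
    for (a in intersect(cfg$arms, unique(inp$frame$arm))) {
      pre <- inp$frame$sample_id[inp$frame$round == cfg$rounds[1L] &
                                   inp$frame$arm == a]
      post <- inp$frame$sample_id[inp$frame$round == cfg$rounds[2L] &
                                    inp$frame$arm == a]
      if (length(pre) < 2L || length(post) < 2L) next
      dr <- delta_permutation_test(hap, pre, post, w,
                                   n_perm = cfg$n_perm, seed = cfg$seed,
                                   alpha = cfg$alpha)
      key <- paste(ctg, a, sep = ".")
      write.table(as.data.frame(dr),
                  file.path(out, paste0("delta_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res[[key]] <- dr
    }
  }
  write_manifest(out, "delta",
                 cfg[c("window_snps", "n_perm", "alpha", "seed")])
  invisible(res)
}

#' Run the F_ST resampling analysis between regions
#'
#' @inheritParams run_scan
#' @return Invisibly, the `fst_null` object (first contig).
#' @export
run_fst <- function(vcf, metadata, out, config = NULL) {
  cfg <- if (is.null(config)) load_config() else config
  inp <- load_inputs(vcf, metadata)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dip <- inp$sets[[1L]]$dip
  ids_a <- inp$frame$sample_id[inp$frame$region == cfg$regions[1L]]
  ids_b <- inp$frame$sample_id[inp$frame$region == cfg$regions[2L]]
  null <- fst_resampling_null(dip, ids_a, ids_b,
                              n_snps = min(cfg$fst_n_snps,
                                           sum(!rowSums(is.na(dip$G)))),
                              n_iter = cfg$fst_n_iter, seed = cfg$seed)
  write.table(data.frame(within_a = null$within_a,
                         within_b = null$within_b,
                         between = null$between),
              file.path(out, "fst_null.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(out, "fst",
                 list(n_snps = null$n_snps, n_iter = null$n_iter,
                      seed = cfg$seed, p_within_a = null$mw_a$p,
                      p_within_b = null$mw_b$p))
  invisible(null)
}

#' Run diplotype clustering at a locus
#'
#' @inheritParams run_scan
#' @param locus Length-3 list/vector: contig, bp_start, bp_end.
#' @param k Number of flat clusters to report (default 4).
#' @return Invisibly, a list with the linkage, assignment and summary.
#' @export
run_cluster <- function(vcf, metadata, out, locus, k = 4L,
                        config = NULL) {
  inp <- load_inputs(vcf, metadata)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dip <- inp$sets[[as.character(locus[[1L]])]]$dip
  loc <- extract_locus(dip, as.numeric(locus[[2L]]),
                       as.numeric(locus[[3L]]))
  hc <- complete_linkage(manhattan_dist(loc))
  assignment <- cut_clusters(hc, k = min(k, length(loc$samples)))
  summ <- annotate_clusters(assignment, loc, frame = inp$frame)
  write_linkage(hc, file.path(out, "linkage.tsv"))
  write.table(summ$clusters, file.path(out, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(out, "cluster", list(locus = as.list(locus), k = k))
  invisible(list(linkage = hc, assignment = assignment, summary = summ))
}

#' Run the per-SNP round-association GWAS
#'
#' @inheritParams run_scan
#' @return Invisibly, the [gwas_scan()] table (first contig).
#' @export
run_gwas <- function(vcf, metadata, out, config = NULL) {
  cfg <- if (is.null(config)) load_config() else config
  inp <- load_inputs(vcf, metadata)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tab <- gwas_scan(inp$sets[[1L]]$dip, inp$frame, rounds = cfg$rounds)
  write.table(tab, file.path(out, "gwas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_manifest(out, "gwas",
                 list(rounds = cfg$rounds, n_tested = nrow(tab),
                      n_discoveries = sum(tab$discovery)))
  invisible(tab)
}
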