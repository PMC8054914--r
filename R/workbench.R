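#' Run the full simulate -> cluster -> consensus -> correct -> evaluate
#' pipeline
#'
#' Orchestrates the package end to end on simulated tumors: for each tumor a
#' random architecture is drawn on a synthetic copy-number profile, read
#' counts are simulated, several clusterers are run (the Gaussian-mixture
#' reference clusterer plus jittered replicates standing in for independent
#' methods, and the random baselines), their outputs combined by the
#' weighted-median consensus, the winner's curse corrected, mutations
#' assigned, and the reconstruction scored against truth. Artifacts are
#' written as TSV/JSON under `out_dir` together with a manifest.
#'
#' @param config Named list; recognized keys (with defaults):
#'   `n_tumors` (3), `n_methods` (3), `purity` (0.7), `coverage` (48.46621),
#'   `n_clonal` (600), `f_clonal` (0.7), `n_subclones` (1), `min_count` (3),
#'   `seed` (1), `diploid` (TRUE).
#' @param out_dir Output directory (created); NULL skips writing.
#' @return Invisible list of per-tumor results (`truth`, `consensus`,
#'   `scores`, `correction`) plus the manifest.
#' @export
pipeline_run <- function(config = list(), out_dir = NULL) {
  defaults <- list(
    n_tumors = 3L, n_methods = 3L, purity = 0.7, coverage = 48.46621,
    n_clonal = 600L, f_clonal = 0.7, n_subclones = 1L, min_count = 3L,
    seed = 1L, diploid = TRUE)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  set.seed(cfg$seed)
  profile <- sample_profile(cfg$purity, tumor_ploidy = 2,
                            coverage = cfg$coverage)
  results <- vector("list", cfg$n_tumors)
  for (i in seq_len(cfg$n_tumors)) {
    tumor_seed <- sample.int(1e8, 1)
    cn <- synthetic_cn_profile(genome_length = 2e8, n_chroms = 4,
                               diploid = cfg$diploid, rng_seed = tumor_seed)
    arch <- draw_architecture(cfg$n_subclones, cfg$n_clonal, cfg$f_clonal,
                              rng_seed = tumor_seed + 1)
    sim <- simulate_reads(arch, cn, profile, min_count = cfg$min_count,
                          rng_seed = tumor_seed + 2)
    est <- snv_ccf(sim$alt_count / pmax(sim$total_count, 1), profile,
                   sim$major_cn + sim$minor_cn)
    ccfs <- pmin(est$ccf, 1.5)
    cfac <- ccf_conversion_factor(profile, sim$major_cn + sim$minor_cn,
                                  est$multiplicity)
    base <- reference_cluster(ccfs, sim$alt_count, sim$total_count, cfac)
    methods <- list(reference = base)
    for (m in seq_len(max(cfg$n_methods - 1L, 0))) {
      jl <- pmax(base$locations +
                   stats::rnorm(n_clusters(base), 0, 0.02), 0.01)
      jp <- pmax(base$proportions +
                   stats::rnorm(n_clusters(base), 0, 0.02), 0.02)
      methods[[paste0("replicate", m)]] <- clustering(jp / sum(jp), jl)
    }
    methods$stick <- randomclone(ccfs, "stick", rng_seed = tumor_seed + 3)
    cons <- weme_consensus(methods)
    truth <- clustering(arch$cluster_sizes / sum(arch$cluster_sizes),
                        arch$cluster_ccfs, scale = "CCF")
    # per-SNV hard truth/call assignments for the RMSE metric
    truth_assign <- matrix(0, nrow(sim), n_clusters(truth))
    truth_assign[cbind(seq_len(nrow(sim)),
                       match(sim$true_ccf, truth$locations))] <- 1
    truth$assignments <- truth_assign
    post <- assign_mutations(cons, sim, profile)
    cons$assignments <- post
    scores <- score_reconstruction(truth, cons, cfg$purity)
    sub_idx <- which(cons$locations < 0.9)
    correction <- NULL
    if (length(sub_idx)) {
      j <- sub_idx[which.max(cons$proportions[sub_idx])]
      correction <- spoilsport_correct(
        cluster_cp = cons$locations[j] * cfg$purity, purity = cfg$purity,
        ploidy = 2, mean_depth = mean(sim$total_count),
        n_snvs_observed = round(cons$proportions[j] * nrow(sim)))
    }
    if (!is.null(out_dir)) {
      td <- file.path(out_dir, sprintf("tumor%02d", i))
      dir.create(td, showWarnings = FALSE)
      write_snv_tsv(sim, file.path(td, "snvs.tsv"))
      write_clustering_tsv(truth, file.path(td, "truth.tsv"))
      write_clustering_tsv(cons, file.path(td, "consensus.tsv"))
      write_manifest(list(seed = tumor_seed, purity = cfg$purity,
                          n_clonal = cfg$n_clonal, f_clonal = cfg$f_clonal,
                          n_subclones = cfg$n_subclones),
                     file.path(td, "manifest.txt"))
    }
    results[[i]] <- list(snvs = sim, truth = truth, consensus = cons,
                         scores = scores, correction = correction,
                         seed = tumor_seed)
  }
  if (!is.null(out_dir)) {
    score_mat <- do.call(rbind, lapply(results, `[[`, "scores"))
    jsonlite::write_json(
      list(config = cfg, scores = as.data.frame(score_mat)),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tumors = results, config = cfg))
}

#' Deterministic toy datasets for every module
#'
#' Regenerates, from fixed seeds, the small worked-example inputs used in
#' the documentation and tests: the 600-cell simulation grid, toy
#' clusterings for the earth-mover-distance examples, a small simulated
#' tumor, phasing evidence for linear and branching pairs, and a synthetic
#' two-signature catalog with orthogonal support.
#'
#' @return Named list of fixtures.
#' @export
fixture_suite <- function() {
  grid <- build_grid()
  emd_toys <- list(
    a = clustering(1, 0.2),
    b = clustering(1, 0.6),
    c = clustering(c(0.5, 0.5), c(0.2, 0.8)),
    d = clustering(1, 0.5))
  profile <- sample_profile(0.5, 2, coverage = 100)
  cn <- synthetic_cn_profile(genome_length = 1e8, n_chroms = 2,
                             diploid = TRUE, rng_seed = 11)
  arch <- architecture_spec(c(1, 0.4), c(300, 200))
  tumor <- simulate_reads(arch, cn, profile, rng_seed = 11)
  phasing <- list(
    linear = simulate_phase_pair("linear", rng_seed = 7),
    branching = simulate_phase_pair("branching", rng_seed = 7))
  catalog <- matrix(0, 96, 2, dimnames = list(NULL, c("S1", "S2")))
  catalog[1:48, 1] <- 1 / 48
  catalog[49:96, 2] <- 1 / 48
  list(grid = grid, emd_toys = emd_toys, tumor = tumor, profile = profile,
       phasing = phasing, catalog = catalog)
}
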