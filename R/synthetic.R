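#' Configuration for the synthetic-data generators
#'
#' The generators emulate the statistical structure the signature
#' analysis assumes: one latent driver factor per sample, a planted
#' module of genes loading on it, independent background genes,
#' probe-level replication with within-gene coherence, and (for the
#' driver) one optionally decorrelated probe to exercise coherence
#' selection. A module gene's population correlation with the latent
#' factor is `beta / sqrt(beta^2 + sigma^2)`; the defaults
#' (`beta = 1`, `sigma = 0.75`) plant the module at population
#' `r = 0.8` in a cohort of 40 samples — a strong driver-linked module
#' in a mid-sized tumour series.
#'
#' @param n_samples samples in the cohort (default 40).
#' @param n_module_genes genes loading on the latent factor
#'   (default 120).
#' @param n_background_genes independent-noise genes (default 2000).
#' @param probes_per_gene probes interrogating each gene: a single
#'   integer or a `c(min, max)` range sampled per gene (default 4).
#' @param beta module loading on the latent factor (default 1).
#' @param sigma gene-level noise SD (default 0.75).
#' @param probe_noise_sd SD of the probe-level replicate noise added
#'   on top of each gene's value (default 0.3, i.e. probes of one gene
#'   cohere strongly).
#' @param background_sd SD of background gene values (default 1).
#' @param driver_probe_count probes interrogating the driver
#'   (default 6).
#' @param decorrelate_driver_probe replace the driver's last probe by
#'   independent noise, reproducing the situation where one of a
#'   driver's probesets fails to track the others (default `TRUE`).
#' @param driver_symbol gene symbol given to the driver
#'   (default `"MYC"`).
#' @param baseline_log_mean natural-log mean count for the count-scale
#'   generator (default `log(100)`).
#' @param nb_dispersion negative-binomial dispersion for the
#'   count-scale generator (default 0.1).
#' @param seed integer seed governing the whole generation;
#'   per-stage sub-streams are derived from it deterministically.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 40, n_module_genes = 120,
                             n_background_genes = 2000,
                             probes_per_gene = 4, beta = 1, sigma = 0.75,
                             probe_noise_sd = 0.3, background_sd = 1,
                             driver_probe_count = 6,
                             decorrelate_driver_probe = TRUE,
                             driver_symbol = "MYC",
                             baseline_log_mean = log(100),
                             nb_dispersion = 0.1, seed = 1L) {
  if (length(probes_per_gene) == 1) probes_per_gene <- rep(probes_per_gene, 2)
  stopifnot(n_samples >= 3, n_module_genes >= 1, n_background_genes >= 0,
            all(probes_per_gene >= 1),
            probes_per_gene[1] <= probes_per_gene[2],
            sigma > 0, probe_noise_sd >= 0, background_sd > 0,
            driver_probe_count >= 1, nb_dispersion > 0,
            is.finite(seed), abs(seed) < 2^31)
  structure(list(n_samples = as.integer(n_samples),
                 n_module_genes = as.integer(n_module_genes),
                 n_background_genes = as.integer(n_background_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 beta = beta, sigma = sigma,
                 probe_noise_sd = probe_noise_sd,
                 background_sd = background_sd,
                 driver_probe_count = as.integer(driver_probe_count),
                 decorrelate_driver_probe = decorrelate_driver_probe,
                 driver_symbol = driver_symbol,
                 baseline_log_mean = baseline_log_mean,
                 nb_dispersion = nb_dispersion,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic per-stage sub-stream seeds, kept inside 32-bit range
.substream <- function(seed, stage) {
  (as.numeric(seed) * 1009 + stage * 9176) %% 2147483647
}

#' Population correlation implied by the latent-factor model
#'
#' For a gene `g = beta * latent + sigma * noise` with standard-normal
#' latent factor and noise, the population Pearson correlation between
#' the gene and the latent factor is `beta / sqrt(beta^2 + sigma^2)`.
#'
#' @param beta module loading.
#' @param sigma gene-level noise SD (> 0).
#' @return the population correlation, in `[-1, 1]`.
#' @examples
#' expected_population_correlation(1, 0.75)  # 0.8
#' @export
expected_population_correlation <- function(beta, sigma) {
  stopifnot(sigma > 0)
  beta / sqrt(beta^2 + sigma^2)
}

#' Simulate a probe-level exon-array style dataset
#'
#' Gene-level values follow the latent-factor model of
#' [synthetic_config()]; the driver gene's value is the latent factor
#' itself. Each gene is expanded to its probes as the gene value plus
#' independent probe noise; the driver receives `driver_probe_count`
#' probes, the last of which is replaced by independent noise when
#' `decorrelate_driver_probe` is set, so that coherent-probe selection
#' has something to reject. Values are tagged as log-scale, mimicking
#' normalized log intensities. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `matrix` (probe-level [expr_matrix()]),
#'   `annotation` ([probe_annotation()]), and `truth` (list: `latent`,
#'   `module_genes`, `background_genes`, `beta` named per-gene map,
#'   `expected_population_r`, `decorrelated_probe`).
#' @export
simulate_exon_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(.substream(cfg$seed, 1), {
    n <- cfg$n_samples
    samples <- sprintf("S%02d", seq_len(n))
    latent <- stats::rnorm(n)
    module_genes <- sprintf("MOD%04d", seq_len(cfg$n_module_genes))
    background_genes <- if (cfg$n_background_genes > 0)
      sprintf("BG%04d", seq_len(cfg$n_background_genes)) else character(0)
    gene_vals <- rbind(
      matrix(rep(cfg$beta * latent, each = cfg$n_module_genes),
             cfg$n_module_genes, n) +
        cfg$sigma * matrix(stats::rnorm(cfg$n_module_genes * n),
                           cfg$n_module_genes, n),
      cfg$background_sd *
        matrix(stats::rnorm(cfg$n_background_genes * n),
               cfg$n_background_genes, n))
    rownames(gene_vals) <- c(module_genes, background_genes)
    genes <- rownames(gene_vals)
    npr <- if (cfg$probes_per_gene[1] == cfg$probes_per_gene[2])
      rep(cfg$probes_per_gene[1], length(genes))
    else sample(cfg$probes_per_gene[1]:cfg$probes_per_gene[2],
                length(genes), replace = TRUE)
    gi <- rep(seq_along(genes), npr)
    probe_ids <- paste0(genes[gi], "_p",
                        sequence(npr))
    probes <- gene_vals[gi, , drop = FALSE] +
      cfg$probe_noise_sd * matrix(stats::rnorm(length(gi) * n),
                                  length(gi), n)
    # driver probes track the latent factor directly
    d_ids <- paste0(cfg$driver_symbol, "_p",
                    seq_len(cfg$driver_probe_count))
    d_probes <- matrix(rep(latent, each = cfg$driver_probe_count),
                       cfg$driver_probe_count, n) +
      cfg$probe_noise_sd * matrix(stats::rnorm(cfg$driver_probe_count * n),
                                  cfg$driver_probe_count, n)
    decor <- NA_character_
    if (cfg$decorrelate_driver_probe && cfg$driver_probe_count > 1) {
      d_probes[cfg$driver_probe_count, ] <- stats::rnorm(n)
      decor <- d_ids[cfg$driver_probe_count]
    }
    all_vals <- rbind(d_probes, probes)
    rownames(all_vals) <- c(d_ids, probe_ids)
    m <- expr_matrix(all_vals, sample_ids = samples, scale = "log",
                     platform = "synthetic-exon")
    ann <- probe_annotation(c(d_ids, probe_ids),
                            c(rep(cfg$driver_symbol,
                                  cfg$driver_probe_count), genes[gi]))
    beta_map <- stats::setNames(
      c(rep(cfg$beta, cfg$n_module_genes),
        rep(0, cfg$n_background_genes)), genes)
    list(matrix = m, annotation = ann,
         truth = list(latent = stats::setNames(latent, samples),
                      module_genes = module_genes,
                      background_genes = background_genes,
                      beta = beta_map,
                      expected_population_r =
                        expected_population_correlation(cfg$beta,
                                                        cfg$sigma),
                      decorrelated_probe = decor))
  })
}

#' Simulate a gene-level RNA-seq style count dataset (CPM)
#'
#' Counts are drawn from a negative binomial whose natural-log mean is
#' `baseline_log_mean + beta * latent` for module genes and the driver
#' (loading 1), and `baseline_log_mean` for background genes;
#' dispersion is fixed at `cfg$nb_dispersion`. Counts are converted to
#' counts-per-million with per-sample totals, the unit a gene-level
#' signature fit expects.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `matrix` (gene-level [expr_matrix()], CPM, linear
#'   scale; driver row named `cfg$driver_symbol`), `counts` (raw count
#'   matrix) and `truth` (as in [simulate_exon_dataset()]).
#' @export
simulate_count_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(.substream(cfg$seed, 2), {
    n <- cfg$n_samples
    samples <- sprintf("S%02d", seq_len(n))
    latent <- stats::rnorm(n)
    module_genes <- sprintf("MOD%04d", seq_len(cfg$n_module_genes))
    background_genes <- if (cfg$n_background_genes > 0)
      sprintf("BG%04d", seq_len(cfg$n_background_genes)) else character(0)
    genes <- c(cfg$driver_symbol, module_genes, background_genes)
    loading <- c(1, rep(cfg$beta, cfg$n_module_genes),
                 rep(0, cfg$n_background_genes))
    log_mu <- outer(loading, latent) + cfg$baseline_log_mean
    counts <- matrix(stats::rnbinom(length(log_mu),
                                    size = 1 / cfg$nb_dispersion,
                                    mu = exp(log_mu)),
                     nrow(log_mu), ncol(log_mu))
    dimnames(counts) <- list(genes, samples)
    totals <- colSums(counts)
    if (any(totals == 0)) stop("zero-total sample in simulation",
                               call. = FALSE)
    cpm <- sweep(counts, 2, totals, "/") * 1e6
    list(matrix = expr_matrix(cpm, scale = "linear",
                              platform = "synthetic-rnaseq"),
         counts = counts,
         truth = list(latent = stats::setNames(latent, samples),
                      module_genes = module_genes,
                      background_genes = background_genes,
                      beta = stats::setNames(loading, genes),
                      expected_population_r =
                        expected_population_correlation(cfg$beta,
                                                        cfg$sigma),
                      decorrelated_probe = NA_character_))
  })
}

#' Apply a monotone per-sample platform distortion
#'
#' Emulates measuring the same biology on a different platform: each
#' sample's values are raised to the power `gamma` (a monotone
#' compressive or expansive response), multiplied by a random
#' per-sample scale factor, and optionally perturbed by multiplicative
#' log-normal jitter. With `jitter_sd = 0` the map is strictly
#' monotone within every sample, so rank structure — and hence the
#' cumulative-proportion transform up to value magnitudes — is
#' preserved.
#'
#' @param m an [expr_matrix()] with non-negative values.
#' @param gamma power-response exponent (> 0).
#' @param jitter_sd SD of the log-normal multiplicative jitter
#'   (default 0).
#' @param seed integer seed for the scale factors and jitter.
#' @return a distorted [expr_matrix()] of the same shape.
#' @export
apply_platform_distortion <- function(m, gamma, jitter_sd = 0, seed = 1L) {
  stopifnot(is_expr_matrix(m), jitter_sd >= 0)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  v <- .values(m)
  if (any(v < 0)) stop("negative values", call. = FALSE)
  .with_seed(.substream(seed, 3), {
    scl <- exp(stats::rnorm(ncol(v), sd = 0.5))
    out <- sweep(v^gamma, 2, scl, "*")
    if (jitter_sd > 0)
      out <- out * exp(matrix(stats::rnorm(length(out), sd = jitter_sd),
                              nrow(out), ncol(out)))
    expr_matrix(out, scale = scale_tag(m),
                platform = paste0(attr(m, "platform_tag"), "-distorted"))
  })
}

#' Simulate a cohort of samples in separated driver-expression groups
#'
#' Builds a gene-by-sample matrix in which the latent driver factor
#' takes one of several group levels — the structure behind a
#' high/medium/low driver partition of tumours. Adjacent group means
#' are `separation` gene-noise SDs apart (i.e. `separation * sigma`
#' on the latent scale), and samples jitter around their group mean
#' with SD `latent_jitter_sd` (default half a gene-noise SD). Module
#' genes load on the latent factor as in [synthetic_config()].
#'
#' @param n_per_group samples per group.
#' @param n_groups number of driver-expression groups (default 3).
#' @param separation spacing of adjacent group means, in units of the
#'   gene-level noise SD `sigma` (default 3).
#' @param n_genes module genes tracking the factor.
#' @param beta,sigma loading and gene-level noise SD, as in
#'   [synthetic_config()].
#' @param latent_jitter_sd within-group SD of the latent factor
#'   (default `sigma / 2`).
#' @param seed integer seed.
#' @return list with `matrix` (genes x samples [expr_matrix()]),
#'   `group` (true group index per sample) and `latent` (the driver
#'   reference per sample).
#' @export
simulate_group_cohort <- function(n_per_group = 10, n_groups = 3,
                                  separation = 3, n_genes = 40,
                                  beta = 1, sigma = 0.75,
                                  latent_jitter_sd = sigma / 2,
                                  seed = 1L) {
  stopifnot(n_per_group >= 2, n_groups >= 2, separation > 0, sigma > 0,
            latent_jitter_sd >= 0)
  .with_seed(.substream(seed, 4), {
    n <- n_per_group * n_groups
    group <- rep(seq_len(n_groups), each = n_per_group)
    latent <- (group - 1) * separation * sigma +
      latent_jitter_sd * stats::rnorm(n)
    vals <- outer(rep(beta, n_genes), latent) +
      sigma * matrix(stats::rnorm(n_genes * n), n_genes, n)
    dimnames(vals) <- list(sprintf("MOD%04d", seq_len(n_genes)),
                           sprintf("S%02d", seq_len(n)))
    list(matrix = expr_matrix(vals, scale = "log",
                              platform = "synthetic-groups"),
         group = stats::setNames(group, colnames(vals)),
         latent = stats::setNames(latent, colnames(vals)))
  })
}
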