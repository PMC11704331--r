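#' Configuration for the expression + survival cohort generator
#'
#' Defines a cohort in which a per-sample latent activity score drives both
#' the expression of a planted gene signature and a proportional-hazards
#' survival model, so that signature scoring and survival stratification can
#' be validated against known ground truth.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param signature_size Number of planted signature genes
#'   (`< n_genes`).
#' @param effect_size Expression shift per unit latent score for signature
#'   genes.
#' @param noise_sd Gaussian expression noise.
#' @param baseline_hazard Baseline event rate (events per time unit).
#' @param log_hr_per_score Log hazard ratio per unit latent score (gamma).
#' @param censor_max Uniform censoring horizon (same time unit).
#' @param seed Integer seed.
#'
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_genes = 2000L,
                              n_samples = 200L,
                              signature_size = 37L,
                              effect_size = 1,
                              noise_sd = 1,
                              baseline_hazard = 0.02,
                              log_hr_per_score = log(2),
                              censor_max = 120,
                              seed = 1L) {
  check_scalar(n_genes, "n_genes", positive = TRUE)
  check_scalar(n_samples, "n_samples", positive = TRUE)
  check_scalar(signature_size, "signature_size", positive = TRUE)
  if (signature_size >= n_genes) {
    stop_spatsig("'signature_size' must be < 'n_genes'")
  }
  check_scalar(effect_size, "effect_size")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(baseline_hazard, "baseline_hazard", positive = TRUE)
  check_scalar(log_hr_per_score, "log_hr_per_score")
  check_scalar(censor_max, "censor_max", positive = TRUE)
  structure(
    list(
      n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
      signature_size = as.integer(signature_size),
      effect_size = effect_size, noise_sd = noise_sd,
      baseline_hazard = baseline_hazard,
      log_hr_per_score = log_hr_per_score,
      censor_max = censor_max, seed = seed
    ),
    class = "cohort_sim_config"
  )
}

#' Simulate an expression cohort with a planted prognostic signature
#'
#' Per sample j a latent score u_j ~ N(0, 1). Signature genes get mean shift
#' `effect_size * u_j`; all genes carry N(0, `noise_sd`) noise. Event times
#' are exponential with hazard `baseline_hazard * exp(log_hr_per_score *
#' u_j)`; censoring is uniform on (0, `censor_max`], the observed time is the
#' minimum, and the event indicator marks whether the event preceded
#' censoring.
#'
#' @param config A [cohort_sim_config()].
#' @return A list with `expr` (genes x samples matrix; signature genes named
#'   `sig_*`, background `bg_*`), `survival` (data.frame `sample_id`, `time`,
#'   `event`), `latent` (named latent scores) and `signature_genes`.
#' @export
simulate_expression_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    n <- config$n_samples
    k <- config$signature_size
    u <- stats::rnorm(n)
    samples <- sprintf("sample_%04d", seq_len(n))
    names(u) <- samples
    genes <- c(sprintf("sig_%04d", seq_len(k)), sprintf("bg_%05d", seq_len(G - k)))
    expr <- matrix(stats::rnorm(G * n, sd = config$noise_sd), nrow = G,
                   dimnames = list(genes, samples))
    expr[seq_len(k), ] <- expr[seq_len(k), ] +
      matrix(config$effect_size * u, nrow = k, ncol = n, byrow = TRUE)

    hazard <- config$baseline_hazard * exp(config$log_hr_per_score * u)
    t_event <- stats::rexp(n, rate = hazard)
    t_cens <- stats::runif(n, 0, config$censor_max)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    surv <- data.frame(sample_id = samples, time = time, event = event,
                       stringsAsFactors = FALSE)
    list(expr = expr, survival = surv, latent = u,
         signature_genes = genes[seq_len(k)])
  })
}

#' Configuration for the cell-line panel generator
#'
#' @param n_cell_lines Panel size; the default mirrors a 46-line pancreatic
#'   cancer cell-line panel.
#' @param n_negative,n_positive,n_null Numbers of genes anti-correlated,
#'   positively correlated, and uncorrelated with the anchor gene.
#' @param correlation_strength Target absolute correlation in (0, 1].
#' @param seed Integer seed.
#' @return A list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_cell_lines = 46L,
                             n_negative = 37L,
                             n_positive = 40L,
                             n_null = 400L,
                             correlation_strength = 0.7,
                             seed = 1L) {
  check_scalar(n_cell_lines, "n_cell_lines", positive = TRUE)
  check_scalar(n_negative, "n_negative", nonneg = TRUE)
  check_scalar(n_positive, "n_positive", nonneg = TRUE)
  check_scalar(n_null, "n_null", nonneg = TRUE)
  check_scalar(correlation_strength, "correlation_strength")
  if (correlation_strength <= 0 || correlation_strength > 1) {
    stop_spatsig("'correlation_strength' must be in (0, 1]")
  }
  structure(
    list(
      n_cell_lines = as.integer(n_cell_lines),
      n_negative = as.integer(n_negative),
      n_positive = as.integer(n_positive),
      n_null = as.integer(n_null),
      correlation_strength = correlation_strength,
      seed = seed
    ),
    class = "panel_sim_config"
  )
}

#' Simulate a cell-line expression panel around an anchor gene
#'
#' The anchor gene is standard normal across cell lines. A negative-class
#' gene is `-c * anchor + sqrt(1 - c^2) * noise` (positive class with `+`),
#' so its population correlation with the anchor is `-c` (`+c`); null genes
#' are independent noise. At `correlation_strength = 1` the noise term
#' vanishes and sample Spearman correlations are exactly -1/+1.
#'
#' @param config A [panel_sim_config()].
#' @return A list with `expr` (genes x cell lines, first row `ANCHOR`),
#'   `anchor` (the anchor gene name) and `classes` (named vector with values
#'   `negative`, `positive`, `null`).
#' @export
simulate_cellline_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  if (config$n_cell_lines < 4L) {
    stop_spatsig("'n_cell_lines' must be >= 4 for correlation to be meaningful")
  }
  with_seed(config$seed, {
    n <- config$n_cell_lines
    cc <- config$correlation_strength
    anchor <- stats::rnorm(n)
    gene_block <- function(k, sign) {
      if (k == 0L) return(matrix(numeric(0), ncol = n))
      noise <- matrix(stats::rnorm(k * n), nrow = k)
      sign * cc * matrix(anchor, nrow = k, ncol = n, byrow = TRUE) +
        sqrt(1 - cc^2) * noise
    }
    neg <- gene_block(config$n_negative, -1)
    pos <- gene_block(config$n_positive, +1)
    nul <- if (config$n_null > 0L) {
      matrix(stats::rnorm(config$n_null * n), nrow = config$n_null)
    } else {
      matrix(numeric(0), ncol = n)
    }
    expr <- rbind(matrix(anchor, nrow = 1L), neg, pos, nul)
    rownames(expr) <- c(
      "ANCHOR",
      sprintf("neg_%04d", seq_len(config$n_negative)),
      sprintf("pos_%04d", seq_len(config$n_positive)),
      sprintf("null_%04d", seq_len(config$n_null))
    )
    colnames(expr) <- sprintf("line_%03d", seq_len(n))
    classes <- c(
      rep.int("negative", config$n_negative),
      rep.int("positive", config$n_positive),
      rep.int("null", config$n_null)
    )
    names(classes) <- rownames(expr)[-1L]
    list(expr = expr, anchor = "ANCHOR", classes = classes)
  })
}

#' Configuration for the dual-species read-score generator
#'
#' @param n_reads Number of reads.
#' @param species_fraction Fraction of reads truly from the graft species
#'   (genome A).
#' @param divergence_penalty_mean,divergence_penalty_sd Alignment-score
#'   deficit on the wrong genome (Gaussian, truncated at 0).
#' @param score_noise_sd Per-read noise on the own-genome score.
#' @param unmapped_fraction Fraction of reads whose wrong-genome alignment is
#'   missing.
#' @param seed Integer seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = 10000L,
                            species_fraction = 0.9,
                            divergence_penalty_mean = 20,
                            divergence_penalty_sd = 5,
                            score_noise_sd = 2,
                            unmapped_fraction = 0.05,
                            seed = 1L) {
  check_scalar(n_reads, "n_reads", positive = TRUE)
  check_fraction(species_fraction, "species_fraction")
  check_scalar(divergence_penalty_mean, "divergence_penalty_mean", nonneg = TRUE)
  check_scalar(divergence_penalty_sd, "divergence_penalty_sd", nonneg = TRUE)
  check_scalar(score_noise_sd, "score_noise_sd", nonneg = TRUE)
  check_fraction(unmapped_fraction, "unmapped_fraction")
  structure(
    list(
      n_reads = as.integer(n_reads), species_fraction = species_fraction,
      divergence_penalty_mean = divergence_penalty_mean,
      divergence_penalty_sd = divergence_penalty_sd,
      score_noise_sd = score_noise_sd,
      unmapped_fraction = unmapped_fraction, seed = seed
    ),
    class = "read_sim_config"
  )
}

#' Simulate per-read alignment scores against two genomes
#'
#' Each read scores `N(100, score_noise_sd)` on its own genome and that score
#' minus a divergence penalty (Gaussian, clamped at 0) on the other genome.
#' A fraction of reads lack the wrong-genome alignment entirely (score `NA`),
#' mimicking reads that fail to map across species.
#'
#' @param config A [read_sim_config()].
#' @return A list with `pairs` (data.frame `read_id`, `score_a`, `score_b`,
#'   `gene_a`, `gene_b`) and `truth` (named character vector, `"graft"` /
#'   `"host"`). Gene labels cycle over a small synthetic gene vocabulary per
#'   genome.
#' @export
simulate_dual_species_reads <- function(config) {
  stopifnot(inherits(config, "read_sim_config"))
  with_seed(config$seed, {
    n <- config$n_reads
    is_graft <- stats::runif(n) < config$species_fraction
    own <- stats::rnorm(n, 100, config$score_noise_sd)
    penalty <- pmax(0, stats::rnorm(n, config$divergence_penalty_mean,
                                    config$divergence_penalty_sd))
    other <- own - penalty
    unmapped <- stats::runif(n) < config$unmapped_fraction

    score_a <- ifelse(is_graft, own, other)
    score_b <- ifelse(is_graft, other, own)
    score_a[!is_graft & unmapped] <- NA_real_
    score_b[is_graft & unmapped] <- NA_real_

    gene_pool_a <- sprintf("GRAFT_G%02d", 1:20)
    gene_pool_b <- sprintf("HOST_G%02d", 1:20)
    pairs <- data.frame(
      read_id = sprintf("read_%06d", seq_len(n)),
      score_a = score_a, score_b = score_b,
      gene_a = ifelse(is.na(score_a), NA_character_,
                      gene_pool_a[(seq_len(n) %% 20L) + 1L]),
      gene_b = ifelse(is.na(score_b), NA_character_,
                      gene_pool_b[(seq_len(n) %% 20L) + 1L]),
      stringsAsFactors = FALSE
    )
    truth <- ifelse(is_graft, "graft", "host")
    names(truth) <- pairs$read_id
    list(pairs = pairs, truth = truth)
  })
}
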