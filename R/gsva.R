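#' Single-sample gene-set enrichment (GSVA-style) scores
#'
#' Computes per-sample enrichment scores for a gene set with the published
#' gene-set variation analysis statistic. Per gene, expression is
#' transformed into a kernel-estimated cumulative density across the
#' samples of the cohort (Gaussian kernel with bandwidth sd/4; or the
#' empirical CDF for count-like data). Per sample, genes are ranked by that
#' statistic (decreasing) and re-weighted by the symmetric rank statistic
#' `|N/2 - rank|` raised to `tau`; a weighted random walk steps up at
#' set genes (by normalized weight) and down at non-set genes (by
#' `1/(N - n_set)`). The score is the maximum positive deviation plus the
#' maximum negative deviation of the walk (max-diff scoring).
#'
#' Scores are relative within a cohort: the kernel CDF is estimated across
#' the samples of the supplied matrix, so cohorts must be scored
#' individually and never on a merged matrix.
#'
#' @param expr Gene x sample expression matrix with rownames.
#' @param signature A `gene_signature` or a character vector of genes; at
#'   least 2 signature genes must be present in `expr`.
#' @param tau Rank-weight exponent (default 1).
#' @param kcdf `"gaussian"` (continuous data) or `"ecdf"` (counts).
#' @return A named numeric vector of class `score_vector` (one score per
#'   sample/column).
#' @export
gsva_scores <- function(expr, signature, tau = 1,
                        kcdf = c("gaussian", "ecdf")) {
  kcdf <- match.arg(kcdf)
  check_scalar(tau, "tau", nonneg = TRUE)
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3L) stop_spatsig("need >= 3 samples")
  present <- intersect(genes, rownames(expr))
  if (length(present) < 2L) {
    stop_spatsig("fewer than 2 signature genes present in the matrix; missing: ",
                 paste(setdiff(genes, rownames(expr)), collapse = ", "))
  }

  z <- kcdf_matrix(expr, kcdf)
  N <- nrow(expr)
  in_set <- rownames(expr) %in% present
  n_set <- sum(in_set)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(z[, j], decreasing = TRUE)
    r <- abs(N / 2 - seq_len(N))  # symmetric rank weight along the ordering
    set_ord <- in_set[ord]
    w <- r^tau
    up <- ifelse(set_ord, w, 0)
    up <- up / sum(w[set_ord])
    down <- ifelse(set_ord, 0, 1 / (N - n_set))
    v <- cumsum(up - down)
    max(c(0, v)) + min(c(0, v))
  }, numeric(1L))
  names(scores) <- colnames(expr)
  class(scores) <- "score_vector"
  scores
}

#' @export
print.score_vector <- function(x, ...) {
  cat("Enrichment scores for", length(x), "samples\n")
  print(summary(unclass(x)))
  invisible(x)
}

# Kernel CDF transform: per gene, the estimated cumulative density of each
# sample's value across the cohort.
kcdf_matrix <- function(expr, kcdf) {
  n <- ncol(expr)
  t(apply(expr, 1L, function(x) {
    if (kcdf == "gaussian") {
      h <- stats::sd(x) / 4
      if (!is.finite(h) || h == 0) {
        colMeans(outer(x, x, `<=`))
      } else {
        # z_j = mean_k Phi((x_j - x_k) / h)
        colMeans(stats::pnorm(outer(x, x, function(a, b) (b - a) / h)))
      }
    } else {
      colMeans(outer(x, x, `<=`))
    }
  }))
}

#' Preranked gene-set enrichment (GSEA) statistic
#'
#' Enrichment of a gene set toward either end of a score-ranked gene list.
#' The running sum increments by `|score|^p` (normalized over the set's
#' total) at set genes and decrements by `1/(N - n_set)` at others; the
#' enrichment score (ES) is the signed maximum deviation. The null
#' distribution is built by shuffling gene labels (drawing random sets of
#' the same size, seeded); NES is ES divided by the mean absolute null ES
#' of matching sign, and the p-value is the fraction of null ES at least as
#' extreme in absolute value.
#'
#' @param scores Named numeric vector: the ranking metric per gene (any
#'   order; sorted decreasingly internally). Names must be unique.
#' @param gene_set Character vector; must intersect the ranked genes.
#' @param p Weight exponent on `|score|` (default 1).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutation null.
#' @return An object of class `gsea_result`: `es`, `nes`, `p_value`,
#'   `n_permutations`, `n_set`, `n_genes`.
#' @export
preranked_gsea <- function(scores, gene_set, p = 1, n_perm = 1000L, seed = 1L) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (anyDuplicated(names(scores))) stop_spatsig("ranked genes must be unique")
  check_scalar(p, "p", nonneg = TRUE)
  hit <- names(scores) %in% gene_set
  if (!any(hit)) stop_spatsig("gene set is disjoint from the ranked list")

  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  hit_sorted <- hit[ord]
  es <- gsea_es(s_sorted, hit_sorted, p)

  n_set <- sum(hit_sorted)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      fake <- logical(length(s_sorted))
      fake[sample.int(length(s_sorted), n_set)] <- TRUE
      gsea_es(s_sorted, fake, p)
    }, numeric(1L))
  })
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign) > 0L) es / mean(abs(same_sign)) else NA_real_
  p_value <- mean(abs(null_es) >= abs(es))

  structure(
    list(es = es, nes = nes, p_value = p_value, n_permutations = n_perm,
         n_set = n_set, n_genes = length(s_sorted)),
    class = "gsea_result"
  )
}

# ES of a decreasingly sorted score vector with hit indicator.
gsea_es <- function(s_sorted, hit_sorted, p) {
  n <- length(s_sorted)
  n_set <- sum(hit_sorted)
  w <- abs(s_sorted)^p
  up <- ifelse(hit_sorted, w, 0)
  tot <- sum(up)
  up <- if (tot > 0) up / tot else up
  down <- if (n > n_set) ifelse(hit_sorted, 0, 1 / (n - n_set)) else rep(0, n)
  v <- cumsum(up - down)
  unname(v[which.max(abs(v))])
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("Preranked GSEA: ES = %.4f, NES = %.3f, p = %.4g (%d/%d set genes, %d permutations)\n",
              x$es, x$nes, x$p_value, x$n_set, x$n_genes, x$n_permutations))
  invisible(x)
}
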