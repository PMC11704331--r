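#' Derive a transcription-factor repression signature
#'
#' Implements the three-filter derivation of a repression signature: genes
#' that are (1) bound by the TF, (2) significantly up-regulated upon TF
#' silencing (`p_adj <= p_adj_max` and `log2fc >= log2fc_min`), and (3)
#' anti-correlated (negative Spearman rho) with the TF across a cell-line
#' expression panel. Genes passing all three filters form the signature;
#' provenance records every intermediate set size and the thresholds used.
#'
#' @param bound Character vector of TF-bound genes (e.g. from
#'   [annotate_peaks_to_genes()]).
#' @param de data.frame with `gene`, `log2fc`, `p_adj` (silencing vs
#'   control differential expression; positive `log2fc` = up on silencing).
#' @param panel Gene x cell-line expression matrix with gene rownames.
#' @param anchor Anchor (TF) gene name, present in `panel`.
#' @param p_adj_max,log2fc_min Upregulation thresholds.
#' @param name Signature name.
#' @return An object of class `gene_signature`: `name`, `genes` (sorted),
#'   `provenance` (thresholds and intermediate set sizes, plus per-gene
#'   Spearman rho of the candidates). An empty signature is returned, not
#'   an error, when no gene survives.
#' @export
derive_repression_signature <- function(bound, de, panel, anchor,
                                        p_adj_max = 0.05, log2fc_min = 0,
                                        name = "repression_signature") {
  stopifnot(is.data.frame(de), all(c("gene", "log2fc", "p_adj") %in% names(de)))
  if (anyDuplicated(de$gene)) stop_spatsig("genes in 'de' must be unique")
  if (any(de$p_adj < 0 | de$p_adj > 1, na.rm = TRUE)) {
    stop_spatsig("'p_adj' must lie in [0, 1]")
  }
  if (!anchor %in% rownames(panel)) {
    stop_spatsig("anchor gene '", anchor, "' not found in the panel")
  }
  if (ncol(panel) < 4L) stop_spatsig("panel needs >= 4 samples")

  up <- de$gene[!is.na(de$p_adj) & de$p_adj <= p_adj_max &
                  de$log2fc >= log2fc_min]
  candidates <- intersect(intersect(bound, up), rownames(panel))
  candidates <- setdiff(candidates, anchor)
  anchor_expr <- panel[anchor, ]
  rho <- vapply(candidates, function(g) {
    spearman_cor(panel[g, ], anchor_expr)$rho
  }, numeric(1L))
  keep <- !is.na(rho) & rho < 0
  genes <- sort(candidates[keep])

  structure(
    list(
      name = name, genes = genes,
      provenance = list(
        p_adj_max = p_adj_max, log2fc_min = log2fc_min,
        n_bound = length(unique(bound)), n_up = length(unique(up)),
        n_candidates = length(candidates),
        n_anticorrelated = length(genes),
        candidate_rho = stats::setNames(rho, candidates)
      )
    ),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$genes), " gene(s)\n", sep = "")
  p <- x$provenance
  cat(sprintf("  filters: bound %d -> up-regulated overlap (p_adj <= %g, log2FC >= %g) -> %d candidates -> %d anti-correlated\n",
              p$n_bound, p$p_adj_max, p$log2fc_min, p$n_candidates,
              p$n_anticorrelated))
  if (length(x$genes) > 0L) {
    cat("  ", paste(utils::head(x$genes, 10L), collapse = ", "),
        if (length(x$genes) > 10L) ", ...", "\n", sep = "")
  }
  invisible(x)
}
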