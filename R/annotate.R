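#' Annotate peaks to genes by the basal-plus-extension rule
#'
#' Assigns binding peaks to genes the way GREAT-style regulatory-domain
#' annotation does. Each gene gets a strand-aware basal domain around its
#' TSS (`basal_up` bp upstream, `basal_down` bp downstream), which is then
#' extended in both directions up to `extension` bp but never into another
#' gene's basal domain. A gene is "bound" iff at least one peak overlaps its
#' regulatory domain. All coordinates are 0-based half-open.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genes data.frame with `gene`, `chrom`, `tss`, `strand` (`+`/`-`).
#' @param basal_up,basal_down Basal domain, bp up/downstream of the TSS.
#' @param extension Maximum extension in bp on each side.
#' @return Character vector of bound gene identifiers.
#' @export
annotate_peaks_to_genes <- function(peaks, genes, basal_up = 5000,
                                    basal_down = 1000, extension = 1e6) {
  stopifnot(is.data.frame(genes), all(c("gene", "chrom", "tss", "strand") %in% names(genes)))
  stopifnot(is.data.frame(peaks), all(c("chrom", "start", "end") %in% names(peaks)))
  if (anyDuplicated(genes$gene)) stop_spatsig("gene identifiers must be unique")
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    stop_spatsig("unknown strand for gene(s): ",
                 paste(genes$gene[bad], collapse = ", "))
  }
  if (nrow(peaks) == 0L) return(character(0))

  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  basal_start <- pmax(basal_start, 0)

  ext_start <- numeric(nrow(genes))
  ext_end <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    same <- which(genes$chrom == genes$chrom[i])
    same <- same[same != i]
    # nearest basal boundary blocking extension on each side; a basal domain
    # already overlapping this gene's basal edge blocks extension entirely
    left_block <- 0
    right_block <- Inf
    if (length(same) > 0L) {
      ends <- basal_end[same]
      starts <- basal_start[same]
      le <- ends[ends <= basal_start[i]]
      if (length(le) > 0L) left_block <- max(le)
      if (any(starts < basal_start[i] & ends > basal_start[i])) {
        left_block <- basal_start[i]
      }
      rs <- starts[starts >= basal_end[i]]
      if (length(rs) > 0L) right_block <- min(rs)
      if (any(starts < basal_end[i] & ends > basal_end[i])) {
        right_block <- basal_end[i]
      }
    }
    ext_start[i] <- min(basal_start[i], max(basal_start[i] - extension, left_block, 0))
    ext_end[i] <- max(basal_end[i], min(basal_end[i] + extension, right_block))
  }

  # half-open [s, e) in 0-based coordinates == 1-based closed [s + 1, e]
  dom <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = ext_start + 1, end = ext_end)
  )
  pk <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end)
  )
  # disjoint chromosome sets are a legitimate zero-overlap case, not a problem
  hits <- suppressWarnings(GenomicRanges::findOverlaps(dom, pk))
  sort(unique(genes$gene[unique(S4Vectors::queryHits(hits))]))
}
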