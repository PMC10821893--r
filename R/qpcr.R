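# Cytosolic mtDNA enrichment from fraction-resolved qPCR Ct values:
# 2^-dCt levels against nuclear 18S, cytosolic/mitochondrial ratios per
# mtDNA-encoded gene, then group contrasts through the normality-gated
# test policy. Amplification efficiency is fixed at 2 (plain 2^-dCt
# with no efficiency correction); technical replicates are averaged on
# the Ct scale before transformation; undetermined Ct values are
# treated as missing, never imputed.

#' Normalized abundance from a Ct pair
#'
#' \eqn{2^{-(Ct_{gene} - Ct_{ref})}}: one cycle below the reference
#' doubles the level.
#'
#' @param ctGene Ct of the gene in the fraction of interest.
#' @param ctRef reference Ct (nuclear 18S).
#' @return scalar relative level.
#' @examples
#' normalizedLevel(25, 18)  # 2^-7
#' @export
normalizedLevel <- function(ctGene, ctRef) {
  if (!all(is.finite(ctGene)) || !all(is.finite(ctRef)))
    stop("Ct values must be finite")
  2^-(ctGene - ctRef)
}

.avg_ct <- function(records, frac, gene) {
  r <- records[records$fraction == frac & records$gene == gene, ]
  r <- r[is.finite(r$ct), ]
  if (!nrow(r)) return(NA_real_)
  mean(r$ct)
}

#' Cytosolic/mitochondrial ratio for one sample and gene
#'
#' Replicate Cts are averaged per fraction, both fractions are
#' normalized to the sample's nuclear 18S, and their ratio is returned.
#' The 18S term cancels algebraically
#' (\eqn{R = 2^{-(Ct_{cyto} - Ct_{mito})}}), but both normalized levels
#' are still reported.
#'
#' @param records data.frame rows of one sample (columns
#'   \code{fraction}, \code{gene}, \code{ct}).
#' @param gene mtDNA-encoded gene name.
#' @return list with \code{ratio}, \code{cyto_level},
#'   \code{mito_level}.
#' @export
cytoMitoRatio <- function(records, gene) {
  ct_c <- .avg_ct(records, "cytosolic", gene)
  ct_m <- .avg_ct(records, "mitochondrial", gene)
  ct_r <- .avg_ct(records, "nuclear", "18S")
  if (!is.finite(ct_c) || !is.finite(ct_m))
    stop("missing fraction for gene ", gene)
  if (!is.finite(ct_r))
    stop("missing nuclear 18S reference")
  cyto <- normalizedLevel(ct_c, ct_r)
  mito <- normalizedLevel(ct_m, ct_r)
  list(ratio = cyto / mito, cyto_level = cyto, mito_level = mito)
}

#' Cohort-level cytosolic mtDNA analysis
#'
#' Per (sample, gene) cytosolic/mitochondrial ratios, per (group, gene)
#' mean and s.e.m., per-gene old/young fold change of the group means,
#' and a per-gene group comparison through the normality-gated policy
#' (\code{\link{compareTwoGroups}}), which may take the parametric or
#' the rank-based route per gene.
#'
#' @param records data.frame with columns \code{sample_id},
#'   \code{group}, \code{fraction}, \code{gene}, \code{ct}.
#' @param groups length-2 character: reference group first (young),
#'   contrast group second (old).
#' @return list of class \code{RatioResult}: \code{perSample},
#'   \code{perGroup}, \code{perGene} data.frames.
#' @export
cohortAnalysis <- function(records, groups = c("young", "old")) {
  stopifnot(all(c("sample_id", "group", "fraction", "gene", "ct") %in%
                  names(records)))
  records <- records[records$group %in% groups, ]
  genes <- setdiff(unique(records$gene), "18S")
  samples <- unique(records[, c("sample_id", "group")])
  for (g in groups)
    if (sum(samples$group == g) < 2L)
      stop("group '", g, "' has fewer than 2 samples")
  per <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    rec <- records[records$sample_id == samples$sample_id[i], ]
    do.call(rbind, lapply(genes, function(gn) {
      r <- cytoMitoRatio(rec, gn)
      data.frame(sample_id = samples$sample_id[i],
                 group = samples$group[i], gene = gn,
                 cyto_level = r$cyto_level, mito_level = r$mito_level,
                 ratio = r$ratio)
    }))
  }))
  agg <- do.call(rbind, lapply(genes, function(gn) {
    do.call(rbind, lapply(groups, function(g) {
      v <- per$ratio[per$gene == gn & per$group == g]
      data.frame(gene = gn, group = g, n = length(v), mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)))
    }))
  }))
  gene_rows <- lapply(genes, function(gn) {
    young <- per$ratio[per$gene == gn & per$group == groups[1L]]
    old <- per$ratio[per$gene == gn & per$group == groups[2L]]
    st <- compareTwoGroups(young, old)
    data.frame(gene = gn, fold_change = mean(old) / mean(young),
               test = testName(st), p_value = pValue(st))
  })
  structure(list(perSample = per, perGroup = agg,
                 perGene = do.call(rbind, gene_rows)),
            class = "RatioResult")
}

#' @export
print.RatioResult <- function(x, ...) {
  cat("Cytosolic/mitochondrial mtDNA ratio analysis\n")
  print(x$perGroup, row.names = FALSE)
  cat("\nPer-gene fold change (contrast/reference):\n")
  print(x$perGene, row.names = FALSE)
  invisible(x)
}
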