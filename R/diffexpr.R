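#' Per-condition mean expression
#'
#' Averages replicate abundances per gene within each condition; these
#' per-condition means are the gene "representation" values used as edge
#' weights in the bipartite networks.
#'
#' @param m An [expression_matrix()] object.
#' @return Data frame with columns `gene_id`, `mean_wt`, `mean_ko`.
#' @export
condition_means <- function(m) {
  wt <- m$values[, m$condition == "WT", drop = FALSE]
  ko <- m$values[, m$condition == "KO", drop = FALSE]
  data.frame(gene_id = rownames(m$values),
             mean_wt = rowMeans(wt),
             mean_ko = rowMeans(ko),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample Student/Welch t-test
#'
#' Two-sided two-sample t-test. With `equal_variance = TRUE` the pooled
#' estimate is used (df = nx + ny - 2); otherwise the Welch-Satterthwaite
#' approximation. Degenerate inputs where both groups have (numerically)
#' zero variance are not an error: equal means give t = 0, p = 1 and
#' unequal means give infinite t, p = 0, both with `zero_variance = TRUE`.
#'
#' @param x,y Numeric replicate vectors, length >= 2, finite.
#' @param equal_variance Pooled-variance (classical Student) test if TRUE.
#' @return List with `t`, `p`, `df`, `zero_variance`.
#' @export
two_sample_t <- function(x, y, equal_variance = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  vx <- stats::var(x); vy <- stats::var(y)
  scale2 <- max(mean(x^2), mean(y^2), 1)
  if (vx + vy < 1e-24 * scale2) {
    df <- if (equal_variance) length(x) + length(y) - 2 else NA_real_
    if (abs(mean(x) - mean(y)) < sqrt(1e-24 * scale2))
      return(list(t = 0, p = 1, df = df, zero_variance = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = df,
                zero_variance = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = equal_variance,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), zero_variance = FALSE)
}

#' log2 fold change with zero floor
#'
#' Computes `log2(mean_ko / mean_wt)` on the KO/WT scale. When either mean
#' is zero a symmetric pseudo-value `floor` is added to both means so the
#' ratio stays finite; the floor is not applied otherwise.
#'
#' @param mean_ko,mean_wt Non-negative means.
#' @param floor Pseudo-value (expression units) used only when a mean is 0.
#' @return Numeric log2 fold change.
#' @export
log2_fold_change <- function(mean_ko, mean_wt, floor = 1.0) {
  stopifnot(floor > 0)
  z <- mean_ko == 0 | mean_wt == 0
  f <- ifelse(z, floor, 0)
  log2((mean_ko + f) / (mean_wt + f))
}

#' Per-gene differential expression table
#'
#' Runs the per-gene two-sample t-test between KO and WT replicates on the
#' abundances as given (optionally log2(x+1)-transformed first), computes
#' KO/WT log2 fold changes from condition means, and applies the
#' significance / selection rules: `significant` iff p < alpha and
#' `selected` iff additionally |log2fc| strictly exceeds `lfc_cut`.
#' No multiple-testing correction is applied by default; set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted p-values.
#'
#' @param m An [expression_matrix()] object.
#' @param alpha Significance level for the raw (or adjusted) p-value.
#' @param lfc_cut Strict absolute log2-fold-change cutoff.
#' @param equal_variance Passed to [two_sample_t()].
#' @param log_transform Apply log2(x+1) to abundances before testing.
#' @param floor Zero-handling floor for [log2_fold_change()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame of class `DEResult` with columns `gene_id`,
#'   `mean_wt`, `mean_ko`, `log2fc`, `t`, `p`, `significant`, `selected`,
#'   `direction`.
#' @export
de_table <- function(m, alpha = 0.05, lfc_cut = 2, equal_variance = TRUE,
                     log_transform = FALSE, floor = 1.0, adjust = "none") {
  vals <- if (log_transform) log2(m$values + 1) else m$values
  wt <- vals[, m$condition == "WT", drop = FALSE]
  ko <- vals[, m$condition == "KO", drop = FALSE]
  cm <- condition_means(m)
  tt <- lapply(seq_len(nrow(vals)), function(i)
    two_sample_t(ko[i, ], wt[i, ], equal_variance = equal_variance))
  p <- vapply(tt, `[[`, 0, "p")
  if (identical(adjust, "BH")) p <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    gene_id = cm$gene_id,
    mean_wt = cm$mean_wt,
    mean_ko = cm$mean_ko,
    log2fc = log2_fold_change(cm$mean_ko, cm$mean_wt, floor = floor),
    t = vapply(tt, `[[`, 0, "t"),
    p = p,
    row.names = NULL, stringsAsFactors = FALSE)
  res$significant <- res$p < alpha
  res$selected <- res$significant & abs(res$log2fc) > lfc_cut
  res$direction <- ifelse(res$log2fc > 0, "up",
                          ifelse(res$log2fc < 0, "down", "none"))
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Select differentially expressed genes
#'
#' Subsets a [de_table()] to genes with p < alpha and log2 fold change
#' strictly below `-lfc_cut` or strictly above `+lfc_cut`.
#'
#' @param results A `DEResult` data frame (needs `p` and `log2fc`).
#' @param alpha Significance level.
#' @param lfc_cut Strict absolute log2-fold-change cutoff.
#' @return The selected subset, with `direction` labelled by sign.
#' @export
select_de_genes <- function(results, alpha = 0.05, lfc_cut = 2) {
  keep <- results$p < alpha &
    (results$log2fc < -lfc_cut | results$log2fc > lfc_cut)
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' qPCR record
#'
#' Replicate threshold cycles for a target transcript and the reference
#' (housekeeping) transcript in one experimental group.
#'
#' @param ct_target,ct_reference Positive Ct vectors (one value per
#'   replicate).
#' @param group Group label (e.g. `"KO"`, `"WT"`).
#' @return List of class `QPCRRecord`.
#' @export
qpcr_record <- function(ct_target, ct_reference, group = "") {
  stopifnot(all(ct_target > 0), all(ct_reference > 0))
  structure(list(ct_target = ct_target, ct_reference = ct_reference,
                 group = group), class = "QPCRRecord")
}

#' ddCt relative fold change
#'
#' The delta-delta-Ct method: per group, dCt = mean(Ct_target) -
#' mean(Ct_reference); ddCt = dCt_test - dCt_control; fold = 2^(-ddCt).
#'
#' @param test,control [qpcr_record()] objects.
#' @return List with `ddct` and `fold`.
#' @export
ddct_fold_change <- function(test, control) {
  dct_t <- mean(test$ct_target) - mean(test$ct_reference)
  dct_c <- mean(control$ct_target) - mean(control$ct_reference)
  ddct <- dct_t - dct_c
  list(ddct = ddct, fold = 2^(-ddct))
}

#' Protein quantification table
#'
#' SWATH-style table of extracted-ion-chromatogram peak areas per protein
#' and sample, with the number of peptides available for quantitation.
#'
#' @param protein_id Character vector.
#' @param peptide_count Integer vector (>= 0), one per protein.
#' @param areas Numeric matrix proteins x samples, finite and >= 0.
#' @return List of class `ProteinQuantTable`.
#' @export
protein_quant_table <- function(protein_id, peptide_count, areas) {
  areas <- as.matrix(areas)
  stopifnot(length(protein_id) == nrow(areas),
            length(peptide_count) == nrow(areas),
            all(is.finite(areas)), all(areas >= 0),
            all(peptide_count >= 0))
  rownames(areas) <- protein_id
  structure(list(protein_id = as.character(protein_id),
                 peptide_count = as.integer(peptide_count),
                 areas = areas), class = "ProteinQuantTable")
}

#' Total Area Sums (TAS) global normalisation
#'
#' Rescales each sample so that its total area equals the mean of the
#' original per-sample totals. Relative abundances within a sample are
#' unchanged.
#'
#' @param t A [protein_quant_table()].
#' @return A normalised [protein_quant_table()].
#' @export
tas_normalize <- function(t) {
  totals <- colSums(t$areas)
  if (any(totals == 0))
    stop("sample(s) with zero total area: ",
         paste(colnames(t$areas)[totals == 0], collapse = ", "))
  target <- mean(totals)
  scaled <- sweep(t$areas, 2, target / totals, `*`)
  protein_quant_table(t$protein_id, t$peptide_count, scaled)
}

#' Filter proteins by peptide support
#'
#' Keeps proteins with at least `min_peptides` peptides available for
#' quantitation.
#'
#' @param t A [protein_quant_table()].
#' @param min_peptides Minimum peptide count (inclusive).
#' @return The filtered [protein_quant_table()].
#' @export
filter_by_peptide_count <- function(t, min_peptides = 3) {
  keep <- t$peptide_count >= min_peptides
  protein_quant_table(t$protein_id[keep], t$peptide_count[keep],
                      t$areas[keep, , drop = FALSE])
}
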