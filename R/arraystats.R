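#' Peptide array container
#'
#' Spot-level relative fluorescence (RFU) measurements from a peptide
#' array probed with one protein, including empty control spots used for
#' background normalisation.
#'
#' @param spots Data frame with columns `peptide_id`, `replicate`,
#'   `rfu` (>= 0 before normalisation; subtract-normalised arrays may
#'   carry the floor at 0) and `is_empty_control` (logical).
#' @param protein_label Name of the probed protein.
#' @return List of class `PeptideArray`.
#' @export
peptide_array <- function(spots, protein_label = "") {
  need <- c("peptide_id", "replicate", "rfu", "is_empty_control")
  stopifnot(all(need %in% names(spots)))
  if (!any(spots$is_empty_control))
    stop("array must contain at least one empty control spot")
  stopifnot(all(is.finite(spots$rfu)))
  structure(list(spots = spots[need], protein_label = protein_label,
                 normalized = FALSE),
            class = "PeptideArray")
}

#' Read a peptide array from TSV
#'
#' Columns: `peptide_id`, `replicate`, `rfu`, `is_empty` (0/1).
#'
#' @param path Input TSV.
#' @param protein_label Name of the probed protein.
#' @return A [peptide_array()].
#' @export
read_peptide_array <- function(path, protein_label = "") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  peptide_array(data.frame(peptide_id = as.character(df$peptide_id),
                           replicate = df$replicate,
                           rfu = as.numeric(df$rfu),
                           is_empty_control = df$is_empty != 0,
                           stringsAsFactors = FALSE),
                protein_label)
}

#' Normalize array fluorescence against empty control spots
#'
#' The background is the mean RFU over all empty control spots.
#' `subtract` mode removes it (floored at zero); `ratio` mode divides by
#' it (background must be positive).
#'
#' @param a A [peptide_array()].
#' @param mode `"subtract"` (default) or `"ratio"`.
#' @return The normalised [peptide_array()] (control spots retained,
#'   normalised like the rest).
#' @export
normalize_empty_spots <- function(a, mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  b <- mean(a$spots$rfu[a$spots$is_empty_control])
  if (mode == "ratio" && b <= 0)
    stop("ratio normalisation requires a positive empty-spot background")
  a$spots$rfu <- if (mode == "subtract") pmax(a$spots$rfu - b, 0)
                 else a$spots$rfu / b
  a$normalized <- TRUE
  a
}

#' Per-peptide comparison of two arrays
#'
#' Two-sided two-sample t-test per peptide between the test protein and a
#' negative-control protein. Peptides missing from either array are
#' skipped with a warning. With only two technical replicates per array,
#' zero-variance cases are common; they are flagged
#' (`zero_variance = TRUE`, p = 1 when means agree) rather than erroring.
#'
#' @param test,control Normalised [peptide_array()] objects.
#' @param alpha Significance level.
#' @param equal_variance Passed to [two_sample_t()].
#' @return Data frame with columns `peptide_id`, `mean_test`,
#'   `mean_control`, `t`, `p`, `significant`, `zero_variance`.
#' @export
compare_arrays <- function(test, control, alpha = 0.05,
                           equal_variance = TRUE) {
  ts <- test$spots[!test$spots$is_empty_control, ]
  cs <- control$spots[!control$spots$is_empty_control, ]
  shared <- intersect(unique(ts$peptide_id), unique(cs$peptide_id))
  skipped <- setdiff(union(unique(ts$peptide_id), unique(cs$peptide_id)),
                     shared)
  if (length(skipped))
    warning("peptide(s) missing from one array skipped: ",
            paste(skipped, collapse = ", "))
  rows <- lapply(shared, function(p) {
    x <- ts$rfu[ts$peptide_id == p]
    y <- cs$rfu[cs$peptide_id == p]
    ht <- two_sample_t(x, y, equal_variance = equal_variance)
    data.frame(peptide_id = p, mean_test = mean(x), mean_control = mean(y),
               t = ht$t, p = ht$p, significant = ht$p < alpha,
               zero_variance = ht$zero_variance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(peptide_id = character(), mean_test = numeric(),
                      mean_control = numeric(), t = numeric(), p = numeric(),
                      significant = logical(), zero_variance = logical())
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA across k groups of replicate
#' values: F = MSB/MSW with df (k - 1, N - k). Delegates to the standard
#' linear-model fit.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0)
    return(list(F = 0, p = 1, df_between = length(groups) - 1L,
                df_within = length(y) - length(groups)))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value,
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]))
}
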