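#' Union of processes annotated to any interacting protein
#'
#' @param ip_ann An [ip_annotation_table()].
#' @return Character vector of distinct term ids.
#' @export
collect_ip_bps <- function(ip_ann) {
  unique(ip_ann$term_id)
}

#' Process coverage by interacting proteins
#'
#' For every distinct biological process among the (DE-restricted)
#' gene annotations, records which interacting proteins also map to it
#' and how many genes it carries. Processes covered by no interacting
#' protein are flagged `akirin2_only`: candidate processes regulated by
#' the cofactor through unknown partners or direct chromatin contacts.
#'
#' @param de_ann An [annotation_table()] restricted to the selected
#'   (differentially expressed) genes.
#' @param ip_ann An [ip_annotation_table()], or a precomputed character
#'   vector of covered term ids.
#' @param by `"term_id"` (default) or `"term_name"` (case-folded) for
#'   matching processes between the two tables.
#' @return Data frame of class `BPCoverage` with columns `bp_id`,
#'   `bp_name`, `covering_ips`, `n_covering_ips`, `gene_count`,
#'   `akirin2_only`, ordered by decreasing gene count.
#' @export
akirin2_only_bps <- function(de_ann, ip_ann, by = c("term_id", "term_name")) {
  by <- match.arg(by)
  stopifnot(nrow(de_ann) > 0)
  key_de <- if (by == "term_id") de_ann$term_id else tolower(de_ann$term_name)
  if (is.character(ip_ann) && !is.data.frame(ip_ann)) {
    covered <- unique(if (by == "term_id") ip_ann else tolower(ip_ann))
    ip_by_key <- stats::setNames(rep(list(character()), length(covered)),
                                 covered)
  } else {
    ip_key_all <- if (by == "term_id") ip_ann$term_id else
      tolower(ip_ann$term_name)
    ip_by_key <- lapply(split(ip_ann$ip_id, ip_key_all), unique)
    covered <- names(ip_by_key)
  }
  bps <- unique(key_de)
  genes_by_bp <- split(de_ann$gene_id, key_de)
  name_by_bp <- tapply(de_ann$term_name, key_de, function(x) x[1])
  cov <- lapply(bps, function(b)
    if (b %in% names(ip_by_key)) ip_by_key[[b]] else character())
  out <- data.frame(
    bp_id = if (by == "term_id") bps else NA_character_,
    bp_name = if (by == "term_id") as.character(name_by_bp[bps]) else bps,
    covering_ips = vapply(cov, paste, "", collapse = ","),
    n_covering_ips = vapply(cov, length, 0L),
    gene_count = vapply(bps, function(b) length(unique(genes_by_bp[[b]])), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  out$akirin2_only <- !(bps %in% covered)
  out <- out[order(-out$gene_count, out$bp_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("BPCoverage", "data.frame")
  out
}

#' Gene membership partition across a set of processes
#'
#' For an ordered set of k biological processes, computes per-gene
#' membership bit-vectors over the set and summarises how the annotated
#' genes distribute: how many are unique to each single process, how many
#' belong to all k, and the total (the union).
#'
#' @param de_ann An [annotation_table()] (typically restricted to
#'   DE-selected genes).
#' @param bp_set Character vector of term ids (ordered, length k >= 1).
#' @return List of class `MembershipPartition` with `bp_set`,
#'   `membership` (logical gene x k matrix), `unique_counts` (named, one
#'   per process), `in_all`, and `total`.
#' @export
membership_partition <- function(de_ann, bp_set) {
  stopifnot(length(bp_set) >= 1)
  ann <- de_ann[de_ann$term_id %in% bp_set, , drop = FALSE]
  genes <- unique(ann$gene_id)
  memb <- matrix(FALSE, length(genes), length(bp_set),
                 dimnames = list(genes, bp_set))
  if (nrow(ann))
    memb[cbind(match(ann$gene_id, genes), match(ann$term_id, bp_set))] <- TRUE
  sizes <- rowSums(memb)
  unique_counts <- vapply(seq_along(bp_set), function(j)
    sum(memb[, j] & sizes == 1L), 0L)
  names(unique_counts) <- bp_set
  structure(list(bp_set = bp_set,
                 membership = memb,
                 unique_counts = unique_counts,
                 in_all = sum(sizes == length(bp_set)),
                 total = length(genes)),
            class = "MembershipPartition")
}

#' @export
print.MembershipPartition <- function(x, ...) {
  cat(sprintf("MembershipPartition over %d processes: %d genes total, %d in all\n",
              length(x$bp_set), x$total, x$in_all))
  for (b in x$bp_set)
    cat(sprintf("  unique to %s: %d\n", b, x$unique_counts[[b]]))
  invisible(x)
}
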