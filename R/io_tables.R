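#' Construct an expression matrix object
#'
#' Container for a genes x samples abundance matrix with a WT/KO condition
#' label per sample. Values are normalized abundances (e.g. averaged read
#' counts), not raw sequencer output.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values finite and >= 0.
#' @param condition Named character vector mapping every sample id to
#'   `"WT"` or `"KO"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `condition`.
#' @export
expression_matrix <- function(values, condition) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")
  missing <- setdiff(colnames(values), names(condition))
  if (length(missing))
    stop("sample(s) without condition label: ", paste(missing, collapse = ", "))
  condition <- condition[colnames(values)]
  bad <- !condition %in% c("WT", "KO")
  if (any(bad))
    stop("condition labels must be 'WT' or 'KO'; offending sample(s): ",
         paste(colnames(values)[bad], collapse = ", "))
  if (!all(c("WT", "KO") %in% condition))
    stop("need at least one replicate per condition (WT and KO)")
  structure(list(values = values, condition = condition),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (WT: %d, KO: %d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "WT"), sum(x$condition == "KO")))
  invisible(x)
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row starting with `gene_id` followed by one column per
#' sample. Every sample column must be present in `condition_map`.
#'
#' @param path Path to a delimited text file.
#' @param condition_map Named character vector sample id -> `"WT"`/`"KO"`.
#' @param sep Field separator; tab by default, use `","` for CSV.
#' @return An [expression_matrix()] object; row order is preserved.
#' @export
read_expression <- function(path, condition_map, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (colnames(raw)[1] != "gene_id")
    stop("first column must be 'gene_id', got '", colnames(raw)[1], "'")
  gene_ids <- raw[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  samples <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (gene %s), column '%s'",
                   raw[[j + 1]][bad[1]], bad[1], gene_ids[bad[1]], samples[j]))
    vals[, j] <- v
  }
  missing <- setdiff(samples, names(condition_map))
  if (length(missing))
    stop("sample(s) absent from condition map: ",
         paste(missing, collapse = ", "))
  expression_matrix(vals, condition_map)
}

#' Write an expression matrix to TSV
#'
#' @param m An [expression_matrix()] object.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene -> biological-process annotation table
#'
#' @param gene_id,term_id,term_name Character vectors of equal length.
#'   `(gene_id, term_id)` pairs are deduplicated.
#' @return Data frame of class `AnnotationTable` with columns `gene_id`,
#'   `term_id`, `term_name`.
#' @export
annotation_table <- function(gene_id, term_id, term_name = NA_character_) {
  if (length(term_name) == 1 && length(gene_id) != 1)
    term_name <- rep(term_name, length(gene_id))
  df <- data.frame(gene_id = as.character(gene_id),
                   term_id = as.character(term_id),
                   term_name = as.character(term_name),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("gene_id", "term_id")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("AnnotationTable", "data.frame")
  df
}

#' Read gene -> GO:BP annotations
#'
#' Two formats: `"tsv"` is a 3-column table (gene, term, name; header
#' optional, detected from the first line), `"gaf"` is GAF 2.1 from which
#' only biological-process rows (aspect `P`) are retained; comment lines
#' starting with `!` are skipped and the DB object symbol (column 3) is
#' used as the gene id.
#'
#' @param path Input file.
#' @param fmt `"tsv"` or `"gaf"`.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, fmt = c("tsv", "gaf")) {
  fmt <- match.arg(fmt)
  if (fmt == "tsv") {
    first <- strsplit(readLines(path, n = 1), "\t")[[1]]
    has_header <- identical(tolower(first[1]), "gene_id")
    df <- utils::read.table(path, header = has_header, sep = "\t",
                            colClasses = "character", quote = "",
                            comment.char = "", fill = TRUE)
    if (ncol(df) < 2) stop("annotation TSV needs >= 2 columns")
    if (ncol(df) == 2) df$term_name <- NA_character_
    return(annotation_table(df[[1]], df[[2]], df[[3]]))
  }
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(annotation_table(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 15)
  if (length(bad))
    stop(sprintf("malformed GAF record at line %d: %d columns (>= 15 required)",
                 lineno[bad[1]], nf[bad[1]]))
  gene <- vapply(fields, `[[`, "", 3)
  term <- vapply(fields, `[[`, "", 5)
  aspect <- vapply(fields, `[[`, "", 9)
  p <- aspect == "P"
  ok <- grepl("^GO:[0-9]{7}$", term[p])
  if (!all(ok))
    stop("malformed GO id in GAF: ", term[p][!ok][1])
  annotation_table(gene[p], term[p])
}

#' Construct an interacting-protein annotation table
#'
#' Same shape as [annotation_table()] but keyed by interacting-protein id.
#'
#' @param ip_id,term_id,term_name Character vectors of equal length.
#' @return Data frame of class `IPAnnotationTable`.
#' @export
ip_annotation_table <- function(ip_id, term_id, term_name = NA_character_) {
  if (length(term_name) == 1 && length(ip_id) != 1)
    term_name <- rep(term_name, length(ip_id))
  df <- data.frame(ip_id = as.character(ip_id),
                   term_id = as.character(term_id),
                   term_name = as.character(term_name),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("ip_id", "term_id")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("IPAnnotationTable", "data.frame")
  df
}

#' Read interacting-protein annotations from a 3-column TSV
#'
#' @param path Input file (ip, term, name; header optional).
#' @return An [ip_annotation_table()].
#' @export
read_ip_annotations <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- identical(tolower(first[1]), "ip_id")
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", fill = TRUE)
  if (ncol(df) == 2) df$term_name <- NA_character_
  ip_annotation_table(df[[1]], df[[2]], df[[3]])
}

#' Compute ontology levels from an OBO file
#'
#' Parses OBO 1.2 `[Term]` stanzas, keeps non-obsolete terms in the given
#' namespace, and assigns each term a level: the root (a term with no
#' `is_a` parent inside the namespace) has level 1 and every other term
#' gets 1 + the minimum level over its `is_a` parents (i.e. shortest
#' `is_a` path from the root, counting the root as level 1). Terms not
#' reachable from a root are absent from the result.
#'
#' @param path OBO file.
#' @param namespace Ontology namespace, e.g. `"biological_process"`.
#' @return Named integer vector term id -> level.
#' @export
obo_term_levels <- function(path, namespace = "biological_process") {
  lines <- readLines(path)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(), obsolete = FALSE, ns = NA_character_)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {        # other stanza type
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
      else if (startsWith(ln, "namespace: "))
        cur$ns <- sub("^namespace: ", "", ln)
      else if (startsWith(ln, "is_a: "))
        cur$parents <- c(cur$parents,
                         sub("\\s*!.*$", "", sub("^is_a: ", "", ln)))
      else if (startsWith(ln, "is_obsolete: true")) cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  keep <- vapply(terms, function(t)
    !t$obsolete && identical(t$ns, namespace), logical(1))
  terms <- terms[keep]
  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(t$parents, ids))

  # cycle check on the retained is_a graph (Kahn's algorithm)
  indeg <- lengths(parents)
  children <- split(rep(ids, lengths(parents)), unlist(parents))
  queue <- ids[indeg == 0]
  seen <- 0L
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg2[[ch]] <- indeg2[[ch]] - 1L
      if (indeg2[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids))
    stop("cyclic is_a relationship among retained terms: ",
         paste(ids[indeg2 > 0], collapse = ", "))

  # BFS levels from the root(s)
  level <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  frontier <- ids[indeg == 0]
  level[frontier] <- 1L
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) {
      for (ch in children[[v]]) {
        cand <- level[[v]] + 1L
        if (is.na(level[[ch]]) || cand < level[[ch]]) {
          level[[ch]] <- cand
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- unique(nxt)
  }
  level[!is.na(level)]
}

#' Export a bipartite network as GraphML
#'
#' Writes a directed graph with node attribute `part` (`"gene"`/`"bp"`)
#' and edge attribute `weight`.
#'
#' @param net A [bipartite_net()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net, directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a bipartite network from GraphML
#'
#' Inverse of [write_graphml()]; expects the `part` node attribute.
#'
#' @param path GraphML file.
#' @param condition Condition label to attach (`"WT"`/`"KO"`).
#' @return A [bipartite_net()] object.
#' @export
read_graphml <- function(path, condition = "WT") {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  if (igraph::ecount(g) == 0)
    return(bipartite_net(condition, character(), character(), numeric()))
  bipartite_net(condition, el[, 1], el[, 2], w)
}

#' Write a centrality-change report to TSV
#'
#' One row per gene: WT/KO centralities, relative importances, rate of
#' change (sentinels printed as `inf` / `-100`) and the label.
#'
#' @param report Data frame from [centrality_rate_of_change()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- report
  if ("rate_of_change" %in% names(out)) {
    r <- out$rate_of_change
    out$rate_of_change <- ifelse(is.infinite(r) & r > 0, "inf",
                                 format(r, trim = TRUE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
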