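# Run expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic study configuration
#'
#' Parameters of the simulated knockdown experiment. Defaults emulate
#' the study design the pipeline is built for: 2 conditions x 3
#' biological replicates, log-normally distributed baseline abundances
#' with ~10% replicate variation, a planted differentially expressed
#' fraction at |log2 fold change| 3, six planted functional complements
#' (8-fold KO gain, 5 co-annotated process memberships), and an
#' interacting-protein table that covers all processes except a
#' designated few.
#'
#' @param n_genes,n_bps Numbers of genes and biological processes.
#' @param replicates Replicates per condition.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline abundance
#'   parameters (natural-log scale).
#' @param cv Replicate coefficient of variation.
#' @param de_fraction Fraction of genes given a planted fold change.
#' @param de_log2fc Planted |log2 fold change| (random sign).
#' @param induced_baseline_quantile Planted up-regulated genes draw
#'   their WT baseline from below this quantile: strong induction starts
#'   from low expression, so an induced gene ends near the typical
#'   abundance rather than becoming an implausible giant.
#' @param n_complements Number of planted functional complements.
#' @param complement_fold KO/WT fold gain of planted complements.
#' @param complement_baseline_quantile Planted complements draw their WT
#'   baseline from the bottom of the abundance distribution (quantile in
#'   (0, 1]): they emulate near-silent genes de-repressed by the
#'   knockdown, which is what lets their network importance rise.
#' @param complement_memberships Process memberships per complement,
#'   drawn from a shared pool so complements reinforce each other as
#'   co-annotated immune-effector genes do.
#' @param max_memberships Background genes carry 1..`max_memberships`
#'   memberships.
#' @param n_ips Number of interacting proteins.
#' @param k_uncovered Processes left uncovered by every interacting
#'   protein (the "cofactor-only" processes).
#' @param seed Mandatory integer seed; every generator draw flows from it.
#' @return List of class `SynthConfig`.
#' @export
synth_config <- function(n_genes = 200, n_bps = 20, replicates = 3,
                         baseline_meanlog = 5, baseline_sdlog = 1,
                         cv = 0.10, de_fraction = 0.10, de_log2fc = 3,
                         induced_baseline_quantile = 0.5,
                         n_complements = 6, complement_fold = 32,
                         complement_baseline_quantile = 0.15,
                         complement_memberships = 5, max_memberships = 4,
                         n_ips = 10, k_uncovered = 4, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(de_fraction >= 0, de_fraction <= 1, k_uncovered <= n_bps,
            replicates >= 1, n_complements + de_fraction * n_genes <= n_genes,
            complement_memberships <= n_bps)
  structure(as.list(environment()), class = "SynthConfig")
}

#' Generate a synthetic expression matrix with planted truth
#'
#' WT replicate abundances are log-normal around per-gene baselines with
#' the configured replicate CV. Planted differentially expressed genes
#' have their KO mean shifted by `2^(+/- de_log2fc)`; planted complements
#' gain `complement_fold` in KO. Genes planted as up-regulated (DE genes
#' with positive sign, and all complements) start from low WT baselines
#' (below `induced_baseline_quantile`, respectively
#' `complement_baseline_quantile`): strong induction from a silent state
#' is what lets a complement's network importance rise. Deterministic
#' given the config seed.
#'
#' @param c A [synth_config()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (planted gene sets and signs).
#' @export
gen_expression <- function(c) {
  with_seed(c$seed, {
    genes <- sprintf("G%04d", seq_len(c$n_genes))
    baseline <- stats::rlnorm(c$n_genes, c$baseline_meanlog, c$baseline_sdlog)
    idx <- sample(c$n_genes)
    complements <- genes[idx[seq_len(c$n_complements)]]
    # complements emulate near-silent WT genes de-repressed by the KO
    baseline[idx[seq_len(c$n_complements)]] <- stats::qlnorm(
      stats::runif(c$n_complements, 0, c$complement_baseline_quantile),
      c$baseline_meanlog, c$baseline_sdlog)
    n_de <- round(c$de_fraction * c$n_genes)
    de_idx <- idx[c$n_complements + seq_len(n_de)]
    de_genes <- genes[de_idx]
    de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
    up_idx <- de_idx[de_sign > 0]
    baseline[up_idx] <- stats::qlnorm(
      stats::runif(length(up_idx), 0, c$induced_baseline_quantile),
      c$baseline_meanlog, c$baseline_sdlog)
    mu_wt <- stats::setNames(baseline, genes)
    mu_ko <- mu_wt
    mu_ko[de_genes] <- mu_ko[de_genes] * 2^(de_sign * c$de_log2fc)
    mu_ko[complements] <- mu_ko[complements] * c$complement_fold
    sdlog_rep <- sqrt(log(1 + c$cv^2))
    samples <- c(paste0("WT", seq_len(c$replicates)),
                 paste0("KO", seq_len(c$replicates)))
    cond <- stats::setNames(rep(c("WT", "KO"), each = c$replicates), samples)
    vals <- sapply(samples, function(s) {
      mu <- if (cond[[s]] == "WT") mu_wt else mu_ko
      mu * stats::rlnorm(c$n_genes, -sdlog_rep^2 / 2, sdlog_rep)
    })
    rownames(vals) <- genes
    list(matrix = expression_matrix(vals, cond),
         truth = list(complements = complements, de_genes = de_genes,
                      de_sign = stats::setNames(de_sign, de_genes),
                      mu_wt = mu_wt, mu_ko = mu_ko))
  })
}

#' Generate synthetic gene and interacting-protein annotations
#'
#' Background genes receive 1..`max_memberships` random process
#' memberships; planted complements receive `complement_memberships`
#' memberships drawn from a shared pool (one process larger than the
#' membership count). Interacting proteins jointly cover every process
#' except `k_uncovered` designated ones, which never overlap the
#' complement pool.
#'
#' @param c A [synth_config()].
#' @param truth Optional `truth` list from [gen_expression()] (same
#'   config) so complements get their designated memberships; without it
#'   the first `n_complements` genes are treated as complements.
#' @return List with `ann` ([annotation_table()]), `ip_ann`
#'   ([ip_annotation_table()]) and `truth` (uncovered process ids,
#'   complement pool).
#' @export
gen_annotations <- function(c, truth = NULL) {
  with_seed(c$seed + 1L, {
    genes <- sprintf("G%04d", seq_len(c$n_genes))
    bps <- sprintf("GO:%07d", seq_len(c$n_bps))
    bp_names <- sprintf("process %d", seq_len(c$n_bps))
    complements <- if (!is.null(truth)) truth$complements
                   else genes[seq_len(c$n_complements)]
    bp_order <- sample(c$n_bps)
    uncovered <- bps[bp_order[seq_len(c$k_uncovered)]]
    pool <- bps[bp_order[c$k_uncovered +
                         seq_len(min(c$complement_memberships + 1,
                                     c$n_bps - c$k_uncovered))]]
    rec_g <- character(); rec_t <- character()
    for (g in genes) {
      terms <- if (g %in% complements)
        sample(pool, c$complement_memberships)
      else
        sample(bps, sample.int(c$max_memberships, 1))
      rec_g <- c(rec_g, rep(g, length(terms)))
      rec_t <- c(rec_t, terms)
    }
    ann <- annotation_table(rec_g, rec_t,
                            bp_names[match(rec_t, bps)])
    ips <- sprintf("IP%02d", seq_len(c$n_ips))
    covered <- setdiff(bps, uncovered)
    ip_g <- character(); ip_t <- character()
    for (b in covered) {                  # >=1 interacting protein per process
      who <- sample(ips, sample.int(min(3, c$n_ips), 1))
      ip_g <- c(ip_g, who)
      ip_t <- c(ip_t, rep(b, length(who)))
    }
    ip_ann <- ip_annotation_table(ip_g, ip_t, bp_names[match(ip_t, bps)])
    list(ann = ann, ip_ann = ip_ann,
         truth = list(uncovered_bps = uncovered, complement_pool = pool))
  })
}

#' Generate a synthetic peptide-array pair
#'
#' A negative-control array (background binding only) and a test array
#' in which designated binder peptides gain `effect` RFU. Both arrays
#' carry empty control spots at a lower background so subtract
#' normalisation is exercised.
#'
#' @param binders Character vector of binder peptide ids (subset of the
#'   generated peptides).
#' @param effect RFU gain of binders on the test array (> 0, or 0 for a
#'   null array pair).
#' @param noise_sd Gaussian spot noise (RFU).
#' @param seed Integer seed.
#' @param n_peptides Total peptides on the array.
#' @param replicates Technical replicates per peptide.
#' @param n_empty Empty control spots per array.
#' @param spot_level Mean RFU of a non-binder spot.
#' @param empty_level Mean RFU of an empty control spot.
#' @return List with `test` and `control` [peptide_array()] objects and
#'   `peptides`, the full peptide id vector.
#' @export
gen_array <- function(binders, effect, noise_sd, seed, n_peptides = 20,
                      replicates = 2, n_empty = 8, spot_level = 200,
                      empty_level = 100) {
  stopifnot(effect >= 0)
  with_seed(seed, {
    peptides <- sprintf("P%02d", seq_len(n_peptides))
    stopifnot(all(binders %in% peptides))
    one_array <- function(label, add_effect) {
      mu <- rep(spot_level, n_peptides)
      if (add_effect) mu[peptides %in% binders] <- mu[peptides %in% binders] + effect
      spots <- data.frame(
        peptide_id = rep(peptides, each = replicates),
        replicate = rep(seq_len(replicates), n_peptides),
        rfu = pmax(rep(mu, each = replicates) +
                     stats::rnorm(n_peptides * replicates, 0, noise_sd), 0),
        is_empty_control = FALSE, stringsAsFactors = FALSE)
      empties <- data.frame(
        peptide_id = "EMPTY", replicate = seq_len(n_empty),
        rfu = pmax(empty_level + stats::rnorm(n_empty, 0, noise_sd), 0),
        is_empty_control = TRUE, stringsAsFactors = FALSE)
      peptide_array(rbind(spots, empties), label)
    }
    list(test = one_array("test", TRUE),
         control = one_array("control", FALSE),
         peptides = peptides)
  })
}

#' Generate noisy single-site ITC injection heats
#'
#' [simulate_isotherm()] output plus seeded Gaussian noise. The signal
#' depends only on the parameters and protocol; the noise only on the
#' seed.
#'
#' @param Ka Association constant (1/M).
#' @param dH Enthalpy (kcal/mol).
#' @param n Stoichiometry.
#' @param p An [itc_protocol()].
#' @param noise_sd Gaussian noise on each injection heat (ucal).
#' @param seed Integer seed.
#' @return Numeric vector of noisy heats (ucal).
#' @export
gen_itc <- function(Ka, dH, n, p, noise_sd, seed) {
  q <- simulate_isotherm(Ka, dH, n, p)
  with_seed(seed, q + stats::rnorm(length(q), 0, noise_sd))
}

#' Write a complete synthetic study to disk
#'
#' Emits the expression matrix, condition map, gene and
#' interacting-protein annotations and the planted ground truth to
#' `out_dir` in the formats the pipeline reads.
#'
#' @param c A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file manifest and the truth.
#' @export
simulate_study <- function(c, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ex <- gen_expression(c)
  an <- gen_annotations(c, ex$truth)
  paths <- list(
    expr = file.path(out_dir, "expr.tsv"),
    conditions = file.path(out_dir, "conditions.yaml"),
    ann = file.path(out_dir, "ann.tsv"),
    ip_ann = file.path(out_dir, "ip_ann.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_expression(ex$matrix, paths$expr)
  yaml::write_yaml(as.list(ex$matrix$condition), paths$conditions)
  utils::write.table(an$ann, paths$ann, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(an$ip_ann, paths$ip_ann, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- c(ex$truth[c("complements", "de_genes", "de_sign")], an$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth))
}
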