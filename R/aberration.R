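## Single-sample rank-walk AUC scoring with permutation-based empirical
## confidence. This is the analytical core of the package.
##
## For one sample, all measured genes are ranked from most up- to most
## downregulated. Walking down that list, each gene is labelled 1 if it
## belongs to the pathway and 0 otherwise; plotting the fraction of 1's
## against the fraction of 0's encountered so far traces an ROC-style step
## curve whose area (AUC) measures how near the top the pathway's members
## sit. The AUC is a rescaled Mann-Whitney concordance: with member ranks
## r_1 < ... < r_m among n genes,
##   AUC = (m*n - sum(r) - m*(m-1)/2) / (m * (n - m)),
## the fraction of member/non-member pairs in which the member outranks the
## non-member. Depletion is the same walk started from the bottom of the
## list; with a strict total order AUC_dep = 1 - AUC_enr.
##
## Significance is empirical: the gene list is permuted B times (realized
## as drawing uniform m-subsets of positions, which is equivalent and
## cheaper), and the one-sided add-one estimator
##   p = (1 + #{AUC_b >= AUC_obs}) / (B + 1)
## gives confidence scores in [1/(B+1), 1] for enrichment and depletion
## separately. The two are combined into one signed value: log2 of the
## smaller score, negated when depletion dominates, so enriched pathways go
## negative and depleted pathways positive. No multiple-testing correction
## is applied anywhere in scoring — deliberately exploratory.

auc_from_ranks <- function(member_ranks, n) {
  m <- length(member_ranks)
  (m * n - sum(member_ranks) - m * (m - 1) / 2) / (m * (n - m))
}

#' Rank a sample's genes from most up- to most downregulated
#'
#' Descending by log ratio; exact ties broken by ascending gene symbol so
#' the order is total and deterministic. Genes with missing values are
#' excluded from the list.
#'
#' @param sample_values named numeric vector, gene symbol -> log ratio.
#' @return character vector of gene symbols, rank 1 = most upregulated.
#' @export
rank_genes <- function(sample_values) {
  v <- sample_values[!is.na(sample_values)]
  if (length(v) < 2) stop_ps("need >= 2 genes with non-missing values")
  if (is.null(names(v)) || anyDuplicated(names(v)))
    stop_ps("sample values must be uniquely named by gene symbol")
  names(v)[order(-v, names(v), method = "radix")]
}

#' Rank-walk enrichment AUC of a gene set in a ranked list
#'
#' @param ranked character vector from [rank_genes()] (rank 1 = top).
#' @param members character vector of pathway gene symbols.
#' @return list with `auc` in `[0, 1]` and `m`, the effective set size
#'   (members present in the ranked list). `auc = 1` iff all members precede
#'   all non-members.
#' @examples
#' enrichment_auc(c("A", "B", "C", "D", "E", "F"), c("A", "C"))$auc  # 0.875
#' @export
enrichment_auc <- function(ranked, members) {
  pos <- which(ranked %in% members)
  n <- length(ranked); m <- length(pos)
  if (m == 0 || m == n)
    stop_ps("AUC undefined: effective set size must satisfy 1 <= m < n (m = ",
            m, ", n = ", n, ")")
  list(auc = auc_from_ranks(pos, n), m = m)
}

#' Rank-walk depletion AUC (walk from the most downregulated gene)
#'
#' Equals [enrichment_auc()] on the reversed list; under the strict total
#' order produced by [rank_genes()] this is exactly `1 - enrichment AUC`.
#'
#' @inheritParams enrichment_auc
#' @return list with `auc` and `m` as in [enrichment_auc()].
#' @export
depletion_auc <- function(ranked, members) {
  enrichment_auc(rev(ranked), members)
}

#' Permutation-based empirical confidence for an observed AUC
#'
#' Draws `B` uniform m-subsets of the n list positions (equivalent to
#' permuting the gene list), recomputes the AUC for each, and returns the
#' one-sided add-one tail estimate
#' `p = (1 + #(AUC_b >= auc_obs)) / (B + 1)`, in `[1/(B+1), 1]`.
#' Deterministic given `seed`.
#'
#' @param auc_obs observed AUC.
#' @param n ranked-list length.
#' @param m effective set size (1 <= m < n).
#' @param B number of permutations (default 1000).
#' @param seed integer seed for the null draws.
#' @return the empirical confidence score (numeric scalar).
#' @export
permutation_pvalue <- function(auc_obs, n, m, B = 1000L, seed = 1L) {
  stopifnot(m >= 1, m < n, B >= 1)
  null_auc <- with_seed(seed, null_auc_draws(n, m, B))
  (1 + sum(null_auc >= auc_obs - 1e-12)) / (B + 1)
}

## B null AUC draws for (n, m); caller controls the RNG state
null_auc_draws <- function(n, m, B) {
  sums <- vapply(seq_len(B), function(b) sum(sample.int(n, m)), numeric(1))
  (m * n - sums - m * (m - 1) / 2) / (m * (n - m))
}

#' Exact permutation null tail probability by subset enumeration
#'
#' Enumerates all `choose(n, m)` member-position subsets and returns
#' `P(AUC >= auc_obs)` under the uniform null — the ground truth the
#' Monte-Carlo estimate of [permutation_pvalue()] converges to. Guarded to
#' at most 1e6 subsets.
#'
#' @inheritParams permutation_pvalue
#' @return exact tail probability.
#' @export
exact_null_pvalue <- function(auc_obs, n, m) {
  stopifnot(m >= 1, m < n)
  if (choose(n, m) > 1e6)
    stop_ps("choose(n, m) exceeds 1e6: use permutation_pvalue()")
  subsets <- utils::combn(n, m)
  aucs <- (m * n - colSums(matrix(subsets, nrow = m)) - m * (m - 1) / 2) /
    (m * (n - m))
  mean(aucs >= auc_obs - 1e-12)
}

## full exact null support for (n, m): sorted unique attainable AUC values
exact_null_support <- function(n, m) {
  subsets <- utils::combn(n, m)
  sort(unique((m * n - colSums(matrix(subsets, nrow = m)) -
                 m * (m - 1) / 2) / (m * (n - m))))
}

#' Combine enrichment and depletion confidence scores into one signed value
#'
#' Takes the smaller of the two scores and maps it to log2 space for
#' enrichment, -log2 space for depletion: enriched pathways get negative
#' values, depleted positive, and ties resolve toward enrichment.
#'
#' @param p_enrichment,p_depletion empirical confidence scores in (0, 1].
#' @return signed combined value.
#' @export
combine_scores <- function(p_enrichment, p_depletion) {
  if (any(c(p_enrichment, p_depletion) <= 0))
    stop_ps("confidence scores must be positive")
  if (p_enrichment <= p_depletion) log2(p_enrichment) else -log2(p_depletion)
}

#' Score a whole cohort: pathway aberration profiles for every sample
#'
#' For each sample the measured genes are ranked once; for each pathway the
#' enrichment and depletion AUCs and their permutation confidence scores are
#' computed and combined. Null AUC distributions are cached per effective
#' set size within a sample (distributionally identical to drawing fresh
#' nulls per pathway), and every (sample, set-size) null stream is seeded
#' from `(seed, sample_id, m)`, so results are reproducible and invariant
#' to sample or pathway ordering.
#'
#' @param values genes x samples numeric matrix of log ratios.
#' @param collection a `gene_set_collection`; every set must overlap the
#'   matrix's genes on 1 <= m < n_measured genes per sample.
#' @param B permutations per null (default 1000).
#' @param seed integer master seed.
#' @return an `aberration_profiles` object: list with matrices `combined`,
#'   `p_enrichment`, `p_depletion`, `auc_enrichment`, `m` (all pathways x
#'   samples) plus `B` and `seed`.
#' @export
score_cohort <- function(values, collection, B = 1000L, seed = 1L) {
  validate_expression_matrix(values)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection) == 0) stop_ps("empty gene set collection")
  if (ncol(values) == 0) stop_ps("empty expression matrix")

  pathways <- names(collection$sets)
  samples <- colnames(values)
  dims <- list(pathways, samples)
  mk <- function() matrix(NA_real_, length(pathways), length(samples),
                          dimnames = dims)
  out <- list(combined = mk(), p_enrichment = mk(), p_depletion = mk(),
              auc_enrichment = mk(), m = mk(), B = as.integer(B),
              seed = as.integer(seed))

  gene_syms <- rownames(values)
  for (j in seq_along(samples)) {
    sid <- samples[j]
    v <- values[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2) stop_ps("sample '", sid, "' has < 2 measured genes")
    ord <- order(-v[ok], gene_syms[ok], method = "radix")
    ranked <- gene_syms[ok][ord]
    n <- length(ranked)
    rank_of <- seq_len(n); names(rank_of) <- ranked
    null_cache <- new.env(parent = emptyenv())

    for (i in seq_along(pathways)) {
      pos <- unname(rank_of[collection$sets[[i]]])
      pos <- pos[!is.na(pos)]
      m <- length(pos)
      if (m == 0 || m == n)
        stop_ps("pathway '", pathways[i], "' has effective size ", m,
                " in sample '", sid, "': restrict the collection with ",
                "filter_sets() first")
      auc_e <- auc_from_ranks(pos, n)
      auc_d <- 1 - auc_e                       # strict total order
      key <- as.character(m)
      if (is.null(null_cache[[key]]))
        null_cache[[key]] <- with_seed(derive_seed(seed, sid, m),
                                       null_auc_draws(n, m, B))
      null_auc <- null_cache[[key]]
      p_e <- (1 + sum(null_auc >= auc_e - 1e-12)) / (B + 1)
      p_d <- (1 + sum(null_auc >= auc_d - 1e-12)) / (B + 1)
      out$p_enrichment[i, j] <- p_e
      out$p_depletion[i, j] <- p_d
      out$auc_enrichment[i, j] <- auc_e
      out$m[i, j] <- m
      out$combined[i, j] <- combine_scores(p_e, p_d)
    }
  }
  structure(out, class = "aberration_profiles")
}

#' @export
print.aberration_profiles <- function(x, ...) {
  cat(sprintf("aberration_profiles: %d pathways x %d samples (B = %d, seed = %d)\n",
              nrow(x$combined), ncol(x$combined), x$B, x$seed))
  cat(sprintf("  combined signed scores in [%.2f, %.2f]; negative = enriched\n",
              min(x$combined), max(x$combined)))
  invisible(x)
}

#' Write an aberration profile set as TSV matrices plus a JSON manifest
#'
#' Emits `combined.tsv`, `p_enrichment.tsv`, `p_depletion.tsv` (pathways x
#' samples) and `manifest.json` recording B, seed, dimensions and package
#' version into `dir`.
#'
#' @param profiles an `aberration_profiles` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  stopifnot(inherits(profiles, "aberration_profiles"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(mat, name) {
    df <- data.frame(pathway = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(profiles$combined, "combined.tsv")
  wr(profiles$p_enrichment, "p_enrichment.tsv")
  wr(profiles$p_depletion, "p_depletion.tsv")
  manifest <- list(B = profiles$B, seed = profiles$seed,
                   n_pathways = nrow(profiles$combined),
                   n_samples = ncol(profiles$combined),
                   package_version = as.character(utils::packageVersion("pathscape")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
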