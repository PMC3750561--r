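## Clinical association testing: Kaplan-Meier / log-rank survival scans,
## Fisher's exact label enrichment, Wilcoxon rank-sum differential
## expression. Standard tests are delegated to survival:: and stats::; the
## scan logic, directionality and reporting conventions live here. No
## multiple-testing correction is applied to the scans themselves (the
## method is deliberately exploratory); a Benjamini-Hochberg column is
## appended to scan outputs as supplementary information only.

as_survival_df <- function(records) {
  df <- as.data.frame(records)
  req <- c("sample_id", "time", "event")
  if (!all(req %in% names(df)))
    stop_ps("survival records need columns: ", paste(req, collapse = ", "))
  if (any(df$time <= 0)) stop_ps("survival times must be positive")
  if (anyDuplicated(df$sample_id)) stop_ps("one survival record per sample")
  df$event <- as.logical(df$event)
  df
}

#' Two-group Kaplan-Meier estimators and Mantel-Cox (log-rank) test
#'
#' Product-limit survival estimators per group under right censoring
#' (`event = FALSE` means censored at `time`), compared with the unweighted
#' two-group log-rank chi-square on 1 degree of freedom.
#'
#' @param group_a,group_b data frames (or coercible) with columns
#'   `sample_id`, `time` (days, > 0), `event` (logical, `TRUE` = death).
#' @return a list with `chisq`, `p_value`, `direction` (`"a-worse"` /
#'   `"a-better"` by observed-vs-expected events in group a), `n` (group
#'   sizes) and `km` — a list of two step tables (time, n_risk, n_event,
#'   survival) suitable for replotting.
#' @export
km_logrank <- function(group_a, group_b) {
  a <- as_survival_df(group_a); b <- as_survival_df(group_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop_ps("both groups must be non-empty")
  if (sum(a$event) + sum(b$event) == 0)
    stop_ps("log-rank undefined with zero observed events")
  df <- rbind(cbind(a, group = "a"), cbind(b, group = "b"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- unname(sd$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  direction <- if (sd$obs[1] >= sd$exp[1]) "a-worse" else "a-better"
  km <- lapply(split(df, df$group), function(g) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = g)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, survival = fit$surv)
  })
  list(chisq = chisq, p_value = p, direction = direction,
       n = c(a = nrow(a), b = nrow(b)), km = km)
}

#' Scan every subgroup for survival difference against the rest of its cohort
#'
#' For each subgroup in the assignment, a log-rank test of the subgroup
#' versus all other samples of the same cohort. Subgroups with fewer than 2
#' survival records (or an empty complement) are skipped with a warning.
#' No multiple-testing correction is applied to the significance flags; a
#' supplementary BH-adjusted column is included.
#'
#' @param assignment a `subgroup_assignment`.
#' @param survival_records data frame with `sample_id`, `time`, `event`.
#' @param alpha significance threshold (default 0.05).
#' @return data frame: subgroup, n_subgroup, n_rest, chisq, p_value,
#'   direction, significant (p < alpha), p_bh (supplementary).
#' @export
survival_scan <- function(assignment, survival_records, alpha = 0.05) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  surv <- as_survival_df(survival_records)
  surv <- surv[surv$sample_id %in% names(assignment$assignment), ]
  grp <- assignment$assignment[surv$sample_id]
  rows <- list()
  for (k in sort(unique(assignment$assignment))) {
    a <- surv[grp == k, ]; b <- surv[grp != k, ]
    if (nrow(a) < 2 || nrow(b) < 1) {
      warning("subgroup ", k, " skipped: insufficient survival records",
              call. = FALSE)
      next
    }
    res <- tryCatch(km_logrank(a, b), error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      subgroup = k, n_subgroup = nrow(a), n_rest = nrow(b),
      chisq = res$chisq, p_value = res$p_value,
      direction = sub("^a-", "", res$direction))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(subgroup = integer(0), n_subgroup = integer(0),
                         n_rest = integer(0), chisq = numeric(0),
                         p_value = numeric(0), direction = character(0))
  out$significant <- out$p_value < alpha
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Fisher's exact association between subgroups and a binary label
#'
#' For each subgroup, the 2x2 table (in/out of subgroup) x (label +/-) over
#' labelled samples, tested with the two-sided Fisher exact test (sum of
#' hypergeometric probabilities of tables at most as likely as the observed
#' one). Degenerate margins give p = 1 with a warning.
#'
#' @param assignment a `subgroup_assignment`.
#' @param labels named logical (or coercible) vector, sample id -> label;
#'   samples absent from `labels` (or `NA`) are excluded.
#' @param alpha significance threshold (default 0.05).
#' @return data frame: subgroup, in_pos, in_neg, out_pos, out_neg, odds
#'   ratio estimate, p_value, direction, significant, p_bh.
#' @export
fisher_association <- function(assignment, labels, alpha = 0.05) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  lab <- labels[!is.na(labels)]
  common <- intersect(names(assignment$assignment), names(lab))
  if (length(common) == 0) stop_ps("labels cover no assigned sample")
  grp <- assignment$assignment[common]
  lab <- as.logical(lab[common])
  rows <- lapply(sort(unique(assignment$assignment)), function(k) {
    tab <- matrix(c(sum(grp == k & lab), sum(grp == k & !lab),
                    sum(grp != k & lab), sum(grp != k & !lab)),
                  nrow = 2, byrow = TRUE)
    if (all(lab) || all(!lab) || all(grp == k) || all(grp != k)) {
      warning("subgroup ", k, ": degenerate margin, p = 1", call. = FALSE)
      p <- 1; or <- NA_real_
    } else {
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      p <- ft$p.value; or <- unname(ft$estimate)
    }
    in_rate <- if (sum(grp == k)) mean(lab[grp == k]) else 0
    out_rate <- if (sum(grp != k)) mean(lab[grp != k]) else 0
    data.frame(subgroup = k,
               in_pos = tab[1, 1], in_neg = tab[1, 2],
               out_pos = tab[2, 1], out_neg = tab[2, 2],
               odds_ratio = or, p_value = p,
               direction = if (in_rate >= out_rate) "enriched" else "depleted")
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Per-gene Wilcoxon rank-sum differential expression between two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test per gene: exact when both
#' groups have at most 12 usable values and the gene has no ties, normal
#' approximation with tie correction otherwise. Genes with fewer than 2
#' usable values in either group are skipped.
#'
#' @param values genes x samples numeric matrix.
#' @param group_a,group_b character vectors of sample ids (>= 2 each).
#' @param alpha significance threshold (default 0.05; 0.01 is conventional
#'   for cross-branch gene comparisons).
#' @return data frame: gene, statistic (Mann-Whitney U of group a),
#'   p_value, direction (`"up"` when group a's median is higher),
#'   median_diff, significant, p_bh.
#' @export
wilcoxon_de <- function(values, group_a, group_b, alpha = 0.05) {
  validate_expression_matrix(values)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_ps("both groups need >= 2 samples")
  missing_ids <- setdiff(c(group_a, group_b), colnames(values))
  if (length(missing_ids))
    stop_ps("sample id(s) not in matrix: ", paste(missing_ids, collapse = ", "))
  rows <- lapply(rownames(values), function(g) {
    xa <- values[g, group_a]; xb <- values[g, group_b]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) return(NULL)
    if (length(unique(c(xa, xb))) == 1)   # degenerate all-tied gene
      return(data.frame(gene = g, statistic = length(xa) * length(xb) / 2,
                        p_value = 1, direction = "up", median_diff = 0))
    ties <- anyDuplicated(c(xa, xb)) > 0
    exact <- length(xa) <= 12 && length(xb) <= 12 && !ties
    wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = exact,
                                              correct = !exact))
    md <- stats::median(xa) - stats::median(xb)
    data.frame(gene = g, statistic = unname(wt$statistic),
               p_value = wt$p.value,
               direction = if (md >= 0) "up" else "down",
               median_diff = md)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(gene = character(0), statistic = numeric(0),
                      p_value = numeric(0), direction = character(0),
                      median_diff = numeric(0), significant = logical(0),
                      p_bh = numeric(0)))
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
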