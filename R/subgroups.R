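## Aberration calling, group frequencies, and subgroup discovery by
## hierarchical clustering (Ward linkage on Euclidean distances).

#' Call per-sample pathway aberrations at a significance threshold
#'
#' A pathway is called enriched in a sample when its enrichment confidence
#' score is below `alpha` and no larger than the depletion score; depleted
#' when the depletion score is below `alpha` and strictly smaller than the
#' enrichment score; neutral otherwise. Calls are mutually exclusive.
#'
#' @param profiles an `aberration_profiles` object from [score_cohort()].
#' @param alpha significance threshold in (0, 1); default 0.05.
#' @return an `aberration_calls` object: list with `calls` (pathways x
#'   samples character matrix over `"E"`, `"D"`, `"N"`), `alpha`, and
#'   `counts` (per-pathway tallies of each call).
#' @export
call_aberrations <- function(profiles, alpha = 0.05) {
  stopifnot(inherits(profiles, "aberration_profiles"),
            alpha > 0, alpha < 1)
  pe <- profiles$p_enrichment; pd <- profiles$p_depletion
  calls <- matrix("N", nrow(pe), ncol(pe), dimnames = dimnames(pe))
  calls[pe < alpha & pe <= pd] <- "E"
  calls[pd < alpha & pd < pe] <- "D"
  counts <- data.frame(
    pathway = rownames(calls),
    enriched = rowSums(calls == "E"),
    depleted = rowSums(calls == "D"),
    neutral = rowSums(calls == "N"),
    row.names = NULL)
  structure(list(calls = calls, alpha = alpha, counts = counts),
            class = "aberration_calls")
}

#' Per-group enrichment and depletion frequencies
#'
#' For each group (cohort, subgroup, ...) and each pathway, the fraction of
#' the group's samples in which the pathway is called enriched, and the
#' fraction called depleted.
#'
#' @param calls an `aberration_calls` object.
#' @param grouping named character/integer vector mapping every sample id in
#'   the call matrix to a group label.
#' @return a `frequency_profiles` object: list with `enr_freq` and
#'   `dep_freq` (pathways x groups matrices) and `group_size` (named
#'   integer vector).
#' @export
aberration_frequencies <- function(calls, grouping) {
  stopifnot(inherits(calls, "aberration_calls"))
  samples <- colnames(calls$calls)
  if (!all(samples %in% names(grouping)))
    stop_ps("grouping is missing sample(s): ",
            paste(setdiff(samples, names(grouping)), collapse = ", "))
  g <- as.character(grouping[samples])
  groups <- unique(g)
  enr <- vapply(groups, function(gl)
    rowMeans(calls$calls[, g == gl, drop = FALSE] == "E"),
    numeric(nrow(calls$calls)))
  dep <- vapply(groups, function(gl)
    rowMeans(calls$calls[, g == gl, drop = FALSE] == "D"),
    numeric(nrow(calls$calls)))
  if (nrow(calls$calls) == 1) {          # vapply drops to vector
    enr <- matrix(enr, nrow = 1, dimnames = list(rownames(calls$calls), groups))
    dep <- matrix(dep, nrow = 1, dimnames = list(rownames(calls$calls), groups))
  }
  structure(list(enr_freq = enr, dep_freq = dep,
                 group_size = setNames(as.integer(table(g)[groups]), groups)),
            class = "frequency_profiles")
}

#' Agglomerative clustering with Ward's linkage on Euclidean distances
#'
#' Thin, opinionated front end to [stats::hclust()] with `method =
#' "ward.D2"` on [stats::dist()] Euclidean distances — the classical Ward
#' minimum-variance criterion; merge heights are in (square-root of twice
#' the) within-cluster sum-of-squares-increase units and are non-decreasing.
#'
#' @param features items x features numeric matrix with item rownames;
#'   no missing values.
#' @return an object of class `hclust` (labels = item rownames).
#' @export
hierarchical_cluster <- function(features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 2) stop_ps("need at least 2 items to cluster")
  if (anyNA(features)) stop_ps("features contain missing values")
  if (is.null(rownames(features)))
    rownames(features) <- paste0("item", seq_len(nrow(features)))
  stats::hclust(stats::dist(features, method = "euclidean"),
                method = "ward.D2")
}

## leaf indices under each internal node of an hclust merge matrix
node_members <- function(tree) {
  n <- length(tree$order)
  members <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    take <- function(x) if (x < 0) -x else members[[x]]
    members[[i]] <- c(take(tree$merge[i, 1]), take(tree$merge[i, 2]))
  }
  members
}

#' Extract subgroups of bounded size from a dendrogram
#'
#' Reproduces "distinct branches of 20-30 samples" as a deterministic
#' procedure: descend from the root splitting any cluster larger than
#' `max_size`; clusters smaller than `min_size` produced by such forced
#' splits are merged into their nearest sibling (the current subgroup with
#' the lowest cophenetic attachment height; ties broken toward the smaller
#' subgroup, then the earlier one in dendrogram order). Alternatively,
#' `k_override` cuts the tree into exactly `k` clusters
#' ([stats::cutree()]), the escape hatch for reproducing a stated cluster
#' count.
#'
#' @param tree an `hclust` object (e.g. from [hierarchical_cluster()]).
#' @param min_size,max_size subgroup size bounds (defaults 20 and 30).
#' @param k_override optional integer: cut into exactly this many clusters.
#' @param cohort optional cohort label stored with the assignment.
#' @return a `subgroup_assignment` object: list with `assignment` (named
#'   integer vector, sample -> subgroup), `sizes`, `cohort`, `tree` and the
#'   cut parameters.
#' @export
extract_subgroups <- function(tree, min_size = 20L, max_size = 30L,
                              k_override = NULL, cohort = "cohort") {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  labels <- tree$labels %||% as.character(seq_len(n))

  if (!is.null(k_override)) {
    if (k_override < 1 || k_override > n)
      stop_ps("k_override must be in [1, n_items]")
    cl <- stats::cutree(tree, k = k_override)
  } else {
    if (min_size > max_size) stop_ps("min_size must be <= max_size")
    if (min_size > n) stop_ps("min_size exceeds the number of items")
    members <- node_members(tree)
    clusters <- list()
    descend <- function(node) {
      size <- if (node < 0) 1L else length(members[[node]])
      if (node > 0 && size > max_size) {
        descend(tree$merge[node, 1])
        descend(tree$merge[node, 2])
      } else {
        clusters[[length(clusters) + 1L]] <<-
          if (node < 0) -node else members[[node]]
      }
    }
    descend(n - 1L)

    if (length(clusters) > 1 && any(lengths(clusters) < min_size)) {
      coph <- as.matrix(stats::cophenetic(tree))
      repeat {
        sizes <- lengths(clusters)
        small <- which(sizes < min_size)
        if (length(small) == 0 || length(clusters) == 1) break
        u <- small[order(sizes[small], small)][1]
        others <- setdiff(seq_along(clusters), u)
        att <- vapply(others, function(v)
          coph[clusters[[u]][1], clusters[[v]][1]], numeric(1))
        best <- others[order(att, lengths(clusters)[others], others)][1]
        clusters[[best]] <- c(clusters[[best]], clusters[[u]])
        clusters[[u]] <- NULL
      }
    }
    ## number subgroups left-to-right in dendrogram order
    first_pos <- vapply(clusters, function(cl)
      min(match(cl, tree$order)), numeric(1))
    clusters <- clusters[order(first_pos)]
    cl <- integer(n)
    for (k in seq_along(clusters)) cl[clusters[[k]]] <- k
    names(cl) <- labels
  }
  sizes <- table(cl)
  structure(list(assignment = setNames(as.integer(cl), labels),
                 sizes = setNames(as.integer(sizes), names(sizes)),
                 cohort = cohort, tree = tree,
                 parameters = list(min_size = min_size, max_size = max_size,
                                   k_override = k_override)),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("subgroup_assignment (%s): %d samples in %d subgroups, sizes %s\n",
              x$cohort, length(x$assignment), length(x$sizes),
              paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Frequency-based feature matrix for clustering subgroups across cohorts
#'
#' One row per group, features = the concatenation of the group's
#' enrichment-frequency vector and depletion-frequency vector (2 x
#' n_pathways columns), ready for [hierarchical_cluster()]. When several
#' `frequency_profiles` objects are supplied (one per cohort) their pathway
#' lists must match exactly.
#'
#' @param profiles a `frequency_profiles` object or a list of them.
#' @return groups x 2P numeric matrix.
#' @export
cross_group_features <- function(profiles) {
  if (inherits(profiles, "frequency_profiles")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "frequency_profiles")))
  pw <- rownames(profiles[[1]]$enr_freq)
  for (p in profiles)
    if (!identical(rownames(p$enr_freq), pw))
      stop_ps("pathway lists differ between frequency profiles")
  rows <- do.call(rbind, lapply(profiles, function(p)
    cbind(t(p$enr_freq), t(p$dep_freq))))
  colnames(rows) <- c(paste0("enr_", pw), paste0("dep_", pw))
  rows
}

#' Export a dendrogram as a Newick string or file
#'
#' Converts an `hclust` tree to `ape`'s `phylo` representation (merge
#' heights become branch lengths) and writes Newick.
#'
#' @param tree an `hclust` object.
#' @param path optional output path; when `NULL` the Newick string is
#'   returned instead.
#' @return the Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
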