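## Synthetic cohort generator with known ground truth.
##
## Emulates the statistical structure of pan-cancer log-ratio expression
## cohorts: per-gene log2 ratios against a common reference, several cancer
## types with distinct sparse baseline shifts (so cohorts separate in PCA),
## planted subgroups whose designated pathways' member genes are coherently
## shifted up (enrichment) or down (depletion), near-copy duplicate samples
## sharing a patient id for QC testing, and exponential survival times whose
## hazard depends on subgroup. Every generator is bit-reproducible given its
## seed.

#' Describe a synthetic cohort
#'
#' @param n_genes number of measured genes.
#' @param cancers list of cancer descriptions; each a list with `label` and
#'   `subgroups`, itself a list of subgroup descriptions: `size` (samples),
#'   `aberrations` (named character vector, pathway name -> `"ENRICHED"` or
#'   `"DEPLETED"`; may be empty) and optional `hazard` multiplier (default
#'   1). A cancer's sample count is the sum of its subgroup sizes.
#' @param delta planted effect size: member genes of an enriched (depleted)
#'   pathway are shifted by `+delta` (`-delta`) log2 units (default 1).
#' @param sigma Gaussian noise standard deviation on the log-ratio scale
#'   (default 1).
#' @param baseline_fraction fraction of genes carrying a cancer-specific
#'   baseline shift (default 0.1).
#' @param baseline_shift magnitude of those shifts, applied with random sign
#'   (default 1).
#' @param n_duplicates number of near-copy duplicate samples to inject
#'   (default 0).
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_genes, cancers, delta = 1, sigma = 1,
                          baseline_fraction = 0.1, baseline_shift = 1,
                          n_duplicates = 0L) {
  stopifnot(n_genes >= 2, delta > 0, sigma > 0,
            baseline_fraction >= 0, baseline_fraction <= 1)
  for (ca in cancers) {
    if (is.null(ca$label) || is.null(ca$subgroups))
      stop_ps("each cancer needs a label and a list of subgroups")
    for (sg in ca$subgroups) {
      if (is.null(sg$size) || sg$size < 1)
        stop_ps("each subgroup needs a positive size")
      if (length(sg$aberrations) &&
          !all(sg$aberrations %in% c("ENRICHED", "DEPLETED")))
        stop_ps("planted aberrations must be ENRICHED or DEPLETED")
    }
  }
  structure(list(n_genes = as.integer(n_genes), cancers = cancers,
                 delta = delta, sigma = sigma,
                 baseline_fraction = baseline_fraction,
                 baseline_shift = baseline_shift,
                 n_duplicates = as.integer(n_duplicates)),
            class = "cohort_design")
}

synthetic_gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Generate a synthetic gene-set collection
#'
#' Draws `n_sets` sets with sizes uniform in `size_range` over a universe of
#' `universe_size` synthetic gene symbols; a fraction of each set's genes is
#' shared with the previous set (`overlap_fraction`), the rest are drawn
#' from still-unused genes while any remain (so `overlap_fraction = 0`
#' yields pairwise-disjoint sets where the universe permits). When the
#' universe is large enough, two sentinel sets of sizes 9 and 1001 are
#' appended to exercise the 10/1000 size filter.
#'
#' @param n_sets number of regular sets.
#' @param size_range integer pair `(low, high)`.
#' @param universe_size number of genes in the synthetic universe.
#' @param overlap_fraction fraction in `[0, 1)` of a set shared with its
#'   predecessor.
#' @param seed integer seed.
#' @param sentinels include the filter-sentinel sets (default TRUE).
#' @return a `gene_set_collection` over genes `G00001 ...`.
#' @export
generate_genesets <- function(n_sets, size_range = c(10L, 50L),
                              universe_size = 2000L, overlap_fraction = 0,
                              seed = 1L, sentinels = TRUE) {
  stopifnot(length(size_range) == 2, size_range[1] >= 1,
            size_range[2] >= size_range[1], size_range[2] <= universe_size,
            overlap_fraction >= 0, overlap_fraction < 1)
  universe <- synthetic_gene_names(universe_size)
  with_seed(derive_seed(seed, "genesets"), {
    sets <- list()
    unused <- universe
    prev <- character(0)
    size_choices <- seq(size_range[1], size_range[2])
    for (i in seq_len(n_sets)) {
      s <- size_choices[sample.int(length(size_choices), 1)]
      n_shared <- min(floor(overlap_fraction * s), length(prev))
      shared <- if (n_shared > 0) sample(prev, n_shared) else character(0)
      n_fresh <- s - n_shared
      pool <- setdiff(unused, shared)
      if (length(pool) >= n_fresh) {
        fresh <- sample(pool, n_fresh)
      } else {  # universe exhausted: reuse measured genes
        fresh <- c(pool,
                   sample(setdiff(universe, c(shared, pool)),
                          n_fresh - length(pool)))
      }
      members <- c(shared, fresh)
      sets[[sprintf("SET%03d", i)]] <- sort(members)
      unused <- setdiff(unused, members)
      prev <- members
    }
    if (sentinels && universe_size >= 9)
      sets[["SENTINEL_SMALL"]] <- sort(sample(universe, 9))
    if (sentinels && universe_size >= 1001)
      sets[["SENTINEL_LARGE"]] <- sort(sample(universe, 1001))
    new_gene_set_collection(
      sets,
      source = setNames(rep("synthetic", length(sets)), names(sets)))
  })
}

#' Generate an expression cohort with planted pathway aberrations
#'
#' Each entry is cancer baseline + planted pathway shift + Gaussian noise:
#' a sample in a subgroup planted with an ENRICHED (DEPLETED) pathway has
#' that pathway's member genes shifted by `+delta` (`-delta`). Duplicates
#' are injected as near-copies (noise sd `sigma / 10`) sharing the source
#' sample's patient id. All ground truth is recorded.
#'
#' @param design a [cohort_design()].
#' @param collection a `gene_set_collection` containing every planted
#'   pathway; its genes must lie within the design's synthetic universe.
#' @param seed integer seed.
#' @return list with `values` (genes x samples), `metadata` (sample_id,
#'   patient_id, cancer_label, subgroup), and `truth`: `subgroup` (named
#'   global subgroup label per sample), `aberrations` (per global subgroup,
#'   named pathway -> state), `hazard` (named multiplier per sample),
#'   `duplicate_pairs` (data frame), `planted` (per sample, named list of
#'   pathway states).
#' @export
generate_cohort <- function(design, collection, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(collection, "gene_set_collection"))
  genes <- synthetic_gene_names(design$n_genes)
  planted_pw <- unique(unlist(lapply(design$cancers, function(ca)
    lapply(ca$subgroups, function(sg) names(sg$aberrations)))))
  missing_pw <- setdiff(planted_pw, names(collection$sets))
  if (length(missing_pw))
    stop_ps("planted pathway(s) not in collection: ",
            paste(missing_pw, collapse = ", "))

  with_seed(derive_seed(seed, "cohort"), {
    cols <- list(); meta <- list()
    subgroup_of <- character(0); hazard_of <- numeric(0)
    aberrations <- list()
    for (ca in design$cancers) {
      baseline <- numeric(design$n_genes)
      n_shift <- round(design$baseline_fraction * design$n_genes)
      if (n_shift > 0) {
        idx <- sample(design$n_genes, n_shift)
        baseline[idx] <- sample(c(-1, 1), n_shift, replace = TRUE) *
          design$baseline_shift
      }
      s_idx <- 0L
      for (g in seq_along(ca$subgroups)) {
        sg <- ca$subgroups[[g]]
        sg_label <- paste0(ca$label, ".", g)
        shift <- numeric(design$n_genes)
        for (pw in names(sg$aberrations)) {
          members <- match(collection$sets[[pw]], genes)
          members <- members[!is.na(members)]
          shift[members] <- shift[members] +
            if (sg$aberrations[[pw]] == "ENRICHED") design$delta else -design$delta
        }
        aberrations[[sg_label]] <-
          if (length(sg$aberrations)) sg$aberrations
          else setNames(character(0), character(0))
        for (s in seq_len(sg$size)) {
          s_idx <- s_idx + 1L
          sid <- sprintf("%s-S%03d", ca$label, s_idx)
          cols[[sid]] <- baseline + shift +
            stats::rnorm(design$n_genes, 0, design$sigma)
          meta[[sid]] <- data.frame(sample_id = sid,
                                    patient_id = sprintf("%s-P%03d", ca$label, s_idx),
                                    cancer_label = ca$label,
                                    subgroup = sg_label)
          subgroup_of[sid] <- sg_label
          hazard_of[sid] <- sg$hazard %||% 1
        }
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL

    dup_pairs <- data.frame(original = character(0), duplicate = character(0))
    if (design$n_duplicates > 0) {
      src <- sample(colnames(values), design$n_duplicates)
      for (sid in src) {
        did <- paste0(sid, "-DUP")
        values <- cbind(values,
                        setNames(data.frame(values[, sid] +
                          stats::rnorm(design$n_genes, 0, design$sigma / 10)),
                          did))
        values <- as.matrix(values)
        row <- metadata[metadata$sample_id == sid, ]
        row$sample_id <- did
        metadata <- rbind(metadata, row)
        subgroup_of[did] <- subgroup_of[sid]
        hazard_of[did] <- hazard_of[sid]
        dup_pairs <- rbind(dup_pairs,
                           data.frame(original = sid, duplicate = did))
      }
      rownames(metadata) <- NULL
    }
    list(values = values, metadata = metadata,
         truth = list(subgroup = subgroup_of,
                      aberrations = aberrations,
                      hazard = hazard_of,
                      duplicate_pairs = dup_pairs))
  })
}

#' Generate survival records whose hazard depends on subgroup
#'
#' Event times are exponential with rate `base_rate` times the sample's true
#' hazard multiplier; censoring times are independent uniform on `(0, c)`
#' with `c` calibrated so the expected censored fraction over the cohort
#' equals `censoring_fraction` (for Exp(lambda) vs U(0, c), P(censored) =
#' (1 - exp(-lambda c)) / (lambda c), averaged over samples and solved for
#' `c`). `censoring_fraction = 0` yields fully observed events.
#'
#' @param truth the `truth` component of [generate_cohort()] (needs
#'   `hazard`).
#' @param base_rate baseline exponential event rate per day (> 0).
#' @param censoring_fraction expected fraction censored, in `[0, 1)`.
#' @param seed integer seed.
#' @return data frame: sample_id, time, event (logical).
#' @export
generate_survival <- function(truth, base_rate = 1 / 365,
                              censoring_fraction = 0.2, seed = 1L) {
  stopifnot(base_rate > 0, censoring_fraction >= 0, censoring_fraction < 1)
  lambda <- base_rate * truth$hazard
  n <- length(lambda)
  with_seed(derive_seed(seed, "survival"), {
    event_time <- stats::rexp(n, rate = lambda)
    if (censoring_fraction == 0) {
      time <- event_time; event <- rep(TRUE, n)
    } else {
      frac_censored <- function(cmax)
        mean((1 - exp(-lambda * cmax)) / (lambda * cmax)) - censoring_fraction
      cmax <- stats::uniroot(frac_censored,
                             lower = 1e-9 / base_rate,
                             upper = 1e6 / base_rate)$root
      cens_time <- stats::runif(n, 0, cmax)
      event <- event_time <= cens_time
      time <- pmin(event_time, cens_time)
    }
    data.frame(sample_id = names(truth$hazard), time = time, event = event,
               row.names = NULL)
  })
}
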