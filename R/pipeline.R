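## End-to-end orchestration: load/QC -> gene-set prep -> scoring -> calls ->
## frequencies -> per-cohort subgrouping -> survival / label associations ->
## cross-cohort subgroup clustering, with per-stage outputs and a checksummed
## run manifest. Intermediate matrices are written to disk so the expensive
## scoring stage can be reused across clustering parameter changes.

#' Validate and normalize a pipeline run configuration
#'
#' @param config a list or a path to a YAML file with fields: `expression`,
#'   `metadata`, `gmt` (input paths), optional `alias_map` (TSV alias ->
#'   canonical) and `blacklist` (one patient id per line), `output_dir`,
#'   `B` (>= 100, default 1000), `seed` (default 1), `alpha` (default 0.05),
#'   `min_set_size` / `max_set_size` (defaults 10 / 1000), `subgroup_min` /
#'   `subgroup_max` (defaults 20 / 30), optional `k_override` (named list,
#'   cohort label -> cluster count), optional `corr_threshold` (default
#'   0.99).
#' @return the validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_ps("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(B = 1000L, seed = 1L, alpha = 0.05,
                   min_set_size = 10L, max_set_size = 1000L,
                   subgroup_min = 20L, subgroup_max = 30L,
                   corr_threshold = 0.99, k_override = NULL,
                   alias_map = NULL, blacklist = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("expression", "metadata", "gmt", "output_dir"))
    if (is.null(config[[nm]])) stop_ps("config is missing '", nm, "'")
  for (nm in c("expression", "metadata", "gmt", "alias_map", "blacklist"))
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]]))
      stop_ps("config input does not exist: ", nm, " = ", config[[nm]])
  if (config$B < 100) stop_ps("B must be >= 100")
  if (config$alpha <= 0 || config$alpha >= 1) stop_ps("alpha must be in (0, 1)")
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pathway aberration analysis
#'
#' Executes, in order: expression loading and QC (quantile normalization for
#' PCA, duplicate/blacklist screening), gene-set ingestion/harmonization/
#' filtering against the measured-gene universe, cohort scoring, aberration
#' calling, per-cancer aberration frequencies, per-cancer subgroup discovery,
#' survival and prior-label association scans (when metadata permits), and
#' cross-cancer clustering of subgroup frequency features. Each stage writes
#' its outputs under `output_dir` and the run ends with a checksummed JSON
#' manifest; a failing stage aborts with its name while earlier outputs stay
#' intact.
#'
#' @param config see [read_run_config()].
#' @return invisibly, a list with the main in-memory results (`profiles`,
#'   `calls`, `assignments`, `manifest_path`).
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop_ps("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    message(sprintf("[pathscape] %-22s %6.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  ## --- load + QC -----------------------------------------------------
  loaded <- stage("load_expression",
                  load_expression(config$expression, config$metadata))
  values <- loaded$values; metadata <- loaded$metadata

  qc <- stage("qc", {
    norm <- quantile_normalize(values)
    emb <- pca_embed(norm, k = 2)
    outputs <<- c(outputs, write_tsv(
      data.frame(sample_id = rownames(emb$coords), emb$coords),
      file.path(out_dir, "pca_coordinates.tsv")))
    blacklist <- if (!is.null(config$blacklist))
      readLines(config$blacklist, warn = FALSE) else character(0)
    dup <- detect_duplicates(values, metadata,
                             corr_threshold = config$corr_threshold,
                             blacklist = blacklist)
    outputs <<- c(outputs, write_tsv(dup$flagged,
                                     file.path(out_dir, "flagged_samples.tsv")))
    dup
  })
  values <- values[, qc$retained, drop = FALSE]
  metadata <- metadata[metadata$sample_id %in% qc$retained, , drop = FALSE]

  ## --- gene sets ------------------------------------------------------
  collection <- stage("gene_sets", {
    coll <- read_gmt(config$gmt)
    if (!is.null(config$alias_map)) {
      am <- utils::read.delim(config$alias_map, header = TRUE,
                              stringsAsFactors = FALSE)
      coll <- harmonize_symbols(coll, setNames(am[[2]], am[[1]]))
    }
    coll <- filter_sets(coll, universe = rownames(values),
                        min_size = config$min_set_size,
                        max_size = config$max_set_size)
    outputs <<- c(outputs,
                  write_gmt(coll, file.path(out_dir, "filtered_sets.gmt")),
                  write_removal_report(coll,
                                       file.path(out_dir, "removed_sets.tsv")))
    coll
  })

  ## --- scoring + calls ------------------------------------------------
  profiles <- stage("score_cohort",
                    score_cohort(values, collection, B = config$B,
                                 seed = config$seed))
  write_profiles(profiles, file.path(out_dir, "profiles"))
  outputs <- c(outputs,
               file.path(out_dir, "profiles",
                         c("combined.tsv", "p_enrichment.tsv",
                           "p_depletion.tsv", "manifest.json")))
  calls <- stage("call_aberrations", call_aberrations(profiles, config$alpha))
  outputs <- c(outputs, write_tsv(
    data.frame(pathway = rownames(calls$calls), calls$calls,
               check.names = FALSE),
    file.path(out_dir, "calls.tsv")))

  ## --- per-cancer frequencies ------------------------------------------
  cancer_of <- setNames(metadata$cancer_label, metadata$sample_id)
  freq_cancer <- stage("frequencies", {
    fr <- aberration_frequencies(calls, cancer_of)
    outputs <<- c(outputs, write_tsv(
      data.frame(pathway = rownames(fr$enr_freq),
                 setNames(as.data.frame(fr$enr_freq),
                          paste0("enr_", colnames(fr$enr_freq))),
                 setNames(as.data.frame(fr$dep_freq),
                          paste0("dep_", colnames(fr$dep_freq))),
                 check.names = FALSE),
      file.path(out_dir, "cancer_frequencies.tsv")))
    fr
  })

  ## --- per-cancer subgrouping -------------------------------------------
  assignments <- stage("subgrouping", {
    res <- list()
    for (ca in unique(metadata$cancer_label)) {
      ids <- metadata$sample_id[metadata$cancer_label == ca]
      if (length(ids) < 2) next
      feats <- t(profiles$combined[, ids, drop = FALSE])
      tree <- hierarchical_cluster(feats)
      k <- config$k_override[[ca]]
      res[[ca]] <- extract_subgroups(tree,
                                     min_size = config$subgroup_min,
                                     max_size = config$subgroup_max,
                                     k_override = k, cohort = ca)
      outputs <<- c(outputs, {
        nw <- file.path(out_dir, paste0("tree_", ca, ".nwk"))
        write_newick(tree, nw); nw
      })
    }
    asg <- do.call(rbind, lapply(res, function(a)
      data.frame(sample_id = names(a$assignment), cohort = a$cohort,
                 subgroup = unname(a$assignment))))
    outputs <<- c(outputs, write_tsv(asg,
                                     file.path(out_dir, "subgroups.tsv")))
    res
  })

  ## --- clinical associations --------------------------------------------
  has_surv <- all(c("survival_days", "event") %in% names(metadata)) &&
    any(!is.na(metadata$survival_days))
  if (has_surv) {
    stage("survival_scan", {
      surv_all <- data.frame(sample_id = metadata$sample_id,
                             time = metadata$survival_days,
                             event = metadata$event)
      surv_all <- surv_all[!is.na(surv_all$time) & surv_all$time > 0, ]
      res <- do.call(rbind, lapply(names(assignments), function(ca) {
        sc <- survival_scan(assignments[[ca]], surv_all, alpha = config$alpha)
        if (nrow(sc)) cbind(cohort = ca, sc) else NULL
      }))
      if (!is.null(res))
        outputs <<- c(outputs, write_tsv(res,
                                         file.path(out_dir, "survival_scan.tsv")))
      res
    })
  }
  if ("prior_subtype" %in% names(metadata) &&
      any(!is.na(metadata$prior_subtype))) {
    stage("label_associations", {
      res <- list()
      for (ca in names(assignments)) {
        sub_meta <- metadata[metadata$cancer_label == ca, ]
        for (lab in unique(stats::na.omit(sub_meta$prior_subtype))) {
          labels <- setNames(sub_meta$prior_subtype == lab,
                             sub_meta$sample_id)
          fa <- withCallingHandlers(
            fisher_association(assignments[[ca]], labels,
                               alpha = config$alpha),
            warning = function(w) invokeRestart("muffleWarning"))
          res[[paste(ca, lab)]] <- cbind(cohort = ca, label = lab, fa)
        }
      }
      if (length(res))
        outputs <<- c(outputs, write_tsv(do.call(rbind, res),
                                         file.path(out_dir, "label_associations.tsv")))
    })
  }

  ## --- cross-cancer subgroup clustering ---------------------------------
  if (length(assignments) >= 1) {
    stage("cross_cancer", {
      global <- character(0)
      for (a in assignments)
        global <- c(global, setNames(paste0(a$cohort, ".", a$assignment),
                                     names(a$assignment)))
      fr <- aberration_frequencies(calls, global[colnames(calls$calls)])
      feats <- cross_group_features(fr)
      if (nrow(feats) >= 2) {
        tree <- hierarchical_cluster(feats)
        nw <- file.path(out_dir, "tree_cross_cancer.nwk")
        write_newick(tree, nw)
        outputs <<- c(outputs, nw)
      }
      outputs <<- c(outputs, write_tsv(
        data.frame(subgroup = rownames(feats), feats, check.names = FALSE),
        file.path(out_dir, "subgroup_frequency_features.tsv")))
    })
  }

  ## --- manifest ----------------------------------------------------------
  manifest_path <- file.path(out_dir, "run_manifest.json")
  manifest <- list(
    parameters = config[c("B", "seed", "alpha", "min_set_size",
                          "max_set_size", "subgroup_min", "subgroup_max",
                          "corr_threshold")],
    inputs = lapply(config[c("expression", "metadata", "gmt")],
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    outputs = lapply(unique(outputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    package_version = as.character(utils::packageVersion("pathscape")))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(profiles = profiles, calls = calls,
                 assignments = assignments, manifest_path = manifest_path))
}

#' Write a synthetic cohort in the exact formats the pipeline consumes
#'
#' Emits `expression.tsv` (genes x samples), `metadata.tsv`, `genesets.gmt`
#' and `truth.json` into `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param collection the `gene_set_collection` used to generate it.
#' @param dir output directory.
#' @param survival optional data frame from [generate_survival()]; merged
#'   into the metadata as `survival_days` / `event`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, collection, dir, survival = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(gene = rownames(cohort$values), cohort$values,
                       check.names = FALSE),
            file.path(dir, "expression.tsv"))
  meta <- cohort$metadata
  if (!is.null(survival)) {
    idx <- match(meta$sample_id, survival$sample_id)
    meta$survival_days <- survival$time[idx]
    meta$event <- survival$event[idx]
  }
  write_tsv(meta, file.path(dir, "metadata.tsv"))
  write_gmt(collection, file.path(dir, "genesets.gmt"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
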