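# Small in-code fixtures shared across test files.

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tiny_collection <- function(sets) {
  path <- tempfile(fileext = ".gmt")
  on.exit(unlink(path))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "d", sets[[nm]]), collapse = "\t"), character(1)), path)
  read_gmt(path)
}

# minimal aberration_profiles object with prescribed confidence scores
fake_profiles <- function(p_enr, p_dep) {
  stopifnot(identical(dim(p_enr), dim(p_dep)))
  combined <- matrix(mapply(combine_scores, p_enr, p_dep),
                     nrow(p_enr), dimnames = dimnames(p_enr))
  structure(list(combined = combined, p_enrichment = p_enr,
                 p_depletion = p_dep, auc_enrichment = p_enr * NA,
                 m = p_enr * NA, B = 1000L, seed = 1L),
            class = "aberration_profiles")
}

fake_assignment <- function(assignment, cohort = "COH") {
  sizes <- table(assignment)
  structure(list(assignment = assignment,
                 sizes = setNames(as.integer(sizes), names(sizes)),
                 cohort = cohort, tree = NULL,
                 parameters = list()),
            class = "subgroup_assignment")
}

# expression TSV + metadata TSV on disk from a matrix
write_tmp_cohort_files <- function(values, metadata, envir = parent.frame()) {
  mat_path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  meta_path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  utils::write.table(data.frame(gene = rownames(values), values,
                                check.names = FALSE),
                     mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(metadata, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(expression = mat_path, metadata = meta_path)
}
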