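## Gene-set collections: GMT ingestion, symbol harmonization, size filtering.
##
## A gene_set_collection is a light S3 container:
##   sets        named list of character vectors (unique, uppercase symbols)
##   description named character, one entry per set (GMT field 2)
##   source      named character, database tag per set (KEGG/BIOCARTA/PWC/
##               GO/WIKIPW or user-defined)
##   universe    optional character vector of measured symbols the collection
##               has been restricted to (NULL until filter_sets is given one)

new_gene_set_collection <- function(sets, description = NULL, source = NULL,
                                    universe = NULL) {
  nm <- names(sets)
  if (length(sets) > 0 && (is.null(nm) || anyNA(nm) || any(nm == "")))
    stop_ps("every gene set must have a non-empty name")
  if (anyDuplicated(nm))
    stop_ps("duplicate gene set name(s): ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(lengths(sets) == 0))
    stop_ps("empty gene set(s): ",
            paste(nm[lengths(sets) == 0], collapse = ", "))
  description <- description %||% setNames(rep("", length(sets)), nm)
  source <- source %||% setNames(rep("user", length(sets)), nm)
  structure(list(sets = sets,
                 description = description,
                 source = source,
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %s\n", length(x),
              if (length(x)) paste0("[", min(lengths(x$sets)), ", ",
                                    max(lengths(x$sets)), "]") else "[]"))
  if (!is.null(x$universe))
    cat(sprintf("  restricted to a universe of %d measured genes\n",
                length(x$universe)))
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is the standard tab-separated gene-set exchange format: one set per
#' line, fields are set name, description, then member gene symbols. Symbols
#' are uppercased (HUGO convention) and de-duplicated within each set.
#'
#' @param path path to a GMT file.
#' @param source database tag recorded for every set in this file (e.g.
#'   `"KEGG"`, `"GO"`); defaults to `"user"`.
#' @return a `gene_set_collection`.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdesc\tTP53\tEGFR\tTP53", gmt)
#' read_gmt(gmt)
#' @export
read_gmt <- function(path, source = "user") {
  if (!file.exists(path)) stop_ps("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descr <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop_ps("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    name <- trimws(fields[1])
    genes <- toupper(trimws(fields[-(1:2)]))
    genes <- unique(genes[nzchar(genes)])
    if (name %in% names(sets))
      stop_ps("duplicate gene set name '", name, "' at line ", i)
    sets[[name]] <- genes
    descr[name] <- fields[2]
  }
  new_gene_set_collection(sets, description = descr,
                          source = setNames(rep(source, length(sets)),
                                            names(sets)))
}

#' Write a gene-set collection to a GMT file
#'
#' Inverse of [read_gmt()]: set names and memberships round-trip exactly.
#'
#' @param collection a `gene_set_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Map gene symbols to a canonical namespace
#'
#' Replaces every symbol that appears as a key of `alias_map` by its
#' canonical value, then re-deduplicates each set (aliases of the same gene
#' collapse to one member). Unmapped symbols pass through unchanged, so an
#' empty map is the identity.
#'
#' @param collection a `gene_set_collection`.
#' @param alias_map named character vector, `names = alias`, `value =
#'   canonical symbol`; both sides are uppercased before matching.
#' @return the harmonized `gene_set_collection`.
#' @export
harmonize_symbols <- function(collection, alias_map = character(0)) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(alias_map) == 0) return(collection)
  canon <- toupper(as.character(alias_map))
  if (any(!nzchar(trimws(canon))))
    stop_ps("alias map contains an empty canonical symbol")
  names(canon) <- toupper(names(alias_map))
  collection$sets <- lapply(collection$sets, function(genes) {
    hit <- genes %in% names(canon)
    genes[hit] <- canon[genes[hit]]
    unique(genes)
  })
  collection
}

#' Filter gene sets by effective size
#'
#' Optionally restricts every set to the universe of measured genes, then
#' keeps sets whose (post-intersection) size lies in `[min_size, max_size]`
#' — the conventional 10–1000 bounds by default. Sizes are counted after
#' intersection because the score's permutation null depends only on the
#' members that are actually measured.
#'
#' @param collection a `gene_set_collection`.
#' @param universe optional character vector of measured gene symbols.
#' @param min_size,max_size inclusive retention bounds (defaults 10 and 1000).
#' @return the filtered collection, with a `removed` attribute: a data frame
#'   (name, original_size, effective_size, reason) describing dropped sets.
#' @export
filter_sets <- function(collection, universe = NULL,
                        min_size = 10L, max_size = 1000L) {
  stopifnot(inherits(collection, "gene_set_collection"),
            min_size >= 1, max_size >= min_size)
  if (!is.null(universe)) universe <- unique(toupper(universe))
  orig_sizes <- lengths(collection$sets)
  eff <- if (is.null(universe)) collection$sets
         else lapply(collection$sets, intersect, y = universe)
  eff_sizes <- lengths(eff)
  keep <- eff_sizes >= min_size & eff_sizes <= max_size
  removed <- data.frame(
    name = names(collection$sets)[!keep],
    original_size = unname(orig_sizes[!keep]),
    effective_size = unname(eff_sizes[!keep]),
    reason = ifelse(eff_sizes[!keep] < min_size,
                    paste0("size<", min_size), paste0("size>", max_size)),
    stringsAsFactors = FALSE)
  out <- new_gene_set_collection(eff[keep],
                                 description = collection$description[keep],
                                 source = collection$source[keep],
                                 universe = universe)
  attr(out, "removed") <- removed
  out
}

#' Write a set-removal report produced by [filter_sets()]
#'
#' @param collection a filtered `gene_set_collection`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_removal_report <- function(collection, path) {
  removed <- attr(collection, "removed")
  if (is.null(removed))
    removed <- data.frame(name = character(0), original_size = integer(0),
                          effective_size = integer(0), reason = character(0))
  utils::write.table(removed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
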