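# Plain-text interchange: BED+ catalog, genotype tables, manifests,
# signature JSON, BED tracks.

#' Write / read the catalog as BED+ TSV
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open), `locus_id`,
#' `motif`, `ref_length`, `region_class`, `gene`, `left_flank`,
#' `right_flank`.
#'
#' @param catalog Catalog `data.frame`.
#' @param path Output path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns
#'   the catalog `data.frame`.
#' @export
write_catalog <- function(catalog, path) {
  cols <- c("chrom", "start", "end", "locus_id", "motif", "ref_length",
            "region_class", "gene", "left_flank", "right_flank")
  data.table::fwrite(catalog[, cols], path, sep = "\t")
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE,
                         na.strings = c("", "NA"))
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x[, c("locus_id", "chrom", "start", "end", "motif", "ref_length",
        "left_flank", "right_flank", "region_class", "gene")]
}

#' Read a cohort manifest TSV
#'
#' @param path TSV with columns `sample_id`, `cohort`, `path`. Relative
#'   alignment paths are resolved against the manifest's directory.
#' @return `data.frame` manifest.
#' @export
read_manifest <- function(path) {
  m <- data.table::fread(path, sep = "\t", data.table = FALSE)
  stopifnot(all(c("sample_id", "cohort", "path") %in% names(m)))
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Write / read a genotype table TSV
#'
#' @param table Long genotype table.
#' @param path TSV path.
#' @export
write_genotypes <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = TRUE,
                         na.strings = c("NA", ""))
  x$genotype <- as.character(x$genotype)
  x
}

#' Write / read a signature as JSON
#'
#' @param signature A `caml_signature`.
#' @param path JSON path.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(
    list(label = signature$label,
         alpha = signature$alpha,
         fdr_rule = signature$fdr_rule,
         caml_genotypes = signature$caml_genotypes),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- as.data.frame(x$caml_genotypes, stringsAsFactors = FALSE)
  structure(list(label = x$label, caml_genotypes = members,
                 alpha = x$alpha, fdr_rule = x$fdr_rule),
            class = "caml_signature")
}

#' Read / write minimal BED (chrom, start, end[, name])
#'
#' @param path BED path (no header, tab-separated, 0-based half-open).
#' @return `data.frame` with `chrom`, `start`, `end` and, when present, a
#'   fourth column named `gene`.
#' @export
read_bed <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = FALSE,
                         data.table = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4L) names(x)[4L] <- "gene"
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

#' @rdname read_bed
#' @param track `data.frame` with `chrom`, `start`, `end` and optional
#'   `gene`.
#' @export
write_bed <- function(track, path) {
  cols <- intersect(c("chrom", "start", "end", "gene"), names(track))
  data.table::fwrite(track[, cols], path, sep = "\t", col.names = FALSE)
  invisible(path)
}
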