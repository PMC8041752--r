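#' Read a count matrix (MatrixMarket trio or dense TSV)
#'
#' A directory is read as a CellRanger-style trio (`matrix.mtx`,
#' `barcodes.tsv`, `features.tsv`; genes in rows, 1-based indices on disk).
#' A file is read as a dense TSV with gene identifiers in the first column
#' and barcodes as the header.
#'
#' @param path Directory containing the trio, or a TSV file.
#'
#' @return A `dgCMatrix`, genes x cells.
#' @export
read_count_matrix <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
    for (f in c(mtx, bc, ft)) {
      if (!file.exists(f)) abort(sprintf("missing file: %s", f))
    }
    m <- as_sparse(Matrix::readMM(mtx))
    barcodes <- readr::read_tsv(bc, col_names = FALSE, show_col_types = FALSE)[[1L]]
    features <- readr::read_tsv(ft, col_names = FALSE, show_col_types = FALSE)[[1L]]
    if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
      abort(sprintf(
        "dimension mismatch: matrix is %d x %d but %d features / %d barcodes.",
        nrow(m), ncol(m), length(features), length(barcodes)
      ))
    }
    dimnames(m) <- list(features, barcodes)
    return(m)
  }
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(tbl[-1L])
  rownames(m) <- tbl[[1L]]
  as_sparse(m)
}

#' Write a count matrix as a MatrixMarket trio
#'
#' @param counts Genes x cells matrix (coerced to sparse).
#' @param path Output directory (created if needed).
#'
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- as_sparse(counts)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(path, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(x = colnames(counts)),
                   file.path(path, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(x = rownames(counts)),
                   file.path(path, "features.tsv"), col_names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene identifiers. Empty lines are skipped; duplicate set names are
#' an error.
#'
#' @param path GMT file.
#'
#' @return Named list of character vectors; descriptions in attribute
#'   `"descriptions"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort(sprintf("malformed GMT line %d: need name, description and >= 1 gene.", bad[1L]))
  }
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate gene-set name: '%s'.", nms[duplicated(nms)][1L]))
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nms
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2L), nms)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional per-set descriptions (defaults to the set
#'   names).
#'
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(gene_sets)
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a TRRUST-style regulon table
#'
#' Four tab-separated columns: TF, target, mode (Activation / Repression /
#' Unknown) and references; a missing fourth column is tolerated.
#'
#' @param path TSV file (no header).
#' @param network Label recorded in the `network` column (defaults to the
#'   file name).
#'
#' @return Tibble with columns `tf`, `target`, `mode`, `ref`, `network`.
#' @export
read_regulons <- function(path, network = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    abort(sprintf("malformed regulon line %d: need at least TF and target.",
                  which(lengths(parts) < 2L)[1L]))
  }
  tibble::tibble(
    tf = vapply(parts, `[[`, "", 1L),
    target = vapply(parts, `[[`, "", 2L),
    mode = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "Unknown", ""),
    ref = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, ""),
    network = network %||% basename(path)
  )
}

#' Write a regulon table as TRRUST-style TSV
#'
#' @param regulons Tibble with `tf`, `target` and optionally `mode`, `ref`.
#' @param path Output file.
#'
#' @return `path`, invisibly.
#' @export
write_regulons <- function(regulons, path) {
  out <- tibble::tibble(
    tf = regulons$tf,
    target = regulons$target,
    mode = if ("mode" %in% names(regulons)) regulons$mode else "Unknown",
    ref = if ("ref" %in% names(regulons)) regulons$ref else "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

# write a tibble as TSV with a provenance header line
write_output_tsv <- function(tbl, path, config_hash, seed) {
  header <- sprintf("# cyclereg %s config=%s seed=%s",
                    as.character(utils::packageVersion("cyclereg")),
                    config_hash, seed)
  writeLines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
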