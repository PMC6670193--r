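delim_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Read a gene abundance table
#'
#' Delimited text (delimiter inferred from the extension: `.csv` comma,
#' otherwise tab) with a header row of sample ids and gene ids in the
#' first column. Transposed files (samples as rows) are accepted via
#' `orientation`.
#'
#' @param path File path.
#' @param orientation `"genes_rows"` (canonical) or `"samples_rows"`.
#' @param normalized Whether values are already relative abundances.
#' @return An [abundance_matrix()].
#' @export
read_abundance <- function(path, orientation = c("genes_rows", "samples_rows"),
                           normalized = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, sep = delim_for(path), header = TRUE,
                      row.names = 1, check.names = FALSE,
                      comment.char = "", quote = ""),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at row '%s', column '%s' in %s",
                 rownames(m)[bad[1]], colnames(m)[bad[2]], path),
         call. = FALSE)
  }
  if (orientation == "samples_rows") m <- t(m)
  abundance_matrix(m, normalized = normalized)
}

#' Write a gene abundance table
#'
#' @param m An [abundance_matrix()].
#' @param path Output path; delimiter inferred from the extension.
#' @export
write_abundance <- function(m, path) {
  utils::write.table(data.frame(gene = rownames(m), unclass(m),
                                check.names = FALSE),
                     path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write sample metadata (CSV: sample,subject,status,cohort)
#'
#' @param path File path.
#' @param abundance Optional [abundance_matrix()] to validate coverage
#'   against: every sample must have exactly one metadata row.
#' @return data.frame with columns `sample`, `subject`, `status`, `cohort`.
#' @export
read_metadata <- function(path, abundance = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "subject", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (anyNA(df$status) || !all(df$status %in% c(0, 1)))
    stop("disease status must be 0/1 and non-missing", call. = FALSE)
  if (!is.null(abundance)) {
    m <- setdiff(colnames(abundance), df$sample)
    if (length(m))
      stop("no metadata for sample(s): ",
           paste(utils::head(m, 3), collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_metadata
#' @param meta Metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a CAG catalog (CSV: gene,cag)
#'
#' @param path File path.
#' @return A [cag_catalog()].
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "cag") %in% names(df)))
    stop("catalog file needs columns gene,cag", call. = FALSE)
  cag_catalog(stats::setNames(df$cag, df$gene))
}

#' @rdname read_catalog
#' @param catalog A [cag_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(gene = names(catalog$gene), cag = unname(catalog$gene))
  df <- df[order(df$cag, df$gene), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write association results
#' (CSV: cag,estimate,se,p,q,model,discovered,validated)
#'
#' @param path File path.
#' @return data.frame of per-CAG association results.
#' @export
read_association <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(cag = "character"))
}

#' @rdname read_association
#' @param results data.frame from [fit_cag_association()], optionally with
#'   logical `discovered`/`validated` columns.
#' @export
write_association <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-cell detection table (CSV: cell,gene)
#'
#' @param path File path.
#' @return data.frame with columns `cell`, `gene`.
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell", "gene") %in% names(df)))
    stop("cell table needs columns cell,gene", call. = FALSE)
  df
}

#' Read an annotation table (CSV: gene,label)
#'
#' @param path File path.
#' @return data.frame with columns `gene`, `label`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "label") %in% names(df)))
    stop("annotation table needs columns gene,label", call. = FALSE)
  df
}

# --- grouped HDF5 results store --------------------------------------------

#' Persist pipeline outputs in one hierarchical HDF5 store
#'
#' Writes the supplied components under the groups `abund`, `cags`,
#' `stats`, and `metadata` of a single HDF5 file. A `complete` marker is
#' written last; [read_results_store()] refuses files without it, so an
#' interrupted write is detected rather than silently read as partial
#' data.
#'
#' @param path Output `.h5` path (overwritten).
#' @param abundance Optional [abundance_matrix()].
#' @param catalog Optional [cag_catalog()].
#' @param stats Optional association results data.frame.
#' @param metadata Optional sample metadata data.frame.
#' @return `path`, invisibly.
#' @export
write_results_store <- function(path, abundance = NULL, catalog = NULL,
                                stats = NULL, metadata = NULL) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (!is.null(abundance)) {
    rhdf5::h5createGroup(path, "abund")
    rhdf5::h5write(unclass(abundance), path, "abund/values")
    rhdf5::h5write(rownames(abundance), path, "abund/genes")
    rhdf5::h5write(colnames(abundance), path, "abund/samples")
    rhdf5::h5write(as.integer(is_normalized(abundance)), path,
                   "abund/normalized")
  }
  if (!is.null(catalog)) {
    rhdf5::h5createGroup(path, "cags")
    rhdf5::h5write(names(catalog$gene), path, "cags/gene")
    rhdf5::h5write(unname(catalog$gene), path, "cags/cag")
  }
  if (!is.null(stats)) rhdf5::h5write(stats, path, "stats")
  if (!is.null(metadata)) rhdf5::h5write(metadata, path, "metadata")
  rhdf5::h5write(1L, path, "complete")
  invisible(path)
}

#' @rdname write_results_store
#' @return For `read_results_store()`: list with any of `abundance`,
#'   `catalog`, `stats`, `metadata`.
#' @export
read_results_store <- function(path) {
  if (!file.exists(path)) stop("store not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- tryCatch(rhdf5::h5ls(path, recursive = FALSE)$name,
                       error = function(e)
                         stop("unreadable or corrupted store: ", path,
                              call. = FALSE))
  if (!"complete" %in% contents)
    stop("store is marked invalid (incomplete write): ", path, call. = FALSE)
  out <- list()
  if ("abund" %in% contents) {
    v <- rhdf5::h5read(path, "abund/values")
    dimnames(v) <- list(as.character(rhdf5::h5read(path, "abund/genes")),
                        as.character(rhdf5::h5read(path, "abund/samples")))
    out$abundance <- abundance_matrix(
      v, normalized = rhdf5::h5read(path, "abund/normalized") == 1L)
  }
  if ("cags" %in% contents)
    out$catalog <- cag_catalog(stats::setNames(
      as.integer(rhdf5::h5read(path, "cags/cag")),
      as.character(rhdf5::h5read(path, "cags/gene"))))
  if ("stats" %in% contents) {
    st <- rhdf5::h5read(path, "stats")
    st[] <- lapply(st, function(x) {
      if (is.raw(x)) as.logical(x) else as.vector(x)   # drop 1-d dims
    })
    out$stats <- st
  }
  if ("metadata" %in% contents) out$metadata <- rhdf5::h5read(path, "metadata")
  out
}
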