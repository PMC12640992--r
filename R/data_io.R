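# Readers/writers for the package's external formats: expression matrices
# (TSV/CSV or MatrixMarket triplets), survival tables, GMT gene sets, and
# the composite cell-death gene set with overlap bookkeeping.
#
# The canonical in-memory form of an expression matrix is a plain numeric
# matrix, genes in rows, samples in columns, with unique rownames/colnames.
# Missing or non-numeric cells are load errors, never silent fills.

#' Validate an expression matrix
#'
#' Checks the canonical genes-by-samples contract: numeric matrix, finite
#' throughout, unique non-empty gene and sample identifiers.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and sample colnames")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite value at gene '", rownames(x)[bad[1L]], "', sample '",
         colnames(x)[bad[2L]], "'")
  }
  invisible(x)
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Load an expression matrix
#'
#' Reads a delimited text matrix (TSV/CSV with a header row and an
#' identifier column) or a MatrixMarket `.mtx` triplet with sidecar row/
#' column name files, and returns it in canonical genes-by-samples
#' orientation regardless of the on-disk orientation. Identifiers are
#' preserved verbatim and matched case-sensitively.
#'
#' @param path file path (`.tsv`/`.txt`/`.csv`, or `.mtx`).
#' @param orientation `"genes_by_samples"` (default) or
#'   `"samples_by_genes"`: how the file on disk is laid out.
#' @param rownames_file,colnames_file for `.mtx` input, one-identifier-per-
#'   line sidecar files; default `<path minus .mtx>_rows.txt` / `_cols.txt`.
#' @return A validated numeric matrix, genes in rows.
#' @export
load_expression <- function(path,
                            orientation = c("genes_by_samples",
                                            "samples_by_genes"),
                            rownames_file = NULL, colnames_file = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)

  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    rownames_file <- rownames_file %||% paste0(stem, "_rows.txt")
    colnames_file <- colnames_file %||% paste0(stem, "_cols.txt")
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rownames_file)
    cn <- readLines(colnames_file)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("MTX dimensions do not match sidecar name files")
    dimnames(m) <- list(rn, cn)
  } else {
    raw <- read.delim(path, sep = .delim_for(path), header = TRUE,
                      check.names = FALSE, colClasses = "character",
                      row.names = NULL)
    if (ncol(raw) < 2L) stop("expected an identifier column plus data columns")
    ids <- raw[[1L]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop("duplicate identifiers in '", path, "': ",
           paste(dup, collapse = ", "))
    body <- raw[, -1L, drop = FALSE]
    m <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
    for (j in seq_len(ncol(body))) {
      v <- suppressWarnings(as.numeric(body[[j]]))
      bad <- which(is.na(v))
      if (length(bad))
        stop("non-numeric or missing cell at row '", ids[bad[1L]],
             "', column '", colnames(body)[j], "' (value: '",
             body[[j]][bad[1L]], "')")
      m[, j] <- v
    }
  }
  if (orientation == "samples_by_genes") m <- t(m)
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param x validated genes-by-samples matrix.
#' @param path output path; the first column is named `gene_id`.
#' @return `path`, invisibly.
#' @export
save_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load and validate a survival table
#'
#' Expects a TSV with columns `sample_id`, `time`, `event`. Times must be
#' strictly positive and events coded 0 (censored) / 1 (event); violations
#' are errors naming the offending sample.
#'
#' @param path TSV file path.
#' @return A `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
load_survival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  validate_survival(df)
}

#' Validate a survival table
#'
#' @param df data.frame with columns `sample_id`, `time`, `event`.
#' @return The validated data.frame (invisibly usable), columns coerced.
#' @export
validate_survival <- function(df) {
  need <- c("sample_id", "time", "event")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col))
    stop("survival table is missing column(s): ",
         paste(missing_col, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample identifiers: ", paste(dup, collapse = ", "))
  df$time <- as.numeric(df$time)
  bad_t <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_t))
    stop("non-positive or missing time for sample(s): ",
         paste(df$sample_id[bad_t], collapse = ", "))
  ev <- suppressWarnings(as.numeric(df$event))
  bad_e <- which(!(ev %in% c(0, 1)))
  if (length(bad_e))
    stop("event must be 0 or 1; offending sample(s): ",
         paste(df$sample_id[bad_e], collapse = ", "))
  df$event <- as.integer(ev)
  df[, need]
}

#' Write a survival table as TSV
#' @param df survival data.frame (`sample_id`, `time`, `event`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_survival <- function(df, path) {
  df <- validate_survival(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard tab-delimited format: set name, description, then member
#' symbols. Symbols are preserved verbatim (case-sensitive).
#'
#' @param path GMT file path.
#' @return Named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ", ln)
    nm <- parts[1L]
    if (nm %in% names(sets)) stop("duplicate pathway name: ", nm)
    sets[[nm]] <- parts[-(1:2)]
  }
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description one description per set (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a composite gene set from overlapping pathway lists
#'
#' Programmed-cell-death pathway lists (e.g. pyroptosis, apoptosis,
#' necroptosis) share regulators; this merges them either by dropping every
#' symbol claimed by two or more pathways (`drop_shared`) or by keeping the
#' full union with per-gene provenance recording which pathways name it
#' (`keep_annotated`, the default). Output gene order is lexicographic.
#'
#' @param lists named list of character vectors, pathway name to gene list.
#' @param overlap_mode `"keep_annotated"` or `"drop_shared"`.
#' @return An object of class `gene_set_collection`: list with elements
#'   `genes` (sorted unique output genes), `sets` (the per-pathway lists
#'   restricted to output genes), `provenance` (named list: gene ->
#'   pathways naming it), `mode`.
#' @export
build_composite_geneset <- function(lists,
                                    overlap_mode = c("keep_annotated",
                                                     "drop_shared")) {
  overlap_mode <- match.arg(overlap_mode)
  if (!length(lists) || all(!lengths(lists)))
    stop("all pathway lists are empty")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    stop("pathway lists must be named")
  if (anyDuplicated(names(lists)))
    stop("pathway names must be unique")
  lists <- lapply(lists, function(g) unique(as.character(g)))

  all_genes <- sort(unique(unlist(lists, use.names = FALSE)))
  prov <- lapply(setNames(all_genes, all_genes), function(g)
    names(lists)[vapply(lists, function(s) g %in% s, logical(1L))])
  multiplicity <- lengths(prov)

  keep <- if (overlap_mode == "drop_shared") all_genes[multiplicity == 1L]
          else all_genes
  structure(list(
    genes = keep,
    sets = lapply(lists, function(s) sort(intersect(s, keep))),
    provenance = prov[keep],
    mode = overlap_mode
  ), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Composite gene set (", x$mode, "): ", length(x$genes), " genes from ",
      length(x$sets), " pathways\n", sep = "")
  shared <- sum(lengths(x$provenance) > 1L)
  cat("  genes named by >1 pathway: ", shared, "\n", sep = "")
  invisible(x)
}

#' Write cluster labels as TSV
#' @param df data.frame whose first column is `sample_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(df, path) {
  stopifnot(is.data.frame(df), "sample_id" %in% names(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
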