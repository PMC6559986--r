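#' gliastate: astrocyte reactive-state scoring and subgroup discovery
#'
#' Orientation convention used throughout: expression and count matrices are
#' genes-as-rows, samples-as-columns. No function transposes silently.
#'
#' @keywords internal
"_PACKAGE"

## ---- count matrix container ------------------------------------------------

#' Construct a count matrix container
#'
#' Raw gene x sample integer counts plus per-sample metadata. Genes are rows,
#' samples are columns, everywhere in this package.
#'
#' @param counts integer matrix, genes x samples, with unique row and column
#'   names. Entries must be finite, integer-valued and non-negative.
#' @param sample_meta optional `data.frame` with one row per sample, aligned
#'   with `colnames(counts)`. Must carry a `condition` column before
#'   differential expression or clustering is run on the object.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   and `sample_meta`.
#' @export
count_matrix <- function(counts, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at gene '%s', sample '%s' (must be a finite non-negative integer)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(row.names = colnames(counts))
  } else {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != ncol(counts))
      stop("sample_meta must have one row per sample")
    if (!is.null(rownames(sample_meta)) &&
        !all(rownames(sample_meta) == as.character(seq_len(nrow(sample_meta)))) &&
        !identical(rownames(sample_meta), colnames(counts)))
      stop("sample_meta row names disagree with sample IDs")
    rownames(sample_meta) <- colnames(counts)
  }
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (ncol(x$sample_meta))
    cat("sample_meta columns:", paste(names(x$sample_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV, CSV or MatrixMarket triplet
#'
#' TSV/CSV layout: header row of sample IDs, first column of gene IDs. The
#' `mtx` format expects a MatrixMarket coordinate file plus sidecar files
#' (one ID per line) for genes (rows) and samples (columns).
#'
#' @param path file path (the `.mtx` file for `format = "mtx"`).
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`.
#' @param genes_file,samples_file sidecar ID files, required for `"mtx"`.
#' @param sample_meta optional metadata `data.frame` (see [count_matrix()]).
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("tsv", "csv", "mtx"),
                              genes_file = NULL, samples_file = NULL,
                              sample_meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, colClasses = NA,
                            stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                     !is.na(m), arr.ind = TRUE)
      if (nrow(bad))
        stop(sprintf("non-numeric entry at row %d, column '%s'",
                     bad[1, 1], colnames(m)[bad[1, 2]]))
      storage.mode(m) <- "double"
    }
    rownames(m) <- genes
  } else {
    if (is.null(genes_file) || is.null(samples_file))
      stop("mtx format requires genes_file and samples_file")
    if (!file.exists(genes_file)) stop("file not found: ", genes_file)
    if (!file.exists(samples_file)) stop("file not found: ", samples_file)
    mm <- as.matrix(Matrix::readMM(path))
    rownames(mm) <- readLines(genes_file)
    colnames(mm) <- readLines(samples_file)
    m <- mm
  }
  count_matrix(m, sample_meta = sample_meta)
}

#' Write a count matrix
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"mtx"` (the latter writes sidecar
#'   `<path>.genes` / `<path>.samples` ID files).
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "count_matrix"))
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene = rownames(x$counts), x$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(rownames(x$counts), paste0(path, ".genes"))
    writeLines(colnames(x$counts), paste0(path, ".samples"))
  }
  invisible(path)
}

## ---- gene sets (GMT) -------------------------------------------------------

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then one or more gene symbols.
#' Duplicated genes within a set are removed with a warning; a line with
#' fewer than three fields, a duplicated set name, or a set that is empty
#' after deduplication is an error naming the offending line.
#'
#' @param path GMT file path.
#' @return a named list of character vectors of class `gene_set_collection`;
#'   set descriptions are kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(f)))
    nm <- f[1]
    if (nm %in% names(sets))
      stop(sprintf("GMT line %d: duplicate set name '%s'", i, nm))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    ug <- unique(genes)
    if (length(ug) < length(genes))
      warning(sprintf("[read_gmt] set '%s': %d duplicated gene(s) removed",
                      nm, length(genes) - length(ug)))
    if (!length(ug))
      stop(sprintf("GMT line %d: set '%s' empty after deduplication", i, nm))
    sets[[nm]] <- ug
    descs[nm] <- f[2]
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors (or `gene_set_collection`).
#' @param path output path.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- generic tabular results ----------------------------------------------

#' Write a result table as TSV
#'
#' All tabular pipeline outputs are TSV with a header row; values round-trip
#' through [read_results()] at full stored precision.
#'
#' @param x a `data.frame`.
#' @param path output path; the parent directory must exist.
#' @export
write_results <- function(x, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV result table written by [write_results()]
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

## ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' A single nested list carrying the seed and per-stage parameters. Unknown
#' keys in a user file are errors (typo protection); known keys override the
#' defaults.
#'
#' @return nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    normalize = list(pseudocount = 1),
    de = list(alpha_floor = 1e-8, pseudocount = 1),
    rankshift = list(top_n = 30L, highlight_fold = 12),
    cluster = list(k_min = 2L, k_max = 6L, top_genes = 200L, n_resample = 100L,
                   subsample_frac = 0.8, distance = "euclidean"),
    markers = list(n_delta = 30L, cv_folds = 10L, glm_cap = 10),
    gsea = list(weight_p = 1, n_perm = 1000L),
    astro_state = list(min_genes = 10L, margin = 0.25, z_score = TRUE),
    facs = list(cofactor = 150, perplexity = 30, overdispersion = "var_mean")
  ), class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file; keys must be a subset of [default_config()] keys.
#' @return merged `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge1 <- function(base, user, prefix = "") {
    for (nm in names(user)) {
      key <- paste0(prefix, nm)
      if (!nm %in% names(base))
        stop("unknown config key: ", key)
      if (is.list(base[[nm]])) {
        if (!is.list(user[[nm]]))
          stop("config key ", key, " must be a mapping")
        base[[nm]] <- merge1(base[[nm]], user[[nm]], paste0(key, "."))
      } else {
        base[[nm]] <- user[[nm]]
      }
    }
    base
  }
  structure(merge1(unclass(base), user), class = "run_config")
}

#' Stage-tagged logging to stderr
#'
#' Results go to files/stdout only; all progress messages go to stderr with
#' a `[stage]` tag.
#'
#' @param stage short stage tag.
#' @param ... passed to [sprintf()] (first element is the format string).
#' @export
log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}

#' Cohort positive fraction as a printed percentage
#'
#' Summarizes a marker-positivity count (e.g. CD274-positive patients) as a
#' percentage, truncated (not rounded) to the requested number of decimals,
#' matching the convention of clinical cohort reporting.
#'
#' @param n_positive,n_total non-negative counts, `n_positive <= n_total`.
#' @param digits decimals kept after truncation (default 1).
#' @return percentage in `[0, 100]`.
#' @examples
#' percent_positive(42, 43) # 97.6
#' @export
percent_positive <- function(n_positive, n_total, digits = 1) {
  stopifnot(n_total > 0, n_positive >= 0, n_positive <= n_total)
  f <- 10^digits
  trunc(n_positive / n_total * 100 * f) / f
}
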