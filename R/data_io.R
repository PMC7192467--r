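# Reading and writing count matrices and sample metadata, offsets,
# simple dataset descriptors.

#' Read a feature-by-sample count matrix
#'
#' Two plain-text formats are supported.  \code{"tsv"}: tab-separated with
#' a header row of sample ids and feature ids in the first column.
#' \code{"mtx"}: MatrixMarket sparse format with feature and sample ids in
#' sidecar files (one id per line), by default \code{<path>.rows} and
#' \code{<path>.cols}.
#'
#' Entries must be finite non-negative integers; the first offending cell
#' is named in the error.
#'
#' @param path file to read.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param featureIdFile,sampleIdFile sidecar id files for \code{"mtx"}.
#' @return Integer matrix with feature row names and sample column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCounts(matrix(0:3, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2"))), tf)
#' readCounts(tf)
#' @export
readCounts <- function(path, format = c("tsv", "mtx"),
                       featureIdFile = paste0(path, ".rows"),
                       sampleIdFile = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                            colClasses = "character", quote = "", comment.char = "")
    if (ncol(df) < 2) stop("malformed header: need a feature id column and at least one sample column")
    ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage <- matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(storage) | !is.finite(storage) | storage < 0 | storage != floor(storage))
    if (length(bad)) {
      i <- ((bad[1] - 1) %% nrow(m)) + 1
      j <- ((bad[1] - 1) %/% nrow(m)) + 1
      stop(sprintf("invalid count '%s' at feature '%s', sample '%s'",
                   m[i, j], ids[i], colnames(m)[j]))
    }
    counts <- storage
    dimnames(counts) <- list(ids, colnames(m))
  } else {
    sm <- Matrix::readMM(path)
    counts <- as.matrix(sm)
    bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts))
    if (length(bad)) {
      i <- ((bad[1] - 1) %% nrow(counts)) + 1
      j <- ((bad[1] - 1) %/% nrow(counts)) + 1
      stop(sprintf("invalid count at row %d, column %d of '%s'", i, j, path))
    }
    rn <- if (file.exists(featureIdFile)) readLines(featureIdFile) else paste0("feature", seq_len(nrow(counts)))
    cn <- if (file.exists(sampleIdFile)) readLines(sampleIdFile) else paste0("sample", seq_len(ncol(counts)))
    if (length(rn) != nrow(counts) || length(cn) != ncol(counts))
      stop("sidecar id files do not match the matrix dimensions")
    dimnames(counts) <- list(rn, cn)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  storage.mode(counts) <- "integer"
  counts
}

#' Write a count matrix as tab-separated text
#'
#' The canonical on-disk format: header row of sample ids, feature ids in
#' the first column.  \code{readCounts(writeCounts(x))} round-trips
#' bit-identically.
#'
#' @param counts integer matrix with dimnames.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns \code{sample_id}, a grouping column (default
#' \code{group}) and optionally \code{library_size}.
#'
#' @param path file to read.
#' @return data.frame with row names set to sample ids.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("metadata must contain a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  rownames(df) <- df$sample_id
  df
}

#' Construct an NBCountSet
#'
#' Joins a count matrix with sample metadata into the validated container
#' used by all tests in the package.  The grouping column is converted to a
#' two-level factor whose \emph{first observed} level is the reference
#' (coded 0 in the regression dummy), making the coding deterministic.
#' Library sizes default to column sums of the full matrix (computed before
#' any filtering); a \code{library_size} metadata column overrides them.
#'
#' @param counts integer matrix (features x samples) with dimnames.
#' @param meta data.frame of sample metadata with row names or a
#'   \code{sample_id} column matching \code{colnames(counts)}.  May be
#'   omitted if \code{group} is a vector.
#' @param group name of the grouping column in \code{meta}, or a vector of
#'   group labels aligned with the samples.
#' @return An \linkS4class{NBCountSet}.
#' @examples
#' counts <- matrix(rpois(40, 5), 4, 10,
#'                  dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
#' cs <- NBCountSet(counts, group = rep(c("a", "b"), each = 5))
#' libSizes(cs)
#' @export
NBCountSet <- function(counts, meta = NULL, group = "group") {
  if (is.null(dim(counts))) stop("'counts' must be a matrix")
  if (length(group) > 1 || is.null(meta)) {
    g <- group
    if (length(g) != ncol(counts)) stop("group vector length must match the number of samples")
    meta <- data.frame(row.names = colnames(counts))
  } else {
    if (!is.null(meta$sample_id)) rownames(meta) <- meta$sample_id
    missing <- setdiff(colnames(counts), rownames(meta))
    if (length(missing))
      stop("samples without metadata: ", paste(missing, collapse = ", "))
    meta <- meta[colnames(counts), , drop = FALSE]
    if (!group %in% colnames(meta)) stop("grouping column '", group, "' not in metadata")
    g <- meta[[group]]
  }
  g <- factor(g, levels = unique(as.character(g)))
  if (nlevels(g) != 2) stop("grouping variable must have exactly 2 observed levels")
  ls <- meta$library_size
  if (is.null(ls)) {
    ls <- colSums(counts)
    if (any(ls <= 0))
      stop("samples with zero library size: ",
           paste(colnames(counts)[ls <= 0], collapse = ", "),
           " (remove them explicitly)")
  }
  cd <- S4Vectors::DataFrame(meta)
  cd$group <- g
  cd$libSize <- as.numeric(ls)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  methods::new("NBCountSet", se)
}

#' @describeIn NBCountSet counts accessor (features x samples integer matrix).
#' @param object an \code{NBCountSet}.
#' @export
setMethod("counts", "NBCountSet", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname groupFactor
#' @export
setMethod("groupFactor", "NBCountSet", function(object) {
  SummarizedExperiment::colData(object)$group
})

#' @rdname groupFactor
#' @export
setMethod("groupCodes", "NBCountSet", function(object) {
  g <- as.integer(groupFactor(object)) - 1L
  names(g) <- colnames(object)
  g
})

#' @rdname libSizes
#' @export
setMethod("libSizes", "NBCountSet", function(object) {
  ls <- SummarizedExperiment::colData(object)$libSize
  names(ls) <- colnames(object)
  ls
})

#' @rdname computeOffsets
#' @export
setMethod("computeOffsets", "NBCountSet", function(object) {
  ls <- libSizes(object)
  if (any(ls <= 0)) stop("library sizes must be positive")
  log(ls)
})

#' @rdname zeroFreeProportion
#' @export
setMethod("zeroFreeProportion", "matrix", function(object) {
  if (nrow(object) < 1) stop("empty count matrix")
  mean(apply(object > 0, 1, all))
})

#' @rdname zeroFreeProportion
#' @export
setMethod("zeroFreeProportion", "NBCountSet", function(object) {
  zeroFreeProportion(counts(object))
})

setMethod("show", "NBCountSet", function(object) {
  cat("NBCountSet:", nrow(object), "features x", ncol(object), "samples\n")
  tab <- table(groupFactor(object))
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  library sizes: median", format(stats::median(libSizes(object)), digits = 4),
      " range", paste(format(range(libSizes(object)), digits = 4), collapse = " - "), "\n")
  cat("  zero-free features:", format(zeroFreeProportion(object), digits = 3), "\n")
})
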