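#' Feature-set specification
#'
#' Describes one block of the feature table: a feature type (patch volume or
#' patch mean thickness), the parcellation scale that produced it (target
#' members per patch, or `"ROI"` for unparcellated region features) and its
#' dimension (number of columns).
#'
#' @param feature_type `"volume"` or `"thickness"`.
#' @param scale one of `"ROI"`, `"500"`, `"1000"`, `"2000"` (numeric accepted).
#' @param dimension positive integer, number of features in the block.
#' @return An object of class `feature_set_spec`.
#' @export
feature_set_spec <- function(feature_type, scale, dimension) {
  feature_type <- match.arg(feature_type, c("volume", "thickness"))
  scale <- as.character(scale)
  scale <- match.arg(scale, c("ROI", "500", "1000", "2000"))
  dimension <- as.integer(dimension)
  stopifnot(length(dimension) == 1L, dimension >= 1L)
  structure(list(feature_type = feature_type, scale = scale,
                 dimension = dimension),
            class = "feature_set_spec")
}

#' Default six-block feature-set configuration
#'
#' The canonical configuration: gray-matter patch volumes at scales
#' 500/1000/2000 voxels per patch (1488, 705 and 343 patches) and cortical
#' patch thicknesses at 500/1000/2000 vertices per patch (527, 255 and 131
#' patches), 3449 features in total.
#'
#' @return list of six `feature_set_spec` objects in canonical block order.
#' @export
default_feature_sets <- function() {
  list(
    feature_set_spec("volume",    500, 1488),
    feature_set_spec("volume",   1000,  705),
    feature_set_spec("volume",   2000,  343),
    feature_set_spec("thickness", 500,  527),
    feature_set_spec("thickness", 1000, 255),
    feature_set_spec("thickness", 2000, 131)
  )
}

#' Small six-block configuration for examples and simulation at desk scale
#'
#' Same block structure as [default_feature_sets()] with reduced dimensions,
#' keeping the 2:1 ratio between successive scales and the roughly 3:1 ratio
#' between volume and thickness blocks.
#'
#' @param base dimension of the finest volume block; remaining blocks scale
#'   proportionally.
#' @return list of six `feature_set_spec` objects.
#' @export
reduced_feature_sets <- function(base = 60L) {
  base <- as.integer(base)
  stopifnot(base >= 8L)
  list(
    feature_set_spec("volume",    500, base),
    feature_set_spec("volume",   1000, max(1L, base %/% 2L)),
    feature_set_spec("volume",   2000, max(1L, base %/% 4L)),
    feature_set_spec("thickness", 500, max(1L, round(base * 527 / 1488))),
    feature_set_spec("thickness", 1000, max(1L, round(base * 255 / 1488))),
    feature_set_spec("thickness", 2000, max(1L, round(base * 131 / 1488)))
  )
}

set_block_table <- function(sets) {
  dims <- vapply(sets, function(s) s$dimension, integer(1))
  data.frame(
    feature_type = vapply(sets, function(s) s$feature_type, character(1)),
    scale = vapply(sets, function(s) s$scale, character(1)),
    dim = dims,
    start = cumsum(c(1L, dims[-length(dims)])),
    end = cumsum(dims),
    stringsAsFactors = FALSE
  )
}

default_block_colnames <- function(sets) {
  # naming convention: <type>_<scale>_<roiId>_<patchIdx>; when features are
  # generated without an atlas the roi id is 0 and the patch index enumerates
  # the block.
  unlist(lapply(sets, function(s) {
    sprintf("%s_%s_0_%d", s$feature_type, s$scale, seq_len(s$dimension) - 1L)
  }), use.names = FALSE)
}

#' Construct a feature table
#'
#' The central container of the pipeline: one row per (subject, visit) scan,
#' columns partitioned into ordered feature-set blocks. Block order is fixed
#' as volume 500/1000/2000 then thickness 500/1000/2000 and is preserved
#' bit-exactly through I/O round trips.
#'
#' @param ids data.frame with columns `subject_id`, `visit_id` (one row per scan).
#' @param X numeric matrix, `nrow(ids)` rows; column count must equal the sum
#'   of block dimensions. Column names are generated from the naming
#'   convention `<type>_<scale>_<roiId>_<patchIdx>` when absent.
#' @param sets list of [feature_set_spec()] blocks, in canonical order.
#' @param kind `"raw"` (mm^3 / mm) or `"wscore"` (unitless standardized residuals).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(ids, X, sets, kind = c("raw", "wscore")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(ids), all(c("subject_id", "visit_id") %in% names(ids)))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  blocks <- set_block_table(sets)
  total <- sum(blocks$dim)
  if (ncol(X) != total)
    stop(sprintf("feature matrix has %d columns but the spec requires %d",
                 ncol(X), total))
  if (nrow(X) != nrow(ids))
    stop("ids and feature matrix disagree on the number of rows")
  if (is.null(colnames(X))) colnames(X) <- default_block_colnames(sets)
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("missing values in feature columns: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(ids = ids[, c("subject_id", "visit_id")], X = X,
                 sets = sets, blocks = blocks, kind = kind),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d scans x %d features (%s)\n",
              nrow(x$X), ncol(x$X), x$kind))
  b <- x$blocks
  for (i in seq_len(nrow(b)))
    cat(sprintf("  block %d: %s @ scale %s, %d features\n",
                i, b$feature_type[i], b$scale[i], b$dim[i]))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$X)

#' Extract the columns of one feature block
#'
#' @param table a [feature_table()].
#' @param i block index (1-6 in the default configuration).
#' @return numeric matrix of that block's columns.
#' @export
feature_block <- function(table, i) {
  b <- table$blocks
  stopifnot(i >= 1, i <= nrow(b))
  table$X[, b$start[i]:b$end[i], drop = FALSE]
}

#' Stable digest of the column layout
#'
#' Used by tests to assert that block ordering and within-block column
#' ordering survive every operation.
#'
#' @param table a [feature_table()].
#' @return character scalar.
#' @export
column_digest <- function(table) {
  s <- paste(colnames(table$X), collapse = "|")
  # simple polynomial rolling hash; no digest dependency
  v <- utf8ToInt(s)
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 512))) {
    for (x in chunk) h <- (h * 131 + x) %% 2147483647
  }
  sprintf("%d:%d", nchar(s), h)
}

#' Write a feature table to CSV
#'
#' Comma-delimited, UTF-8, header row, full float precision: re-reading with
#' [read_feature_table()] reproduces every value exactly.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.table::data.table(subject_id = table$ids$subject_id,
                               visit_id = table$ids$visit_id)
  if (nrow(table$X) > 0) {
    # %.17g guarantees a binary-exact double round trip
    C <- data.table::as.data.table(
      matrix(sprintf("%.17g", table$X), nrow(table$X),
             dimnames = dimnames(table$X)))
    df <- cbind(df, C)
  } else {
    for (nm in colnames(table$X)) df[[nm]] <- numeric(0)
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path with `subject_id`, `visit_id` and one column per
#'   feature, ordered by block.
#' @param sets list of [feature_set_spec()]; dimensions are validated against
#'   the file.
#' @param kind `"raw"` or `"wscore"`.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, sets = default_feature_sets(),
                               kind = c("raw", "wscore")) {
  kind <- match.arg(kind)
  df <- data.table::fread(path, header = TRUE)
  for (idc in c("subject_id", "visit_id"))
    if (!idc %in% names(df)) stop("missing id column: ", idc)
  feat <- setdiff(names(df), c("subject_id", "visit_id"))
  total <- sum(vapply(sets, function(s) s$dimension, integer(1)))
  if (length(feat) != total)
    stop(sprintf("file has %d feature columns but the spec requires %d",
                 length(feat), total))
  Xdf <- df[, feat, with = FALSE]
  if (nrow(Xdf) > 0) {
    nonnum <- feat[!vapply(Xdf, is.numeric, logical(1))]
    if (length(nonnum))
      stop("non-numeric feature column(s): ", paste(utils::head(nonnum, 5), collapse = ", "))
  }
  X <- matrix(numeric(0), 0, length(feat), dimnames = list(NULL, feat))
  if (nrow(Xdf) > 0) X <- as.matrix(Xdf)
  ids <- data.frame(subject_id = as.character(df$subject_id),
                    visit_id = as.character(df$visit_id),
                    stringsAsFactors = FALSE)
  feature_table(ids, X, sets, kind = kind)
}
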