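#' Write / read dissimilarity-vector tables
#'
#' Tab-delimited text with one torus point per row; the header names the
#' leaf pairs (\code{"i|j"}), and an optional \code{label} column carries
#' class labels.
#'
#' @param x Matrix of row points.
#' @param path File path.
#' @param y Optional binary labels written as a \code{label} column.
#' @return \code{path} invisibly (writer); a list with \code{x} and
#'   \code{y} (\code{NULL} when no label column) for the reader.
#' @export
write_points <- function(x, path, y = NULL) {
  X <- .point_matrix(x)
  if (is.null(colnames(X))) {
    m <- .m_from_e(ncol(X))
    colnames(X) <- if (!is.na(m)) leaf_pairs(paste0("t", seq_len(m)))
                   else paste0("x", seq_len(ncol(X)))
  }
  df <- as.data.frame(X)
  if (!is.null(y)) df$label <- .binary_labels(y)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  y <- NULL
  if ("label" %in% names(df)) {
    y <- .binary_labels(df$label)
    df$label <- NULL
  }
  list(x = as.matrix(df), y = y)
}

#' Serialize / restore a fitted model as JSON
#'
#' Stores the model form and the fitted parameters (centers, scales, rate
#' and threshold, or baseline coefficients) with enough metadata for
#' [predict.tlr()] to work after restoring.
#'
#' @param object A fitted [tlr()] model.
#' @param path JSON file path.
#' @return \code{path} invisibly (writer); a \code{"tlr"} object (reader).
#' @export
write_tlr <- function(object, path) {
  if (!inherits(object, "tlr")) stop("'object' must be a tlr fit")
  keep <- c("model", "method", "n", "e", "pair_names", "center0", "center1",
            "sigma", "center", "rate", "threshold", "coefficients",
            "label_swap", "separation", "logLik")
  payload <- object[intersect(keep, names(object))]
  payload$package_version <- as.character(utils::packageVersion("troplr"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tlr
#' @export
read_tlr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$package_version <- NULL
  for (fld in c("center0", "center1", "center", "coefficients"))
    if (!is.null(payload[[fld]])) payload[[fld]] <- unlist(payload[[fld]])
  payload$fitted <- NULL
  structure(payload, class = "tlr")
}
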