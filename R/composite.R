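#' Principal-component composite index
#'
#' Builds a one-component composite (e.g. a socio-economic status score)
#' from a unit x indicator table: indicators are z-scored, the first
#' principal component of their correlation matrix is extracted, loadings
#' are reported on the correlation scale (eigenvector times the square
#' root of the eigenvalue, i.e. indicator-component correlations), the
#' percent of variance is the first eigenvalue's share of total
#' standardized variance, and unit scores are computed by the regression
#' method (least-squares projection onto the component, normalized to unit
#' variance).
#'
#' The component's sign is arbitrary in the eigendecomposition; it is
#' oriented so the loading of \code{positive_pole} (default: the first
#' indicator) is positive, matching the convention of coding the index so
#' that e.g. income loads positively and poverty negatively.
#'
#' @param indicators data.frame or matrix of unit-level indicators
#'   (>= 2 columns, >= 3 rows, no missing values).  A \code{unit_id}
#'   column, if present, is used for score labels.
#' @param positive_pole name of the indicator whose loading is forced
#'   positive.
#' @return A list of class \code{"composite_index"}: \code{loadings}
#'   (named, in [-1, 1]), \code{pct_variance} (percent of total
#'   standardized variance on component 1), \code{scores} (per-unit,
#'   mean 0, sd 1), \code{eigenvalues}.
#' @export
pca_composite <- function(indicators, positive_pole = NULL) {
  ids <- NULL
  if (is.data.frame(indicators) && "unit_id" %in% names(indicators)) {
    ids <- as.character(indicators$unit_id)
    indicators <- indicators[, setdiff(names(indicators), "unit_id"),
                             drop = FALSE]
  }
  X <- as.matrix(indicators)
  if (ncol(X) < 2) stop("need at least two indicators")
  if (nrow(X) < 3) stop("need at least three units")
  if (anyNA(X)) stop("indicators contain missing values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant indicator: ", colnames(X)[which(sds == 0)[1]])
  Z <- scale(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  l1 <- eig$values[1]
  if (is.null(positive_pole)) positive_pole <- colnames(X)[1]
  pole <- match(positive_pole, colnames(X))
  if (is.na(pole)) stop("positive_pole not among indicators: ", positive_pole)
  if (v1[pole] < 0) v1 <- -v1
  loadings <- v1 * sqrt(l1)
  # regression-method scores for a principal component reduce to the
  # standardized component scores Z v1 / sqrt(l1)
  scores <- as.numeric(Z %*% v1) / sqrt(l1)
  names(loadings) <- colnames(X)
  if (!is.null(ids)) names(scores) <- ids
  structure(list(loadings = loadings,
                 pct_variance = 100 * l1 / sum(eig$values),
                 scores = scores, eigenvalues = eig$values),
            class = "composite_index")
}

#' @export
print.composite_index <- function(x, ...) {
  cat(sprintf("<composite_index: component 1 carries %.2f%% of variance>\n",
              x$pct_variance))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Write composite-index outputs to CSV
#'
#' @param ci a \code{"composite_index"}.
#' @param loadings_path CSV for the loadings table (or NULL to skip).
#' @param scores_path CSV for per-unit scores (or NULL to skip).
#' @return \code{ci}, invisibly.
#' @export
write_composite <- function(ci, loadings_path = NULL, scores_path = NULL) {
  stopifnot(inherits(ci, "composite_index"))
  if (!is.null(loadings_path))
    utils::write.csv(data.frame(indicator = names(ci$loadings),
                                loading = unname(ci$loadings)),
                     loadings_path, row.names = FALSE)
  if (!is.null(scores_path))
    utils::write.csv(data.frame(unit_id = names(ci$scores) %||%
                                  seq_along(ci$scores),
                                score = unname(ci$scores)),
                     scores_path, row.names = FALSE)
  invisible(ci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
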