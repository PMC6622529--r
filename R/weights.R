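#' Spatial weights objects
#'
#' A weights matrix is stored in neighbor-list form: for each unit an
#' integer vector of neighbor indices and a parallel numeric vector of
#' weights.  \code{style} is \code{"binary"} (w_ij = 1 for neighbors) or
#' \code{"row_standardized"} (rows with at least one neighbor sum to 1).
#' Units with no neighbors (islands) keep empty rows and are listed in
#' \code{islands}.
#'
#' @param neighbours list of integer vectors (1-based indices).
#' @param weights list of numeric vectors parallel to \code{neighbours};
#'   defaults to binary weights.
#' @param ids character vector of unit ids (default seq indices).
#' @param style \code{"binary"} or \code{"row_standardized"}.
#' @return An object of class \code{"weights_matrix"}.
#' @export
weights_matrix <- function(neighbours, weights = NULL, ids = NULL,
                           style = "binary") {
  n <- length(neighbours)
  if (is.null(weights))
    weights <- lapply(neighbours, function(nb) rep(1, length(nb)))
  if (is.null(ids)) ids <- as.character(seq_len(n))
  stopifnot(length(weights) == n, length(ids) == n)
  for (i in seq_len(n)) {
    if (length(neighbours[[i]]) != length(weights[[i]]))
      stop("neighbour/weight length mismatch at unit ", ids[i])
    if (any(neighbours[[i]] == i)) stop("self-neighbor at unit ", ids[i])
  }
  islands <- ids[vapply(neighbours, length, integer(1)) == 0]
  structure(list(n = n, neighbours = neighbours, weights = weights,
                 ids = ids, style = style, islands = islands),
            class = "weights_matrix")
}

#' @export
print.weights_matrix <- function(x, ...) {
  nl <- vapply(x$neighbours, length, integer(1))
  cat(sprintf("<weights_matrix: n = %d, style = %s, avg links %.2f%s>\n",
              x$n, x$style, mean(nl),
              if (length(x$islands) > 0)
                paste0(", ", length(x$islands), " island(s)") else ""))
  invisible(x)
}

#' Contiguity-based spatial weights from polygons
#'
#' Two units are queen-contiguous when their boundaries share at least one
#' point and rook-contiguous when they share at least one boundary segment.
#' Detection works on snap-rounded ring vertices (queen: >= 1 shared vertex;
#' rook: >= 2 shared vertices), which is exact on lattices and on polygon
#' layers whose shared borders are identically noded.
#'
#' @param geo a [geography].
#' @param rule \code{"queen"} (default) or \code{"rook"}.
#' @param snap coordinate rounding tolerance for vertex matching
#'   (default 1e-8).
#' @param require_connected error when any unit has no neighbors
#'   (islands break spatial-lag models; the reference analysis dropped a
#'   disconnected city section for the same reason).  Default FALSE.
#' @return A binary [weights_matrix].
#' @export
contiguity_weights <- function(geo, rule = c("queen", "rook"), snap = 1e-8,
                               require_connected = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(geo, "geography"))
  n <- length(geo$unit_id)
  vkeys <- lapply(geo$unit_id, function(uid) {
    p <- geo$polygons[[uid]]
    p <- p[!duplicated(p), , drop = FALSE]
    paste(round(p[, 1] / snap), round(p[, 2] / snap))
  })
  # invert: vertex -> units touching it
  vert_units <- split(rep(seq_len(n), lengths(vkeys)), unlist(vkeys))
  shared <- new.env(hash = TRUE)
  for (us in vert_units) {
    us <- unique(us)
    if (length(us) < 2) next
    for (a in seq_len(length(us) - 1L)) for (b in seq((a + 1L), length(us))) {
      key <- paste(min(us[a], us[b]), max(us[a], us[b]))
      shared[[key]] <- (if (is.null(shared[[key]])) 0L else shared[[key]]) + 1L
    }
  }
  need <- if (rule == "queen") 1L else 2L
  neighbours <- rep(list(integer(0)), n)
  for (key in ls(shared)) {
    if (shared[[key]] < need) next
    ij <- as.integer(strsplit(key, " ")[[1]])
    neighbours[[ij[1]]] <- c(neighbours[[ij[1]]], ij[2])
    neighbours[[ij[2]]] <- c(neighbours[[ij[2]]], ij[1])
  }
  neighbours <- lapply(neighbours, sort)
  w <- weights_matrix(neighbours, ids = geo$unit_id, style = "binary")
  if (require_connected && length(w$islands) > 0)
    stop("disconnected units (islands): ", paste(w$islands, collapse = ", "))
  w
}

#' Row-standardize a weights matrix
#'
#' Divides each nonzero row by its sum so rows sum to 1; island rows stay
#' zero.  Idempotent.
#'
#' @param w a [weights_matrix].
#' @return A row-standardized [weights_matrix].
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "weights_matrix"))
  w$weights <- lapply(w$weights, function(wi)
    if (length(wi) > 0) wi / sum(wi) else wi)
  w$style <- "row_standardized"
  w
}

#' Convert a weights matrix to a sparse Matrix
#'
#' @param w a [weights_matrix].
#' @return A \code{dgCMatrix} of dimension n x n.
#' @export
as_spmatrix <- function(w) {
  stopifnot(inherits(w, "weights_matrix"))
  i <- rep(seq_len(w$n), vapply(w$neighbours, length, integer(1)))
  j <- unlist(w$neighbours)
  x <- unlist(w$weights)
  if (length(i) == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(w$n, w$n)))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(w$n, w$n))
}

#' Spatial lag of a vector
#'
#' @param w a [weights_matrix].
#' @param x numeric vector of length n.
#' @return \code{W x} as a plain numeric vector.
#' @export
spatial_lag <- function(w, x) {
  stopifnot(inherits(w, "weights_matrix"), length(x) == w$n)
  vapply(seq_len(w$n), function(i)
    sum(w$weights[[i]] * x[w$neighbours[[i]]]), numeric(1))
}

#' Write spatial weights in GAL format
#'
#' The GAL text format: a header line with n, then per unit a line
#' \code{id k} followed by a line of k neighbor ids.  Weights are not
#' stored (GAL is a contiguity format), so row standardization is lost.
#'
#' @param w a [weights_matrix].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gal <- function(w, path) {
  stopifnot(inherits(w, "weights_matrix"))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(as.character(w$n), con)
  for (i in seq_len(w$n)) {
    nb <- w$neighbours[[i]]
    writeLines(paste(w$ids[i], length(nb)), con)
    writeLines(paste(w$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Read spatial weights from GAL format
#'
#' @param path GAL file.
#' @return A binary [weights_matrix].
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]][1])
  ids <- character(n); nb_ids <- vector("list", n)
  k <- 2L
  for (i in seq_len(n)) {
    hdr <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1]]
    ids[i] <- hdr[1]
    cnt <- as.integer(hdr[2])
    nb_ids[[i]] <- if (cnt > 0)
      strsplit(trimws(lines[k + 1L]), "[[:space:]]+")[[1]] else character(0)
    k <- k + 2L
  }
  neighbours <- lapply(nb_ids, function(v) sort(match(v, ids)))
  weights_matrix(neighbours, ids = ids, style = "binary")
}

#' Write spatial weights as sparse-triplet CSV
#'
#' Columns: from_id, to_id, weight.
#'
#' @param w a [weights_matrix].
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_weights_csv <- function(w, path) {
  stopifnot(inherits(w, "weights_matrix"))
  tab <- data.frame(
    from_id = rep(w$ids, vapply(w$neighbours, length, integer(1))),
    to_id = w$ids[unlist(w$neighbours)],
    weight = unlist(w$weights),
    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read spatial weights from sparse-triplet CSV
#'
#' @param path CSV with from_id, to_id, weight columns.
#' @param ids optional full id vector (to preserve islands with no rows).
#' @return A [weights_matrix] with style \code{"binary"} if all weights are
#'   1, otherwise \code{"row_standardized"}.
#' @export
read_weights_csv <- function(path, ids = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(from_id = "character",
                                        to_id = "character"))
  if (is.null(ids)) ids <- sort(unique(c(tab$from_id, tab$to_id)))
  n <- length(ids)
  fi <- match(tab$from_id, ids); ti <- match(tab$to_id, ids)
  neighbours <- rep(list(integer(0)), n)
  weights <- rep(list(numeric(0)), n)
  for (r in seq_len(nrow(tab))) {
    neighbours[[fi[r]]] <- c(neighbours[[fi[r]]], ti[r])
    weights[[fi[r]]] <- c(weights[[fi[r]]], tab$weight[r])
  }
  style <- if (all(unlist(weights) == 1)) "binary" else "row_standardized"
  weights_matrix(neighbours, weights, ids = ids, style = style)
}
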