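#' Default source whitelist of interactive Twitter clients
#'
#' The set of "clean" client source strings used to keep hand-typed posts
#' and drop automated services (job ads, traffic feeds, cross-posts from
#' other platforms).  Matching in [whitelist_filter()] is exact and
#' case-sensitive by default.
#'
#' @return Character vector of source strings.
#' @export
default_source_whitelist <- function() {
  c("Fenix for Android", "Flamingo for Android", "Tweetbot for Mac",
    "Tweetbot for iOS", "Tweetings for iPad", "Tweetings for iPhone",
    "Twitter for Android", "Twitter for Android Tablets",
    "Twitter for BlackBerry", "Twitter for Windows",
    "Twitter for Windows Phone", "Twitter for iPad", "Twitter for iPhone")
}

message_columns <- c("message_id", "user_id", "timestamp", "lon", "lat",
                     "source", "text")

validate_messages <- function(corpus) {
  stopifnot(is.data.frame(corpus))
  missing <- setdiff(message_columns, names(corpus))
  if (length(missing) > 0)
    stop("message table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(corpus$message_id))
    stop("duplicate message_id values in corpus")
  if (nrow(corpus) > 0) {
    if (any(corpus$lon < -180 | corpus$lon > 180, na.rm = TRUE) ||
        any(corpus$lat < -90 | corpus$lat > 90, na.rm = TRUE))
      stop("message coordinates outside WGS84 bounds")
  }
  invisible(corpus)
}

#' Read a geolocated message table
#'
#' Accepts CSV or newline-delimited JSON with one record per message and
#' the columns \code{message_id, user_id, timestamp, lon, lat, source,
#' text}.  Timestamps are kept as ISO-8601 strings.
#'
#' @param path input file.
#' @param format \code{"csv"} or \code{"ndjson"}; guessed from the file
#'   extension by default.
#' @return A data.frame of messages.
#' @export
read_messages <- function(path, format = NULL) {
  if (!file.exists(path)) stop("message file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.(ndjson|jsonl)$", path)) "ndjson" else "csv"
  corpus <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(message_id = "character",
                                         user_id = "character")),
    ndjson = jsonlite::stream_in(file(path), verbose = FALSE),
    stop("unknown message format: ", format))
  corpus$message_id <- as.character(corpus$message_id)
  corpus$user_id <- as.character(corpus$user_id)
  validate_messages(corpus)
}

#' Write a message table
#'
#' @param corpus message data.frame.
#' @param path output file; extension \code{.csv} or \code{.ndjson}.
#' @return \code{path}, invisibly.
#' @export
write_messages <- function(corpus, path) {
  validate_messages(corpus)
  if (grepl("\\.(ndjson|jsonl)$", path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(corpus, con, verbose = FALSE)
  } else {
    utils::write.csv(corpus, path, row.names = FALSE)
  }
  invisible(path)
}

#' Filter messages by client source string
#'
#' Retains exactly the records whose \code{source} equals a whitelist entry;
#' record order is preserved.  Matching is exact and case-sensitive unless
#' \code{ignore_case = TRUE}.
#'
#' @param corpus message data.frame.
#' @param whitelist character vector of allowed source strings
#'   (default [default_source_whitelist()]).
#' @param ignore_case compare case-insensitively (default FALSE).
#' @return The filtered data.frame.
#' @export
whitelist_filter <- function(corpus, whitelist = default_source_whitelist(),
                             ignore_case = FALSE) {
  validate_messages(corpus)
  if (length(whitelist) == 0) stop("whitelist must be non-empty")
  src <- corpus$source
  if (ignore_case) {
    keep <- tolower(src) %in% tolower(whitelist)
  } else {
    keep <- src %in% whitelist
  }
  corpus[keep, , drop = FALSE]
}

#' Remove duplicate messages
#'
#' A record is a duplicate when its \code{(user_id, text)} pair repeats an
#' earlier record; the first occurrence is kept.  Scoping the rule to the
#' same user avoids deleting genuine reposts of the same text by different
#' users; set \code{by_user = FALSE} to deduplicate on text alone.
#'
#' @param corpus message data.frame.
#' @param by_user key duplicates on \code{(user_id, text)} (default) rather
#'   than text alone.
#' @return The deduplicated data.frame, original order preserved.
#' @export
deduplicate <- function(corpus, by_user = TRUE) {
  validate_messages(corpus)
  if (nrow(corpus) == 0) return(corpus)
  key <- if (by_user) paste0(corpus$user_id, "\r", corpus$text) else corpus$text
  corpus[!duplicated(key), , drop = FALSE]
}

#' Construct an areal geography
#'
#' @param unit_id character vector of unique unit labels.
#' @param polygons named list (by unit_id) of two-column matrices of
#'   lon/lat ring vertices (outer ring only, need not repeat the first
#'   vertex).
#' @param covariates data.frame of unit-level covariates with a
#'   \code{unit_id} column, or NULL.
#' @param outcomes data.frame of unit-level outcomes with a
#'   \code{unit_id} column, or NULL.
#' @return An object of class \code{"geography"}.
#' @export
geography <- function(unit_id, polygons, covariates = NULL, outcomes = NULL) {
  unit_id <- as.character(unit_id)
  if (anyDuplicated(unit_id)) stop("unit_id values must be unique")
  if (!all(unit_id %in% names(polygons)))
    stop("every unit needs a polygon")
  polygons <- polygons[unit_id]
  for (uid in unit_id) {
    p <- polygons[[uid]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      stop("invalid polygon for unit ", uid)
  }
  align <- function(tab, what) {
    if (is.null(tab)) return(data.frame(unit_id = unit_id))
    stopifnot("unit_id" %in% names(tab))
    tab$unit_id <- as.character(tab$unit_id)
    if (!setequal(tab$unit_id, unit_id))
      stop(what, " table does not cover exactly the geography's units")
    tab[match(unit_id, tab$unit_id), , drop = FALSE]
  }
  structure(list(unit_id = unit_id, polygons = polygons,
                 covariates = align(covariates, "covariate"),
                 outcomes = align(outcomes, "outcome")),
            class = "geography")
}

#' @export
print.geography <- function(x, ...) {
  cat(sprintf("<geography: %d units, %d covariates, %d outcomes>\n",
              length(x$unit_id), ncol(x$covariates) - 1L,
              ncol(x$outcomes) - 1L))
  invisible(x)
}

#' Read a geography from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features (outer rings only;
#' MultiPolygon and holes are not supported).  All non-geometry properties
#' other than the id property are carried as unit-level attributes; which of
#' those are covariates vs outcomes is decided downstream by name.
#'
#' @param path GeoJSON file.
#' @param id_property name of the feature property holding the unit id
#'   (default \code{"unit_id"}).
#' @return A [geography].
#' @export
read_geography <- function(path, id_property = "unit_id") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  ids <- character(0); polys <- list(); props <- list()
  for (f in gj$features) {
    uid <- as.character(f$properties[[id_property]])
    if (length(uid) != 1 || !nzchar(uid))
      stop("feature without '", id_property, "' property in ", path)
    if (!identical(f$geometry$type, "Polygon"))
      stop("unsupported geometry type for unit ", uid)
    ring <- f$geometry$coordinates[[1]]
    polys[[uid]] <- do.call(rbind, lapply(ring, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    p <- f$properties; p[[id_property]] <- NULL
    props[[uid]] <- p
    ids <- c(ids, uid)
  }
  prop_names <- unique(unlist(lapply(props, names)))
  attrs <- data.frame(unit_id = ids, stringsAsFactors = FALSE)
  for (nm in prop_names)
    attrs[[nm]] <- vapply(props, function(p)
      if (is.null(p[[nm]])) NA_real_ else as.numeric(p[[nm]]), numeric(1))
  geography(ids, polys, covariates = attrs)
}

#' Write a geography to GeoJSON
#'
#' Covariate and outcome columns are written as feature properties.
#'
#' @param geo a [geography].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_geography <- function(geo, path) {
  stopifnot(inherits(geo, "geography"))
  feats <- lapply(seq_along(geo$unit_id), function(i) {
    uid <- geo$unit_id[i]
    ring <- close_ring(geo$polygons[[uid]])
    props <- c(list(unit_id = uid),
               as.list(geo$covariates[i, setdiff(names(geo$covariates), "unit_id"),
                                      drop = FALSE]),
               as.list(geo$outcomes[i, setdiff(names(geo$outcomes), "unit_id"),
                                    drop = FALSE]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(p) {
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ]) else p
}

ring_is_valid <- function(p) {
  # rejects self-intersecting rings by pairwise proper segment crossing
  p <- close_ring(p)
  n <- nrow(p) - 1L
  if (n < 3) return(FALSE)
  seg <- cbind(p[1:n, , drop = FALSE], p[2:(n + 1L), , drop = FALSE])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (i == 1L && j == n) next  # adjacent through the closure
      a1 <- seg[i, 1:2]; a2 <- seg[i, 3:4]
      b1 <- seg[j, 1:2]; b2 <- seg[j, 3:4]
      d1 <- cross(a2[1] - a1[1], a2[2] - a1[2], b1[1] - a1[1], b1[2] - a1[2])
      d2 <- cross(a2[1] - a1[1], a2[2] - a1[2], b2[1] - a1[1], b2[2] - a1[2])
      d3 <- cross(b2[1] - b1[1], b2[2] - b1[2], a1[1] - b1[1], a1[2] - b1[2])
      d4 <- cross(b2[1] - b1[1], b2[2] - b1[2], a2[1] - b1[1], a2[2] - b1[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(FALSE)
    }
  }
  TRUE
}

#' Assign messages to areal units by point-in-polygon
#'
#' Planar point-in-polygon in lon/lat (curvature is negligible at tract
#' scale).  A point on a shared boundary is assigned to the
#' lowest-sorted containing \code{unit_id}, so assignment is deterministic
#' and invariant to record order.
#'
#' @param corpus message data.frame with \code{lon}/\code{lat}.
#' @param geo a [geography].
#' @return Character vector of unit ids parallel to \code{corpus} rows,
#'   \code{NA} for points contained in no unit, named by \code{message_id}.
#' @export
assign_units <- function(corpus, geo) {
  validate_messages(corpus)
  stopifnot(inherits(geo, "geography"))
  for (uid in geo$unit_id)
    if (!ring_is_valid(geo$polygons[[uid]]))
      stop("invalid (self-intersecting) polygon for unit ", uid)
  n <- nrow(corpus)
  assigned <- rep(NA_character_, n)
  # visit units in sorted order; first hit wins => lowest-id tie-break
  for (uid in sort(geo$unit_id, method = "radix")) {
    todo <- which(is.na(assigned))
    if (length(todo) == 0) break
    p <- geo$polygons[[uid]]
    inside <- pracma::inpolygon(corpus$lon[todo], corpus$lat[todo],
                                p[, 1], p[, 2], boundary = TRUE)
    assigned[todo[inside]] <- uid
  }
  stats::setNames(assigned, corpus$message_id)
}

#' Construct a single unit corpus
#'
#' @param unit_id unit label.
#' @param token_counts named integer vector of lexicon-matched token
#'   frequencies f(w).
#' @param message_count number of messages pooled into the corpus.
#' @param user_count number of distinct users.
#' @return An object of class \code{"unit_corpus"}.
#' @export
unit_corpus <- function(unit_id, token_counts, message_count = NA_integer_,
                        user_count = NA_integer_) {
  counts <- as.numeric(token_counts)
  if (any(counts < 0)) stop("token counts must be nonnegative")
  structure(list(unit_id = as.character(unit_id),
                 token_counts = stats::setNames(counts, names(token_counts)),
                 message_count = as.integer(message_count),
                 user_count = as.integer(user_count)),
            class = "unit_corpus")
}

#' @export
print.unit_corpus <- function(x, ...) {
  cat(sprintf("<unit_corpus %s: %d messages, %d matched tokens (%d types)>\n",
              x$unit_id, x$message_count, round(sum(x$token_counts)),
              length(x$token_counts)))
  invisible(x)
}

#' Build per-unit token frequency tables
#'
#' Tokenizes every message, keeps only tokens present in the lexicon, and
#' pools counts per assigned unit.  Units receiving fewer than
#' \code{min_messages} messages are dropped (the small-sample exclusion
#' rule; the reference analysis used 1,000).  Units whose messages match no
#' lexicon word are retained with empty counts and flagged.
#'
#' @param corpus message data.frame.
#' @param assignment output of [assign_units()] for this corpus.
#' @param geo a [geography].
#' @param lex a [lexicon] (typically already neutral-filtered).
#' @param min_messages minimum messages per retained unit (default 1000).
#' @return A list of [unit_corpus] objects (one per retained unit, in
#'   geography order), with attributes \code{dropped} (data.frame
#'   unit_id/message_count of excluded units) and \code{no_match}
#'   (ids of retained units with zero matched tokens).
#' @export
build_unit_corpora <- function(corpus, assignment, geo, lex,
                               min_messages = 1000) {
  validate_messages(corpus)
  stopifnot(inherits(geo, "geography"), inherits(lex, "lexicon"),
            min_messages >= 0)
  unit_of <- assignment[corpus$message_id]
  keep <- !is.na(unit_of)
  corpus <- corpus[keep, , drop = FALSE]
  unit_of <- unit_of[keep]
  toks <- tokenize(corpus$text)
  if (nrow(corpus) == 1) toks <- list(toks)
  vocab <- names(lex$entries)
  out <- list(); dropped <- list(); no_match <- character(0)
  for (uid in geo$unit_id) {
    rows <- which(unit_of == uid)
    m <- length(rows)
    if (m < min_messages) {
      if (m > 0) dropped[[uid]] <- m
      next
    }
    tk <- unlist(toks[rows], use.names = FALSE)
    tk <- tk[tk %in% vocab]
    counts <- if (length(tk) > 0) table(tk) else integer(0)
    if (length(counts) == 0) no_match <- c(no_match, uid)
    out[[uid]] <- unit_corpus(uid,
                              stats::setNames(as.integer(counts), names(counts)),
                              message_count = m,
                              user_count = length(unique(corpus$user_id[rows])))
  }
  attr(out, "dropped") <- data.frame(
    unit_id = names(dropped),
    message_count = as.integer(unlist(dropped, use.names = FALSE)),
    stringsAsFactors = FALSE)
  attr(out, "no_match") <- no_match
  out
}

#' Summarize unit corpora as a data.frame
#'
#' @param corpora output of [build_unit_corpora()].
#' @return data.frame with unit_id, message_count, user_count,
#'   matched_token_count.
#' @export
unit_corpora_summary <- function(corpora) {
  data.frame(
    unit_id = vapply(corpora, `[[`, character(1), "unit_id"),
    message_count = vapply(corpora, `[[`, integer(1), "message_count"),
    user_count = vapply(corpora, `[[`, integer(1), "user_count"),
    matched_token_count = vapply(corpora, function(u)
      as.integer(sum(u$token_counts)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
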