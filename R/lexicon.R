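#' Construct a sentiment lexicon
#'
#' A lexicon maps lower-case words to average happiness ratings on the
#' 1--9 hedonometer scale (1 = least happy, 9 = most happy).  The neutral
#' window, centered by default on the scale midpoint 5 with halfwidth 1,
#' records which ratings count as emotionally neutral; words inside the
#' window are removed by [apply_neutral_filter()] before scoring.
#'
#' @param ratings named numeric vector, \code{word -> rating}; names are
#'   case-normalized to lower case and must be unique and non-empty.
#' @param neutral_center center of the neutral window (default 5).
#' @param neutral_halfwidth halfwidth of the neutral window (default 1).
#' @param name label for the lexicon.
#' @return An object of class \code{"lexicon"}.
#' @export
lexicon <- function(ratings, neutral_center = 5, neutral_halfwidth = 1,
                    name = "lexicon") {
  words <- tolower(names(ratings))
  if (length(ratings) > 0 && (is.null(names(ratings)) || any(words == "" | is.na(words))))
    stop("lexicon words must be non-empty strings")
  if (anyDuplicated(words))
    stop("duplicate lexicon words: ",
         paste(unique(words[duplicated(words)]), collapse = ", "))
  r <- as.numeric(ratings)
  if (any(!is.finite(r)) || any(r < 1 | r > 9))
    stop("lexicon ratings must lie in [1, 9]")
  names(r) <- words
  structure(
    list(entries = r, neutral_center = neutral_center,
         neutral_halfwidth = neutral_halfwidth, name = name),
    class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s': %d words, neutral window [%g, %g]>\n",
              x$name, length(x$entries),
              x$neutral_center - x$neutral_halfwidth,
              x$neutral_center + x$neutral_halfwidth))
  invisible(x)
}

#' @export
length.lexicon <- function(x) length(x$entries)

#' Read a lexicon from a tab-separated file
#'
#' Two dialects are supported.  \code{format = "labmt"} expects the labMT 1.0
#' column layout: a header row and (at least) the columns \code{word},
#' \code{happiness_rank}, \code{happiness_average},
#' \code{happiness_standard_deviation}; only \code{word} and
#' \code{happiness_average} are used.  \code{format = "minimal"} expects two
#' columns, \code{word<TAB>rating}, with a header row.
#'
#' @param path path to a TSV file.
#' @param format \code{"labmt"} (default) or \code{"minimal"}.
#' @param name lexicon label; defaults to the file name.
#' @return A [lexicon] object.
#' @export
load_lexicon <- function(path, format = c("labmt", "minimal"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  if (is.null(name)) name <- basename(path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "", fill = FALSE,
                           check.names = TRUE)
  rating_col <- if (format == "labmt") "happiness_average" else names(tab)[2]
  if (!("word" %in% names(tab)))
    stop("lexicon file lacks a 'word' column: ", path)
  if (format == "labmt" && !(rating_col %in% names(tab)))
    stop("lexicon file lacks a 'happiness_average' column: ", path)
  if (nrow(tab) == 0)
    return(lexicon(stats::setNames(numeric(0), character(0)), name = name))
  ratings <- suppressWarnings(as.numeric(tab[[rating_col]]))
  bad <- which(!is.finite(ratings))
  if (length(bad) > 0)
    stop(sprintf("malformed rating at line %d of %s", bad[1] + 1L, path))
  out_of_range <- which(ratings < 1 | ratings > 9)
  if (length(out_of_range) > 0)
    stop(sprintf("rating outside [1, 9] at line %d of %s (value %g)",
                 out_of_range[1] + 1L, path, ratings[out_of_range[1]]))
  words <- tolower(as.character(tab$word))
  if (anyDuplicated(words))
    stop("duplicate word in lexicon file: ",
         words[duplicated(words)][1], " (", path, ")")
  lexicon(stats::setNames(ratings, words), name = name)
}

#' Write a lexicon to a tab-separated file
#'
#' Emits the labMT 1.0 column layout (word, happiness_rank,
#' happiness_average, happiness_standard_deviation), sorted by word, UTF-8.
#' Rank is recomputed from the ratings (1 = happiest); the standard
#' deviation column is written as NA since a plain lexicon does not carry
#' rater-level detail.
#'
#' @param lex a [lexicon].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "lexicon"))
  e <- lex$entries[order(names(lex$entries), method = "radix")]
  tab <- data.frame(
    word = names(e),
    happiness_rank = rank(-e, ties.method = "min"),
    happiness_average = unname(e),
    happiness_standard_deviation = NA_real_,
    stringsAsFactors = FALSE)
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.table(tab, utf8, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove neutral words from a lexicon
#'
#' Drops every entry whose rating falls inside the closed neutral window
#' \code{[neutral_center - neutral_halfwidth, neutral_center + neutral_halfwidth]}
#' (so with the defaults, any rating r with |r - 5| <= 1 is removed and
#' ratings of exactly 4 or 6 are excluded).  This is the hedonometer's
#' standard robustification: words near the scale midpoint carry little
#' emotional signal and mostly add rater noise.
#'
#' @param lex a [lexicon].
#' @return A new [lexicon] containing only the non-neutral entries; the
#'   input is not modified.  Idempotent.
#' @export
apply_neutral_filter <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  keep <- abs(lex$entries - lex$neutral_center) > lex$neutral_halfwidth
  out <- lex
  out$entries <- lex$entries[keep]
  out
}

#' Tokenize raw text for lexicon matching
#'
#' Lower-cases, splits on whitespace, and strips leading/trailing
#' punctuation from each chunk while preserving internal apostrophes, so
#' that dialect forms such as \code{don't} and \code{dont} stay distinct.
#' Leading \code{#} and \code{@} (hashtags, mentions) are stripped with the
#' rest of the leading punctuation, so the residual token still matches the
#' lexicon.  No stemming and no stop-word removal.
#'
#' @param text character vector of raw texts (any length, possibly empty
#'   strings).
#' @return For a single string, a character vector of tokens; for a vector
#'   of texts, a list of such vectors.  Deterministic and order-preserving.
#' @export
tokenize <- function(text) {
  single <- length(text) == 1L
  chunks <- strsplit(tolower(text), "[[:space:]]+")
  out <- lapply(chunks, function(ch) {
    ch <- gsub("^[^a-z0-9']+|[^a-z0-9']+$", "", ch)
    # apostrophes are kept only when internal ("don't"), never as edges
    ch <- gsub("^'+|'+$", "", ch)
    ch[nzchar(ch)]
  })
  if (single) out[[1]] else out
}
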