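#' Score a token sequence with the hedonometer
#'
#' The happiness of a text T is the frequency-weighted mean of the
#' happiness ratings of its lexicon-matched words,
#' \deqn{h_{avg}(T) = \sum_i h(w_i) f(w_i) / \sum_i f(w_i),}
#' where f(w) counts occurrences of w among the tokens.  The caller is
#' expected to have applied the neutral filter to the lexicon already; the
#' scorer does not re-filter.
#'
#' @param tokens character vector of normalized tokens (e.g. from
#'   [tokenize()]), or a named count vector via [score_counts()].
#' @param lex a [lexicon].
#' @return A list of class \code{"sentiment_score"} with fields
#'   \code{value} (NA when no token matches), \code{matched_tokens}, and
#'   \code{coverage} (fraction of input tokens matched).
#' @export
score_text <- function(tokens, lex) {
  stopifnot(inherits(lex, "lexicon"))
  n_total <- length(tokens)
  r <- lex$entries[tokens]
  r <- r[!is.na(r)]
  score_from(sum(r), length(r), n_total)
}

#' Score a word-count table with the hedonometer
#'
#' Identical arithmetic to [score_text()] on a pre-tabulated
#' \code{word -> count} vector.
#'
#' @param counts named numeric vector of token counts.
#' @param lex a [lexicon].
#' @return A \code{"sentiment_score"}; coverage is the matched fraction of
#'   the total count mass.
#' @export
score_counts <- function(counts, lex) {
  stopifnot(inherits(lex, "lexicon"))
  r <- lex$entries[names(counts)]
  ok <- !is.na(r)
  score_from(sum(r[ok] * counts[ok]), sum(counts[ok]), sum(counts))
}

#' Score a unit corpus with the hedonometer
#'
#' Pooled-token scoring: the unit's token frequencies are treated as one
#' large concatenated text, so the result is a frequency-weighted mean over
#' all matched tokens, not an average of per-message scores.
#'
#' @param uc a [unit_corpus].
#' @param lex a [lexicon].
#' @return A \code{"sentiment_score"}.
#' @export
score_unit <- function(uc, lex) {
  stopifnot(inherits(uc, "unit_corpus"))
  score_counts(uc$token_counts, lex)
}

score_from <- function(weighted_sum, matched, total) {
  structure(list(
    value = if (matched > 0) weighted_sum / matched else NA_real_,
    matched_tokens = matched,
    coverage = if (total > 0) matched / total else 0),
    class = "sentiment_score")
}

#' @export
print.sentiment_score <- function(x, ...) {
  if (is.na(x$value)) {
    cat("<sentiment_score: no lexicon match>\n")
  } else {
    cat(sprintf("<sentiment_score: h_avg = %.4f (%d matched tokens, coverage %.1f%%)>\n",
                x$value, round(x$matched_tokens), 100 * x$coverage))
  }
  invisible(x)
}

matched_props <- function(counts, lex) {
  r <- lex$entries[names(counts)]
  ok <- !is.na(r)
  counts <- counts[ok]
  if (sum(counts) == 0) return(stats::setNames(numeric(0), character(0)))
  counts / sum(counts)
}

#' Word-shift decomposition of a happiness difference
#'
#' Attributes the difference in happiness between a comparison corpus and a
#' reference corpus to individual words.  For word i with rating h(w_i) and
#' relative frequencies p_i(comp), p_i(ref) (computed over lexicon-matched
#' tokens only), the normalized per-word shift is
#' \deqn{\delta h_{avg,i} = \frac{100}{|h_{avg}(comp) - h_{avg}(ref)|}
#'   \,[h(w_i) - h_{avg}(ref)]\,[p_i(comp) - p_i(ref)],}
#' so that over the whole lexicon the contributions sum to +100 when the
#' comparison text is happier than the reference and -100 otherwise.
#'
#' @param comp comparison [unit_corpus].
#' @param ref reference [unit_corpus] (e.g. the pooled all-units corpus
#'   from [pool_corpora()]).
#' @param lex a [lexicon].
#' @param top_k how many words to keep in the ranked report (default 20);
#'   \code{Inf} keeps all.
#' @return A list of class \code{"shift_report"}: \code{h_comp},
#'   \code{h_ref}, \code{delta_sum} (the untruncated total, ±100), and
#'   \code{shifts}, a data.frame (word, delta, freq_direction in up/down,
#'   sent_direction in plus/minus, p_comp, p_ref) ranked by |delta|
#'   descending with alphabetical tie-break.
#' @export
word_shift <- function(comp, ref, lex, top_k = 20) {
  stopifnot(inherits(comp, "unit_corpus"), inherits(ref, "unit_corpus"),
            inherits(lex, "lexicon"))
  h_comp <- score_unit(comp, lex)$value
  h_ref <- score_unit(ref, lex)$value
  if (is.na(h_comp) || is.na(h_ref))
    stop("both corpora must contain at least one lexicon-matched token")
  if (h_comp == h_ref)
    stop("degenerate shift: h_avg(comp) equals h_avg(ref), normalizer is zero")
  pc <- matched_props(comp$token_counts, lex)
  pr <- matched_props(ref$token_counts, lex)
  words <- union(names(pc), names(pr))
  p_comp <- ifelse(words %in% names(pc), pc[words], 0)
  p_ref <- ifelse(words %in% names(pr), pr[words], 0)
  h_w <- lex$entries[words]
  delta <- 100 / abs(h_comp - h_ref) * (h_w - h_ref) * (p_comp - p_ref)
  tab <- data.frame(
    word = words,
    delta = unname(delta),
    freq_direction = ifelse(p_comp >= p_ref, "up", "down"),
    sent_direction = ifelse(h_w >= h_ref, "plus", "minus"),
    p_comp = unname(p_comp),
    p_ref = unname(p_ref),
    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$delta), tab$word, method = "radix"), ]
  rownames(tab) <- NULL
  structure(list(h_comp = h_comp, h_ref = h_ref,
                 delta_sum = sum(delta),
                 shifts = utils::head(tab, top_k)),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("<shift_report: h_comp = %.4f, h_ref = %.4f (total shift %+g)>\n",
              x$h_comp, x$h_ref, round(x$delta_sum)))
  print(utils::head(x$shifts, 10))
  invisible(x)
}

#' Pool unit corpora into one reference corpus
#'
#' Sums token counts (and message/user counts) across units; the usual
#' reference for published word-shift rankings is the pooled all-units
#' corpus.
#'
#' @param corpora list of [unit_corpus] objects.
#' @param unit_id label for the pooled corpus (default \code{"pooled"}).
#' @return A [unit_corpus].
#' @export
pool_corpora <- function(corpora, unit_id = "pooled") {
  all_words <- unique(unlist(lapply(corpora, function(u) names(u$token_counts))))
  counts <- stats::setNames(numeric(length(all_words)), all_words)
  for (u in corpora)
    counts[names(u$token_counts)] <- counts[names(u$token_counts)] + u$token_counts
  unit_corpus(unit_id, counts,
              message_count = sum(vapply(corpora, `[[`, integer(1),
                                         "message_count")),
              user_count = NA_integer_)
}

#' Write a shift report to CSV
#'
#' @param report a \code{"shift_report"}.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_shift_report <- function(report, path) {
  stopifnot(inherits(report, "shift_report"))
  utils::write.csv(report$shifts, path, row.names = FALSE)
  invisible(path)
}
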