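#' Configuration for the synthetic world generator
#'
#' Bundles every knob of the data-generating process.  Defaults describe
#' the reference study conditions at desk scale: a 20 x 20 lattice of
#' square "tracts" (same order of magnitude as the 281 tracts of a
#' mid-sized city study), a spatially smooth disadvantage covariate plus
#' an independent noise covariate, SARAR outcomes, and per-tract message
#' corpora a little above the 1,000-message inclusion threshold.
#'
#' @param rows,cols lattice dimensions (>= 2 each).
#' @param beta coefficients of the covariates (x_smooth, x_noise) in the
#'   outcome DGP; intercept is \code{intercept}.
#' @param intercept outcome intercept (default 0).
#' @param lambda_lag spatial-lag parameter in (-1, 1).
#' @param rho_err spatial-error parameter in (-1, 1).
#' @param sigma innovation standard deviation.
#' @param smooth_kappa spatial-smoothing parameter of the disadvantage
#'   covariate, in (-1, 1).
#' @param messages_per_unit messages generated per unit: a single count or
#'   a length-2 range sampled uniformly per unit.
#' @param tokens_per_message mean tokens per message (Poisson, min 1).
#' @param dialect_gradient strength of the association between the latent
#'   disadvantage covariate and dialect-marked word use (log-odds units per
#'   sd of the covariate); 0 disables the confound.
#' @param dialect_base baseline mixture weight of the dialect pool.
#' @param mood share of the standard-word mass drawn from the positive
#'   pool; constant across units, so with \code{dialect_gradient = 0}
#'   measured happiness varies only by sampling noise.
#' @param p_offlist_source fraction of messages tagged with a
#'   non-whitelisted source (exercises the source filter).
#' @param p_duplicate fraction of messages duplicated verbatim from an
#'   earlier message by the same user (exercises deduplication).
#' @param seed master seed; all generation streams derive from it.
#' @return A list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(rows = 20, cols = 20,
                             beta = c(x_smooth = 1, x_noise = 2),
                             intercept = 0,
                             lambda_lag = 0.4, rho_err = 0.3, sigma = 1,
                             smooth_kappa = 0.7,
                             messages_per_unit = 1200,
                             tokens_per_message = 8,
                             dialect_gradient = 0, dialect_base = 0.15,
                             mood = 0.6,
                             p_offlist_source = 0.1, p_duplicate = 0.02,
                             seed = 1L) {
  stopifnot(rows >= 2, cols >= 2,
            abs(lambda_lag) < 1, abs(rho_err) < 1, abs(smooth_kappa) < 1,
            sigma > 0, all(messages_per_unit > 0), tokens_per_message >= 1,
            dialect_base > 0, dialect_base < 1, mood >= 0, mood <= 1)
  structure(list(rows = rows, cols = cols, beta = beta,
                 intercept = intercept, lambda_lag = lambda_lag,
                 rho_err = rho_err, sigma = sigma,
                 smooth_kappa = smooth_kappa,
                 messages_per_unit = messages_per_unit,
                 tokens_per_message = tokens_per_message,
                 dialect_gradient = dialect_gradient,
                 dialect_base = dialect_base, mood = mood,
                 p_offlist_source = p_offlist_source,
                 p_duplicate = p_duplicate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Named sub-streams off one master seed, so regenerating one component
# never perturbs another.  Plain 31-bit string hash mixed with the seed.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a lattice geography of unit squares
#'
#' rows x cols unit squares in row-major order; unit ids are zero-padded
#' so lexicographic and spatial order agree.  Unit squares keep
#' point-in-polygon assignment exact, and their queen/rook adjacency is
#' the textbook lattice structure.
#'
#' @param rows,cols lattice dimensions (>= 2).
#' @return A [geography] with empty covariate/outcome tables.
#' @export
make_lattice <- function(rows, cols) {
  stopifnot(rows >= 2, cols >= 2)
  width <- nchar(as.character(rows * cols))
  ids <- sprintf(paste0("u%0", width, "d"), seq_len(rows * cols))
  polys <- list()
  k <- 0L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    k <- k + 1L
    x0 <- c - 1; y0 <- r - 1
    polys[[ids[k]]] <- cbind(c(x0, x0 + 1, x0 + 1, x0),
                             c(y0, y0, y0 + 1, y0 + 1))
  }
  geography(ids, polys)
}

#' Generate SARAR outcomes and covariates on a geography
#'
#' Covariates: \code{x_smooth}, a spatially autocorrelated standardized
#' field (emulating clustered socio-economic disadvantage), generated as
#' \eqn{(I - \kappa W)^{-1} \xi} with iid normal \eqn{\xi}; and
#' \code{x_noise}, iid standard normal.  Outcomes follow the SARAR
#' reduced form, solved exactly:
#' \deqn{y = (I - \lambda W)^{-1} (\alpha + X\beta + (I - \rho M)^{-1}\varepsilon),
#'   \qquad \varepsilon \sim N(0, \sigma^2 I).}
#'
#' @param geo a [geography].
#' @param w,m row-standardized [weights_matrix] objects for lag and error.
#' @param config a [synthetic_config]; \code{lambda_lag}, \code{rho_err},
#'   \code{beta}, \code{intercept}, \code{sigma}, \code{smooth_kappa} and
#'   \code{seed} are used.
#' @return A [geography] equal to \code{geo} but with covariates
#'   (x_smooth, x_noise) and outcome \code{y} filled in; the innovation
#'   vector is stored in \code{attr(, "epsilon")}.
#' @export
gen_outcomes <- function(geo, w, m, config) {
  stopifnot(inherits(geo, "geography"), inherits(config, "synthetic_config"))
  n <- length(geo$unit_id)
  W <- as_spmatrix(w); M <- as_spmatrix(m)
  I_n <- Matrix::Diagonal(n)
  draws <- with_seed(substream_seed(config$seed, "outcomes"), {
    list(xi = stats::rnorm(n), x_noise = stats::rnorm(n),
         eps = stats::rnorm(n, sd = config$sigma))
  })
  x_smooth <- as.numeric(Matrix::solve(I_n - config$smooth_kappa * W, draws$xi))
  x_smooth <- as.numeric(scale(x_smooth))
  X <- cbind(x_smooth = x_smooth, x_noise = draws$x_noise)
  u <- as.numeric(Matrix::solve(I_n - config$rho_err * M, draws$eps))
  rhs <- config$intercept + as.numeric(X %*% config$beta) + u
  y <- as.numeric(Matrix::solve(I_n - config$lambda_lag * W, rhs))
  covariates <- data.frame(unit_id = geo$unit_id, x_smooth = x_smooth,
                           x_noise = draws$x_noise,
                           stringsAsFactors = FALSE)
  outcomes <- data.frame(unit_id = geo$unit_id, y = y,
                         stringsAsFactors = FALSE)
  out <- geography(geo$unit_id, geo$polygons, covariates, outcomes)
  attr(out, "epsilon") <- draws$eps
  out
}

#' Fixture sentiment lexicon with designated word pools
#'
#' A small labMT-dialect lexicon built in code, with three designated
#' pools used by [gen_corpus()]: \code{standard_positive} (ratings
#' 6.4--8.6), \code{standard_negative} (1.4--3.6), and \code{dialect}
#' (dialect-marked forms that human raters score negatively, 2.2--3.8,
#' emulating rating panels calibrated to the standard dialect).  A few
#' neutral words (ratings in [4, 6]) are included so the neutral filter
#' has something to remove.
#'
#' @return A [lexicon] with a \code{pools} attribute (list of character
#'   vectors).
#' @export
synthetic_lexicon <- function() {
  pos <- c(happy = 8.3, love = 8.42, laughter = 8.5, sunshine = 7.9,
           friend = 7.66, beach = 7.52, music = 7.67, weekend = 7.45,
           dinner = 7.1, beautiful = 7.92, excited = 7.3, winning = 7.0,
           family = 7.6, holiday = 7.8, smile = 7.89, party = 7.2,
           amazing = 7.8, fun = 7.96)
  neg <- c(sad = 2.38, lost = 2.76, sick = 2.2, pain = 2.13, war = 1.8,
           dead = 1.54, broke = 2.9, tired = 3.1, angry = 2.26,
           crash = 2.6, fired = 2.5, alone = 3.2, failed = 2.1,
           jail = 1.9)
  dialect <- c(shit = 2.5, gone = 3.42, damn = 3.1, hell = 2.2,
               "ain't" = 3.3, ass = 3.0, bitch = 2.9, nobody = 3.08,
               finna = 3.5, tryna = 3.6)
  neutral <- c(the = 4.98, and = 5.22, street = 5.22, today = 5.3,
               going = 5.11, fuck = 4.14, animals = 6.0)
  lex <- lexicon(c(pos, neg, dialect, neutral), name = "synthetic")
  attr(lex, "pools") <- list(standard_positive = names(pos),
                             standard_negative = names(neg),
                             dialect = names(dialect))
  lex
}

#' Generate a message corpus over a geography
#'
#' Per unit, message texts are sampled from a three-pool word mixture
#' (standard-positive, standard-negative, dialect-marked).  The mixture
#' weight of the dialect pool increases with the unit's standardized
#' \code{x_smooth} covariate on the log-odds scale by
#' \code{dialect_gradient}; the split of the remaining mass between the
#' positive and negative pools is the constant \code{mood}.  Because
#' dialect-marked words carry low ratings while true mood is held
#' constant, a positive gradient makes measured happiness a proxy for the
#' latent demographic factor — the confounding mechanism under study.
#' Message points are uniform inside the unit polygon's bounding box
#' (exact for lattice squares); sources are drawn from the interactive
#' whitelist with a configurable off-list fraction, and a small fraction
#' of messages is duplicated to exercise deduplication.
#'
#' @param geo a [geography] whose covariates include \code{x_smooth}
#'   (e.g. from [gen_outcomes()]); if absent, a zero field is used.
#' @param lex a [lexicon] carrying a \code{pools} attribute, or a lexicon
#'   plus an explicit \code{pools} list.
#' @param config a [synthetic_config].
#' @param pools optional list with character vectors standard_positive,
#'   standard_negative, dialect; defaults to \code{attr(lex, "pools")}.
#' @return A message data.frame (message_id, user_id, timestamp, lon, lat,
#'   source, text).
#' @export
gen_corpus <- function(geo, lex, config, pools = NULL) {
  stopifnot(inherits(geo, "geography"), inherits(lex, "lexicon"),
            inherits(config, "synthetic_config"))
  if (is.null(pools)) pools <- attr(lex, "pools")
  if (is.null(pools) || !all(c("standard_positive", "standard_negative",
                               "dialect") %in% names(pools)) ||
      any(lengths(pools[c("standard_positive", "standard_negative",
                          "dialect")]) == 0))
    stop("lexicon must designate non-empty standard_positive, ",
         "standard_negative and dialect word pools")
  n <- length(geo$unit_id)
  g <- if ("x_smooth" %in% names(geo$covariates))
    as.numeric(scale(geo$covariates$x_smooth)) else numeric(n)
  whitelist <- default_source_whitelist()
  offlist <- c("Instagram", "FourSquare", "dlvr.it", "IFTTT")
  t0 <- as.POSIXct("2014-12-06 00:00:00", tz = "UTC")
  t1 <- as.POSIXct("2017-05-24 00:00:00", tz = "UTC")
  with_seed(substream_seed(config$seed, "corpus"), {
    per_unit <- if (length(config$messages_per_unit) == 2)
      sample(config$messages_per_unit[1]:config$messages_per_unit[2], n,
             replace = TRUE)
    else rep(config$messages_per_unit, n)
    total <- sum(per_unit)
    unit_idx <- rep(seq_len(n), per_unit)
    d_w <- stats::plogis(stats::qlogis(config$dialect_base) +
                           config$dialect_gradient * g)
    texts <- character(total)
    lons <- numeric(total); lats <- numeric(total)
    users <- character(total)
    pos <- 0L
    for (i in seq_len(n)) {
      m_i <- per_unit[i]
      if (m_i == 0) next
      idx <- pos + seq_len(m_i)
      probs <- c(dialect = d_w[i],
                 pos = (1 - d_w[i]) * config$mood,
                 neg = (1 - d_w[i]) * (1 - config$mood))
      n_tok <- pmax(1L, stats::rpois(m_i, config$tokens_per_message))
      pool_of <- sample(c("dialect", "pos", "neg"), sum(n_tok),
                        replace = TRUE, prob = probs)
      words <- character(sum(n_tok))
      for (p in c("dialect", "pos", "neg")) {
        sel <- pool_of == p
        src_pool <- switch(p, dialect = pools$dialect,
                           pos = pools$standard_positive,
                           neg = pools$standard_negative)
        words[sel] <- sample(src_pool, sum(sel), replace = TRUE)
      }
      texts[idx] <- vapply(split(words, rep(seq_len(m_i), n_tok)),
                           paste, character(1), collapse = " ")
      box <- geo$polygons[[geo$unit_id[i]]]
      lons[idx] <- stats::runif(m_i, min(box[, 1]), max(box[, 1]))
      lats[idx] <- stats::runif(m_i, min(box[, 2]), max(box[, 2]))
      n_users <- max(1L, ceiling(m_i / 10))
      users[idx] <- sprintf("%s_user%03d", geo$unit_id[i],
                            sample.int(n_users, m_i, replace = TRUE))
      pos <- pos + m_i
    }
    source <- ifelse(stats::runif(total) < config$p_offlist_source,
                     sample(offlist, total, replace = TRUE),
                     sample(whitelist, total, replace = TRUE))
    # verbatim same-user duplicates
    dup <- which(stats::runif(total) < config$p_duplicate)
    dup <- dup[dup > 1]
    for (j in dup) {
      k <- sample.int(j - 1L, 1L)
      texts[j] <- texts[k]; users[j] <- users[k]
      lons[j] <- lons[k]; lats[j] <- lats[k]
    }
    stamp <- t0 + stats::runif(total) * as.numeric(difftime(t1, t0,
                                                            units = "secs"))
    data.frame(
      message_id = sprintf("m%07d", seq_len(total)),
      user_id = users,
      timestamp = format(stamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      lon = lons, lat = lats, source = source, text = texts,
      stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic world
#'
#' Lattice geography, queen-contiguity weights, SARAR outcomes and
#' covariates, and a message corpus — every input the pipeline needs,
#' fully reproducible from the config's seed, with independent
#' sub-streams per component.
#'
#' @param config a [synthetic_config].
#' @param rule contiguity rule for the generated weights (default queen).
#' @param corpus generate the message corpus (default TRUE; outcome-only
#'   studies can skip it).
#' @return A list of class \code{"synthetic_world"}: \code{geography}
#'   (with covariates and outcomes), \code{w}, \code{m} (row-standardized
#'   weights), \code{lexicon}, \code{corpus} (or NULL), \code{truth}
#'   (the config).
#' @export
synthetic_world <- function(config = synthetic_config(),
                            rule = c("queen", "rook"), corpus = TRUE) {
  rule <- match.arg(rule)
  stopifnot(inherits(config, "synthetic_config"))
  geo <- make_lattice(config$rows, config$cols)
  w <- row_standardize(contiguity_weights(geo, rule = rule))
  geo <- gen_outcomes(geo, w, w, config)
  lex <- synthetic_lexicon()
  msgs <- if (corpus) gen_corpus(geo, lex, config) else NULL
  structure(list(geography = geo, w = w, m = w, lexicon = lex,
                 corpus = msgs, truth = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world: %d x %d lattice, lambda = %g, rho = %g, %s messages, seed %d>\n",
    x$truth$rows, x$truth$cols, x$truth$lambda_lag, x$truth$rho_err,
    if (is.null(x$corpus)) "no" else format(nrow(x$corpus), big.mark = ","),
    x$truth$seed))
  invisible(x)
}
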