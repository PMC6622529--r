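#' Pipeline run configuration
#'
#' Collects every input and tuning parameter of the end-to-end analysis.
#' Inputs may be given as file paths (lexicon TSV, message CSV/ND-JSON,
#' geography GeoJSON) or as in-memory objects from this package.
#'
#' @param lexicon path to a lexicon TSV or a [lexicon].
#' @param corpus path to a message table or a message data.frame.
#' @param geography path to a GeoJSON file or a [geography]; must carry
#'   the outcome and covariate columns.
#' @param outcomes character vector of outcome column names.
#' @param covariates character vector of covariate column names used in
#'   the full models (may be empty).
#' @param min_messages per-unit message threshold (default 1000).
#' @param contiguity \code{"queen"} or \code{"rook"}.
#' @param permutations Moran/LISA permutations (default 999).
#' @param seed master seed for all randomness in the run (mandatory).
#' @param alpha significance level for LISA flags and the LM decision
#'   rule (default 0.05).
#' @param top_k words kept in word-shift reports (default 20).
#' @param wordshift_units unit ids to decompose against the pooled
#'   reference; \code{NULL} picks the lowest- and highest-happiness units.
#' @param lexicon_format forwarded to [load_lexicon()].
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(lexicon, corpus, geography, outcomes,
                       covariates = character(0), min_messages = 1000,
                       contiguity = c("queen", "rook"), permutations = 999,
                       seed, alpha = 0.05, top_k = 20,
                       wordshift_units = NULL,
                       lexicon_format = "labmt") {
  contiguity <- match.arg(contiguity)
  if (missing(seed)) stop("a seed is mandatory for pipeline runs")
  structure(list(lexicon = lexicon, corpus = corpus, geography = geography,
                 outcomes = outcomes, covariates = covariates,
                 min_messages = min_messages, contiguity = contiguity,
                 permutations = permutations, seed = as.integer(seed),
                 alpha = alpha, top_k = top_k,
                 wordshift_units = wordshift_units,
                 lexicon_format = lexicon_format),
            class = "run_config")
}

resolve_input <- function(x, loader, class_name) {
  if (inherits(x, class_name)) return(x)
  if (is.character(x) && length(x) == 1) return(loader(x))
  if (class_name == "data.frame" && is.data.frame(x)) return(x)
  stop("cannot resolve input of class ", paste(class(x), collapse = "/"))
}

#' Restrict a geography to a subset of units
#'
#' @param geo a [geography].
#' @param ids unit ids to keep (original order preserved).
#' @return A [geography].
#' @export
subset_geography <- function(geo, ids) {
  stopifnot(inherits(geo, "geography"), all(ids %in% geo$unit_id))
  keep <- geo$unit_id %in% ids
  geography(geo$unit_id[keep], geo$polygons[keep],
            geo$covariates[keep, , drop = FALSE],
            geo$outcomes[keep, , drop = FALSE])
}

pipeline_model_table <- function(fits, model_names) {
  rows <- list()
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    tab <- coef_table(f)
    tab$model <- model_names[i]
    tab <- tab[, c("model", "term", "estimate", "se", "z", "p", "stars")]
    extra <- data.frame(
      model = model_names[i],
      term = c("lambda_lag", "rho_err", "loglik"),
      estimate = c(if (inherits(f, "sarar_fit")) f$lambda_lag else NA,
                   if (inherits(f, "sarar_fit")) f$rho_err else NA,
                   f$loglik),
      se = c(if (inherits(f, "sarar_fit")) f$lambda_se else NA, NA, NA),
      z = NA, p = NA, stars = "", stringsAsFactors = FALSE)
    rows[[i]] <- rbind(tab, extra)
  }
  do.call(rbind, rows)
}

#' Run the end-to-end neighborhood sentiment analysis
#'
#' Executes the full sequence: source whitelist filter, deduplication,
#' point-in-polygon assignment, per-unit corpora with the message
#' threshold, hedonometer scoring, descriptives, global Moran's I and
#' LISA per outcome, then per outcome a three-model ladder — OLS on
#' standardized sentiment, SARAR on the same design, SARAR with the full
#' covariate set — with LM diagnostics on the OLS residuals and a
#' Clogg-style comparison of the sentiment coefficient between the OLS
#' and base SARAR fits.  Word-shift reports decompose selected units
#' against the pooled all-units reference.
#'
#' All outputs are plain CSV plus a JSON manifest, written under
#' \code{out_dir}: \code{descriptives.csv}, \code{unit_scores.csv},
#' \code{dropped_units.csv}, \code{moran.csv}, \code{lisa_<outcome>.csv},
#' \code{models_<outcome>.csv}, \code{lm_tests_<outcome>.csv},
#' \code{comparisons.csv}, \code{wordshift_<unit>.csv},
#' \code{manifest.json}.  Reruns with the same config and seed are
#' byte-identical.
#'
#' @param cfg a [run_config].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the assembled analysis table, fits,
#'   Moran results and paths of written files.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lex <- resolve_input(cfg$lexicon,
                       function(p) load_lexicon(p, cfg$lexicon_format),
                       "lexicon")
  lex <- apply_neutral_filter(lex)
  corpus <- resolve_input(cfg$corpus, read_messages, "data.frame")
  geo <- resolve_input(cfg$geography, read_geography, "geography")
  missing_cols <- setdiff(c(cfg$outcomes, cfg$covariates),
                          c(names(geo$outcomes), names(geo$covariates)))
  if (length(missing_cols) > 0)
    stop("geography lacks required columns: ",
         paste(missing_cols, collapse = ", "))

  corpus <- whitelist_filter(corpus)
  corpus <- deduplicate(corpus)
  assignment <- assign_units(corpus, geo)
  corpora <- build_unit_corpora(corpus, assignment, geo, lex,
                                min_messages = cfg$min_messages)
  if (length(corpora) < 10)
    stop("fewer than 10 units retained; lower min_messages or enlarge corpus")
  utils::write.csv(attr(corpora, "dropped"),
                   file.path(out_dir, "dropped_units.csv"), row.names = FALSE)

  scores <- vapply(corpora, function(u) score_unit(u, lex)$value, numeric(1))
  summary_tab <- unit_corpora_summary(corpora)
  summary_tab$h_avg <- unname(scores)
  utils::write.csv(summary_tab, file.path(out_dir, "unit_scores.csv"),
                   row.names = FALSE)

  retained <- summary_tab$unit_id[!is.na(summary_tab$h_avg)]
  geo_r <- subset_geography(geo, retained)
  unit_attrs <- merge(geo_r$covariates, geo_r$outcomes, by = "unit_id",
                      sort = FALSE)
  analysis <- merge(summary_tab[, c("unit_id", "h_avg")], unit_attrs,
                    by = "unit_id", sort = FALSE)
  analysis <- analysis[match(geo_r$unit_id, analysis$unit_id), ]

  vars <- c("h_avg", cfg$outcomes, cfg$covariates)
  desc <- do.call(rbind, lapply(vars, function(v) data.frame(
    variable = v, n = sum(!is.na(analysis[[v]])),
    mean = mean(analysis[[v]]), sd = stats::sd(analysis[[v]]),
    min = min(analysis[[v]]), max = max(analysis[[v]]),
    stringsAsFactors = FALSE)))
  utils::write.csv(desc, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)

  w <- contiguity_weights(geo_r, rule = cfg$contiguity,
                          require_connected = TRUE)
  w <- row_standardize(w)

  moran_rows <- list(); fits_all <- list(); comparisons <- list()
  for (oc in cfg$outcomes) {
    y <- analysis[[oc]]
    mi <- morans_i(y, w, permutations = cfg$permutations,
                   seed = substream_seed(cfg$seed, paste0("moran_", oc)))
    moran_rows[[oc]] <- data.frame(outcome = oc, I = mi$I,
                                   expected = mi$expected, p_perm = mi$p_perm,
                                   permutations = mi$permutations,
                                   stringsAsFactors = FALSE)
    li <- lisa(y, w, permutations = cfg$permutations,
               seed = substream_seed(cfg$seed, paste0("lisa_", oc)),
               alpha = cfg$alpha)
    utils::write.csv(li, file.path(out_dir, paste0("lisa_", oc, ".csv")),
                     row.names = FALSE)

    d_base <- standardize_predictors(design_matrix(analysis, oc, "h_avg"))
    m1 <- ols_fit(d_base)
    lmt <- lm_diagnostics(m1, d_base, w, alpha = cfg$alpha)
    lm_tab <- do.call(rbind, lapply(
      c("lm_lag", "lm_error", "robust_lm_lag", "robust_lm_error"),
      function(nm) data.frame(test = nm, statistic = lmt[[nm]]$statistic,
                              p = lmt[[nm]]$p, stringsAsFactors = FALSE)))
    lm_tab$recommendation <- lmt$recommendation
    utils::write.csv(lm_tab, file.path(out_dir,
                                       paste0("lm_tests_", oc, ".csv")),
                     row.names = FALSE)
    m2 <- sarar_fit(d_base, w)
    m3 <- if (length(cfg$covariates) > 0)
      sarar_fit(standardize_predictors(
        design_matrix(analysis, oc, c("h_avg", cfg$covariates))), w)
    else NULL
    fits <- if (is.null(m3)) list(m1, m2) else list(m1, m2, m3)
    model_names <- c("ols_base", "sarar_base", "sarar_full")[seq_along(fits)]
    utils::write.csv(pipeline_model_table(fits, model_names),
                     file.path(out_dir, paste0("models_", oc, ".csv")),
                     row.names = FALSE)
    cc <- compare_coefficients(m1, m2, "h_avg", variance_rule = "sum")
    comparisons[[oc]] <- data.frame(outcome = oc, term = "h_avg",
                                    models = "ols_base vs sarar_base",
                                    estimate_diff = cc$estimate_diff,
                                    z = cc$z, p = cc$p,
                                    stringsAsFactors = FALSE)
    fits_all[[oc]] <- fits
  }
  utils::write.csv(do.call(rbind, moran_rows),
                   file.path(out_dir, "moran.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, comparisons),
                   file.path(out_dir, "comparisons.csv"), row.names = FALSE)

  pooled <- pool_corpora(corpora)
  ws_units <- cfg$wordshift_units
  if (is.null(ws_units)) {
    ranked <- summary_tab$unit_id[order(summary_tab$h_avg)]
    ws_units <- unique(c(ranked[1], ranked[length(ranked)]))
  }
  for (uid in ws_units) {
    uc <- corpora[[uid]]
    if (is.null(uc)) next
    rep_u <- tryCatch(word_shift(uc, pooled, lex, top_k = cfg$top_k),
                      error = function(e) NULL)
    if (!is.null(rep_u))
      write_shift_report(rep_u, file.path(out_dir,
                                          paste0("wordshift_", uid, ".csv")))
  }

  manifest <- list(
    package = "sentitract",
    version = as.character(utils::packageVersion("sentitract")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("lexicon", "corpus", "geography"))],
    n_messages_in = nrow(corpus), n_units_retained = length(retained))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(analysis = analysis, fits = fits_all,
                 moran = do.call(rbind, moran_rows), weights = w,
                 out_dir = out_dir))
}
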