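test_that("lattice geography has the expected units and adjacency", {
  g <- make_lattice(2, 2)
  expect_equal(length(g$unit_id), 4L)
  g55 <- make_lattice(5, 5)
  wr <- contiguity_weights(g55, "rook")
  expect_equal(length(wr$neighbours[[1]]), 2L)   # corner
  wq <- contiguity_weights(make_lattice(3, 3), "queen")
  expect_equal(length(wq$neighbours[[5]]), 8L)   # center
  # ids sort lexicographically in spatial (row-major) order
  expect_identical(g55$unit_id, sort(g55$unit_id, method = "radix"))
})

test_that("outcome generation reduces to a linear model when lambda = rho = 0", {
  cfg <- synthetic_config(rows = 6, cols = 6, lambda_lag = 0, rho_err = 0,
                          seed = 5)
  geo <- make_lattice(6, 6)
  w <- row_standardize(contiguity_weights(geo, "queen"))
  g <- gen_outcomes(geo, w, w, cfg)
  X <- cbind(g$covariates$x_smooth, g$covariates$x_noise)
  eps <- attr(g, "epsilon")
  expect_equal(g$outcomes$y,
               cfg$intercept + as.numeric(X %*% cfg$beta) + eps,
               tolerance = 1e-10)
})

test_that("reduced-form solve agrees with fixed-point iteration", {
  cfg <- synthetic_config(rows = 5, cols = 5, lambda_lag = 0.4, rho_err = 0.3,
                          seed = 8)
  geo <- make_lattice(5, 5)
  w <- row_standardize(contiguity_weights(geo, "queen"))
  g <- gen_outcomes(geo, w, w, cfg)
  W <- as.matrix(as_spmatrix(w))
  X <- cbind(g$covariates$x_smooth, g$covariates$x_noise)
  u <- solve(diag(25) - cfg$rho_err * W, attr(g, "epsilon"))
  rhs <- cfg$intercept + as.numeric(X %*% cfg$beta) + u
  y <- rep(0, 25)
  for (it in 1:400) y <- rhs + cfg$lambda_lag * (W %*% y)
  expect_equal(g$outcomes$y, as.numeric(y), tolerance = 1e-8)
})

test_that("spatial lag in the DGP raises Moran's I of the outcome", {
  geo <- make_lattice(10, 10)
  w <- row_standardize(contiguity_weights(geo, "queen"))
  base <- synthetic_config(rows = 10, cols = 10, lambda_lag = 0, rho_err = 0,
                           beta = c(x_smooth = 0, x_noise = 0), seed = 3)
  lagd <- synthetic_config(rows = 10, cols = 10, lambda_lag = 0.6, rho_err = 0,
                           beta = c(x_smooth = 0, x_noise = 0), seed = 3)
  I0 <- morans_i(gen_outcomes(geo, w, w, base)$outcomes$y, w,
                 permutations = 0)$I
  I1 <- morans_i(gen_outcomes(geo, w, w, lagd)$outcomes$y, w,
                 permutations = 0)$I
  expect_gt(I1, I0)
  expect_gt(I1, 0)
})

test_that("generation is seed-reproducible with independent sub-streams", {
  cfg <- synthetic_config(rows = 4, cols = 4, messages_per_unit = 20, seed = 9)
  a <- synthetic_world(cfg)
  b <- synthetic_world(cfg)
  expect_identical(a$geography$outcomes$y, b$geography$outcomes$y)
  expect_identical(a$corpus, b$corpus)
  # regenerating the corpus alone leaves outcomes untouched
  c2 <- gen_corpus(a$geography, a$lexicon, cfg)
  expect_identical(c2, a$corpus)
  # a different seed changes both
  d <- synthetic_world(synthetic_config(rows = 4, cols = 4,
                                        messages_per_unit = 20, seed = 10))
  expect_false(identical(a$corpus$text, d$corpus$text))
})

test_that("corpus generation respects pools, units, sources and duplicates", {
  cfg <- synthetic_config(rows = 3, cols = 3, messages_per_unit = 40,
                          p_offlist_source = 0.3, p_duplicate = 0, seed = 14)
  geo <- make_lattice(3, 3)
  lex <- synthetic_lexicon()
  msgs <- gen_corpus(geo, lex, cfg)
  expect_equal(nrow(msgs), 9 * 40)
  # every token comes from the three designated pools
  pools <- attr(lex, "pools")
  toks <- unique(unlist(tokenize(msgs$text)))
  expect_true(all(toks %in% unlist(pools)))
  # points land in their generating unit
  asg <- assign_units(msgs, geo)
  expect_equal(unname(table(asg)), rep(40L, 9), ignore_attr = TRUE)
  # off-list sources present and filterable
  expect_gt(nrow(msgs) - nrow(whitelist_filter(msgs)), 0)
  expect_error(gen_corpus(geo, tiny_lexicon(), cfg), "pools")
})

test_that("a zero dialect gradient leaves happiness unrelated to the latent factor", {
  cfg <- synthetic_config(rows = 20, cols = 20, messages_per_unit = 200,
                          dialect_gradient = 0, seed = 7)
  sw <- synthetic_world(cfg)
  lex <- apply_neutral_filter(sw$lexicon)
  corpus <- deduplicate(whitelist_filter(sw$corpus))
  corp <- build_unit_corpora(corpus, assign_units(corpus, sw$geography),
                             sw$geography, lex, min_messages = 50)
  h <- vapply(corp, function(u) score_unit(u, lex)$value, numeric(1))
  expect_lt(abs(cor(h, sw$geography$covariates$x_smooth)), 0.1)
})

test_that("a strong dialect gradient makes happiness track the latent factor", {
  cfg <- synthetic_config(rows = 10, cols = 10, messages_per_unit = 150,
                          dialect_gradient = 1, seed = 15)
  sw <- synthetic_world(cfg)
  lex <- apply_neutral_filter(sw$lexicon)
  corpus <- deduplicate(whitelist_filter(sw$corpus))
  corp <- build_unit_corpora(corpus, assign_units(corpus, sw$geography),
                             sw$geography, lex, min_messages = 50)
  h <- vapply(corp, function(u) score_unit(u, lex)$value, numeric(1))
  expect_lt(cor(h, sw$geography$covariates$x_smooth), -0.7)
})

test_that("units generated below the message threshold are dropped downstream", {
  cfg <- synthetic_config(rows = 3, cols = 3,
                          messages_per_unit = c(10, 60), seed = 21)
  sw <- synthetic_world(cfg)
  corp <- build_unit_corpora(sw$corpus,
                             assign_units(sw$corpus, sw$geography),
                             sw$geography, apply_neutral_filter(sw$lexicon),
                             min_messages = 40)
  dropped <- attr(corp, "dropped")
  expect_gt(nrow(dropped), 0)
  expect_true(all(dropped$message_count < 40))
  expect_equal(length(corp) + nrow(dropped), 9L)
})
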