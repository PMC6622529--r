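# Shared fixtures and independent brute-force oracles.

# two in-lexicon ratings used throughout the worked examples
tiny_lexicon <- function() {
  lexicon(c(animals = 6.80, lost = 2.76), name = "tiny")
}

# a 50-word lexicon spanning the non-neutral rating range, deterministic
fixture_lexicon_50 <- function() {
  set.seed(101)
  words <- sprintf("w%02d", 1:50)
  ratings <- c(runif(25, 1, 3.9), runif(25, 6.1, 9))
  lexicon(setNames(ratings, words), name = "fixture50")
}

# two adjacent unit squares A (left) and B (right) sharing the edge x = 1
two_square_geography <- function() {
  geography(c("A", "B"),
            list(A = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
                 B = cbind(c(1, 2, 2, 1), c(0, 0, 1, 1))))
}

make_messages <- function(lon, lat, text = "hello", source = "Twitter for iPhone",
                          user_id = NULL, message_id = NULL) {
  n <- max(length(lon), length(text), length(source))
  data.frame(
    message_id = message_id %||% sprintf("m%03d", seq_len(n)),
    user_id = rep_len(user_id %||% "u1", n),
    timestamp = rep_len("2016-01-01T00:00:00Z", n),
    lon = rep_len(lon, n), lat = rep_len(lat, n),
    source = rep_len(source, n), text = rep_len(text, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# textbook double-sum Moran's I on a dense weight matrix
moran_brute <- function(values, W) {
  z <- values - mean(values)
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# textbook one-step IV estimator: delta = (Z'P Z)^-1 Z'P y, P = H(H'H)^-1 H'
iv_brute <- function(y, Z, H) {
  P <- H %*% solve(crossprod(H)) %*% t(H)
  as.numeric(solve(t(Z) %*% P %*% Z, t(Z) %*% P %*% y))
}

# random weights matrix (symmetric contiguity-style), at least one link per
# unit so there are no islands
random_weights <- function(n, p = 0.3) {
  repeat {
    A <- matrix(runif(n * n) < p, n, n)
    A <- A | t(A)
    diag(A) <- FALSE
    if (all(rowSums(A) > 0)) break
  }
  nb <- lapply(seq_len(n), function(i) which(A[i, ]))
  weights_matrix(nb)
}

dense_weights <- function(w) as.matrix(as_spmatrix(w))
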