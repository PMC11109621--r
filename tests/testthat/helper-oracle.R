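# Independent straight-line reference implementations (explicit loops, no
# shared code with the package internals).  These serve as oracles for the
# decoder forward pass and the metrics.

oracle_relu <- function(z) ifelse(z > 0, z, 0)

oracle_layernorm <- function(x, g, b, eps = 1e-5) {
  # x: length-s vector
  mu <- mean(x)
  sdv <- sqrt(mean((x - mu)^2) + eps)
  (x - mu) / sdv * g + b
}

# X: n x P x s array; returns n x P x s
oracle_scm_attention <- function(X, W_qkv, b_qkv, W_out, H, mask = NULL) {
  d <- dim(X); n <- d[1]; P <- d[2]; s <- d[3]
  sh <- s / H
  if (is.null(mask)) {
    mask <- matrix(FALSE, P, P)
    for (i in 1:P) for (j in 1:P) if (j <= i) mask[i, j] <- TRUE
  }
  out <- array(0, dim = d)
  for (ci in 1:n) {
    qkv <- matrix(0, P, 3 * s)
    for (p in 1:P) {
      for (k in 1:(3 * s)) {
        acc <- b_qkv[k]
        for (j in 1:s) acc <- acc + X[ci, p, j] * W_qkv[j, k]
        qkv[p, k] <- oracle_relu(acc)
      }
    }
    conc <- matrix(0, P, s)
    for (h in 1:H) {
      hc <- ((h - 1) * sh + 1):(h * sh)
      for (p in 1:P) {
        a <- numeric(P)
        for (j in 1:P) {
          if (mask[p, j]) {
            sc <- 0
            for (dd in hc) sc <- sc + qkv[p, dd] * qkv[j, s + dd]
            a[j] <- oracle_relu(sc / sqrt(s))
          } else {
            a[j] <- 0
          }
        }
        for (dd in hc) {
          acc <- 0
          for (j in 1:P) acc <- acc + a[j] * qkv[j, 2 * s + dd]
          conc[p, dd] <- acc
        }
      }
    }
    for (p in 1:P) {
      for (k in 1:s) {
        if (is.null(W_out)) {
          out[ci, p, k] <- conc[p, k]
        } else {
          acc <- 0
          for (j in 1:s) acc <- acc + conc[p, j] * W_out[j, k]
          out[ci, p, k] <- acc
        }
      }
    }
  }
  out
}

# full decoder layer: pre-norm residual attention + feed-forward
oracle_decoder_layer <- function(X, w, H, mask = NULL) {
  d <- dim(X); n <- d[1]; P <- d[2]; s <- d[3]
  Xn <- X
  for (ci in 1:n) for (p in 1:P) {
    Xn[ci, p, ] <- oracle_layernorm(X[ci, p, ], w$g1, w$be1)
  }
  A <- oracle_scm_attention(Xn, w$W_qkv, w$b_qkv, w$W_out, H, mask)
  X1 <- X + A
  out <- X1
  for (ci in 1:n) for (p in 1:P) {
    xn <- oracle_layernorm(X1[ci, p, ], w$g2, w$be2)
    h1 <- numeric(2 * s)
    for (k in 1:(2 * s)) {
      acc <- w$b1[k]
      for (j in 1:s) acc <- acc + xn[j] * w$W1[j, k]
      h1[k] <- oracle_relu(acc)
    }
    for (k in 1:s) {
      acc <- w$b2[k]
      for (j in 1:(2 * s)) acc <- acc + h1[j] * w$W2[j, k]
      out[ci, p, k] <- X1[ci, p, k] + acc
    }
  }
  out
}

oracle_foscttm <- function(X, Y) {
  N <- nrow(X)
  n1 <- n2 <- numeric(N)
  for (i in 1:N) {
    dtrue <- sqrt(sum((X[i, ] - Y[i, ])^2))
    for (j in 1:N) {
      if (sqrt(sum((X[j, ] - Y[i, ])^2)) < dtrue) n1[i] <- n1[i] + 1
      if (sqrt(sum((X[i, ] - Y[j, ])^2)) < dtrue) n2[i] <- n2[i] + 1
    }
  }
  (sum(n1 / N) + sum(n2 / N)) / (2 * N)
}

oracle_knn <- function(ref, labels, query, k) {
  out <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    dd <- sqrt(rowSums(sweep(ref, 2, query[i, ])^2))
    nn <- order(dd)[1:k]
    tab <- table(labels[nn])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      cum <- sapply(top, function(l) sum(dd[nn][labels[nn] == l]))
      top <- sort(top[cum == min(cum)])
    }
    out[i] <- top[1]
  }
  out
}

# mean silhouette width on euclidean distances, hand-rolled to avoid an
# extra dependency
mean_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  sil <- numeric(n)
  for (i in 1:n) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), 1))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}
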