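# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# direct Gaussian convolution with edge replication, kernel cut at 4 sigma
oracleSmooth <- function(v, sigmaPx) {
  r <- ceiling(4 * sigmaPx)
  w <- exp(-((-r):r)^2 / (2 * sigmaPx^2))
  w <- w / sum(w)
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in (-r):r) {
      idx <- min(max(i + j, 1L), n)
      acc <- acc + w[j + r + 1L] * v[idx]
    }
    out[i] <- acc
  }
  out
}

# finite differences: central interior, one-sided ends
oracleGradient <- function(v, h) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (i == 1L) (v[2L] - v[1L]) / h
    else if (i == n) (v[n] - v[n - 1L]) / h
    else (v[i + 1L] - v[i - 1L]) / (2 * h)
  }
  out
}

# windowed mean over +-window/2 (in mm), truncated at the ends
oracleNeighbourhood <- function(pos, v, windowMm) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    sel <- abs(pos - pos[i]) <= windowMm / 2 + 1e-12
    out[i] <- mean(v[sel])
  }
  out
}

# two-way ANOVA from cell/marginal means (balanced designs only).
# With one observation per cell: additive model, residual = interaction SS.
# With r > 1 replicates: interaction term included.
oracleTwoWayAnova <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  na <- nlevels(a); nb <- nlevels(b)
  cellN <- table(a, b)
  r <- unique(as.vector(cellN))
  stopifnot(length(r) == 1L)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  ssA <- nb * r * sum((ma - gm)^2)
  ssB <- na * r * sum((mb - gm)^2)
  ssTot <- sum((y - gm)^2)
  ssCells <- r * sum((mab - gm)^2)
  ssAB <- ssCells - ssA - ssB
  if (r == 1L) {
    ssRes <- ssTot - ssA - ssB
    df <- c(na - 1L, nb - 1L, (na - 1L) * (nb - 1L))
    ss <- c(ssA, ssB, ssRes)
    terms <- c("a", "b", "res")
  } else {
    ssRes <- ssTot - ssCells
    df <- c(na - 1L, nb - 1L, (na - 1L) * (nb - 1L), na * nb * (r - 1L))
    ss <- c(ssA, ssB, ssAB, ssRes)
    terms <- c("a", "b", "ab", "res")
  }
  ms <- ss / df
  dfRes <- df[length(df)]
  msRes <- ms[length(ms)]
  Fv <- ms / msRes
  data.frame(term = terms, df = df, sumsq = ss,
             statistic = ifelse(terms == "res", NA, Fv),
             p_value = ifelse(terms == "res", NA,
                              pf(Fv, df, dfRes, lower.tail = FALSE)))
}

# studentized range statistics for all group pairs, from first principles
oracleTukeyQ <- function(y, g) {
  g <- factor(g)
  m <- tapply(y, g, mean)
  n <- tapply(y, g, length)
  dfRes <- length(y) - nlevels(g)
  mse <- sum((y - ave(y, g))^2) / dfRes
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  q <- apply(pairs, 2L, function(p) {
    (m[p[2L]] - m[p[1L]]) /
      sqrt(mse / 2 * (1 / n[p[1L]] + 1 / n[p[2L]]))
  })
  data.frame(group1 = pairs[2L, ], group2 = pairs[1L, ], q = as.numeric(q))
}
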