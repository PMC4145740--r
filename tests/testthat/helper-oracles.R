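# Independent reference implementations used to compute expected values.
# These are deliberately naive (explicit sums, exhaustive enumeration) and
# share no code with the package internals they check.

# Plug-in mutual information from a joint contingency table, by direct
# evaluation of the double sum over cells (natural log, 0 log 0 = 0).
oracleMIFromTable <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log(p[i, j] / (px[i] * py[j]))
      }
    }
  }
  unname(total)
}

oracleMI <- function(x, y) oracleMIFromTable(table(x, y))

oracleEntropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

# Brute-force greedy mRMR on already-discrete columns: the step objective is
# recomputed from scratch at every step.
oracleMrmr <- function(disc, y) {
  p <- ncol(disc)
  selected <- integer(0)
  for (step in seq_len(p)) {
    remaining <- setdiff(seq_len(p), selected)
    obj <- vapply(remaining, function(j) {
      rel <- oracleMI(disc[, j], y)
      if (length(selected) == 0) return(rel)
      red <- mean(vapply(selected, function(i) oracleMI(disc[, j], disc[, i]),
                         numeric(1)))
      rel - red
    }, numeric(1))
    # same tolerant tie rule as the implementation contract: lowest index
    selected <- c(selected, remaining[which(obj >= max(obj) - 1e-10)[1]])
  }
  selected
}

# Exhaustive search over all size-k supports; returns the minimum residual
# norm and every support attaining it (up to a small tolerance).
oracleBestSupport <- function(A, b, k) {
  combos <- utils::combn(ncol(A), k)
  norms <- apply(combos, 2, function(idx) {
    fit <- stats::lm.fit(A[, idx, drop = FALSE], b)
    sqrt(sum(fit$residuals^2))
  })
  best <- min(norms)
  list(residual = best,
       supports = lapply(which(norms <= best + 1e-8),
                         function(i) sort(combos[, i])))
}

# Straight-line kernel sparse-representation classifier: Laplacian Gram
# system solved with a naive OMP, class decided by the masked-residual rule.
oracleKsrcPredict <- function(trainX, trainY, testX, delta, k) {
  gram <- function(A, B) {
    out <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) {
      for (j in seq_len(nrow(B))) {
        out[i, j] <- exp(-sqrt(sum((A[i, ] - B[j, ])^2)) / delta)
      }
    }
    out
  }
  K <- gram(trainX, trainX)
  n <- nrow(trainX)
  classes <- sort(unique(trainY))
  apply(testX, 1, function(x) {
    b <- as.numeric(gram(trainX, matrix(x, 1)))
    sel <- integer(0)
    r <- b
    for (it in seq_len(k)) {
      if (sqrt(sum(r^2)) <= 1e-6) break
      score <- abs(t(K) %*% r) / sqrt(colSums(K^2))
      score[sel] <- -Inf
      sel <- c(sel, which.max(score))
      coef <- qr.solve(K[, sel, drop = FALSE], b)
      r <- b - K[, sel, drop = FALSE] %*% coef
    }
    alpha <- numeric(n)
    alpha[sel] <- qr.solve(K[, sel, drop = FALSE], b)
    res <- vapply(classes, function(cl) {
      a <- alpha
      a[trainY != cl] <- 0
      sqrt(sum((b - K %*% a)^2))
    }, numeric(1))
    classes[which.min(res)]
  })
}
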