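# Independent brute-force oracles: every formula is re-evaluated with plain
# loops (or first principles), never by calling the implementation under
# test.

oracle_rmse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}

oracle_mae <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Kadaba-form CMC evaluated with explicit double loops.
oracle_cmc <- function(Y) {
  P <- nrow(Y)
  Tn <- ncol(Y)
  ybar_t <- numeric(Tn)
  for (tt in seq_len(Tn)) ybar_t[tt] <- sum(Y[, tt]) / P
  ybar <- sum(Y) / (P * Tn)
  num <- 0
  den <- 0
  for (p in seq_len(P)) {
    for (tt in seq_len(Tn)) {
      num <- num + (Y[p, tt] - ybar_t[tt])^2
      den <- den + (Y[p, tt] - ybar)^2
    }
  }
  num <- num / (Tn * (P - 1))
  den <- den / (P * Tn - 1)
  if (den <= .Machine$double.eps) return(NA_real_)
  ratio <- num / den
  if (ratio > 1) return(NA_real_)
  as.numeric(sqrt(1 - ratio))
}

# AUC by exhaustive pair counting (ties count one half).
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}

oracle_confusion <- function(tp, tn, fp, fn) {
  list(accuracy = (tn + tp) / (tp + tn + fp + fn) * 100,
       sensitivity = tp / (tp + fn) * 100,
       specificity = tn / (tn + fp) * 100)
}

# Pooled-variance two-sample t statistic from the textbook formula.
oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sa2 <- sum((a - mean(a))^2) / (na - 1)
  sb2 <- sum((b - mean(b))^2) / (nb - 1)
  sp2 <- ((na - 1) * sa2 + (nb - 1) * sb2) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Elementary rotation matrices (degrees) for building Euler-angle oracles.
rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  imugait:::quat_to_matrix(q)
}

# A 101-sample pseudo-gait cycle with controllable extrema.
random_cycle <- function(lo = -10, hi = 30) {
  phi <- seq(0, 1, length.out = 101)
  base <- cos(2 * pi * phi) + stats::runif(1, 0, 0.5) * cos(4 * pi * phi + stats::runif(1, 0, 2 * pi))
  base <- (base - min(base)) / (max(base) - min(base))
  lo + (hi - lo) * base
}
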