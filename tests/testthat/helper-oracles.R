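## Independent oracles used across the suite: brute-force assignment
## enumeration, hand-formula Pearson/t statistics, normal-equations
## residuals, and small fixture builders.

## all permutations of 1..n (n <= 6)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

## minimal-cost assignment by exhaustive enumeration
brute_assignment <- function(cost) {
  n <- nrow(cost)
  P <- all_perms(n)
  costs <- apply(P, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(assignment = P[which.min(costs), ], cost = min(costs))
}

## best component matching by enumeration over permutations x sign flips,
## maximizing total |pearson r| between matched columns
brute_match <- function(L_boot, L_ref) {
  K <- ncol(L_ref)
  S <- abs(cor(L_boot, L_ref))
  P <- all_perms(K)
  totals <- apply(P, 1, function(p) sum(S[cbind(p, seq_len(K))]))
  best <- P[which.max(totals), ]
  list(order = best, total = max(totals))
}

## textbook Pearson r and two-sided p from the t transform
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- x - mean(x); sy <- y - mean(y)
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

## textbook pooled two-sample t
pooled_t_oracle <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / (n1 + n0 - 2)
  tval <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = n1 + n0 - 2))
}

## residuals by explicit normal equations: X - D (D'D)^-1 D'X
normal_eq_residuals <- function(X, C) {
  D <- cbind(1, scale(C))
  X - D %*% solve(crossprod(D), crossprod(D, X))
}

## small standard test truth: scaled-down block layout
tiny_truth <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    block_sizes = c(GMV = 10, FA = 4, FC = 6),
    seed = seed
  ), list(...))
  do.call(mode_truth, args)
}

## matrix with feature-style column names
rand_features <- function(n, p, seed = 1, prefix = "F") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("%s_%03d", prefix, seq_len(p))
  X
}
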