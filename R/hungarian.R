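## Optimal bipartite assignment (Hungarian algorithm) used to match
## bootstrap components back to the reference model's components.

#' Solve a square linear assignment problem
#'
#' Minimizes `sum_i cost[i, assignment[i]]` over permutations, using the
#' O(n^3) potentials / augmenting-path form of the Hungarian algorithm.
#'
#' @param cost square numeric cost matrix (rows assigned to columns).
#' @return integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
#' @examples
#' solve_assignment(matrix(c(1, 2, 2, 1), 2, 2))  # 1, 2
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) abort("`cost` must be square.")
  if (anyNA(cost) || any(!is.finite(cost))) abort("`cost` must be finite.")
  if (n == 1) return(1L)
  ## indices 1..n are real columns, n + 1 is the virtual start column
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials (incl. virtual)
  p <- integer(n + 1)      # p[j]: row currently assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) assignment[p[j]] <- j
  assignment
}

#' Match bootstrap components to reference components
#'
#' Computes the absolute Pearson correlation similarity matrix between
#' the columns of a bootstrapped loading matrix and the reference loading
#' matrix, then finds the column permutation maximizing the total matched
#' `|r|` by Hungarian assignment. The sign vector is the sign of each
#' matched pair's correlation, so that `L_boot[, order] * signs`
#' reproduces the reference orientation.
#'
#' @param L_boot p x K bootstrapped loading matrix.
#' @param L_ref p x K reference loading matrix (same shape).
#' @param warn_degenerate warn when a zero-variance column is matched by
#'   fallback (its correlations are treated as 0).
#' @return list with `order` (integer permutation: `order[j]` is the boot
#'   column matched to reference column `j`), `signs` (+1/-1 per
#'   reference column), and `similarity` (the matched `|r|` values).
#' @export
match_components <- function(L_boot, L_ref, warn_degenerate = TRUE) {
  L_boot <- as.matrix(L_boot); L_ref <- as.matrix(L_ref)
  if (!all(dim(L_boot) == dim(L_ref))) abort("loading matrices must have equal shape.")
  if (nrow(L_boot) < 2) abort("need at least 2 rows to correlate columns.")
  K <- ncol(L_ref)
  sd_b <- apply(L_boot, 2, sd); sd_r <- apply(L_ref, 2, sd)
  degenerate <- sd_b == 0 | any(sd_r == 0)
  if (any(sd_b == 0) || any(sd_r == 0)) {
    if (warn_degenerate) warn("zero-variance loading column(s); their correlations are treated as 0.")
  }
  S <- matrix(0, K, K)
  ok_b <- sd_b > 0; ok_r <- sd_r > 0
  if (any(ok_b) && any(ok_r)) {
    S[ok_b, ok_r] <- cor(L_boot[, ok_b, drop = FALSE], L_ref[, ok_r, drop = FALSE])
  }
  ## rows of the assignment problem: boot columns; columns: reference
  a <- solve_assignment(-abs(S))
  order_for_ref <- integer(K)
  order_for_ref[a] <- seq_len(K)
  signs <- vapply(seq_len(K), function(j) {
    s <- sign(S[order_for_ref[j], j])
    if (s == 0) 1 else s
  }, numeric(1))
  list(order = order_for_ref, signs = signs,
       similarity = vapply(seq_len(K), function(j) abs(S[order_for_ref[j], j]),
                           numeric(1)))
}
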