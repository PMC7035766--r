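# Independent oracles and small fixtures shared across the suite.

# Vertices of the ranked simplex {k1 >= k2 >= ... >= kn, sum = 1}:
# the n vectors (1/m, ..., 1/m, 0, ..., 0).
ranked_vertices <- function(n) {
  t(vapply(seq_len(n), function(m) c(rep(1 / m, m), rep(0, n - m)),
           numeric(n)))
}

# Brute-force maximum additive value over the ranked simplex by vertex
# enumeration (exact for a linear objective and delta = 0).
vertex_max_value <- function(problem, ranking, alternative) {
  m <- fitradeoff:::normalized_matrix(problem)[, ranking, drop = FALSE]
  V <- ranked_vertices(length(ranking))
  max(as.numeric(V %*% m[alternative, ]))
}

# Dense grid over the ranked simplex at integer resolution 1/step_inv.
ranked_grid <- function(n, step_inv = 100) {
  stopifnot(n == 4)
  pts <- list()
  for (a in seq(ceiling(step_inv / 4), step_inv)) {
    for (b in seq(0, min(a, step_inv - a))) {
      for (d in seq(0, min(b, step_inv - a - b))) {
        e <- step_inv - a - b - d
        if (e <= d && e >= 0) pts[[length(pts) + 1L]] <- c(a, b, d, e)
      }
    }
  }
  do.call(rbind, pts) / step_inv
}

.oracle_cache <- new.env(parent = emptyenv())
get_grid4 <- function() {
  if (is.null(.oracle_cache$grid4)) .oracle_cache$grid4 <- ranked_grid(4)
  .oracle_cache$grid4
}

# Grid-search oracles: maximum value and potential optimality on the ranked
# simplex sampled at step 0.01.
grid_max_value <- function(problem, ranking, alternative, grid = get_grid4()) {
  m <- fitradeoff:::normalized_matrix(problem)[, ranking, drop = FALSE]
  max(as.numeric(grid %*% m[alternative, ]))
}

grid_potentially_optimal <- function(problem, ranking, tol = 1e-9,
                                     grid = get_grid4()) {
  m <- fitradeoff:::normalized_matrix(problem)[, ranking, drop = FALSE]
  vals <- grid %*% t(m)   # grid points x alternatives
  best <- apply(vals, 1, max)
  apply(vals, 2, function(v) any(v >= best - tol)) |>
    stats::setNames(rownames(m))
}

# Is a weight vector inside a space (up to tolerance)?
in_space <- function(space, k, tol = 1e-9) {
  can <- fitradeoff:::canonical_le(space)
  k <- k[space$criteria]
  all(can$A %*% k <= can$b + tol) &&
    abs(sum(k) - 1) <= tol && all(k >= -tol)
}

# A tiny two-criterion problem with hand-checkable normalization:
# c1 column (10, 5, 0) -> (1, 0.5, 0); c2 column (0, 8, 4) -> (0, 1, 0.5).
tiny_problem <- function() {
  as_decision_problem(matrix(
    c(10, 0,
      5, 8,
      0, 4),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("x", "y", "z"), c("c1", "c2"))
  ))
}

# Recorded criterion-level matrix of the triage study (alternatives x
# criteria), transcribed independently of the aggregation code path.
triage_expected_matrix <- function() {
  matrix(
    c(25, 24, 17, 5,
      15, 29, 20, 8,
      13, 10, 22, 12,
      15, 5, 13, 5,
      10, 15, 26, 12),
    nrow = 5, byrow = TRUE,
    dimnames = list(
      c("ATS", "CTAS", "MTS", "ESI", "SET"),
      c("Guidelines", "Ease of Evaluation", "Ease of Use",
        "Ease of Implementation")
    )
  )
}

final_solution_weights <- function() {
  c("Guidelines" = 0.3058, "Ease of Use" = 0.2676,
    "Ease of Implementation" = 0.2389, "Ease of Evaluation" = 0.1877)
}

# Random tradeoff statement drawn inside the currently feasible ratio
# interval of a random ranked pair; NULL when the draw cannot be turned into
# a feasible statement.
random_statement <- function(space) {
  rk <- space$ranking
  n <- length(rk)
  i <- sample.int(n - 1, 1)
  cands <- seq(i + 1, n)
  j <- cands[sample.int(length(cands), 1)]
  int <- ratio_bounds(space, rk[i], rk[j])
  if (int["upper"] - int["lower"] < 1e-3) return(NULL)
  lvl <- stats::runif(1, int["lower"] + 1e-4, int["upper"] - 1e-4)
  lvl <- min(max(lvl, 1e-3), 1 - 1e-3)
  ans <- sample(c("A", "B", "indifferent"), 1, prob = c(0.45, 0.45, 0.1))
  tradeoff_statement(rk[i], rk[j], lvl, ans)
}
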