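# Internal linear-programming solver.
#
# Every LP in this package is tiny (at most ~15 variables and a few dozen
# rows), so a dense textbook two-phase simplex is entirely adequate.  Bland's
# rule is used in both phases: it cannot cycle and is fully deterministic, so
# LP results are reproducible bit-for-bit for a fixed input.
#
# Problem form: optimize obj'x subject to A x (dir) rhs, x >= 0, where dir is
# one of "<=", ">=", "==" per row.  Arbitrary-sign rhs is handled (rows are
# flipped to non-negative rhs before slack/artificial variables are added).

#' @keywords internal
#' @noRd
lp_solve <- function(objective, A, dir, rhs, maximize = TRUE, tol = 1e-9) {
  n <- length(objective)
  A <- matrix(A, ncol = n)
  m <- nrow(A)
  stopifnot(length(dir) == m, length(rhs) == m)

  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }

  n_sl <- sum(dir != "==")
  n_ar <- sum(dir != "<=")
  N <- n + n_sl + n_ar
  tab <- matrix(0, m, N)
  tab[, seq_len(n)] <- A
  basis <- integer(m)
  si <- 0L
  ai <- 0L
  for (r in seq_len(m)) {
    if (dir[r] == "<=") {
      si <- si + 1L
      tab[r, n + si] <- 1
      basis[r] <- n + si
    } else if (dir[r] == ">=") {
      si <- si + 1L
      tab[r, n + si] <- -1
      ai <- ai + 1L
      tab[r, n + n_sl + ai] <- 1
      basis[r] <- n + n_sl + ai
    } else {
      ai <- ai + 1L
      tab[r, n + n_sl + ai] <- 1
      basis[r] <- n + n_sl + ai
    }
  }
  b <- rhs
  art <- if (n_ar > 0) seq(n + n_sl + 1L, N) else integer(0)

  pivot <- function(state, r, j) {
    tab <- state$tab
    b <- state$b
    piv <- tab[r, j]
    tab[r, ] <- tab[r, ] / piv
    b[r] <- b[r] / piv
    for (q in seq_len(m)) {
      f <- tab[q, j]
      if (q != r && f != 0) {
        tab[q, ] <- tab[q, ] - f * tab[r, ]
        b[q] <- b[q] - f * b[r]
      }
    }
    state$tab <- tab
    state$b <- b
    state$basis[r] <- j
    state
  }

  # Bland's rule: entering = lowest-index column with negative reduced cost;
  # leaving = among min-ratio rows, the one whose basic variable has the
  # lowest index.
  run_phase <- function(state, cost, allowed) {
    repeat {
      red <- cost - as.numeric(cost[state$basis] %*% state$tab)
      red[!allowed] <- 0
      j <- which(red < -tol)
      if (length(j) == 0) return(state)
      j <- j[1]
      col <- state$tab[, j]
      ok <- which(col > tol)
      if (length(ok) == 0) {
        state$status <- "unbounded"
        return(state)
      }
      ratio <- state$b[ok] / col[ok]
      rmin <- min(ratio)
      cand <- ok[ratio <= rmin + tol]
      r <- cand[which.min(state$basis[cand])]
      state <- pivot(state, r, j)
    }
  }

  state <- list(tab = tab, b = b, basis = basis, status = "optimal")

  if (n_ar > 0) {
    cost1 <- c(rep(0, n + n_sl), rep(1, n_ar))
    state <- run_phase(state, cost1, allowed = rep(TRUE, N))
    if (state$status != "optimal" ||
        sum(cost1[state$basis] * state$b) > 1e-7) {
      return(list(status = "infeasible", value = NA_real_,
                  x = rep(NA_real_, n)))
    }
    # pivot leftover zero-level artificials out of the basis where possible
    for (r in which(state$basis %in% art)) {
      real <- which(abs(state$tab[r, seq_len(n + n_sl)]) > tol)
      if (length(real) > 0) state <- pivot(state, r, real[1])
    }
  }

  allowed <- c(rep(TRUE, n + n_sl), rep(FALSE, n_ar))
  cost2 <- c(if (maximize) -objective else objective, rep(0, n_sl + n_ar))
  state <- run_phase(state, cost2, allowed = allowed)
  if (state$status == "unbounded") {
    return(list(status = "unbounded", value = if (maximize) Inf else -Inf,
                x = rep(NA_real_, n)))
  }

  x <- numeric(N)
  x[state$basis] <- state$b
  x <- x[seq_len(n)]
  list(status = "optimal", value = sum(objective * x), x = x)
}

# Space constraints in "<=" canonical form over the scale constants only
# (used by callers that need an explicit polytope description; the solver
# itself accepts mixed directions).
#' @keywords internal
#' @noRd
canonical_le <- function(space) {
  A <- space$A
  rhs <- space$rhs
  dir <- space$dir
  flip <- dir == ">="
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
  }
  eq <- dir == "=="
  if (any(eq)) {
    A <- rbind(A, -A[eq, , drop = FALSE])
    rhs <- c(rhs, -rhs[eq])
  }
  list(A = A, b = rhs)
}

# Solve an LP over a weight space.  Variables are the scale constants in the
# space's criteria order, optionally followed by `n_extra` auxiliary
# non-negative variables; `extra_A`/`extra_b` are additional "<=" rows over
# the full variable vector.
#' @keywords internal
#' @noRd
space_lp <- function(space, objective, maximize = TRUE,
                     n_extra = 0L, extra_A = NULL, extra_b = NULL) {
  n <- length(space$criteria)
  A <- space$A
  if (n_extra > 0L && nrow(A) > 0L) {
    A <- cbind(A, matrix(0, nrow(A), n_extra))
  }
  A <- rbind(A, extra_A, c(rep(1, n), rep(0, n_extra)))
  dir <- c(space$dir, rep("<=", NROW(extra_A)), "==")
  rhs <- c(space$rhs, extra_b, 1)
  lp_solve(objective, A, dir, rhs, maximize = maximize)
}
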