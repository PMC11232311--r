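## Dense two-phase tableau simplex.
##
## Solves   maximize c'x   s.t.  A x = b,  x >= 0   (b >= 0 after row
## flips), with Dantzig pricing and a switch to Bland's rule after a fixed
## number of pivots to guarantee termination on degenerate problems. This
## is the numerical core behind every flux LP in the package; problem
## sizes here are a few hundred rows/columns at most, where a dense
## tableau is simple and reliable.

SIMPLEX_TOL <- 1e-9

## one pivot on tableau T at (row, col); basis bookkeeping done by caller
simplex_pivot <- function(T, row, col) {
  piv <- T[row, col]
  T[row, ] <- T[row, ] / piv
  other <- setdiff(seq_len(nrow(T)), row)
  T[other, ] <- T[other, ] - outer(T[other, col], T[row, ])
  T
}

## core iteration: maximize c'x over {A x = b, x >= 0} starting from the
## given feasible basis. Returns list(status, x, basis, T).
simplex_iterate <- function(T, c_full, basis, bland_after = 2000L,
                            max_iter = 20000L) {
  m <- nrow(T); n <- ncol(T) - 1L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) return(list(status = "maxiter", T = T, basis = basis))
    red <- drop(crossprod(c_full[basis], T[, seq_len(n), drop = FALSE])) - c_full
    red[basis] <- 0  # numerical hygiene
    if (all(red >= -SIMPLEX_TOL)) {
      x <- numeric(n)
      x[basis] <- T[, n + 1L]
      return(list(status = "optimal", x = x, T = T, basis = basis))
    }
    if (it <= bland_after) {
      enter <- which.min(red)
    } else {
      enter <- which(red < -SIMPLEX_TOL)[1]  # Bland: smallest index
    }
    col <- T[, enter]
    pos <- which(col > SIMPLEX_TOL)
    if (length(pos) == 0) return(list(status = "unbounded", T = T, basis = basis))
    ratios <- T[pos, n + 1L] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + SIMPLEX_TOL]
    leave <- cand[which.min(basis[cand])]  # Bland-compatible tie break
    T <- simplex_pivot(T, leave, enter)
    basis[leave] <- enter
  }
}

#' Two-phase simplex for a standard-form LP
#'
#' Maximizes `c'x` subject to `A_eq x = b_eq`, `A_le x <= b_le`, `x >= 0`.
#'
#' @param c_obj Objective coefficients.
#' @param A_eq,b_eq Equality block (may be NULL).
#' @param A_le,b_le Inequality block (may be NULL).
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `x`, `objective`.
#' @keywords internal
simplex_standard <- function(c_obj, A_eq = NULL, b_eq = NULL,
                             A_le = NULL, b_le = NULL) {
  n <- length(c_obj)
  A <- NULL; b <- NULL; slack_of_row <- integer(0)
  n_le <- if (is.null(A_le)) 0L else nrow(A_le)
  n_eq <- if (is.null(A_eq)) 0L else nrow(A_eq)
  m <- n_le + n_eq
  ## columns: x (n) | slacks (n_le) | artificials (added as needed)
  A <- matrix(0, m, n + n_le)
  b <- numeric(m)
  if (n_le > 0) {
    A[seq_len(n_le), seq_len(n)] <- A_le
    A[cbind(seq_len(n_le), n + seq_len(n_le))] <- 1
    b[seq_len(n_le)] <- b_le
  }
  if (n_eq > 0) {
    A[n_le + seq_len(n_eq), seq_len(n)] <- A_eq
    b[n_le + seq_len(n_eq)] <- b_eq
  }
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  ## initial basis: slack column when usable (coefficient +1 after flips),
  ## artificial otherwise
  basis <- integer(m)
  art_rows <- integer(0)
  for (i in seq_len(m)) {
    if (i <= n_le && !neg[i]) {
      basis[i] <- n + i
    } else {
      art_rows <- c(art_rows, i)
    }
  }
  n_art <- length(art_rows)
  total <- n + n_le + n_art
  if (n_art > 0) {
    Aa <- matrix(0, m, n_art)
    Aa[cbind(art_rows, seq_len(n_art))] <- 1
    A <- cbind(A, Aa)
    basis[art_rows] <- n + n_le + seq_len(n_art)
  }
  T <- cbind(A, b)

  if (n_art > 0) {
    c1 <- c(rep(0, n + n_le), rep(-1, n_art))
    ph1 <- simplex_iterate(T, c1, basis)
    if (ph1$status != "optimal") return(list(status = "infeasible", x = NULL, objective = NA_real_))
    obj1 <- sum(c1[ph1$basis] * ph1$T[, ncol(ph1$T)])
    if (obj1 < -1e-7) return(list(status = "infeasible", x = NULL, objective = NA_real_))
    T <- ph1$T; basis <- ph1$basis
    ## drive remaining zero-valued artificials out of the basis
    art_cols <- n + n_le + seq_len(n_art)
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        row <- T[i, seq_len(n + n_le)]
        piv_col <- which(abs(row) > SIMPLEX_TOL)[1]
        if (is.na(piv_col)) {
          ## redundant row: harmless, leave the artificial at value 0
          next
        }
        T <- simplex_pivot(T, i, piv_col)
        basis[i] <- piv_col
      }
    }
    ## forbid artificials from re-entering by zeroing their columns
    T[, art_cols] <- 0
  }
  c2 <- c(c_obj, rep(0, n_le + n_art))
  ph2 <- simplex_iterate(T, c2, basis)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = NULL, objective = NA_real_))
  }
  x <- ph2$x[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(c_obj * x))
}
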