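## Linear programming layer.
##
## All steady-state flux questions in this package (flux consistency, task
## feasibility, the relaxation inside the extraction branch-and-bound) reduce
## to LPs of the form
##     maximize c'v   s.t.  A_eq v = b_eq,  A_le v <= b_le,  lb <= v <= ub.
## They are solved with the package's dense two-phase simplex after
## shifting variables to the nonnegative orthant (x = v - lb).

#' Solve a small dense linear program
#'
#' @param obj Objective coefficients (length n).
#' @param A_eq,b_eq Equality constraints (may be `NULL`).
#' @param A_le,b_le Inequality (`<=`) constraints (may be `NULL`).
#' @param lb,ub Variable bounds (finite; recycled to length n).
#' @param maximize Logical; maximize (default) or minimize.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unsolved"`),
#'   `objective` and the solution `v` on the original scale.
#' @keywords internal
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("solve_lp requires finite bounds", call. = FALSE)
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, v = NULL))
  }
  ## shift x = v - lb >= 0; upper bounds become inequality rows
  A1 <- diag(n)                 # x <= ub - lb
  b1 <- ub - lb
  if (!is.null(A_le)) {
    A_le <- matrix(A_le, ncol = n)
    A1 <- rbind(A1, A_le)
    b1 <- c(b1, b_le - drop(A_le %*% lb))
  }
  A3 <- NULL; b3 <- NULL
  if (!is.null(A_eq)) {
    A3 <- matrix(A_eq, ncol = n)
    b3 <- b_eq - drop(A3 %*% lb)
  }
  res <- simplex_standard(if (maximize) obj else -obj,
                          A_eq = A3, b_eq = b3, A_le = A1, b_le = b1)
  if (res$status == "infeasible") {
    return(list(status = "infeasible", objective = NA_real_, v = NULL))
  }
  if (res$status != "optimal") {
    return(list(status = "unsolved", objective = NA_real_, v = NULL))
  }
  v <- res$x + lb
  if (!maximize) res$objective <- -res$objective
  list(status = "optimal", objective = sum(obj * v), v = v)
}

#' Reactions able to carry steady-state flux
#'
#' A reaction is flux consistent when some flux vector `v` with `S v = 0`
#' within the model bounds has `|v_r| >= epsilon`. Each reaction is tested by
#' maximizing (and, for reversible reactions, minimizing) its own flux, so
#' the result does not depend on reaction ordering.
#'
#' @param model A `metabolic_model` with boundary/exchange reactions or open
#'   bounds.
#' @param epsilon Flux threshold (default `1e-4`).
#' @return Character vector of flux-consistent reaction ids.
#' @export
flux_consistent_reactions <- function(model, epsilon = 1e-4) {
  rxn_ids <- model$reactions$id
  if (length(rxn_ids) == 0) return(character(0))
  S <- as.matrix(stoichiometric_matrix(model, sparse = FALSE))
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  b_eq <- rep(0, nrow(S))
  base <- solve_lp(rep(0, length(rxn_ids)), A_eq = S, b_eq = b_eq,
                   lb = lb, ub = ub)
  if (base$status != "optimal") {
    stop("model admits no steady-state flux distribution at all (base LP infeasible)",
         call. = FALSE)
  }
  n <- length(rxn_ids)
  status <- rep(NA, n)  # NA = undecided, TRUE/FALSE decided
  certify <- function(v) {
    ## any reaction carrying |flux| >= epsilon in a feasible v is consistent
    hot <- which(is.na(status) & abs(v) >= epsilon - 1e-9)
    status[hot] <<- TRUE
  }
  for (j in seq_len(n)) {
    if (!is.na(status[j])) next
    obj <- rep(0, n)
    obj[j] <- 1
    up <- solve_lp(obj, A_eq = S, b_eq = b_eq, lb = lb, ub = ub, maximize = TRUE)
    if (up$status == "optimal") {
      certify(up$v)
      if (up$objective >= epsilon - 1e-9) {
        status[j] <- TRUE
        next
      }
    }
    if (lb[j] < 0) {
      dn <- solve_lp(obj, A_eq = S, b_eq = b_eq, lb = lb, ub = ub, maximize = FALSE)
      if (dn$status == "optimal") {
        certify(dn$v)
        if (dn$objective <= -epsilon + 1e-9) {
          status[j] <- TRUE
          next
        }
      }
    }
    if (is.na(status[j])) status[j] <- FALSE
  }
  rxn_ids[status]
}
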