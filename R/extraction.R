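## Task-constrained extraction of a context-specific sub-model.
##
## Given per-reaction expression weights, select the reaction subset
## maximizing total weight subject to every metabolic task remaining
## feasible (one steady-state flux vector per task, coupled to the binary
## selection through big-M constraints), then prune flux-inconsistent
## reactions while re-verifying the tasks. The binary program is solved
## exactly by branch-and-bound on the LP relaxation.

#' Define a metabolic task
#'
#' A task demands net production of one or more metabolites at a minimum
#' rate, optionally allowing free uptake of a set of boundary metabolites.
#'
#' @param id Task id.
#' @param required_production Named numeric vector, metabolite id -> minimum
#'   production rate (> 0).
#' @param allowed_uptakes Character vector of metabolite ids that may be
#'   taken up freely during the task.
#' @return A `metabolic_task` object.
#' @export
metabolic_task <- function(id, required_production, allowed_uptakes = character(0)) {
  stopifnot(is.character(id), length(id) == 1)
  if (length(required_production) == 0 || is.null(names(required_production)) ||
      any(required_production <= 0)) {
    stop("required_production must be a named vector of positive rates", call. = FALSE)
  }
  structure(list(id = id,
                 required_production = required_production,
                 allowed_uptakes = unique(as.character(allowed_uptakes))),
            class = "metabolic_task")
}

#' Read tasks from TSV
#'
#' Columns: `task_id`, `metabolite`, `min_production`, `uptakes`
#' (comma-separated metabolite ids, may be empty). Multiple rows with the
#' same `task_id` contribute multiple required metabolites.
#'
#' @param path TSV path.
#' @return List of `metabolic_task` objects.
#' @export
read_tasks <- function(path) {
  tab <- read_tsv_table(path)
  lapply(split(tab, tab$task_id), function(rows) {
    upt <- unique(unlist(strsplit(paste(rows$uptakes[!is.na(rows$uptakes)], collapse = ","), ",")))
    upt <- trimws(upt[nzchar(trimws(upt))])
    metabolic_task(rows$task_id[1],
                   stats::setNames(as.numeric(rows$min_production), rows$metabolite),
                   upt)
  })
}

## Augmented LP data for one task: columns of S for auxiliary uptake and
## sink fluxes, with their bounds. Uptake: 0 -> met (coef +1, [0, M]);
## sink: met -> 0 (coef -1, [amount, M]) enforcing the production demand.
task_aux <- function(model, task, big_m = 1000) {
  met_ids <- model$metabolites$id
  missing <- setdiff(c(names(task$required_production), task$allowed_uptakes), met_ids)
  if (length(missing)) {
    stop(sprintf("task '%s' references metabolite(s) not in model: %s",
                 task$id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  cols <- list(); lo <- numeric(0); hi <- numeric(0)
  for (met in task$allowed_uptakes) {
    v <- rep(0, length(met_ids)); v[match(met, met_ids)] <- 1
    cols[[length(cols) + 1L]] <- v; lo <- c(lo, 0); hi <- c(hi, big_m)
  }
  for (met in names(task$required_production)) {
    v <- rep(0, length(met_ids)); v[match(met, met_ids)] <- -1
    cols[[length(cols) + 1L]] <- v
    lo <- c(lo, task$required_production[[met]]); hi <- c(hi, big_m)
  }
  list(A = do.call(cbind, cols), lb = lo, ub = hi)
}

#' Is a task feasible in a model?
#'
#' Solves the steady-state feasibility LP of the model augmented with the
#' task's uptake and demand fluxes.
#'
#' @param model A `metabolic_model`.
#' @param task A `metabolic_task`.
#' @param big_m Flux cap for auxiliary task fluxes.
#' @return Logical.
#' @export
task_feasible <- function(model, task, big_m = 1000) {
  if (nrow(model$reactions) == 0 && length(task$allowed_uptakes) == 0) return(FALSE)
  S <- as.matrix(stoichiometric_matrix(model, sparse = FALSE))
  aux <- task_aux(model, task, big_m)
  A <- cbind(S, aux$A)
  lb <- c(model$reactions$lb, aux$lb)
  ub <- c(model$reactions$ub, aux$ub)
  res <- solve_lp(rep(0, ncol(A)), A_eq = A, b_eq = rep(0, nrow(A)),
                  lb = lb, ub = ub)
  res$status == "optimal"
}

## Branch-and-bound for: maximize obj'x over the LP polytope with x[int_idx]
## binary. Returns list(objective, x) or NULL when infeasible.
milp_branch_bound <- function(obj, A_eq, b_eq, A_le, b_le, lb, ub, int_idx,
                              incumbent = NULL, tol = 1e-6) {
  best_obj <- -Inf
  best_x <- NULL
  if (!is.null(incumbent)) {
    best_obj <- incumbent$objective
    best_x <- incumbent$x
  }
  nodes <- list(list(lb = lb, ub = ub))
  n_nodes <- 0L
  while (length(nodes) > 0) {
    node <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    n_nodes <- n_nodes + 1L
    if (n_nodes > 100000L) stop("branch-and-bound node limit exceeded", call. = FALSE)
    rel <- solve_lp(obj, A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = b_le,
                    lb = node$lb, ub = node$ub)
    if (rel$status != "optimal") next
    if (rel$objective <= best_obj + 1e-9) next
    y <- rel$v[int_idx]
    frac <- abs(y - round(y))
    if (max(frac) <= tol) {
      if (rel$objective > best_obj) {
        best_obj <- rel$objective
        best_x <- rel$v
        best_x[int_idx] <- round(best_x[int_idx])
      }
      next
    }
    j <- int_idx[which.max(frac)]
    dn <- node; dn$ub[j] <- 0
    up <- node; up$lb[j] <- 1
    ## explore the y_j = 1 branch first (stack order: push 0-branch first)
    nodes[[length(nodes) + 1L]] <- dn
    nodes[[length(nodes) + 1L]] <- up
  }
  if (is.null(best_x)) return(NULL)
  list(objective = best_obj, x = best_x, nodes = n_nodes)
}

#' Extract a context-specific sub-model
#'
#' Selects reactions `y_r` in `{0,1}` maximizing the total expression weight
#' `sum(w_r * y_r)` subject to, for each task, the existence of a
#' steady-state flux vector using only selected reactions (plus the task's
#' own uptake/demand fluxes) that meets the task's production demands. All
#' tasks share one mixed-integer program so the selected set satisfies them
#' jointly. The optimum is then pruned: flux-inconsistent kept reactions are
#' removed in ascending (weight, id) order, reverting (and locking in) any
#' removal that breaks a task.
#'
#' Ties between equal-weight optima are broken toward the lexicographically
#' smallest kept-reaction id set via an id-indexed perturbation of at most
#' `1e-6` in total, recorded in the result.
#'
#' @param ref Reference `metabolic_model`.
#' @param weights Named numeric vector of reaction weights (missing
#'   reactions default to 0).
#' @param tasks List of `metabolic_task` objects (may be empty).
#' @param epsilon Flux-consistency threshold (default `1e-4`).
#' @param big_m Big-M flux cap coupling fluxes to selection (default 1000,
#'   matching the default bounds).
#' @return An `extraction_result`: list with `sub_model`, `kept`,
#'   `objective` (unperturbed weight sum over the final kept set),
#'   `objective_milp` (the selection optimum before consistency pruning),
#'   `task_report`, `locked`, `perturbation`, `nodes`.
#' @export
extract_context_model <- function(ref, weights, tasks = list(),
                                  epsilon = 1e-4, big_m = 1000) {
  validate_model(ref)
  rxn_ids <- ref$reactions$id
  n <- length(rxn_ids)
  w <- stats::setNames(rep(0, n), rxn_ids)
  w[intersect(names(weights), rxn_ids)] <- weights[intersect(names(weights), rxn_ids)]
  if (n == 0) {
    return(structure(list(sub_model = ref, kept = character(0), objective = 0,
                          objective_milp = 0,
                          task_report = stats::setNames(logical(0), character(0)),
                          locked = character(0), perturbation = 0, nodes = 0L),
                     class = "extraction_result"))
  }
  for (task in tasks) {
    if (!task_feasible(ref, task, big_m)) {
      stop(sprintf("task '%s' is infeasible even in the full reference model",
                   task$id), call. = FALSE)
    }
  }
  ## tie-break perturbation toward lexicographically smallest kept id set
  delta <- 1e-6 / n
  pert <- delta * rank(rxn_ids, ties.method = "first")
  w_pert <- w - pert

  if (length(tasks) == 0) {
    kept <- rxn_ids[w_pert > 0]
    nodes_used <- 0L
    objective_milp <- sum(w[kept])
  } else {
    S <- as.matrix(stoichiometric_matrix(ref, sparse = FALSE))
    m_met <- nrow(S)
    aux <- lapply(tasks, task_aux, model = ref, big_m = big_m)
    n_aux <- vapply(aux, function(a) length(a$lb), integer(1))
    n_task_vars <- n + n_aux
    total <- n + sum(n_task_vars)
    obj <- c(w_pert, rep(0, sum(n_task_vars)))
    lb <- c(rep(0, n))
    ub <- c(rep(1, n))
    A_eq <- NULL; A_le <- NULL
    eq_rows <- list(); le_rows <- list()
    offset <- n
    for (t in seq_along(tasks)) {
      At <- matrix(0, m_met, total)
      At[, offset + seq_len(n)] <- S
      if (n_aux[t] > 0) At[, offset + n + seq_len(n_aux[t])] <- aux[[t]]$A
      eq_rows[[t]] <- At
      ## |v_r| <= big_m * y_r
      Lt <- matrix(0, 2 * n, total)
      for (r in seq_len(n)) {
        Lt[r, offset + r] <- 1; Lt[r, r] <- -big_m
        Lt[n + r, offset + r] <- -1; Lt[n + r, r] <- -big_m
      }
      le_rows[[t]] <- Lt
      lb <- c(lb, ref$reactions$lb, aux[[t]]$lb)
      ub <- c(ub, ref$reactions$ub, aux[[t]]$ub)
      offset <- offset + n_task_vars[t]
    }
    A_eq <- do.call(rbind, eq_rows)
    b_eq <- rep(0, nrow(A_eq))
    A_le <- do.call(rbind, le_rows)
    b_le <- rep(0, nrow(A_le))
    ## incumbent: the full reference is feasible (checked above)
    inc_x <- c(rep(1, n), rep(0, sum(n_task_vars)))
    incumbent <- list(objective = sum(w_pert), x = inc_x)
    sol <- milp_branch_bound(obj, A_eq, b_eq, A_le, b_le, lb, ub,
                             int_idx = seq_len(n), incumbent = incumbent)
    if (is.null(sol)) stop("extraction MILP infeasible", call. = FALSE)
    kept <- rxn_ids[sol$x[seq_len(n)] > 0.5]
    nodes_used <- sol$nodes %||% 0L
    objective_milp <- sum(w[kept])
  }

  ## reaction subset over the full reference metabolite universe, so task
  ## uptake/demand fluxes stay well-defined during pruning
  with_ref_mets <- function(ids) {
    metabolic_model(ref$metabolites,
                    ref$reactions[ref$reactions$id %in% ids, , drop = FALSE],
                    ref$stoichiometry[intersect(ref$reactions$id, ids)])
  }

  ## flux-consistency pruning with task re-verification
  locked <- character(0)
  repeat {
    if (length(kept) == 0) break
    sub <- subset_model(ref, kept)
    consistent <- flux_consistent_reactions(sub, epsilon)
    candidates <- setdiff(setdiff(kept, consistent), locked)
    if (length(candidates) == 0) break
    if (length(tasks) == 0) {
      ## no tasks to break: removing an inconsistent reaction never makes
      ## another one consistent, so the whole batch can go at once
      kept <- intersect(kept, c(consistent, locked))
      next
    }
    ord <- order(w[candidates], candidates)
    removed_any <- FALSE
    for (r in candidates[ord]) {
      trial <- setdiff(kept, r)
      trial_model <- with_ref_mets(trial)
      ok <- all(vapply(tasks, function(tk) task_feasible(trial_model, tk, big_m),
                       logical(1)))
      if (ok) {
        kept <- trial
        removed_any <- TRUE
        break  # recompute consistency from scratch after each removal
      } else {
        locked <- c(locked, r)
      }
    }
    if (!removed_any) break
  }

  sub_model <- subset_model(ref, kept)
  task_report <- vapply(tasks, function(tk) task_feasible(with_ref_mets(kept), tk, big_m),
                        logical(1))
  names(task_report) <- vapply(tasks, `[[`, character(1), "id")
  structure(list(sub_model = sub_model,
                 kept = sort(kept),
                 objective = sum(w[kept]),
                 objective_milp = objective_milp,
                 task_report = task_report,
                 locked = locked,
                 perturbation = max(pert),
                 nodes = nodes_used),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("extraction_result: %d reactions kept, objective %.4g, %d/%d tasks feasible\n",
              length(x$kept), x$objective, sum(x$task_report), length(x$task_report)))
  invisible(x)
}

#' Differential-expression signature of a sub-model
#'
#' Genes of the sub-model differentially expressed below `p_adj_sig`, split
#' by the sign of the fold change. Significant genes with a log2 fold change
#' of exactly zero belong to neither side and are reported separately.
#'
#' @param sub_model A `metabolic_model` (typically an extraction result's
#'   `sub_model`).
#' @param deg Differential-expression data.frame (`gene`, `log2fc`, `p`,
#'   `p_adj`).
#' @param p_adj_sig Adjusted-p threshold (default 0.01).
#' @return List with character vectors `up`, `down` and `zero_fc`.
#' @export
gem_signature <- function(sub_model, deg, p_adj_sig = 0.01) {
  if (is.null(deg) || nrow(deg) == 0) {
    return(list(up = character(0), down = character(0), zero_fc = character(0)))
  }
  sig <- deg[deg$p_adj < p_adj_sig & deg$gene %in% sub_model$genes, , drop = FALSE]
  zero <- sig$gene[sig$log2fc == 0]
  if (length(zero)) {
    message(sprintf("gem_signature: %d significant gene(s) with zero log2fc excluded from both directions",
                    length(zero)))
  }
  list(up = sort(sig$gene[sig$log2fc > 0]),
       down = sort(sig$gene[sig$log2fc < 0]),
       zero_fc = sort(zero))
}
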