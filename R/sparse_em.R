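## EM-PS-Lasso: topology inference by L1 regularization of the association
## constants of an over-complete ("redundant") network.  The M-step maximizes
##
##   Q'(theta, theta_old) = Q(theta, theta_old) - lambda * sum_s |K_s|
##
## and, because every K_s is constrained nonnegative, |K_s| = K_s: the
## penalized objective is smooth on the feasible region and exact zeros arise
## at the bound of the quasi-Newton search.  A network path with K = 0 is
## trajectory-equivalent to a deleted path, so the sparsity pattern of K *is*
## the inferred topology.

#' Penalize a Q evaluator with the Lasso term
#'
#' Wraps a Q evaluator (e.g. `q_fun` from [e_step()]) so that it returns
#' `Q(theta) - lam * sum(K_s)` over the association constants identified by
#' `K_names`.
#'
#' @param q_fun Function taking a flat named `theta_sys` vector (forwarded to
#'   the wrapped evaluator) and returning Q.
#' @param lam Penalty strength, `>= 0`.
#' @param K_names Names of the association-constant entries of `theta_sys`;
#'   default: all entries whose name starts with `"K"`.
#' @return A function with the same signature returning Q'.
#' @export
penalized_q <- function(q_fun, lam, K_names = NULL) {
  force(q_fun); force(lam); force(K_names)
  function(theta_sys, ...) {
    kn <- K_names %||% grep("^K", names(theta_sys), value = TRUE)
    q_fun(theta_sys, ...) - lam * sum(abs(theta_sys[kn]))
  }
}

#' Count effective regulatory paths
#'
#' Paths whose association constant exceeds a practical threshold.  After
#' strong regularization some surviving constants are nonzero but so small
#' that they have no influence on the dynamics; the threshold separates those
#' from genuinely active paths.
#'
#' @param x A `hill_network`, an `em_fit`, or a `lasso_run`.
#' @param threshold Effectiveness threshold on K (units 1/concentration),
#'   default `1e-3`.
#' @return Integer count; the selected path ids are attached as attribute
#'   `"path_ids"`.
#' @export
count_effective_paths <- function(x, threshold = 1e-3) {
  net <- effective_network(x)
  eff <- net$paths$path_id[net$paths$K > threshold]
  structure(length(eff), path_ids = eff)
}

effective_network <- function(x) {
  if (inherits(x, "hill_network")) x
  else if (inherits(x, "em_fit")) x$network
  else if (inherits(x, "lasso_run")) x$fit$network
  else emps_error("emps_contract", "expected a hill_network, em_fit or lasso_run")
}

#' Biological-consistency check of an inferred network
#'
#' Flags any ordered gene pair (source, target) for which both the activator
#' and the repressor path are simultaneously effective — a regulator cannot
#' both activate and repress the same target at once, so such models are
#' rejected from model selection.
#'
#' @param x A fitted network (`hill_network`, `em_fit`, or `lasso_run`).
#' @param threshold Effectiveness threshold on K (see
#'   [count_effective_paths()]).
#' @return List with `consistent` flag and a `violations` data.frame of
#'   offending (source, target) pairs.
#' @export
check_consistency <- function(x, threshold = 1e-3) {
  net <- effective_network(x)
  p <- net$paths[net$paths$K > threshold, , drop = FALSE]
  key <- paste(p$source, p$target, sep = "->")
  both <- unique(key[duplicated(key)])   # a pair can only repeat across signs
  viol <- if (length(both)) {
    sp <- strsplit(both, "->", fixed = TRUE)
    data.frame(source = vapply(sp, `[`, "", 1), target = vapply(sp, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else data.frame(source = character(), target = character(),
                    stringsAsFactors = FALSE)
  list(consistent = nrow(viol) == 0, violations = viol)
}

#' Fit a redundant model by EM-PS-Lasso
#'
#' The EM loop of [run_em()] with the Lasso penalty on association constants
#' in the M-step.  With `lam = 0` this is exactly [run_em()] (bit-identical
#' under the same seed).  Records the per-iteration K values so the path
#' elimination dynamics can be inspected.
#'
#' @inheritParams run_em
#' @param lam Penalty strength `lambda >= 0`.
#' @param test Optional held-out [timecourse_dataset()]; if given, the test
#'   log-likelihood of the final model is evaluated with the particle filter
#'   (test-cell initial means default to the first test observations).
#' @param threshold Effectiveness threshold for path counting.
#' @return Object of class `lasso_run`: `lam`, `fit` (the `em_fit`),
#'   `K_history`, `effective_paths`, `train_loglik`, `test_loglik`,
#'   `consistent`, `violations`.
#' @export
run_em_lasso <- function(model, dataset, lam, P = 500, n_back = P, iters = 100,
                         seed = 1, control = em_control(), test = NULL,
                         threshold = 1e-3) {
  if (lam < 0) emps_error("emps_contract", "lambda must be >= 0")
  fit <- em_core(model, dataset, lam = lam, P = P, n_back = n_back,
                 iters = iters, seed = seed, control = control)
  test_ll <- if (!is.null(test)) {
    m <- fit$model
    m$mu <- NULL   # test cells get their own diffuse initial distributions
    evaluate_loglik(m, test, P = P, seed = seed + 1L)
  } else NA_real_
  eff <- count_effective_paths(fit, threshold)
  cons <- check_consistency(fit, threshold)
  structure(list(lam = lam, fit = fit, K_history = fit$K_history,
                 effective_paths = attr(eff, "path_ids"),
                 n_effective = as.integer(eff),
                 train_loglik = tail(fit$loglik_history, 1),
                 test_loglik = test_ll,
                 consistent = cons$consistent, violations = cons$violations),
            class = "lasso_run")
}

#' @export
print.lasso_run <- function(x, ...) {
  cat(sprintf("<lasso_run> lambda = %g: %d effective paths [%s], %s\n",
              x$lam, x$n_effective, paste(x$effective_paths, collapse = ","),
              if (x$consistent) "consistent" else "INCONSISTENT"))
  cat(sprintf(" train loglik %.3f, test loglik %.3f\n",
              x$train_loglik, x$test_loglik))
  invisible(x)
}

#' Regularization-path sweep and model selection
#'
#' Runs EM-PS-Lasso once per lambda on the training data, evaluates each
#' final model on held-out test data, counts effective paths and applies the
#' selection rule: candidate models are the *consistent* runs whose test
#' log-likelihood is within `sel_tol` of the best consistent run; among
#' candidates the sparsest is reported as the headline selection (ties are
#' kept as co-candidates rather than forced to a single winner).
#'
#' @param model Redundant model ([build_redundant_model()]) wrapped in a
#'   [state_space_model()].
#' @param train,test Training and held-out [timecourse_dataset()]s.
#' @param lam_grid Nonempty vector of penalty strengths; default logarithmic
#'   grid `c(0.1, 0.3, 1, 3, 10, 15, 30)`.
#' @inheritParams run_em_lasso
#' @param sel_tol Log-likelihood tolerance defining "near-maximal" test fit.
#' @return Object of class `lambda_sweep`: `runs` (by increasing lambda),
#'   `summary` table, `candidates` (lambda values), `selected` (headline
#'   lambda), and any per-lambda `failures`.
#' @export
lambda_sweep <- function(model, train, test,
                         lam_grid = c(0.1, 0.3, 1, 3, 10, 15, 30),
                         P = 500, n_back = P, iters = 100, seed = 1,
                         control = em_control(), threshold = 1e-3,
                         sel_tol = 2) {
  if (!length(lam_grid)) emps_error("emps_contract", "lambda grid must be nonempty")
  lam_grid <- sort(lam_grid)
  runs <- list(); failures <- list()
  for (i in seq_along(lam_grid)) {
    lam <- lam_grid[i]
    r <- tryCatch(
      run_em_lasso(model, train, lam = lam, P = P, n_back = n_back,
                   iters = iters, seed = seed, control = control,
                   test = test, threshold = threshold),
      error = function(e) e)
    if (inherits(r, "error")) failures[[as.character(lam)]] <- conditionMessage(r)
    else runs[[length(runs) + 1L]] <- r
  }
  sel <- select_candidates(runs, sel_tol = sel_tol)
  structure(list(runs = runs, summary = sweep_report(runs, sel_tol = sel_tol),
                 candidates = sel$candidates, selected = sel$selected,
                 failures = failures, lam_grid = lam_grid, threshold = threshold),
            class = "lambda_sweep")
}

select_candidates <- function(runs, sel_tol = 2) {
  if (!length(runs)) return(list(candidates = numeric(0), selected = NA_real_))
  lam <- vapply(runs, `[[`, numeric(1), "lam")
  tll <- vapply(runs, `[[`, numeric(1), "test_loglik")
  cons <- vapply(runs, `[[`, logical(1), "consistent")
  neff <- vapply(runs, `[[`, integer(1), "n_effective")
  ok <- cons & is.finite(tll)
  if (!any(ok)) return(list(candidates = numeric(0), selected = NA_real_))
  best <- max(tll[ok])
  cand <- ok & tll >= best - sel_tol
  ## headline: sparsest candidate; ties resolved toward larger lambda
  ord <- order(neff[cand], -lam[cand])
  list(candidates = lam[cand], selected = lam[cand][ord[1]])
}

#' @export
print.lambda_sweep <- function(x, ...) {
  cat("<lambda_sweep>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("candidates: %s; selected: %s\n",
              paste(x$candidates, collapse = ", "), x$selected))
  if (length(x$failures))
    cat("failed lambdas:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
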