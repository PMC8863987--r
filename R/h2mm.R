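#' Fit a photon-by-photon hidden Markov model
#'
#' Maximum-likelihood estimation of a `q`-state model from photon arrival
#' sequences, by Baum-Welch EM in which the transition kernel between
#' consecutive photons separated by `dt` clock ticks is the exact matrix
#' power `trans^dt`, and the E-step transition expectations account exactly
#' for transitions occurring during the unobserved ticks inside each gap.
#' No binning is applied: the data enter as integer arrival times and
#' stream indices.
#'
#' Iteration stops when the absolute log-likelihood improvement falls below
#' `tol` (default 1e-3 nats) or after `max_iter` steps. EM never decreases
#' the likelihood; the fitted object records the full trace. After
#' convergence the most likely state path (Viterbi) is computed and the
#' integrated complete likelihood `ICL = -2 ln p(y, s_hat | m, lambda_hat)
#' + K ln(n)` and `BIC = -2 ln p(y | lambda_hat) + K ln(n)` are filled in,
#' with `K = q^2 + (r - 1) q - 1` free parameters and `n` the total photon
#' count.
#'
#' @param data An [obs_set] (see [as_obs_set()]).
#' @param q Number of states.
#' @param init Optional initial [state_model()]; defaults to
#'   [default_init_model()] with the given `seed`.
#' @param max_iter Maximum EM iterations (default 1000). `max_iter = 0`
#'   returns the evaluated initial model unchanged.
#' @param tol Absolute log-likelihood convergence threshold in nats.
#' @param seed Seed for the default initializer (recorded in the fit).
#' @param verbose Print per-iteration log-likelihoods.
#' @return An object of class `h2mm`: the fitted `model`, `loglik`,
#'   per-iteration `trace`, `converged`, `niter`, `n`, `K`,
#'   `viterbi_logpost`, `ICL`, `BIC`, plus bookkeeping (`q`, `r`,
#'   `clock_period`, `seed`).
#' @seealso [h2mm_scan()] for model selection across state counts,
#'   [predict.h2mm()] for Viterbi decoding and dwells.
#' @export
h2mm <- function(data, q, init = NULL, max_iter = 1000L, tol = 1e-3,
                 seed = 1L, verbose = FALSE) {
  stopifnot(inherits(data, "obs_set"), q >= 1)
  if (is.null(init)) init <- default_init_model(q, data$r, seed)
  stopifnot(inherits(init, "state_model"))
  if (init$q != q) stop("init has ", init$q, " states, expected ", q)
  if (init$r != data$r) stop("init has r = ", init$r, ", data has r = ",
                             data$r)
  run <- cpp_em_run(init$prior, init$trans, init$emission,
                    data$streams, data$gaps, data$lens,
                    as.integer(max_iter), tol)
  if (!isTRUE(run$finite)) {
    bad <- state_model(run$prior, run$trans, run$emis)
    diagnose_nonfinite(bad, data)
  }
  if (isTRUE(run$starved))
    warning("state(s) starved of expected occupancy during EM; ",
            "their emission rows were kept")
  model <- state_model(run$prior, run$trans, run$emis)
  converged <- if (max_iter > 0) isTRUE(run$converged) else FALSE
  iter <- if (max_iter > 0) run$niter else 0L
  final_ll <- run$loglik
  trace <- if (is.null(run$trace)) final_ll else run$trace
  if (verbose)
    message(sprintf("final loglik %.6f after %d EM iterations%s",
                    final_ll, iter,
                    if (converged) " (converged)" else ""))
  vit <- cpp_viterbi(model$prior, model$trans, model$emission,
                     data$streams, data$gaps, data$lens)
  K <- n_free_params(q, data$r)
  out <- list(model = model, loglik = final_ll, trace = trace,
              converged = converged, niter = iter, n = data$n,
              K = K, viterbi_logpost = vit$logpost,
              ICL = icl(vit$logpost, K, data$n),
              BIC = bic(final_ll, K, data$n),
              q = q, r = data$r, clock_period = data$clock_period,
              seed = seed, n_bursts = length(data$lens))
  class(out) <- "h2mm"
  out
}

# locate the first burst with a non-finite likelihood and abort informatively
diagnose_nonfinite <- function(model, data) {
  for (b in seq_along(data$lens)) {
    sub <- obs_subset(data, b)
    ll <- cpp_loglik(model$prior, model$trans, model$emission,
                     sub$streams, sub$gaps, sub$lens)
    if (!is.finite(ll))
      stop("non-finite likelihood (first offending burst: ", b - 1L,
           "); an observed stream may have zero emission probability in ",
           "every state")
  }
  stop("non-finite likelihood")
}

#' One EM (Baum-Welch) step
#'
#' Re-estimates prior, transition and emission parameters from the pooled
#' expected counts across all bursts (including the gap-interior transition
#' expectations), and reports the log-likelihood of the *input* model.
#'
#' @param model A `state_model`.
#' @param data An `obs_set`.
#' @return List with the re-estimated `model` and `loglik` of the input
#'   model.
#' @export
em_step <- function(model, data) {
  stopifnot(inherits(model, "state_model"), inherits(data, "obs_set"))
  st <- cpp_em_step(model$prior, model$trans, model$emission,
                    data$streams, data$gaps, data$lens)
  if (!isTRUE(st$finite)) diagnose_nonfinite(model, data)
  if (any(st$starved))
    warning("state(s) ", paste(which(st$starved) - 1L, collapse = ", "),
            " starved of expected occupancy; emission row kept")
  list(model = state_model(st$prior, st$trans, st$emis), loglik = st$loglik)
}

#' Scaled forward-backward pass
#'
#' Computes the total log-likelihood, per-photon posterior state
#' probabilities (gamma) and the expected-count accumulators of the E-step:
#' prior counts, gap-expanded transition counts and per-state expected
#' stream counts. Per-step normalization keeps the recursion exact for
#' sequences of up to millions of photons.
#'
#' @param model A `state_model`.
#' @param data An `obs_set`.
#' @param want_gamma Return the per-photon posterior matrix.
#' @return List `loglik`, `burst_loglik`, `finite`, `prior_counts`,
#'   `trans_counts`, `emis_counts` and (optionally) `gamma` (n x q).
#' @export
forward_backward <- function(model, data, want_gamma = TRUE) {
  stopifnot(inherits(model, "state_model"), inherits(data, "obs_set"))
  res <- cpp_forward_backward(model$prior, model$trans, model$emission,
                              data$streams, data$gaps, data$lens,
                              want_gamma)
  res
}

#' Most likely state path (Viterbi)
#'
#' Finds the state path maximizing the joint probability of path and
#' observations, with `trans^dt` gap factors, and returns the joint
#' log-posterior `ln p(y, s_hat | m, lambda_hat)` — the quantity entering
#' the ICL.
#'
#' @param model A `state_model`.
#' @param data An `obs_set`.
#' @return List with `paths` (list of 0-based state vectors per burst),
#'   `logpost` (total) and `burst_logpost`.
#' @export
viterbi <- function(model, data) {
  stopifnot(inherits(model, "state_model"), inherits(data, "obs_set"))
  res <- cpp_viterbi(model$prior, model$trans, model$emission,
                     data$streams, data$gaps, data$lens)
  list(paths = split_by_burst(res$path, data$lens),
       logpost = res$logpost, burst_logpost = res$burst_logpost)
}

#' @export
print.h2mm <- function(x, ...) {
  cat("Photon-by-photon HMM fit: q =", x$q, "states, r =", x$r,
      "streams\n")
  cat(sprintf("  %d photons in %d bursts; loglik %.3f (%s after %d EM iterations)\n",
              x$n, x$n_bursts, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$niter))
  cat(sprintf("  ICL %.3f  BIC %.3f  (K = %d)\n", x$ICL, x$BIC, x$K))
  print(x$model)
  invisible(x)
}

#' @export
summary.h2mm <- function(object, ...) {
  es <- state_es(object$model)
  rates <- rates_per_second(object$model, object$clock_period)
  out <- list(fit = object,
              states = data.frame(state = seq_len(object$q) - 1L,
                                  prior = object$model$prior,
                                  E_raw = es$E_raw, S_raw = es$S_raw),
              rates_per_s = rates)
  class(out) <- "summary.h2mm"
  out
}

#' @export
print.summary.h2mm <- function(x, ...) {
  print(x$fit)
  cat("\nTransition rate constants (s^-1, row -> column):\n")
  print(round(x$rates_per_s, 1))
  invisible(x)
}

#' @export
coef.h2mm <- function(object, ...) {
  es <- state_es(object$model)
  list(prior = object$model$prior, trans = object$model$trans,
       emission = object$model$emission, E_raw = es$E_raw,
       S_raw = es$S_raw,
       rates_per_s = rates_per_second(object$model, object$clock_period))
}

#' @export
logLik.h2mm <- function(object, ...) {
  structure(object$loglik, df = object$K, nobs = object$n,
            class = "logLik")
}

#' Viterbi decoding of a fitted model
#'
#' @param object An `h2mm` fit.
#' @param data The `obs_set` to decode (typically the training data).
#' @param type `"states"` for per-burst Viterbi paths, `"dwells"` for the
#'   dwell table of [segment_dwells()].
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.h2mm <- function(object, data, type = c("states", "dwells"), ...) {
  type <- match.arg(type)
  vit <- viterbi(object$model, data)
  if (type == "states") return(vit$paths)
  segment_dwells(vit$paths, data)
}

#' @export
plot.h2mm <- function(x, ...) {
  plot(seq_along(x$trace) - 1L, x$trace, type = "b", pch = 16, cex = 0.6,
       xlab = "EM iteration", ylab = "log-likelihood", ...)
  invisible(x)
}
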