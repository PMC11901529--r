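#' Parameter specification for calibration
#'
#' @param name Parameter name.
#' @param lower,upper Bounds (lower < upper), on the natural scale.
#' @param transform "linear" or "log10" (log10 requires positive bounds;
#'   the optimizer then searches in log10 space).
#' @return List of class `param_spec`.
#' @export
param_spec <- function(name, lower, upper, transform = c("linear", "log10")) {
  transform <- match.arg(transform)
  if (!(lower < upper)) stop("param_spec: need lower < upper")
  if (transform == "log10" && lower <= 0)
    stop("param_spec: log10 transform requires positive bounds")
  structure(list(name = name, lower = lower, upper = upper,
                 transform = transform), class = "param_spec")
}

spec_to_internal <- function(x, specs) {
  vapply(seq_along(specs), function(i) {
    if (specs[[i]]$transform == "log10") log10(x[i]) else x[i]
  }, numeric(1))
}

spec_from_internal <- function(u, specs) {
  x <- vapply(seq_along(specs), function(i) {
    if (specs[[i]]$transform == "log10") 10^u[i] else u[i]
  }, numeric(1))
  names(x) <- vapply(specs, `[[`, character(1), "name")
  x
}

spec_bounds_internal <- function(specs) {
  lo <- vapply(specs, function(s)
    if (s$transform == "log10") log10(s$lower) else s$lower, numeric(1))
  hi <- vapply(specs, function(s)
    if (s$transform == "log10") log10(s$upper) else s$upper, numeric(1))
  list(lower = lo, upper = hi)
}

#' Shuffled Complex Evolution (SCE-UA) global optimizer
#'
#' Canonical SCE-UA: a random initial population on the bounded box is
#' ranked and partitioned into complexes; each complex evolves by
#' competitive complex evolution (simplex reflection / contraction with
#' random replacement of persistent failures, sub-complexes drawn by
#' triangular rank probability); complexes are periodically shuffled.
#' Convergence when the relative best-objective improvement over
#' `kstop` shuffles falls below `tol`, or at `max_eval` evaluations.
#' Deterministic given `seed`; never evaluates outside the bounds.
#'
#' @param objective Function mapping a named parameter vector (natural
#'   scale) to a finite scalar to minimize.
#' @param specs List of [param_spec()].
#' @param n_complexes Number of complexes (default `max(2, dim)`).
#' @param m_per_complex Points per complex (default `2 * dim + 1`).
#' @param n_evolve Evolution steps per complex per shuffle (default
#'   `2 * dim + 1`).
#' @param max_eval Maximum objective evaluations.
#' @param tol Relative convergence tolerance on the best objective.
#' @param kstop Number of shuffles over which improvement is measured.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List of class `calib_result`: `par` (named, natural scale),
#'   `value`, `n_eval`, `trace` (best-so-far per shuffle), `converged`.
#' @export
sce_ua <- function(objective, specs, n_complexes = NULL,
                   m_per_complex = NULL, n_evolve = NULL,
                   max_eval = 5000, tol = 1e-6, kstop = 5, seed = 1) {
  dim <- length(specs)
  stopifnot(dim >= 1)
  if (is.null(n_complexes)) n_complexes <- max(2, dim)
  if (is.null(m_per_complex)) m_per_complex <- 2 * dim + 1
  if (is.null(n_evolve)) n_evolve <- 2 * dim + 1
  q <- dim + 1  # sub-complex (simplex) size
  b <- spec_bounds_internal(specs)
  lo <- b$lower; hi <- b$upper
  rng <- hi - lo
  n_eval <- 0
  f_int <- function(u) {
    n_eval <<- n_eval + 1
    val <- objective(spec_from_internal(u, specs))
    if (!is.finite(val)) Inf else val
  }

  with_seed(seed, {
    npop <- n_complexes * m_per_complex
    if (max_eval <= npop)
      stop("sce_ua: max_eval must exceed the initial population size")
    pop <- matrix(runif(npop * dim), npop, dim)
    pop <- sweep(sweep(pop, 2, rng, "*"), 2, lo, "+")
    fv <- apply(pop, 1, f_int)
    if (mean(!is.finite(fv)) > 0.5)
      stop("sce_ua: objective non-finite at more than half the initial points")
    ord <- order(fv); pop <- pop[ord, , drop = FALSE]; fv <- fv[ord]

    trace <- fv[1]
    converged <- FALSE
    repeat {
      for (ic in seq_len(n_complexes)) {
        idx <- seq(ic, npop, by = n_complexes)  # systematic partition
        cpop <- pop[idx, , drop = FALSE]
        cfv <- fv[idx]
        m <- nrow(cpop)
        for (step in seq_len(n_evolve)) {
          # triangular selection probabilities over ranks
          p <- 2 * (m + 1 - seq_len(m)) / (m * (m + 1))
          sel <- sort(sample.int(m, q, prob = p))
          spop <- cpop[sel, , drop = FALSE]
          sfv <- cfv[sel]
          worst <- which.max(sfv)
          centroid <- colMeans(spop[-worst, , drop = FALSE])
          # reflection
          cand <- 2 * centroid - spop[worst, ]
          if (any(cand < lo | cand > hi))
            cand <- lo + runif(dim) * rng
          fc <- f_int(cand)
          if (fc >= sfv[worst]) {
            # contraction
            cand <- (centroid + spop[worst, ]) / 2
            fc <- f_int(cand)
            if (fc >= sfv[worst]) {
              cand <- lo + runif(dim) * rng
              fc <- f_int(cand)
            }
          }
          spop[worst, ] <- cand
          sfv[worst] <- fc
          cpop[sel, ] <- spop
          cfv[sel] <- sfv
          o <- order(cfv)
          cpop <- cpop[o, , drop = FALSE]
          cfv <- cfv[o]
          if (n_eval >= max_eval) break
        }
        pop[idx, ] <- cpop
        fv[idx] <- cfv
        if (n_eval >= max_eval) break
      }
      ord <- order(fv); pop <- pop[ord, , drop = FALSE]; fv <- fv[ord]
      trace <- c(trace, min(trace[length(trace)], fv[1]))
      ns <- length(trace)
      if (ns > kstop) {
        prev <- trace[ns - kstop]
        if (abs(prev - trace[ns]) <= tol * max(abs(prev), 1e-12)) {
          converged <- TRUE
        }
      }
      if (converged || n_eval >= max_eval) break
    }

    structure(list(par = spec_from_internal(pop[1, ], specs),
                   value = fv[1], n_eval = n_eval, trace = trace,
                   converged = converged),
              class = "calib_result")
  })
}
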