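#' Restricted log-likelihood of the two-component mixed model
#'
#' Evaluates, by dense linear algebra, the REML log-likelihood of
#' `y ~ N(Xb, V)` with `V = G sigma_g2 + I sigma_e2`:
#' \deqn{\ell_R = -\tfrac12\left[(n-p)\log 2\pi + \log|V| +
#'       \log|X^\top V^{-1}X| + y^\top P y\right]}
#' with `P = Vinv - Vinv X (X' Vinv X)^-1 X' Vinv`. The additive constant
#' convention (the `(n-p) log 2pi` term) is fixed and documented here; all
#' package code uses the same convention.
#'
#' @param y numeric response vector (length n).
#' @param X fixed-effect design matrix (n x p, full column rank).
#' @param G symmetric covariance structure matrix (n x n), a `grm`, or a
#'   `grm_eigen`.
#' @param sigma_g2,sigma_e2 variance components; `V` must be positive
#'   definite.
#' @return the restricted log-likelihood (scalar).
#' @export
restricted_log_likelihood <- function(y, X, G, sigma_g2, sigma_e2) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (inherits(G, "grm")) G <- G$matrix
  if (inherits(G, "grm_eigen")) G <- G$vectors %*% (G$values * t(G$vectors))
  V <- sigma_g2 * G + diag(sigma_e2, n)
  R <- tryCatch(chol(V), error = function(e) stop_mlm("V is not positive definite"))
  logdetV <- 2 * sum(log(diag(R)))
  Vinv_y <- backsolve(R, forwardsolve(t(R), y))
  Vinv_X <- backsolve(R, forwardsolve(t(R), X))
  XtVX <- crossprod(X, Vinv_X)
  Rx <- tryCatch(chol(XtVX), error = function(e) stop_mlm("X'V^-1X is singular"))
  logdetXVX <- 2 * sum(log(diag(Rx)))
  beta <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, Vinv_y)))
  yPy <- sum(y * Vinv_y) - sum(crossprod(X, Vinv_y) * beta)
  -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetXVX + yPy)
}

# REML internals in the rotated basis: with G = U D U', V = U (sg D + se I) U',
# so after y* = U'y, X* = U'X the covariance is diagonal with weights
# w_i = sg d_i + se. Returns loglik, P y, traces and quadratic forms needed by
# the AI and EM updates. All O(n p^2) per evaluation.
reml_core <- function(ystar, Xstar, d, sg, se) {
  n <- length(ystar)
  p <- ncol(Xstar)
  w <- sg * d + se
  if (any(w <= 0)) return(NULL)
  a <- 1 / w
  aX <- Xstar * a
  XtVX <- crossprod(Xstar, aX)
  Rx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(Rx)) return(NULL)
  Xty <- crossprod(Xstar, a * ystar)
  beta <- backsolve(Rx, forwardsolve(t(Rx), Xty))
  Py <- a * ystar - aX %*% beta
  yPy <- sum(ystar * Py)
  ll <- -0.5 * ((n - p) * log(2 * pi) + sum(log(w)) + 2 * sum(log(diag(Rx))) + yPy)
  # P z for arbitrary z (diagonal V)
  Pfun <- function(z) {
    a * z - aX %*% backsolve(Rx, forwardsolve(t(Rx), crossprod(Xstar, a * z)))
  }
  # tr(P M) for diagonal M = diag(m): sum(a m) - tr((X'VinvX)^-1 X' a m a X)
  trP <- function(m) {
    B <- crossprod(Xstar * (a * m), aX)
    sum(a * m) - sum(diag(backsolve(Rx, forwardsolve(t(Rx), B))))
  }
  list(ll = ll, Py = as.vector(Py), Pfun = Pfun, trP = trP, beta = beta,
       XtVX = XtVX, Rx = Rx)
}

#' AI-REML estimation of the variance components
#'
#' Estimates `(sigma_g2, sigma_e2)` of the model `y = Xb + g + e`,
#' `g ~ N(0, G sigma_g2)`, `e ~ N(0, I sigma_e2)` by restricted maximum
#' likelihood using the average-information algorithm with an EM fallback:
#' each iteration proposes an AI (quasi-Newton) step; if the step leaves the
#' feasible region or decreases the restricted likelihood, an EM update is
#' tried, then progressively halved AI steps. Accepted iterations therefore
#' never decrease the likelihood. Components are floored at
#' `1e-6 * var(y)` ("bending"). Convergence is declared when the likelihood
#' change and the parameter change both fall below `tol`.
#'
#' Internally the model is rotated by the eigenvectors of `G` so every
#' iteration costs O(n p^2); the optimum is identical to dense evaluation of
#' [restricted_log_likelihood()].
#'
#' @param y response vector (standardized expression for one gene).
#' @param X fixed-effect design (n x p); callers typically pass an intercept
#'   plus the candidate dosage.
#' @param G a `grm`, `grm_eigen`, or symmetric matrix.
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on loglik and parameter change
#'   (default 1e-8).
#' @param start optional length-2 starting values (sigma_g2, sigma_e2);
#'   default splits `var(y)` evenly.
#' @return an object of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `loglik`, `n_iter`, `converged`, plus the accepted `loglik_trace`.
#' @export
reml_fit <- function(y, X = matrix(1, length(y), 1), G, max_iter = 100L,
                     tol = 1e-8, start = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) stop_mlm("need n >= p + 2 observations")
  eg <- grm_eigen(G)
  d <- eg$values
  if (all(abs(d - 1) < 1e-12)) {
    warning("G is (numerically) an identity matrix; sigma_g2 and sigma_e2 are not separately identifiable",
            call. = FALSE)
  }
  ystar <- as.vector(crossprod(eg$vectors, y))
  Xstar <- crossprod(eg$vectors, X)
  vy <- stats::var(y)
  floor_val <- 1e-6 * vy
  theta <- if (is.null(start)) c(vy / 2, vy / 2) else as.numeric(start)
  theta <- pmax(theta, floor_val)
  core <- reml_core(ystar, Xstar, d, theta[1], theta[2])
  if (is.null(core)) stop_mlm("likelihood undefined at starting values")
  trace <- core$ll
  converged <- FALSE
  iter <- 0L
  ll_at <- function(sg, se) {
    cand <- reml_core(ystar, Xstar, d, sg, se)
    if (is.null(cand)) -Inf else cand$ll
  }
  # constrained optimum with one component pinned to the floor (the standard
  # boundary treatment: profile the free component in 1-D)
  profile_boundary <- function(which_floored) {
    upper <- max(10 * vy, 10 * sum(theta))
    if (which_floored == 1L) {
      opt <- stats::optimize(function(se) ll_at(floor_val, se),
                             interval = c(floor_val, upper), maximum = TRUE,
                             tol = 1e-10)
      c(floor_val, opt$maximum)
    } else {
      opt <- stats::optimize(function(sg) ll_at(sg, floor_val),
                             interval = c(floor_val, upper), maximum = TRUE,
                             tol = 1e-10)
      c(opt$maximum, floor_val)
    }
  }
  for (iter in seq_len(max_iter)) {
    Py <- core$Py
    dPy <- d * Py      # A_g P y with A_g = diag(d)
    PdPy <- core$Pfun(dPy)
    PPy <- core$Pfun(Py)
    # score_i = -1/2 [tr(P A_i) - y'P A_i P y]
    score <- -0.5 * c(core$trP(d) - sum(Py * dPy),
                      core$trP(rep(1, n)) - sum(Py * Py))
    # AI_ij = 1/2 y'P A_i P A_j P y
    AI <- 0.5 * matrix(c(sum(dPy * PdPy), sum(dPy * PPy),
                         sum(dPy * PPy), sum(Py * PPy)), 2, 2)
    delta <- tryCatch(solve(AI, score), error = function(e) score / max(diag(AI), 1e-12))
    proposals <- lapply(c(1, 0.5, 0.25, 0.125),
                        function(s) pmax(theta + s * delta, floor_val))
    # EM fallback: theta_i <- theta_i + theta_i^2 (y'P A_i P y - tr(P A_i)) / n
    em <- theta + theta^2 * c(sum(Py * dPy) - core$trP(d),
                              sum(Py * Py) - core$trP(rep(1, n))) / n
    proposals <- c(proposals, list(pmax(em, floor_val)))
    # when a proposal touches a floor, offer the exact constrained optimum
    # along that boundary so iterations do not crawl
    floored <- unique(unlist(lapply(proposals, function(p) which(p <= floor_val))))
    for (wf in floored) proposals <- c(proposals, list(profile_boundary(wf)))
    lls <- vapply(proposals, function(p) ll_at(p[1], p[2]), numeric(1))
    best <- which.max(lls)
    if (lls[best] >= core$ll - 1e-12) {
      prop <- proposals[[best]]
      dll <- lls[best] - core$ll
      dpar <- max(abs(prop - theta))
      theta <- prop
      core <- reml_core(ystar, Xstar, d, prop[1], prop[2])
      trace <- c(trace, core$ll)
      if (abs(dll) < tol || dpar < tol * (1 + max(theta))) converged <- TRUE
    } else {
      converged <- TRUE  # no uphill move: at a (possibly boundary) optimum
    }
    if (converged) break
  }
  structure(
    list(sigma_g2 = theta[1], sigma_e2 = theta[2], loglik = core$ll,
         n_iter = iter, converged = converged, loglik_trace = trace,
         floor = floor_val),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> sigma_g2 = ", signif(x$sigma_g2, 5),
      ", sigma_e2 = ", signif(x$sigma_e2, 5),
      ", loglik = ", signif(x$loglik, 8),
      " (", x$n_iter, " iter, ", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  invisible(x)
}
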