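#' Solve the mixed model for fixed effects and polygenic predictions
#'
#' With variance components fixed at their REML estimates, solves for the
#' fixed-effect vector and the polygenic BLUP either via Henderson's mixed
#' model equations
#' \deqn{\begin{bmatrix} X^\top X & X^\top \\ X & I + G^{-1}\lambda
#'       \end{bmatrix}\begin{bmatrix}\beta\\u\end{bmatrix} =
#'       \begin{bmatrix}X^\top y\\ y\end{bmatrix},\qquad
#'       \lambda = \sigma_e^2/\sigma_g^2,}
#' or via the equivalent generalized-least-squares closed form
#' `beta = (X'Vinv X)^-1 X'Vinv y`, `u = sigma_g2 G Vinv (y - X beta)` with
#' `V = G sigma_g2 + I sigma_e2`. The two routes agree whenever `G` is
#' invertible; `method = "henderson"` falls back to GLS (with a message) when
#' it is not. With `sigma_g2` at the zero floor the fit degenerates to
#' ordinary least squares and `u = 0`.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (n x p).
#' @param G a `grm` or symmetric matrix (dense; this solver is the reference
#'   algebra, not the scan's fast path).
#' @param vc a `variance_components` object (or list with `sigma_g2`,
#'   `sigma_e2`).
#' @param method `"henderson"` (default) or `"gls"`.
#' @return list with `beta` (length p), `u` (length n), `method`.
#' @export
solve_mme <- function(y, X, G, vc, method = c("henderson", "gls")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (inherits(G, "grm")) G <- G$matrix
  sg <- vc$sigma_g2
  se <- vc$sigma_e2
  if (se <= 0) stop_mlm("sigma_e2 must be positive")
  floor_val <- vc$floor %||% 1e-6 * stats::var(y)
  if (sg <= floor_val) {
    beta <- stats::lm.fit(X, y)$coefficients
    return(list(beta = unname(beta), u = rep(0, n), method = "ols"))
  }
  if (method == "henderson") {
    Ginv <- tryCatch(solve(G), error = function(e) NULL)
    if (is.null(Ginv)) {
      message("G is singular; solving via the GLS form instead")
      return(solve_mme(y, X, G, vc, method = "gls"))
    }
    lambda <- se / sg
    C <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + Ginv * lambda))
    rhs <- c(crossprod(X, y), y)
    sol <- tryCatch(solve(C, rhs), error = function(e) stop_mlm("singular Henderson system"))
    p <- ncol(X)
    list(beta = sol[seq_len(p)], u = sol[p + seq_len(n)], method = "henderson")
  } else {
    V <- sg * G + diag(se, n)
    R <- chol(V)
    Vinv_y <- backsolve(R, forwardsolve(t(R), y))
    Vinv_X <- backsolve(R, forwardsolve(t(R), X))
    XtVX <- crossprod(X, Vinv_X)
    beta <- solve(XtVX, crossprod(X, Vinv_y))
    resid <- y - X %*% beta
    Vinv_r <- backsolve(R, forwardsolve(t(R), resid))
    u <- sg * as.vector(G %*% Vinv_r)
    list(beta = as.vector(beta), u = u, method = "gls")
  }
}
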