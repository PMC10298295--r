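#' Test a single variant's effect on one gene's expression
#'
#' Fits the mixed model `y = intercept + x beta + g + e` by AI-REML
#' ([reml_fit()]) and tests `beta = 0` with a 1-df Wald chi-square:
#' `statistic = (beta / se)^2`, with the standard error taken from the
#' `(X' Vinv X)^-1` diagonal at the REML optimum. The sign convention follows
#' the dosage coding: positive beta means the minor allele increases
#' expression. P-values are additionally stored in log10 space so magnitudes
#' far below double underflow remain representable.
#'
#' An intercept is always included: expression is consumed standardized, so
#' the intercept is near zero, but keeping it protects against fixture drift.
#'
#' @param y expression vector for one gene (assumed standardized).
#' @param x_dosage minor-allele dosage vector of the candidate variant; must
#'   be polymorphic in the sample.
#' @param G the candidate's leave-one-chromosome-out `grm` (or `grm_eigen`
#'   when the caller has pre-decomposed it, e.g. inside a scan).
#' @param covariates optional numeric matrix of additional fixed covariates.
#' @param snp_id,gene_id identifiers carried into the result.
#' @return an object of class `association_result`: `beta`, `se`,
#'   `statistic`, `p`, `log10_p`, `vc` (the `variance_components`), `snp_id`,
#'   `gene_id`.
#' @export
test_variant <- function(y, x_dosage, G, covariates = NULL,
                         snp_id = NA_character_, gene_id = NA_character_) {
  y <- as.numeric(y)
  x <- as.numeric(x_dosage)
  if (length(x) != length(y)) stop_mlm("y and x_dosage lengths differ")
  if (stats::var(x, na.rm = TRUE) == 0) {
    stop_mlm("monomorphic dosage for ", snp_id, "; pair must be skipped upstream")
  }
  X <- cbind(`(Intercept)` = 1, dosage = x)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  eg <- grm_eigen(G)
  vc <- reml_fit(y, X, eg)
  # beta and its SE at the optimum, in the rotated basis
  ystar <- as.vector(crossprod(eg$vectors, y))
  Xstar <- crossprod(eg$vectors, X)
  core <- reml_core(ystar, Xstar, eg$values, vc$sigma_g2, vc$sigma_e2)
  if (is.null(core)) stop_mlm("singular system at the REML optimum")
  XtVXinv <- chol2inv(core$Rx)
  beta <- core$beta[2]
  se <- sqrt(XtVXinv[2, 2])
  stat <- (beta / se)^2
  log10_p <- stats::pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  structure(
    list(beta = beta, se = se, statistic = stat,
         p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         log10_p = log10_p, vc = vc, snp_id = snp_id, gene_id = gene_id),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> ", x$snp_id, " x ", x$gene_id,
      ": beta = ", signif(x$beta, 4), " (se ", signif(x$se, 4), "), p = ",
      format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}
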