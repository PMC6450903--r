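#' Per-variant linear GWAS
#'
#' Fits, for every variant, the ordinary least squares regression of the
#' outcome on that variant's dosage plus the covariates (and an
#' intercept). The fits are vectorized by Frisch-Waugh-Lovell
#' residualization: outcome and dosages are residualized on the
#' covariates once, after which each per-variant slope is a simple
#' projection, numerically identical to the full multiple regression.
#'
#' @param dosages Numeric matrix, individuals x variants.
#' @param outcome Numeric vector.
#' @param covariates Optional numeric matrix or vector of covariates
#'   (without intercept).
#' @return Data frame with `beta`, `se` and logical `ok`; zero-variance
#'   variants get `NA` estimates with `ok = FALSE`.
#' @export
per_snp_linear_gwas <- function(dosages, outcome, covariates = NULL) {
  stopifnot(nrow(dosages) == length(outcome))
  n <- length(outcome)
  Q <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, covariates)
  k <- ncol(Q)
  qrq <- qr(Q)
  y_r <- qr.resid(qrq, outcome)
  g_r <- qr.resid(qrq, dosages)
  sgg <- colSums(g_r^2)
  ok <- sgg > 0
  beta <- se <- rep(NA_real_, ncol(dosages))
  beta[ok] <- colSums(g_r[, ok, drop = FALSE] * y_r) / sgg[ok]
  rss <- sum(y_r^2) - beta[ok]^2 * sgg[ok]
  df <- n - k - 1
  se[ok] <- sqrt(pmax(rss, 0) / df / sgg[ok])
  if (any(!ok)) warning(sum(!ok), " zero-variance variant(s) flagged NA")
  data.frame(beta = beta, se = se, ok = ok)
}

#' Per-variant logistic GWAS
#'
#' Maximum-likelihood logistic regression of a binary outcome on each
#' variant's dosage plus covariates, one fit per variant via
#' [stats::glm.fit()]. Non-convergence and (quasi-)separation, detected
#' as extreme coefficients or standard errors, are flagged per variant.
#'
#' @param dosages Numeric matrix, individuals x variants.
#' @param labels Binary outcome (0/1 or logical).
#' @param covariates Optional covariate matrix/vector (without
#'   intercept).
#' @return Data frame with `beta`, `se`, `ok`.
#' @export
per_snp_logistic_gwas <- function(dosages, labels, covariates = NULL) {
  labels <- as.numeric(labels)
  stopifnot(nrow(dosages) == length(labels))
  if (length(unique(labels)) < 2) stop("both outcome classes must be present")
  n <- length(labels)
  base <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, covariates)
  m <- ncol(dosages)
  beta <- se <- rep(NA_real_, m)
  ok <- rep(FALSE, m)
  n_sep <- 0L
  for (j in seq_len(m)) {
    g <- dosages[, j]
    if (stats::var(g) == 0) next
    fit <- suppressWarnings(
      stats::glm.fit(cbind(base, g), labels, family = stats::binomial())
    )
    p <- ncol(base) + 1
    cf <- fit$coefficients[p]
    if (!fit$converged || is.na(cf)) next
    r <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    vcv <- tryCatch(chol2inv(r), error = function(e) NULL)
    if (is.null(vcv)) next
    s <- sqrt(vcv[p, p])
    if (abs(cf) > 15 || s > 100) {     # separation: unbounded likelihood
      n_sep <- n_sep + 1L
      next
    }
    beta[j] <- cf; se[j] <- s; ok[j] <- TRUE
  }
  if (n_sep > 0) warning(n_sep, " variant(s) flagged for separation")
  out <- data.frame(beta = beta, se = se, ok = ok)
  attr(out, "n_separated") <- n_sep
  out
}

#' Per-variant Cox proportional-hazards GWAS
#'
#' Partial-likelihood fit of survival time on each variant's dosage plus
#' covariates, using the Efron approximation for ties.
#'
#' @param dosages Numeric matrix, individuals x variants.
#' @param times Positive survival/censoring times.
#' @param events Event indicator (1 = event, 0 = censored); default all
#'   events (no censoring).
#' @param covariates Optional covariate matrix/vector.
#' @return Data frame with `beta` (log hazard ratio), `se`, `ok`.
#' @export
per_snp_survival_gwas <- function(dosages, times, events = NULL,
                                  covariates = NULL) {
  stopifnot(nrow(dosages) == length(times), all(times > 0))
  if (is.null(events)) events <- rep(1, length(times))
  if (all(events == 0)) stop("no events observed")
  y <- survival::Surv(times, events)
  ctrl <- survival::coxph.control()
  m <- ncol(dosages)
  beta <- se <- rep(NA_real_, m)
  ok <- rep(FALSE, m)
  for (j in seq_len(m)) {
    g <- dosages[, j]
    if (stats::var(g) == 0) next
    x <- if (is.null(covariates)) matrix(g, ncol = 1) else cbind(g, covariates)
    storage.mode(x) <- "double"
    fit <- tryCatch(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL, init = NULL,
                          control = ctrl, weights = NULL,
                          method = "efron", rownames = NULL),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$coefficients[1])) next
    beta[j] <- fit$coefficients[1]
    se[j] <- sqrt(fit$var[1, 1])
    ok[j] <- is.finite(beta[j]) && is.finite(se[j])
  }
  data.frame(beta = beta, se = se, ok = ok)
}
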