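#' Kaplan-Meier survival curve
#'
#' Product-limit estimate; censored observations reduce the at-risk count
#' without a survival drop. S(0) = 1 and S is non-increasing.
#'
#' @param times positive event/censoring times.
#' @param events 1 = event observed, 0 = censored.
#' @return Object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `n_censor`, and the underlying `survfit` object as `fit`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  if (any(!is.finite(times)) || any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor, fit = fit),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km a `km_curve`.
#' @param t times at which to evaluate the step function.
#' @return Survival probabilities S(t).
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    drop_idx <- km$time <= tt
    if (!any(drop_idx)) 1 else km$surv[max(which(drop_idx))]
  }, numeric(1))
}

#' Log-rank test across groups
#'
#' Standard (observed - expected)^2 / variance statistic with
#' `df = groups - 1`.
#'
#' @param groups either a list of `list(times=, events=)` per group, or a
#'   data frame-style call with `times`, `events`, `labels` vectors.
#' @param times,events,labels alternative vector interface.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(groups = NULL, times = NULL, events = NULL,
                         labels = NULL) {
  if (!is.null(groups)) {
    if (length(groups) < 2) stop("log-rank needs at least 2 groups")
    if (any(vapply(groups, function(g) length(g$times) == 0, logical(1))))
      stop("log-rank groups must be non-empty")
    times <- unlist(lapply(groups, `[[`, "times"))
    events <- unlist(lapply(groups, `[[`, "events"))
    labels <- rep(seq_along(groups),
                  vapply(groups, function(g) length(g$times), 1L))
  }
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("log-rank needs at least 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ labels)
  df <- nlevels(labels) - 1
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjustment with monotonicity enforcement; q-values are always >=
#' the raw p-values and the adjustment is invariant to input order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Cox proportional-hazards modeling of gene prognosis
#'
#' Univariate mode loops genes: each covariate column is (optionally)
#' z-scored, fitted alone against progression-free survival with Efron tie
#' handling, and the per-gene Wald p-values are BH-adjusted. A hazard ratio
#' above 1 means higher covariate values associate with shorter survival
#' (detrimental); below 1, protective. Multivariable mode fits all columns
#' jointly.
#'
#' @param covariates samples-by-covariates numeric matrix (rownames = sample
#'   IDs matching the clinical table).
#' @param clinical a `clinical_table`.
#' @param mode `"univariate"` or `"multivariable"`.
#' @param scale_covariates z-score each covariate first (coefficients are
#'   then per SD)? Default `TRUE`.
#' @return Object of class `cox_result`: data frame with `covariate`, `coef`,
#'   `hr`, `se`, `p`, `q`, `flag` (`"ok"`, `"constant"`, or
#'   `"no_convergence"`).
#' @export
cox_fit <- function(covariates, clinical,
                    mode = c("univariate", "multivariable"),
                    scale_covariates = TRUE) {
  mode <- match.arg(mode)
  covariates <- as.matrix(covariates)
  clinical <- clinical_table(as.data.frame(clinical))
  idx <- match(rownames(covariates), clinical$sample)
  if (anyNA(idx)) stop("clinical table does not cover all covariate rows")
  if (sum(clinical$event[idx]) < 1) stop("at least one event is required")
  y <- survival::Surv(clinical$pfs_time[idx], clinical$event[idx])
  if (!all(is.finite(covariates))) stop("covariates must be finite")

  fit_one <- function(xmat) {
    tryCatch({
      fit <- survival::coxph(y ~ xmat, ties = "efron")
      s <- summary(fit)$coefficients
      list(coef = s[, "coef"], se = s[, "se(coef)"],
           p = s[, "Pr(>|z|)"], ok = TRUE)
    }, error = function(e) list(ok = FALSE),
       warning = function(w) {
      fit <- suppressWarnings(survival::coxph(y ~ xmat, ties = "efron"))
      s <- summary(fit)$coefficients
      conv <- all(is.finite(s[, "coef"])) && all(abs(s[, "coef"]) < 15)
      list(coef = s[, "coef"], se = s[, "se(coef)"], p = s[, "Pr(>|z|)"],
           ok = conv)
    })
  }

  if (mode == "univariate") {
    res <- lapply(colnames(covariates), function(gene) {
      x <- covariates[, gene]
      if (stats::sd(x) == 0)
        return(data.frame(covariate = gene, coef = NA_real_, hr = NA_real_,
                          se = NA_real_, p = NA_real_, flag = "constant",
                          stringsAsFactors = FALSE))
      if (scale_covariates) x <- (x - mean(x)) / stats::sd(x)
      f <- fit_one(cbind(x))
      if (!isTRUE(f$ok))
        return(data.frame(covariate = gene, coef = NA_real_, hr = NA_real_,
                          se = NA_real_, p = NA_real_,
                          flag = "no_convergence", stringsAsFactors = FALSE))
      data.frame(covariate = gene, coef = unname(f$coef),
                 hr = exp(unname(f$coef)), se = unname(f$se),
                 p = unname(f$p), flag = "ok", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- NA_real_
    tested <- out$flag == "ok"
    out$q[tested] <- bh_fdr(out$p[tested])
  } else {
    keep <- apply(covariates, 2, stats::sd) > 0
    if (any(!keep))
      warning("dropping constant covariate(s): ",
              paste(colnames(covariates)[!keep], collapse = ", "))
    X <- covariates[, keep, drop = FALSE]
    if (scale_covariates) X <- scale(X)
    f <- fit_one(X)
    if (!isTRUE(f$ok)) stop("multivariable Cox fit did not converge")
    out <- data.frame(covariate = colnames(X), coef = unname(f$coef),
                      hr = exp(unname(f$coef)), se = unname(f$se),
                      p = unname(f$p), flag = "ok", stringsAsFactors = FALSE)
    out$q <- bh_fdr(out$p)
  }
  rownames(out) <- NULL
  class(out) <- c("cox_result", class(out))
  out
}
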