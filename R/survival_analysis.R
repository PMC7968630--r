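## Native survival machinery: Kaplan-Meier product-limit estimator with
## Greenwood variance and complementary log-log confidence bands, the
## two-group log-rank test, and Cox proportional hazards fitted by
## Newton-Raphson on the partial likelihood with Breslow (default) or Efron
## tie handling.  These are deliberately self-contained; an external
## survival library is used only as a cross-check oracle in the test suite.

#' Kaplan-Meier product-limit estimate
#'
#' Survival is estimated over the distinct event times; the variance of
#' log S(t) uses Greenwood's formula and the 95\% band is computed on the
#' complementary log-log scale, which keeps the bounds inside [0, 1] for
#' small cohorts.
#'
#' @param time Follow-up times (months).
#' @param event Logical (or 0/1) event indicators; FALSE = censored.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `km_curve`: data frame with one row per distinct
#'   event time (`time`, `n_risk`, `n_event`, `surv`, `se`, `lower`,
#'   `upper`) plus attributes `n`, `max_time`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), all(time >= 0))
  event <- as.logical(event)
  n <- length(time)
  if (n < 1L) stop("no observations")
  if (!any(event)) {
    warning("no events; survival is 1 everywhere")
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0),
                      se = numeric(0), lower = numeric(0),
                      upper = numeric(0))
    return(structure(out, n = n, max_time = max(time), class =
                       c("km_curve", "data.frame")))
  }
  etimes <- sort(unique(time[event]))
  n_risk <- vapply(etimes, function(t) sum(time >= t), integer(1))
  n_event <- vapply(etimes, function(t) sum(time == t & event), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  ## Greenwood: Var(log S) = cumsum d / (n (n - d))
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), NA_real_))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- upper <- rep(NA_real_, length(surv))
  ok <- surv > 0 & surv < 1 & is.finite(gw)
  se_cll <- sqrt(gw[ok]) / abs(log(surv[ok]))
  lower[ok] <- pmin(pmax(surv[ok]^exp(z * se_cll), 0), 1)
  upper[ok] <- pmin(pmax(surv[ok]^exp(-z * se_cll), 0), 1)
  out <- data.frame(time = etimes, n_risk = n_risk, n_event = n_event,
                    surv = surv, se = se, lower = lower, upper = upper)
  structure(out, n = n, max_time = max(time),
            conf_level = conf_level, class = c("km_curve", "data.frame"))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times\n",
              attr(x, "n"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read a Kaplan-Meier curve at a time point
#'
#' Right-continuous step function: the estimate at `t` is the value at the
#' last event time not exceeding `t` (1 before the first event).
#'
#' @param curve A `km_curve`.
#' @param t Time (months).
#' @return List with `estimate`, `lower`, `upper` and `extrapolated`
#'   (TRUE when `t` lies beyond the last observed follow-up).
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  extrapolated <- t > attr(curve, "max_time")
  if (extrapolated)
    warning("time ", t, " is beyond the last follow-up; returning the ",
            "last estimate")
  i <- findInterval(t, curve$time)
  if (i == 0L || nrow(curve) == 0L)
    return(list(estimate = 1, lower = NA_real_, upper = NA_real_,
                extrapolated = extrapolated))
  list(estimate = curve$surv[i], lower = curve$lower[i],
       upper = curve$upper[i], extrapolated = extrapolated)
}

#' Two-group log-rank test
#'
#' At every distinct event time the observed events in group 1 are compared
#' with the expectation under the hypergeometric null; the summed
#' discrepancy over its variance is referred to chi-square with 1 df.
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param group Two-level grouping vector.
#' @return List with `chi_square`, `p`, `observed`, `expected` (per group)
#'   and `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) == 0L)) stop("both groups must be non-empty")
  if (!any(event)) {
    warning("no events; log-rank p set to 1")
    return(list(chi_square = 0, p = 1,
                observed = c(0, 0), expected = c(0, 0),
                n = as.integer(table(g))))
  }
  etimes <- sort(unique(time[event]))
  is1 <- g == levels(g)[1]
  o_minus_e <- 0; v <- 0; o1 <- 0; e1 <- 0
  for (t in etimes) {
    at_risk <- time >= t
    nj <- sum(at_risk); n1j <- sum(at_risk & is1)
    dj <- sum(time == t & event); d1j <- sum(time == t & event & is1)
    ej <- dj * n1j / nj
    o1 <- o1 + d1j; e1 <- e1 + ej
    o_minus_e <- o_minus_e + (d1j - ej)
    if (nj > 1L)
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  d_total <- sum(event)
  chi <- if (v > 0) o_minus_e^2 / v else 0
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  list(chi_square = chi, p = p,
       observed = c(o1, d_total - o1), expected = c(e1, d_total - e1),
       n = as.integer(table(g)))
}

## Precomputed event-time structure shared by all Newton-Raphson steps:
## rows sorted by ascending time; for each distinct event time its risk-set
## start index, event multiplicity and (for Efron) the tied event rows.
.cox_prep <- function(tt, dd) {
  ue <- unique(tt[dd])
  si <- match(ue, tt)                  # first index with time >= ue (sorted)
  dg <- vapply(ue, function(t) sum(tt == t & dd), integer(1))
  ev_rows <- lapply(ue, function(t) which(tt == t & dd))
  list(ue = ue, si = si, dg = dg, ev_rows = ev_rows)
}

## Partial log-likelihood, score and information at beta, using reverse
## cumulative sums over the sorted times so each evaluation is O(n p^2).
.cox_quantities <- function(beta, tt, dd, X, ties, prep) {
  rc <- function(v) rev(cumsum(rev(v)))
  eta <- drop(X %*% beta)
  shift <- max(eta)                    # overflow guard; cancels in loglik
  w <- exp(eta - shift)
  p <- ncol(X)
  si <- prep$si; dg <- prep$dg
  S0v <- rc(w)
  S1m <- vapply(seq_len(p), function(j) rc(w * X[, j]), numeric(length(w)))
  S0 <- S0v[si]
  S1 <- S1m[si, , drop = FALSE]
  loglik <- sum(eta[dd] - shift)
  U <- colSums(X[dd, , drop = FALSE])
  I <- matrix(0, p, p)
  if (ties == "breslow" || all(dg == 1L)) {
    loglik <- loglik - sum(dg * log(S0))
    U <- U - colSums(dg * S1 / S0)
    for (j in seq_len(p)) for (k in j:p) {
      S2v <- rc(w * X[, j] * X[, k])[si]
      val <- sum(dg * (S2v / S0 - S1[, j] * S1[, k] / S0^2))
      I[j, k] <- val; I[k, j] <- val
    }
  } else {
    S2g <- array(0, c(length(si), p, p))
    for (j in seq_len(p)) for (k in j:p) {
      v <- rc(w * X[, j] * X[, k])[si]
      S2g[, j, k] <- v; S2g[, k, j] <- v
    }
    for (g in seq_along(si)) {
      d <- dg[g]
      s0g <- S0[g]; s1g <- S1[g, ]; s2g <- S2g[g, , , drop = TRUE]
      s2g <- matrix(s2g, p, p)
      if (d == 1L) {
        loglik <- loglik - log(s0g)
        U <- U - s1g / s0g
        I <- I + s2g / s0g - tcrossprod(s1g / s0g)
      } else {
        idx <- prep$ev_rows[[g]]
        wd <- w[idx]; Xd <- X[idx, , drop = FALSE]
        W <- sum(wd)
        S1d <- colSums(wd * Xd)
        S2d <- crossprod(Xd, wd * Xd)
        for (l in seq_len(d)) {
          f <- (l - 1) / d
          s0 <- s0g - f * W
          s1 <- s1g - f * S1d
          s2 <- s2g - f * S2d
          loglik <- loglik - log(s0)
          U <- U - s1 / s0
          I <- I + s2 / s0 - tcrossprod(s1 / s0)
        }
      }
    }
  }
  list(loglik = loglik, U = U, I = I)
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximisation of the partial likelihood, with Breslow
#' (default) or Efron handling of tied event times.  Convergence is
#' declared when the relative change in the partial log-likelihood falls
#' below `tol`; step-halving is applied when a step decreases the
#' likelihood.  A diverging coefficient path (monotone likelihood from
#' perfect separation) is flagged as a non-converged fit rather than
#' returned as a silent estimate.
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param covariates Numeric matrix or data frame of covariates.
#' @param ties `"breslow"` or `"efron"`.
#' @param conf_level Confidence level for the Wald intervals.
#' @param max_iter,tol Newton-Raphson controls.
#' @return Object of class `cox_fit`: coefficient table (`coef`, `se`,
#'   `hr`, `lower`, `upper`, `z`, `p`), `loglik` (null and final),
#'   `iterations`, `converged`, `n`, `n_event`, `ties`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron"),
                    conf_level = 0.95, max_iter = 100L, tol = 1e-9) {
  ties <- match.arg(ties)
  event <- as.logical(event)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(time), length(event) == length(time))
  if (sum(event) < 2L) stop("at least two events required")
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  ## center covariates for numerical stability; beta is unaffected
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ord <- order(time)
  tt <- time[ord]; dd <- event[ord]; Xo <- Xc[ord, , drop = FALSE]
  p <- ncol(X)
  beta <- rep(0, p)
  prep <- .cox_prep(tt, dd)
  q0 <- .cox_quantities(beta, tt, dd, Xo, ties, prep)
  loglik0 <- q0$loglik
  ll <- loglik0
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  q <- q0
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(q$I, q$U), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    new_beta <- beta + step
    qn <- .cox_quantities(new_beta, tt, dd, Xo, ties, prep)
    halvings <- 0L
    while (qn$loglik < ll && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      qn <- .cox_quantities(new_beta, tt, dd, Xo, ties, prep)
      halvings <- halvings + 1L
    }
    rel <- abs(qn$loglik - ll) / (abs(ll) + 0.1)
    beta <- new_beta; ll <- qn$loglik; q <- qn
    if (max(abs(beta)) > 15) { diverged <- TRUE; break }
    if (rel < tol) { converged <- TRUE; break }
  }
  if (diverged)
    warning("monotone partial likelihood (possible perfect separation); ",
            "fit flagged as non-converged")
  vcov <- tryCatch(solve(q$I), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(coef = beta, se = se, hr = exp(beta),
                    lower = exp(beta - z * se), upper = exp(beta + z * se),
                    z = beta / se,
                    p = 2 * stats::pnorm(-abs(beta / se)),
                    row.names = colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 table = tab, vcov = vcov,
                 loglik = c(null = loglik0, final = ll),
                 iterations = iter, converged = converged && !diverged,
                 n = length(tt), n_event = sum(dd), ties = ties,
                 conf_level = conf_level),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  print(round(x$table, digits))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$vcov
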