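## Survival stratification: Kaplan-Meier product-limit estimation,
## log-rank testing, Cox proportional-hazards fitting (Newton-Raphson on
## the Efron partial likelihood) with likelihood-ratio comparison and
## Harrell's concordance, and quartile / median risk-score stratification.

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param group optional group labels; one curve per group.
#' @return data.frame per group with columns \code{group}, \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv}
#'   (survival starts at 1 and is non-increasing).
#' @export
kmEstimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("times must be positive")
  stopifnot(all(event %in% c(0, 1)))
  if (is.null(group)) group <- rep("all", length(time))
  out <- lapply(split(seq_along(time), group), function(idx) {
    t <- time[idx]; e <- event[idx]
    ut <- sort(unique(t))
    s <- 1
    rows <- lapply(ut, function(tt) {
      at_risk <- sum(t >= tt)
      d <- sum(t == tt & e == 1)
      c_ <- sum(t == tt & e == 0)
      if (d > 0) s <<- s * (1 - d / at_risk)
      data.frame(time = tt, n_risk = at_risk, n_event = d, n_censor = c_,
                 surv = s)
    })
    cbind(group = group[idx][1], do.call(rbind, rows))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Log-rank test
#'
#' Observed-minus-expected statistic over the shared event times with
#' hypergeometric variance; chi-squared with (groups - 1) df.
#'
#' @param time positive times.
#' @param event 0/1 indicators.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with \code{chisq}, \code{df}, \code{p_value}.
#' @export
logrankTest <- function(time, event, group) {
  if (any(time <= 0)) stop("times must be positive")
  g <- as.factor(group)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  k <- nlevels(g)
  if (sum(event) == 0) {
    warning("no events: log-rank p = 1")
    return(list(chisq = 0, df = k - 1, p_value = 1))
  }
  dtimes <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (tt in dtimes) {
    at <- time >= tt
    n <- sum(at)
    d <- sum(time == tt & event == 1)
    nj <- vapply(levels(g), function(l) sum(at & g == l), numeric(1))
    dj <- vapply(levels(g), function(l) sum(time == tt & event == 1 & g == l),
                 numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      # multivariate hypergeometric covariance of the group death counts
      for (i in seq_len(k)) for (j in seq_len(k)) {
        V[i, j] <- V[i, j] +
          d * (n - d) / (n - 1) * (nj[i] * ((i == j) * n - nj[j]) / n^2)
      }
    }
  }
  u <- (O - E)[-k]
  Vm <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(drop(t(u) %*% solve(Vm, u)), error = function(e) 0)
  if (!is.finite(chisq) || chisq < 0) chisq <- 0
  list(chisq = chisq, df = k - 1, p_value = pchisq(chisq, k - 1, lower.tail = FALSE))
}

## Efron partial log-likelihood, gradient and information at beta.
.cox_efron <- function(beta, time, event, X) {
  eta <- drop(X %*% beta)
  ex <- exp(eta)
  dtimes <- sort(unique(time[event == 1]))
  ll <- 0
  p <- ncol(X)
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (tt in dtimes) {
    R <- which(time >= tt)
    D <- which(time == tt & event == 1)
    d <- length(D)
    S0 <- sum(ex[R])
    S1 <- colSums(X[R, , drop = FALSE] * ex[R])
    S2 <- crossprod(X[R, , drop = FALSE] * sqrt(ex[R]))
    S0d <- sum(ex[D])
    S1d <- colSums(X[D, , drop = FALSE] * ex[D])
    S2d <- crossprod(X[D, , drop = FALSE] * sqrt(ex[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      f <- l / d
      s0 <- S0 - f * S0d
      s1 <- S1 - f * S1d
      s2 <- S2 - f * S2d
      ll <- ll - log(s0)
      U <- U - s1 / s0
      I <- I + s2 / s0 - tcrossprod(s1 / s0)
    }
    U <- U + colSums(X[D, , drop = FALSE])
  }
  list(loglik = ll, gradient = U, information = I)
}

#' Harrell's concordance index
#'
#' Probability over usable pairs (the earlier time is an event) that the
#' subject with the higher risk score fails first; risk-score ties count
#' one half.
#'
#' @param time,event survival outcome.
#' @param risk per-subject risk score (higher = worse).
#' @return concordance in [0, 1]; NA when no pair is usable.
#' @export
concordanceIndexOf <- function(time, event, risk) {
  n <- length(time)
  conc <- disc <- tied <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # pair usable when the shorter time is an event (or equal-time
      # event/censor with the event first)
      if (time[i] == time[j]) {
        if (event[i] + event[j] != 1) next
        ev <- if (event[i] == 1) i else j
        ot <- if (ev == i) j else i
        if (risk[ev] > risk[ot]) conc <- conc + 1
        else if (risk[ev] < risk[ot]) disc <- disc + 1
        else tied <- tied + 1
        next
      }
      first <- if (time[i] < time[j]) i else j
      other <- if (first == i) j else i
      if (event[first] != 1) next
      if (risk[first] > risk[other]) conc <- conc + 1
      else if (risk[first] < risk[other]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  tot <- conc + disc + tied
  if (tot == 0) return(NA_real_)
  (conc + 0.5 * tied) / tot
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the Efron-tie partial likelihood;
#' standard errors from the inverse observed information; Wald 95\% CIs on
#' the log-hazard scale; Harrell's concordance on the fitted linear
#' predictor. Step halving guards each iteration.
#'
#' @param time positive times (months).
#' @param event 0/1 indicators (>= 1 event required).
#' @param X covariate matrix or data.frame (non-constant columns).
#' @param max_iter Newton-Raphson iteration cap (default 100).
#' @param tol convergence tolerance on the gradient norm (default 1e-8).
#' @return a \code{\link{CoxPHFit}}.
#' @export
coxFit <- function(time, event, X, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  ok <- complete.cases(X) & is.finite(time) & !is.na(event)
  X <- X[ok, , drop = FALSE]; time <- time[ok]; event <- event[ok]
  if (any(time <= 0)) stop("times must be positive")
  if (sum(event) < 1) stop("need at least one event")
  if (any(apply(X, 2, sd) == 0)) stop("constant covariate")
  # center for numerical stability; the partial likelihood is invariant
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  p <- ncol(Xc)
  beta <- rep(0, p)
  e0 <- .cox_efron(beta, time, event, Xc)
  ll0 <- e0$loglik
  ll <- ll0
  converged <- FALSE
  iter <- 0L
  grad_norm <- sqrt(sum(e0$gradient^2))
  cur <- e0
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$information, cur$gradient),
                     error = function(e) NULL)
    if (is.null(step)) stop("singular information matrix (separation?)")
    newbeta <- beta + step
    newe <- .cox_efron(newbeta, time, event, Xc)
    halved <- 0
    while ((!is.finite(newe$loglik) || newe$loglik < ll - 1e-12) && halved < 20) {
      step <- step / 2
      newbeta <- beta + step
      newe <- .cox_efron(newbeta, time, event, Xc)
      halved <- halved + 1
    }
    beta <- newbeta; ll <- newe$loglik; cur <- newe
    grad_norm <- sqrt(sum(cur$gradient^2))
    if (grad_norm < tol) { converged <- TRUE; break }
  }
  if (!converged && grad_norm > 1e-4) {
    stop(sprintf("Cox fit did not converge in %d iterations (|grad| = %.3g)",
                 max_iter, grad_norm))
  }
  vcov <- solve(cur$information)
  se <- sqrt(diag(vcov))
  lp <- drop(Xc %*% beta)
  score_chisq <- drop(t(e0$gradient) %*% solve(e0$information, e0$gradient))
  new("CoxPHFit",
      coef = setNames(beta, colnames(X)),
      se = setNames(se, colnames(X)),
      var = vcov,
      loglik = c(ll0, ll),
      score_test = score_chisq,
      concordance = concordanceIndexOf(time, event, lp),
      n = length(time),
      nevent = as.integer(sum(event)),
      iter = iter,
      converged = TRUE,
      linear_predictor = lp)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' \code{chi2 = 2 (ll_full - ll_nested)} with df the covariate-count
#' difference. Both fits must be on the same subjects (checked via n and
#' the shared null log-likelihood) and the nested covariates must be a
#' subset of the full ones.
#'
#' @param nested,full \code{\link{CoxPHFit}} objects.
#' @return list with \code{chisq}, \code{df}, \code{p_value}.
#' @export
lrTest <- function(nested, full) {
  stopifnot(is(nested, "CoxPHFit"), is(full, "CoxPHFit"))
  if (!all(names(nested@coef) %in% names(full@coef))) {
    stop("models are not nested (covariates differ)")
  }
  if (nested@n != full@n || abs(nested@loglik[1] - full@loglik[1]) > 1e-6) {
    stop("models were fitted on different subjects")
  }
  df <- length(full@coef) - length(nested@coef)
  if (df <= 0) {
    if (df == 0) return(list(chisq = 0, df = 0, p_value = 1))
    stop("full model has fewer covariates than the nested one")
  }
  chisq <- max(0, 2 * (full@loglik[2] - nested@loglik[2]))
  list(chisq = chisq, df = df,
       p_value = pchisq(chisq, df, lower.tail = FALSE))
}

#' Quartile stratification of a score
#'
#' Cutpoints at the 25th/50th/75th linear-interpolation quantiles; ties at
#' a cutpoint go to the lower quartile, so the assignment is invariant
#' under monotone transforms of the score.
#'
#' @param scores numeric vector (>= 8 subjects, non-constant).
#' @return list with \code{labels} (factor Q1-Q4, same order as input)
#'   and \code{cutpoints}.
#' @export
quartileStratify <- function(scores) {
  if (length(scores) < 8) stop("need at least 8 subjects for quartiles")
  if (sd(scores) == 0) stop("constant scores cannot be stratified")
  q <- quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  lab <- cut(scores, breaks = c(-Inf, q, Inf),
             labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  list(labels = lab, cutpoints = q)
}

#' Median risk-score split from a Cox fit
#'
#' Computes the linear predictor eta = sum(beta * x) per subject and
#' splits at its median; ties at the median go to the low-risk group.
#'
#' @param fit converged \code{\link{CoxPHFit}}.
#' @param X covariate matrix aligned to the fit's covariates (optional;
#'   defaults to the fit's own linear predictor).
#' @return list with \code{labels} (\code{"high"} / \code{"low"}),
#'   \code{eta} and the \code{median} cutpoint.
#' @export
riskScoreSplit <- function(fit, X = NULL) {
  stopifnot(is(fit, "CoxPHFit"), fit@converged)
  eta <- if (is.null(X)) fit@linear_predictor
         else drop(as.matrix(X)[, names(fit@coef), drop = FALSE] %*% fit@coef)
  if (sd(eta) == 0) stop("degenerate: constant linear predictor")
  m <- median(eta)
  labels <- ifelse(eta <= m, "low", "high")
  list(labels = labels, eta = eta, median = m)
}
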