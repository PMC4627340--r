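# Survival statistics implemented from first principles: Newton-Raphson
# maximisation of the Cox partial likelihood (Efron or Breslow ties),
# the product-limit estimator with Greenwood variance, the Mantel-Haenszel
# log-rank test, and the Cox score test at beta = 0 (which equals the
# log-rank chi-square when event times are untied).

# risk-set sums at each unique time: v aggregated per time group, then
# reverse-cumulated so entry g = sum over {i : t_i >= ut[g]}.
.risk_cumsum <- function(vg) {
  if (is.matrix(vg)) apply(vg, 2, function(cl) rev(cumsum(rev(cl))))
  else rev(cumsum(rev(vg)))
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximisation of the partial likelihood, Efron tie
#' correction by default. Covariates are mean-centered internally for
#' numerical stability; reported coefficients are on the original scale.
#'
#' @param x numeric vector or matrix of covariates (samples in rows).
#' @param surv `survival_data` (or data.frame with time/event), aligned
#'   row-for-row with `x`.
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   gradient max-norm.
#' @return object of class `cox_fit`: `coef` data.frame (term, beta, se,
#'   hazard_ratio, z, p_value), `loglik`, `n`, `n_events`, `converged`,
#'   `iterations`.
#' @export
fit_cox <- function(x, surv, ties = c("efron", "breslow"),
                    max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X) == 1) "x" else paste0("x", seq_len(ncol(X)))
  time <- surv$time; event <- surv$event
  n <- nrow(X); p <- ncol(X)
  if (length(time) != n) stop_input("covariates and survival are misaligned")
  if (!all(is.finite(X))) stop_input("non-finite covariate value")
  if (sum(event) < 1) stop_input("no events in the data")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop_input("constant covariate: ", colnames(X)[sds == 0][1])
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)

  ord <- order(time)
  t0 <- time[ord]; ev <- event[ord] == 1
  Xs <- Xc[ord, , drop = FALSE]
  ut <- unique(t0)
  g <- match(t0, ut)
  d_g <- as.vector(rowsum(as.numeric(ev), g))
  egrp <- which(d_g > 0)
  # expand each event group into d rows, with Efron fraction l/d, l=0..d-1
  didx <- rep(egrp, d_g[egrp])
  frac <- if (ties == "efron")
    (sequence(d_g[egrp]) - 1) / rep(d_g[egrp], d_g[egrp])
  else rep(0, length(didx))
  sumX_ev <- colSums(Xs[ev, , drop = FALSE])
  XX <- Xs[, rep(seq_len(p), times = p), drop = FALSE] *
    Xs[, rep(seq_len(p), each = p), drop = FALSE]

  beta <- rep(0, p)
  ll_prev <- -Inf
  beta_prev <- beta
  converged <- FALSE
  iter <- 0L
  diverged <- FALSE
  U <- rep(NA_real_, p); Imat <- diag(p)
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Xs %*% beta)
    r <- exp(eta)
    S0 <- .risk_cumsum(as.vector(rowsum(r, g)))
    S1 <- .risk_cumsum(rowsum(r * Xs, g))
    S0d <- as.vector(rowsum(r * ev, g))
    S1d <- rowsum(r * ev * Xs, g)
    S1 <- matrix(S1, ncol = p)
    phi <- S0[didx] - frac * S0d[didx]
    A1 <- S1[didx, , drop = FALSE] - frac * S1d[didx, , drop = FALSE]
    ll <- sum(eta[ev]) - sum(log(phi))
    if (ll < ll_prev - 1e-12) {       # step halving
      beta <- (beta + beta_prev) / 2
      next
    }
    S2 <- .risk_cumsum(rowsum(r * XX, g))
    S2d <- rowsum(r * ev * XX, g)
    S2 <- matrix(S2, ncol = p * p)
    A2 <- S2[didx, , drop = FALSE] - frac * S2d[didx, , drop = FALSE]
    B <- A1 / phi
    U <- sumX_ev - colSums(B)
    Imat <- matrix(colSums(A2 / phi), p, p) - crossprod(B)
    if (max(abs(U)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(Imat, U), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    beta_prev <- beta
    ll_prev <- ll
    beta <- beta + step
    if (any(abs(beta * sds) > 18)) {  # monotone likelihood / separation
      diverged <- TRUE
      break
    }
  }
  vcv <- tryCatch(solve(Imat), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcv), 0))
  z <- beta / se
  coef <- data.frame(term = colnames(X), beta = beta, se = se,
                     hazard_ratio = exp(beta), z = z,
                     p_value = 2 * pnorm(-abs(z)),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coef = coef, loglik = if (iter > 0) ll else NA_real_,
                 n = n, n_events = sum(ev),
                 converged = converged && !diverged,
                 diverged = diverged, iterations = iter,
                 ties = ties, score = U, information = Imat),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit (", x$ties, " ties): n = ", x$n, ", events = ", x$n_events,
      if (!x$converged) ", NOT CONVERGED", "\n", sep = "")
  print(x$coef, digits = 4)
  invisible(x)
}

#' Cox score test at beta = 0 for a binary group
#'
#' Score statistic of the Cox partial likelihood under Breslow tie
#' handling; with untied event times this is algebraically identical to
#' the two-group log-rank chi-square.
#'
#' @param group binary (0/1, logical, or 2-level factor) group indicator.
#' @param surv `survival_data` aligned with `group`.
#' @return list(chi_square, p, df = 1).
#' @export
cox_score_test <- function(group, surv) {
  if (is.factor(group) || is.character(group)) {
    lv <- sort(unique(as.character(group)))
    if (length(lv) != 2) stop_input("group must have exactly 2 levels")
    group <- as.numeric(as.character(group) == lv[2])
  }
  group <- as.numeric(group)
  if (!all(group %in% c(0, 1))) stop_input("group must be binary")
  if (min(table(group)) < 1 || length(unique(group)) != 2)
    stop_input("both groups must be non-empty")
  time <- surv$time; ev <- surv$event == 1
  ord <- order(time)
  t0 <- time[ord]; e0 <- ev[ord]; x0 <- group[ord]
  ut <- unique(t0); g <- match(t0, ut)
  S0 <- .risk_cumsum(as.vector(rowsum(rep(1, length(x0)), g)))
  S1 <- .risk_cumsum(as.vector(rowsum(x0, g)))
  d <- as.vector(rowsum(as.numeric(e0), g))
  dx <- as.vector(rowsum(x0 * e0, g))
  keep <- d > 0
  U <- sum(dx[keep] - d[keep] * S1[keep] / S0[keep])
  Iinf <- sum(d[keep] * (S1[keep] / S0[keep]) * (1 - S1[keep] / S0[keep]))
  chi <- if (Iinf > 0) U^2 / Iinf else 0
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE), df = 1L)
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: censorings at an event time are processed after the
#' events at that time.
#'
#' @param surv `survival_data`.
#' @return object of class `km_estimate`: `time` (ascending unique event
#'   times), `n_risk`, `n_event`, `surv`, `greenwood_var`.
#' @export
kaplan_meier <- function(surv) {
  time <- surv$time; ev <- surv$event == 1
  if (length(time) < 1) stop_input("empty survival data")
  if (any(time < 0)) stop_input("negative survival time")
  et <- sort(unique(time[ev]))
  n_risk <- vapply(et, function(t) sum(time >= t), 1)
  n_event <- vapply(et, function(t) sum(time == t & ev), 1)
  s <- cumprod(1 - n_event / n_risk)
  gw <- s^2 * cumsum(n_event / (n_risk * (n_risk - n_event)))
  structure(list(time = et, n_risk = n_risk, n_event = n_event,
                 surv = s, greenwood_var = gw,
                 max_time = if (length(time)) max(time) else 0),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   surv = x$surv), digits = 4)
  invisible(x)
}

#' Evaluate a Kaplan-Meier step function
#'
#' Right-continuous: at an event time the post-drop value is returned; past
#' the last observed time the final step value is carried forward.
#'
#' @param km `km_estimate`.
#' @param t time (scalar or vector), `>= 0`.
#' @return survival probability S(t).
#' @export
survival_at <- function(km, t) {
  if (any(t < 0)) stop_input("t must be >= 0")
  vapply(t, function(tt) {
    k <- sum(km$time <= tt)
    if (k == 0) 1 else km$surv[k]
  }, 1)
}

#' Log-rank (Mantel-Haenszel) test
#'
#' @param surv `survival_data`.
#' @param groups group labels aligned with `surv` (>= 2 non-empty groups).
#' @return list(chi_square, p, df, observed, expected) with per-group
#'   observed and expected event counts.
#' @export
logrank_test <- function(surv, groups) {
  groups <- factor(groups)
  K <- nlevels(groups)
  if (K < 2) stop_input("log-rank needs >= 2 groups")
  if (any(table(groups) == 0)) stop_input("empty group")
  time <- surv$time; ev <- surv$event == 1
  et <- sort(unique(time[ev]))
  O <- E <- setNames(rep(0, K), levels(groups))
  V <- matrix(0, K, K, dimnames = list(levels(groups), levels(groups)))
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nj <- vapply(levels(groups), function(l) sum(at_risk & groups == l), 1)
    dj <- vapply(levels(groups), function(l) sum(time == t & ev & groups == l), 1)
    d <- sum(dj)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      c1 <- d * (n - d) / (n - 1)
      V <- V + c1 * (diag(nj / n, K) - tcrossprod(nj / n))
    }
  }
  oe <- (O - E)[-K]
  Vk <- V[-K, -K, drop = FALSE]
  chi <- tryCatch(drop(t(oe) %*% solve(Vk, oe)), error = function(e) {
    # singular variance (e.g. a group with no one at risk at any event time)
    sv <- svd(Vk)
    pos <- sv$d > max(sv$d) * 1e-12
    drop(t(oe) %*% sv$v[, pos, drop = FALSE] %*%
           ((t(sv$u[, pos, drop = FALSE]) %*% oe) / sv$d[pos]))
  })
  chi <- max(chi, 0)
  list(chi_square = chi, p = pchisq(chi, df = K - 1, lower.tail = FALSE),
       df = K - 1L, observed = O, expected = E)
}

#' P-value score
#'
#' Negative logarithm of a p-value (base 10 by default), the scale on which
#' prognostic signatures are compared.
#'
#' @param p p-value(s) in (0, 1].
#' @param base logarithm base.
#' @return `-log(p, base)`.
#' @export
pvalue_score <- function(p, base = 10) {
  if (any(p <= 0) || any(p > 1)) stop_input("p must be in (0, 1]")
  -log(p, base = base)
}
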