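# Weighted Cox partial-likelihood engine (Breslow tie handling).
#
# Solves the weighted score equation
#   sum_i w_i I(e_i = k) [ x_i - S1(t_i; beta) / S0(t_i; beta) ] = 0,
# with S_r(t; beta) = sum_j w_j x_j^{(r)} exp(x_j' beta) I(t_j >= t),
# by Newton-Raphson with step halving. The robust (sandwich) variance
# is the weighted Lin-Wei estimator built from per-subject score
# residuals. All risk-set sums are computed with reverse cumulative
# sums over the time-sorted sample, O(n log n) per iteration.

cox_engine <- function(time, status, X, w,
                       init = NULL, max_iter = 30L, tol = 1e-10) {
  n <- length(time)
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(length(status) == n, nrow(X) == n, length(w) == n,
            all(w > 0), all(is.finite(w)))
  if (!any(status == 1)) stop("no events of the requested cause", call. = FALSE)

  ord <- order(time)            # ascending; risk set at t = suffix {tt >= t}
  tt <- time[ord]; ss <- status[ord]; ww <- w[ord]
  XX <- X[ord, , drop = FALSE]

  ev <- which(ss == 1)
  u <- unique(tt[ev])                       # ascending unique event times
  first <- findInterval(u, tt, left.open = TRUE) + 1L  # first index with tt >= u
  # weighted event count and weighted covariate sum at each event time
  grp <- match(tt[ev], u)
  dsum <- as.vector(rowsum(ww[ev], grp))
  xsum <- rowsum(XX[ev, , drop = FALSE] * ww[ev], grp)
  m <- length(u)

  ut <- upper.tri(diag(p), diag = TRUE)
  uidx <- which(ut, arr.ind = TRUE)

  risk_sums <- function(beta) {
    eta <- drop(XX %*% beta)
    r <- ww * exp(eta)
    S0 <- revcumsum(r)[first]
    S1 <- revcumsum(XX * r)[first, , drop = FALSE]
    S2 <- matrix(0, m, nrow(uidx))
    for (k in seq_len(nrow(uidx))) {
      a <- uidx[k, 1L]; b <- uidx[k, 2L]
      S2[, k] <- revcumsum(XX[, a] * XX[, b] * r)[first]
    }
    list(eta = eta, r = r, S0 = S0, S1 = S1, S2 = S2)
  }

  loglik <- function(beta, rs) {
    sum(ww[ev] * drop(XX[ev, , drop = FALSE] %*% beta)) - sum(dsum * log(rs$S0))
  }

  score_info <- function(rs) {
    xbar <- rs$S1 / rs$S0
    U <- colSums(xsum - dsum * xbar)
    I <- matrix(0, p, p)
    for (k in seq_len(nrow(uidx))) {
      a <- uidx[k, 1L]; b <- uidx[k, 2L]
      v <- sum(dsum * (rs$S2[, k] / rs$S0 - xbar[, a] * xbar[, b]))
      I[a, b] <- I[b, a] <- v
    }
    list(U = U, I = I)
  }

  beta <- if (is.null(init)) rep(0, p) else init
  rs <- risk_sums(beta)
  ll <- loglik(beta, rs)
  iter <- 0L
  repeat {
    si <- score_info(rs)
    if (max(abs(si$U)) < tol * max(1, sum(dsum))) break
    if (iter >= max_iter)
      stop("Cox partial-likelihood maximization did not converge after ",
           max_iter, " iterations (|score| = ", format(max(abs(si$U))), ")",
           call. = FALSE)
    step <- tryCatch(solve(si$I, si$U), error = function(e)
      stop("singular information matrix in Cox fit", call. = FALSE))
    halve <- 0L
    repeat {
      cand <- beta + step / 2^halve
      if (max(abs(cand)) > 25)
        stop("monotone partial likelihood (coefficient diverging); ",
             "all events may be ordered by a covariate", call. = FALSE)
      rs_new <- risk_sums(cand)
      ll_new <- loglik(cand, rs_new)
      if (ll_new >= ll - 1e-12 || halve >= 10L) break
      halve <- halve + 1L
    }
    beta <- cand; rs <- rs_new; ll <- ll_new
    iter <- iter + 1L
  }
  si <- score_info(rs)
  if (max(abs(beta)) > 15)
    stop("monotone partial likelihood (coefficient diverging); ",
         "all events may be ordered by a covariate", call. = FALSE)

  # per-subject score residuals for the sandwich variance
  xbar <- rs$S1 / rs$S0              # m x p
  dH <- dsum / rs$S0                 # Breslow increments
  cum_dH <- cumsum(dH)
  cum_xdH <- apply(xbar * dH, 2L, cumsum)
  K <- findInterval(tt, u)           # number of event times <= t_i
  resid <- matrix(0, n, p)
  has <- K > 0L
  expeta <- exp(rs$eta)
  for (j in seq_len(p)) {
    drag <- numeric(n)
    drag[has] <- XX[has, j] * cum_dH[K[has]] - cum_xdH[K[has], j]
    dev <- numeric(n)
    kev <- match(tt[ev], u)
    dev[ev] <- XX[ev, j] - xbar[kev, j]
    resid[, j] <- dev - expeta * drag
  }
  wresid <- resid * ww
  meat <- crossprod(wresid)
  Iinv <- solve(si$I)
  var_robust <- Iinv %*% meat %*% Iinv
  # undo the sort for per-subject residuals
  resid_orig <- matrix(0, n, p)
  resid_orig[ord, ] <- resid

  list(beta = beta, var_naive = Iinv, var_robust = var_robust,
       score = si$U, info = si$I, loglik = ll, iter = iter,
       event_times = u, dsum = dsum, resid = resid_orig,
       n = n, n_events = sum(ss == 1))
}

# score test at beta = 0 (with unit weights this is the log-rank test;
# with IPTW weights, a weighted log-rank test).
cox_score_test <- function(time, status, X, w) {
  n <- length(time)
  X <- as.matrix(X)
  p <- ncol(X)
  ord <- order(time)
  tt <- time[ord]; ss <- status[ord]; ww <- w[ord]
  XX <- X[ord, , drop = FALSE]
  ev <- which(ss == 1)
  if (length(ev) < 2L) stop("fewer than 2 events", call. = FALSE)
  u <- unique(tt[ev])
  first <- findInterval(u, tt, left.open = TRUE) + 1L
  grp <- match(tt[ev], u)
  dsum <- as.vector(rowsum(ww[ev], grp))
  xsum <- rowsum(XX[ev, , drop = FALSE] * ww[ev], grp)
  S0 <- revcumsum(ww)[first]
  S1 <- revcumsum(XX * ww)[first, , drop = FALSE]
  xbar <- S1 / S0
  U <- colSums(xsum - dsum * xbar)
  I <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in a:p) {
    S2ab <- revcumsum(XX[, a] * XX[, b] * ww)[first]
    v <- sum(dsum * (S2ab / S0 - xbar[, a] * xbar[, b]))
    I[a, b] <- I[b, a] <- v
  }
  chisq <- drop(t(U) %*% solve(I, U))
  list(statistic = chisq, df = p, p_value = pchisq(chisq, p, lower.tail = FALSE))
}
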