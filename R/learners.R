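# Five suitability learners spanning envelope, parametric, and
# nonparametric families, mirroring typical multi-algorithm SDM ensembles:
#   envelope     - per-covariate [p5, p95] presence percentile box
#   mahalanobis  - exp(-D^2/2) to the presence centroid (regularized cov)
#   logistic2    - ML logistic regression on linear + quadratic terms
#   knn          - distance-weighted presence fraction among k neighbours
#   boost_stumps - gradient-boosted depth-1 stumps on logistic loss
# Every learner maps a covariate row to suitability in [0, 1].

LEARNER_KINDS <- c("envelope", "mahalanobis", "logistic2", "knn", "boost_stumps")

#' Fit one suitability learner
#'
#' @param kind one of `"envelope"`, `"mahalanobis"`, `"logistic2"`,
#'   `"knn"`, `"boost_stumps"`.
#' @param ds a `modeling_dataset` (see [build_modeling_dataset()]) with at
#'   least 2 presence and 2 background cells.
#' @param k neighbours for knn; default `min(10, n_presence)`.
#' @param n_stumps,learn_rate boosting size and shrinkage.
#' @param seed seed for boosting subsampling (reserved; fitting is
#'   deterministic at default settings).
#' @return fitted learner object with class `c("fc_<kind>", "fc_learner")`.
#' @export
fit_learner <- function(kind, ds, k = NULL, n_stumps = 100, learn_rate = 0.1,
                        seed = 1) {
  kind <- match.arg(kind, LEARNER_KINDS)
  Xp <- ds$X_presence; Xb <- ds$X_background
  if (nrow(Xp) < 2L || nrow(Xb) < 2L)
    fc_stop("fc_fit_failure", "need >= 2 presence and >= 2 background cells")
  fit <- switch(kind,
    envelope = fit_envelope(Xp),
    mahalanobis = fit_mahalanobis(Xp),
    logistic2 = fit_logistic2(Xp, Xb),
    knn = fit_knn(Xp, Xb, k),
    boost_stumps = fit_boost_stumps(Xp, Xb, n_stumps, learn_rate))
  fit$kind <- kind
  class(fit) <- c(paste0("fc_", kind), "fc_learner")
  fit
}

#' Predict suitability from a fitted learner
#'
#' @param object a fitted learner from [fit_learner()].
#' @param X covariate matrix (rows = cells/points).
#' @param ... unused.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict_suitability <- function(object, X, ...) UseMethod("predict_suitability")

fit_envelope <- function(Xp) {
  q <- apply(Xp, 2, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
  list(lo = q[1L, ], hi = q[2L, ])
}

#' @export
predict_suitability.fc_envelope <- function(object, X, ...) {
  inside <- sweep(X, 2, object$lo, ">=") & sweep(X, 2, object$hi, "<=")
  rowMeans(inside)
}

fit_mahalanobis <- function(Xp) {
  mu <- colMeans(Xp)
  S <- stats::cov(Xp)
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0)
    fc_stop("fc_fit_failure", "degenerate presence covariance")
  for (ridge in c(1e-8, 1e-6, 1e-4, 1e-2)) {
    Sr <- S + diag(ridge * scale, ncol(Xp))
    ok <- tryCatch({ chol(Sr); TRUE }, error = function(e) FALSE)
    if (ok) return(list(mu = mu, sigma = Sr))
  }
  fc_stop("fc_fit_failure", "singular covariance after regularization")
}

#' @export
predict_suitability.fc_mahalanobis <- function(object, X, ...) {
  d2 <- stats::mahalanobis(X, object$mu, object$sigma)
  exp(-d2 / 2)
}

quad_expand <- function(X) {
  cbind(X, X^2)
}

fit_logistic2 <- function(Xp, Xb) {
  XX <- quad_expand(rbind(Xp, Xb))
  colnames(XX) <- paste0("v", seq_len(ncol(XX)))
  y <- rep(c(1L, 0L), c(nrow(Xp), nrow(Xb)))
  dat <- data.frame(y = y, XX)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)))
  # keep only coefficients (NA for aliased columns -> treated as 0)
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  list(coef = co)
}

#' @export
predict_suitability.fc_logistic2 <- function(object, X, ...) {
  XX <- cbind(1, quad_expand(X))
  stats::plogis(drop(XX %*% object$coef))
}

fit_knn <- function(Xp, Xb, k = NULL) {
  X <- rbind(Xp, Xb)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd <= 0] <- 1
  if (is.null(k)) k <- min(10L, nrow(Xp))
  k <- max(1L, min(as.integer(k), nrow(X)))
  list(Z = sweep(sweep(X, 2, mu), 2, sd, "/"),
       y = rep(c(1L, 0L), c(nrow(Xp), nrow(Xb))),
       mu = mu, sd = sd, k = k)
}

#' @export
predict_suitability.fc_knn <- function(object, X, ...) {
  Q <- sweep(sweep(X, 2, object$mu), 2, object$sd, "/")
  Tm <- object$Z
  # squared Euclidean distances, blocked to bound memory
  out <- numeric(nrow(Q))
  t2 <- rowSums(Tm^2)
  k <- object$k
  block <- max(1L, floor(4e6 / nrow(Tm)))
  for (start in seq(1L, nrow(Q), by = block)) {
    ii <- start:min(start + block - 1L, nrow(Q))
    d2 <- outer(rowSums(Q[ii, , drop = FALSE]^2), t2, "+") -
      2 * Q[ii, , drop = FALSE] %*% t(Tm)
    d2[d2 < 0] <- 0
    out[ii] <- apply(d2, 1, function(r) {
      nb <- order(r)[seq_len(k)]
      w <- 1 / (sqrt(r[nb]) + 1e-6)
      sum(w * object$y[nb]) / sum(w)
    })
  }
  out
}

# Gradient boosting with depth-1 stumps on logistic loss. Each round fits
# the best least-squares stump to the gradient residual y - p; candidate
# splits are the gaps between consecutive distinct sorted values.
fit_boost_stumps <- function(Xp, Xb, n_stumps = 100, learn_rate = 0.1) {
  X <- rbind(Xp, Xb)
  y <- rep(c(1, 0), c(nrow(Xp), nrow(Xb)))
  n <- nrow(X); p <- ncol(X)
  ord <- lapply(seq_len(p), function(j) order(X[, j]))
  xs <- lapply(seq_len(p), function(j) X[ord[[j]], j])
  valid <- lapply(seq_len(p), function(j) {
    v <- which(diff(xs[[j]]) > 0)
    v
  })
  f0 <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  Fhat <- rep(f0, n)
  stumps <- vector("list", n_stumps)
  for (m in seq_len(n_stumps)) {
    r <- y - stats::plogis(Fhat)
    best <- NULL; best_score <- -Inf
    for (j in seq_len(p)) {
      v <- valid[[j]]
      if (!length(v)) next
      s <- cumsum(r[ord[[j]]])
      tot <- s[n]
      nl <- v
      cl <- s[v] / nl
      cr <- (tot - s[v]) / (n - nl)
      score <- nl * cl^2 + (n - nl) * cr^2
      i <- which.max(score)
      if (score[i] > best_score) {
        best_score <- score[i]
        vi <- v[i]
        best <- list(j = j, t = (xs[[j]][vi] + xs[[j]][vi + 1L]) / 2,
                     cl = cl[i], cr = cr[i])
      }
    }
    if (is.null(best)) { stumps <- stumps[seq_len(m - 1L)]; break }
    Fhat <- Fhat + learn_rate *
      ifelse(X[, best$j] <= best$t, best$cl, best$cr)
    stumps[[m]] <- best
  }
  list(f0 = f0, learn_rate = learn_rate, stumps = stumps)
}

#' @export
predict_suitability.fc_boost_stumps <- function(object, X, ...) {
  Fhat <- rep(object$f0, nrow(X))
  for (st in object$stumps) {
    if (is.null(st)) next
    Fhat <- Fhat + object$learn_rate *
      ifelse(X[, st$j] <= st$t, st$cl, st$cr)
  }
  stats::plogis(Fhat)
}
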