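#' Residualize a phenotype on significant covariates
#'
#' Regresses the phenotype on the supplied covariates, retains only those
#' whose partial F-test is significant at `alpha`, refits, and returns the
#' residuals (mean-centered when no covariate survives).  This mirrors the
#' standard pre-processing of stock phenotypes before kinship-based variance
#' decomposition.
#'
#' @param y Numeric phenotype (NAs dropped pairwise with covariates).
#' @param covariates Data frame of candidate covariates, or NULL.
#' @param alpha Retention threshold for the per-covariate partial F-test.
#' @return Residual vector with attributes `retained` (names of kept
#'   covariates) and `dropped`.
#' @export
residualize <- function(y, covariates = NULL, alpha = 0.05) {
  if (all(is.na(y))) stop("phenotype is entirely missing")
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    r <- y - mean(y, na.rm = TRUE)
    attr(r, "retained") <- character(0); attr(r, "dropped") <- character(0)
    return(r)
  }
  covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.y = y), covariates)
  fit <- stats::lm(.y ~ ., data = dat)
  # drop1 warns on exactly-collinear responses; retention still works
  dr <- suppressWarnings(stats::drop1(fit, test = "F"))
  pv <- dr[["Pr(>F)"]][-1]
  keep <- rownames(dr)[-1][!is.na(pv) & pv < alpha]
  if (length(keep)) {
    fml <- stats::reformulate(keep, response = ".y")
    fit <- stats::lm(fml, data = dat)
    r <- stats::residuals(fit)
  } else {
    r <- y - mean(y, na.rm = TRUE)
  }
  attr(r, "retained") <- keep
  attr(r, "dropped") <- setdiff(rownames(dr)[-1], keep)
  r
}

# Average-information REML for y = Xb + sum_k u_k + e with
# var(y) = sum_k sigma_k K_k + sigma_e I.  Components are floored at a small
# positive value (boundary flagged); steps that leave V non-positive-definite
# or decrease the restricted likelihood are halved, with an EM fallback.
.reml <- function(y, K_list, X, max_iter = 100, tol = 1e-8) {
  n <- length(y)
  m <- length(K_list)
  nc <- m + 1L
  vy <- stats::var(y)
  floor_v <- 1e-8 * vy
  theta <- c(rep(0.5 * vy / m, m), 0.5 * vy)

  build_V <- function(th) {
    V <- diag(th[nc], n)
    for (k in seq_len(m)) V <- V + th[k] * K_list[[k]]
    V
  }
  # restricted loglik and the P-projections needed by AI-REML.  K- is
  # indefinite, so V can drift toward (numerical) indefiniteness where a
  # bare Cholesky still "succeeds" but the likelihood is meaningless;
  # positive definiteness is therefore enforced with a small margin.
  pd_margin <- 1e-6 * vy
  eval_theta <- function(th) {
    V <- build_V(th)
    ok <- tryCatch({chol(V - diag(pd_margin, n)); TRUE},
                   error = function(e) FALSE)
    if (!ok) return(NULL)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    Cx <- chol2inv(chx)
    Py <- Vi %*% y - ViX %*% (Cx %*% crossprod(ViX, y))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(ll = ll, Vi = Vi, ViX = ViX, Cx = Cx, Py = drop(Py))
  }
  Pv <- function(st, v) {
    drop(st$Vi %*% v - st$ViX %*% (st$Cx %*% crossprod(st$ViX, v)))
  }

  st <- eval_theta(theta)
  if (is.null(st)) stop("initial variance matrix not positive definite")
  converged <- FALSE
  AI <- NULL
  n_flat <- 0L
  for (it in seq_len(max_iter)) {
    KPy <- vector("list", nc)
    trPK <- numeric(nc)
    for (k in seq_len(m)) {
      KPy[[k]] <- K_list[[k]] %*% st$Py
      trPK[k] <- sum(st$Vi * K_list[[k]]) -
        sum(st$Cx * crossprod(st$ViX, K_list[[k]] %*% st$ViX))
    }
    KPy[[nc]] <- st$Py
    trPK[nc] <- sum(diag(st$Vi)) - sum(st$Cx * crossprod(st$ViX))
    score <- vapply(seq_len(nc), function(k)
      -0.5 * (trPK[k] - sum(st$Py * KPy[[k]])), numeric(1))
    PKPy <- lapply(KPy, function(v) Pv(st, v))
    AI <- matrix(0, nc, nc)
    for (k in seq_len(nc)) for (l in k:nc) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(KPy[[k]] * PKPy[[l]])
    }
    # active set: components pinned at the zero boundary with an inward
    # gradient are excluded from the AI solve (keeps it well conditioned)
    free <- !(theta <= floor_v * (1 + 1e-6) & score < 0)
    step <- numeric(nc)
    if (any(free)) {
      sf <- tryCatch(solve(AI[free, free, drop = FALSE] + diag(1e-10, sum(free)),
                           score[free]), error = function(e) NULL)
      if (is.null(sf)) { # EM fallback direction
        sf <- (theta^2 * vapply(seq_len(nc), function(k)
          (sum(st$Py * KPy[[k]]) - trPK[k]) / n, numeric(1)))[free]
      }
      step[free] <- sf
    }
    improved <- FALSE
    for (half in 0:10) {
      cand <- pmax(theta + step / 2^half, floor_v)
      st2 <- eval_theta(cand)
      if (!is.null(st2) && st2$ll >= st$ll - 1e-10) {
        improved <- TRUE; break
      }
    }
    if (!improved) { # EM step as a last resort
      cand <- pmax(theta^2 * vapply(seq_len(nc), function(k)
        sum(st$Py * KPy[[k]]) / n, numeric(1)) +
          theta * (1 - theta * trPK / n), floor_v)
      st2 <- eval_theta(cand)
      if (is.null(st2)) break
    }
    dll <- st2$ll - st$ll
    dth <- max(abs(cand - theta)) / max(vy, .Machine$double.eps)
    theta <- cand; st <- st2
    # converged when the restricted likelihood is flat (several consecutive
    # sub-tolerance changes guard against slow traverses of a ridge)
    n_flat <- if (abs(dll) < tol) n_flat + 1L else 0L
    if (n_flat >= 3L || (abs(dll) < tol && dth < 1e-6)) { converged <- TRUE; break }
  }
  if (!converged && it == max_iter)
    warning("REML did not converge in ", max_iter, " iterations", call. = FALSE)

  cov_theta <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, nc, nc))
  kappa_ai <- tryCatch(kappa(AI), error = function(e) Inf)
  list(theta = theta, loglik = st$ll, cov_theta = cov_theta,
       converged = converged, iterations = it,
       boundary = theta <= floor_v * (1 + 1e-6),
       identifiable = is.finite(kappa_ai) && kappa_ai < 1e8)
}

.make_X <- function(y, covariates) {
  if (is.null(covariates)) return(matrix(1, length(y), 1))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qr_ <- qr(X)
  X[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
}

.h2_from_theta <- function(theta, cov_theta) {
  S <- sum(theta)
  h <- theta / S
  J <- (diag(length(theta)) * S - outer(theta, rep(1, length(theta)))) / S^2
  cov_h <- J %*% cov_theta %*% t(J)
  list(h = h, se = sqrt(pmax(diag(cov_h), 0)))
}

#' Two-component heritability fit (same- vs opposite-parental-sex kinship)
#'
#' Fits \eqn{var(y) = K^+\sigma^2_{g+} + K^-\sigma^2_{g-} + I\sigma^2_e}
#' by average-information REML with EM fallback and boundary constraints
#' \eqn{\sigma^2 \ge 0}.  `h2_plus` is \eqn{\sigma^2_{g+}} divided by the
#' total variance, and measures the fraction of phenotypic variance carried
#' by allele sharing through parents of the same sex; under no
#' parent-of-origin (or parental) effects the model collapses to the
#' ordinary kinship model and `h2_plus ~= h2_minus`.
#'
#' @param y Phenotype vector (aligned with the kinship matrices).
#' @param K_plus,K_minus The decomposed kinship matrices.
#' @param covariates Optional data frame of fixed-effect covariates.
#' @return Object of class `varcomp_fit`: `sigma2` (named vector with
#'   standard errors in `se_sigma2`), `h2`/`se_h2`, `loglik`, `converged`,
#'   `boundary`, `identifiable`, `iterations`, `n`.
#' @export
fit_two_component <- function(y, K_plus, K_minus, covariates = NULL) {
  stopifnot(length(y) == nrow(K_plus), nrow(K_plus) == nrow(K_minus))
  X <- .make_X(y, covariates)
  fit <- .reml(y, list(K_plus, K_minus), X)
  names(fit$theta) <- c("sigma2_g_plus", "sigma2_g_minus", "sigma2_e")
  hh <- .h2_from_theta(fit$theta, fit$cov_theta)
  structure(list(sigma2 = fit$theta,
                 se_sigma2 = sqrt(pmax(diag(fit$cov_theta), 0)),
                 h2 = c(h2_plus = unname(hh$h[1]), h2_minus = unname(hh$h[2])),
                 se_h2 = c(h2_plus = unname(hh$se[1]), h2_minus = unname(hh$se[2])),
                 loglik = fit$loglik, converged = fit$converged,
                 boundary = fit$boundary, identifiable = fit$identifiable,
                 iterations = fit$iterations, n = length(y),
                 model = "two_component"),
            class = "varcomp_fit")
}

#' One-component (ordinary kinship) heritability fit
#'
#' Fits the standard model \eqn{var(y) = K^\pm\sigma^2_g + I\sigma^2_e},
#' the collapse of the two-component model under
#' \eqn{\sigma^2_{g+} = \sigma^2_{g-}}.
#'
#' @inheritParams fit_two_component
#' @param K_pm The ordinary (summed) kinship matrix.
#' @return A `varcomp_fit` with components `sigma2_g`, `sigma2_e` and `h2`.
#' @export
fit_one_component <- function(y, K_pm, covariates = NULL) {
  stopifnot(length(y) == nrow(K_pm))
  X <- .make_X(y, covariates)
  fit <- .reml(y, list(K_pm), X)
  names(fit$theta) <- c("sigma2_g", "sigma2_e")
  hh <- .h2_from_theta(fit$theta, fit$cov_theta)
  structure(list(sigma2 = fit$theta,
                 se_sigma2 = sqrt(pmax(diag(fit$cov_theta), 0)),
                 h2 = c(h2 = unname(hh$h[1])),
                 se_h2 = c(h2 = unname(hh$se[1])),
                 loglik = fit$loglik, converged = fit$converged,
                 boundary = fit$boundary, identifiable = fit$identifiable,
                 iterations = fit$iterations, n = length(y),
                 model = "one_component"),
            class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("<varcomp_fit> ", x$model, ", n = ", x$n, "\n", sep = "")
  print(round(rbind(estimate = x$sigma2, se = x$se_sigma2), 4))
  cat("h2:", paste(names(x$h2), round(x$h2, 3), collapse = ", "),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Mixed-model whitening transform
#'
#' Fits (or reuses) the one-component kinship model, forms
#' \eqn{\hat V = K^\pm\hat\sigma^2_g + I\hat\sigma^2_e}, decomposes it into a
#' symmetric square root \eqn{V = W^2}, and premultiplies the phenotype and
#' fixed-effect design by \eqn{W^{-1}}.  After whitening, locus association
#' tests can be run by ordinary least squares as if the individuals were
#' equally related.
#'
#' @inheritParams fit_one_component
#' @param fit Optional pre-computed one-component `varcomp_fit`.
#' @return Object of class `whitened_design`: `y_w`, `X_w`, `W`, `Wi`
#'   (the inverse square root), and `fit`.
#' @export
whiten <- function(y, covariates = NULL, K_pm, fit = NULL) {
  X <- .make_X(y, covariates)
  if (is.null(fit)) fit <- fit_one_component(y, K_pm, covariates)
  V <- fit$sigma2[1] * K_pm + diag(fit$sigma2[2], length(y))
  ee <- eigen(V, symmetric = TRUE)
  if (any(ee$values <= 0)) stop("fitted covariance matrix is not positive definite")
  W <- ee$vectors %*% (sqrt(ee$values) * t(ee$vectors))
  Wi <- ee$vectors %*% ((1 / sqrt(ee$values)) * t(ee$vectors))
  structure(list(y_w = drop(Wi %*% y), X_w = Wi %*% X, W = W, Wi = Wi,
                 fit = fit), class = "whitened_design")
}

#' Compare parent-of-origin heritabilities across many traits
#'
#' Counts traits with `h2_plus > h2_minus`, excluding exact ties, and
#' reports a one-sided exact binomial p-value under the null that either
#' ordering is equally likely, plus the median of the per-trait ratio.
#'
#' @param fits List of two-component `varcomp_fit` objects (one per trait).
#' @return List: `n_traits`, `n_greater`, `n_ties`, `prop_greater`,
#'   `median_h2_plus`, `median_h2_minus`, `median_ratio`, `p_value`
#'   (exact one-sided binomial tail, by direct summation), and the
#'   per-trait table.
#' @export
compare_h2_across_traits <- function(fits) {
  if (length(fits) < 1) stop("no fits supplied")
  tab <- data.frame(
    h2_plus = vapply(fits, function(f) unname(f$h2["h2_plus"]), numeric(1)),
    h2_minus = vapply(fits, function(f) unname(f$h2["h2_minus"]), numeric(1)))
  tab$ratio <- tab$h2_plus / tab$h2_minus
  ties <- tab$h2_plus == tab$h2_minus
  k <- sum(tab$h2_plus > tab$h2_minus & !ties)
  n <- sum(!ties)
  p <- if (n == 0) NA_real_ else sum(stats::dbinom(k:n, n, 0.5))
  list(n_traits = length(fits), n_greater = k, n_ties = sum(ties),
       prop_greater = if (n > 0) k / n else NA_real_,
       median_h2_plus = stats::median(tab$h2_plus),
       median_h2_minus = stats::median(tab$h2_minus),
       median_ratio = stats::median(tab$ratio),
       p_value = p, table = tab)
}
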