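# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force path enumeration for the phasing
# HMM, direct restricted-likelihood evaluation for REML, hypergeometric
# enumeration for the exact 2x2 test.

# Posterior ordered-diplotype probabilities by exhaustive enumeration over
# all F^(2M) ordered founder-path pairs (single chromosome).
enum_phase_posterior <- function(child, sire, dam, panel, error, lambda) {
  alleles <- panel$alleles
  Fn <- nrow(alleles); M <- ncol(alleles)
  stay <- exp(-diff(panel$map$cM) * lambda)

  trans <- function(from, to, st) st * (from == to) + (1 - st) / Fn

  emis <- function(L, s, t) {
    g <- child[L]
    if (is.na(g)) return(1)
    e <- function(read, truth) if (read == truth) 1 - error else error
    As <- alleles[s, L]; At <- alleles[t, L]
    if (g == 1) {
      ps <- if (is.na(sire[L])) 0.5 else sire[L] / 2
      pd <- if (is.na(dam[L])) 0.5 else dam[L] / 2
      w10 <- ps * (1 - pd); w01 <- (1 - ps) * pd
      if (w10 + w01 == 0) { w10 <- 0.5; w01 <- 0.5 }
      else { tt <- w10 + w01; w10 <- w10 / tt; w01 <- w01 / tt }
      return(w10 * e(1, As) * e(0, At) + w01 * e(0, As) * e(1, At))
    }
    a <- if (g == 2) 1 else 0
    e(a, As) * e(a, At)
  }

  paths <- as.matrix(expand.grid(rep(list(seq_len(Fn)), M)))
  post <- array(0, c(Fn, Fn, M))
  total <- 0
  for (i in seq_len(nrow(paths))) for (j in seq_len(nrow(paths))) {
    pat <- paths[i, ]; mat <- paths[j, ]
    pr <- 1 / Fn^2
    for (L in seq_len(M)) {
      if (L > 1) pr <- pr * trans(pat[L - 1], pat[L], stay[L - 1]) *
          trans(mat[L - 1], mat[L], stay[L - 1])
      pr <- pr * emis(L, pat[L], mat[L])
    }
    total <- total + pr
    for (L in seq_len(M)) post[pat[L], mat[L], L] <- post[pat[L], mat[L], L] + pr
  }
  post / total
}

# Restricted log-likelihood of var(y) = sum_k theta_k K_k + theta_e I,
# evaluated from the definition (generalized least squares + determinants).
# The same positive-definiteness margin as the fitted model applies: with
# an indefinite K component the unconstrained surface has spurious
# near-singular ridges.
reml_loglik_direct <- function(theta, y, K_list, X) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(K_list)) V <- V + theta[k] * K_list[[k]]
  ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-6 * stats::var(y)) return(-Inf)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r))
}

# Two-sided Fisher exact p for a 2x2 table by enumeration over all tables
# with the observed margins (minimum-likelihood rule).
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(r1 + r2, c1)
  p_obs <- pr[ks == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# small dense-map population for tests that need phasing-friendly data
make_test_population <- function(n_families = 10, sibs = 3, n_gen = 3,
                                 markers = 60, n_chr = 1, seed = 42, ...) {
  simulate_hs_population(n_families = n_families, sibs_per_family = sibs,
                         n_generations = n_gen, markers_per_chr = markers,
                         n_chr = n_chr, seed = seed, ...)
}

# planted two-component phenotype: y ~ N(0, s_p K+ + s_m K- + s_e I)
draw_vc_phenotype <- function(K_plus, K_minus, s_p, s_m, s_e) {
  n <- nrow(K_plus)
  V <- s_p * K_plus + s_m * K_minus + s_e * diag(n)
  ee <- eigen(V, symmetric = TRUE)
  drop(ee$vectors %*% (sqrt(pmax(ee$values, 0)) * stats::rnorm(n)))
}
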