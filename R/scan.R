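# locus design matrices from phased marginals; the additive model needs
# founder dosage phi + psi (haplotype-effect columns sum to a constant, so
# one founder column is dropped per block: F-1 free parameters for the
# additive model, 2(F-1) for the parent-of-origin model)
.locus_designs <- function(phased, L) {
  phi <- phased$phi[, L, ]; psi <- phased$psi[, L, ]
  Fn <- ncol(phi)
  list(add = (phi + psi)[, -Fn, drop = FALSE],
       poe = cbind(phi[, -Fn, drop = FALSE], psi[, -Fn, drop = FALSE]))
}

.rss <- function(X, y) {
  q <- qr(X)
  r <- qr.resid(q, y)
  list(rss = sum(r^2), rank = q$rank)
}

# partial F-test of the extra columns in X1 over X0 on already-whitened data
.partial_f_logp <- function(y, X0, X1, rss0 = NULL, rank0 = NULL) {
  n <- length(y)
  if (is.null(rss0)) { f0 <- .rss(X0, y); rss0 <- f0$rss; rank0 <- f0$rank }
  f1 <- .rss(cbind(X0, X1), y)
  df1 <- f1$rank - rank0
  df2 <- n - f1$rank
  if (df1 <= 0 || df2 <= 0 || f1$rss <= 0) return(list(logp = 0, rss = f1$rss, df = df1))
  Fst <- ((rss0 - f1$rss) / df1) / (f1$rss / df2)
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  list(logp = -log10(max(p, .Machine$double.xmin)), rss = f1$rss, df = df1)
}

#' Scan a QTL region for additive parent-of-origin effects
#'
#' At every locus of the region, fits on whitened data (i) the additive
#' no-parent-of-origin model, in which the two parental copies of a founder
#' haplotype have a common effect entering through the symmetrized
#' probabilities, and (ii) the additive parent-of-origin model, in which
#' maternally and paternally inherited copies have separate effects entering
#' through the ordered-diplotype marginals.  Each model is scored by the
#' partial F-test of its haplotype block against the covariate-only model,
#' reported as `logP = -log10 p`.
#'
#' @param wd A [whiten()]ed design.
#' @param phased A `phased_population` aligned with `wd` (same individuals,
#'   same order).
#' @param loci Marker indices forming the region (a QTL region is typically
#'   around ten consecutive intervals).
#' @return Object of class `region_scan`: data frame `table` with columns
#'   `locus`, `logp_add`, `logp_poe`, plus `peak_add`, `peak_poe` (loci of
#'   the two maxima, leftmost on ties) and `delta_logp`.
#' @export
scan_region <- function(wd, phased, loci) {
  if (length(loci) < 1) stop("region contains no loci")
  X0 <- wd$X_w; y <- wd$y_w
  f0 <- .rss(X0, y)
  res <- lapply(loci, function(L) {
    dz <- .locus_designs(phased, L)
    a <- .partial_f_logp(y, X0, wd$Wi %*% dz$add, f0$rss, f0$rank)
    p <- .partial_f_logp(y, X0, wd$Wi %*% dz$poe, f0$rss, f0$rank)
    c(a$logp, p$logp, a$rss, p$rss)
  })
  res <- do.call(rbind, res)
  tab <- data.frame(locus = loci, logp_add = res[, 1], logp_poe = res[, 2],
                    rss_add = res[, 3], rss_poe = res[, 4])
  structure(list(table = tab,
                 peak_add = loci[which.max(tab$logp_add)],
                 peak_poe = loci[which.max(tab$logp_poe)],
                 delta_logp = max(tab$logp_poe) - max(tab$logp_add)),
            class = "region_scan")
}

#' Region-level parent-of-origin evidence statistic
#'
#' `DeltaLogP` is the difference between the maxima, over the same region,
#' of the parent-of-origin and additive logP curves:
#' \eqn{\Delta logP = \max_L logP^+_L - \max_L logP^\pm_L}.  The two peaks
#' need not be at the same locus, and the statistic may be negative.
#'
#' @param x A `region_scan`, or a numeric vector of additive logP values.
#' @param logp_poe When `x` is numeric, the matching parent-of-origin logP
#'   curve.
#' @return A single number.
#' @export
delta_logp <- function(x, logp_poe = NULL) {
  if (inherits(x, "region_scan")) return(x$delta_logp)
  if (is.null(logp_poe)) stop("supply a region_scan or both logP curves")
  max(logp_poe) - max(x)
}

#' Simulate the null distribution of DeltaLogP
#'
#' Simulates non-imprinted complex traits (by default seven additive QTLs of
#' 5% variance each) on a population, pushes each through the same mixed
#' model machinery as a real trait — one-component REML on `K±`, whitening,
#' then a region scan around each of its own QTLs — and collects the
#' resulting `DeltaLogP` values.  Because the traits carry no
#' parent-of-origin effects, the sample estimates the null distribution of
#' the statistic under realistic family structure, including the
#' confounding between sibship and parent-of-origin sharing that makes
#' naive per-locus tests anticonservative.
#'
#' @param pop An `hs_population`.
#' @param phased Its `phased_population` (final generation).
#' @param kin A `kinship_set` for the same individuals.
#' @param n_traits Number of simulated traits (values below 50 give an
#'   unstable tail and trigger a warning).
#' @param n_qtls,variance_per_qtl Architecture of each simulated trait.
#' @param window Number of consecutive loci per scanned region.
#' @param seed Optional integer seed.
#' @return Object of class `null_calibration`: `delta_logp` (length
#'   `n_traits * n_qtls`), and the simulation `spec`.
#' @export
calibrate_null <- function(pop, phased, kin, n_traits = 100, n_qtls = 7,
                           variance_per_qtl = 0.05, window = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_traits < 50)
    warning("fewer than 50 null traits gives an unstable tail", call. = FALSE)
  deltas <- numeric(0)
  for (r in seq_len(n_traits)) {
    tr <- simulate_trait(pop, n_qtls = n_qtls, variance_per_qtl = variance_per_qtl,
                         poe_mode = "none", individuals = phased$ids)
    y <- residualize(tr$y)
    wd <- whiten(y, K_pm = kin$K_pm)
    for (q in tr$truth$qtl_loci) {
      loci <- region_around(phased$map, q, window)
      sc <- scan_region(wd, phased, loci)
      deltas <- c(deltas, sc$delta_logp)
    }
  }
  structure(list(delta_logp = deltas,
                 spec = list(n_traits = n_traits, n_qtls = n_qtls,
                             variance_per_qtl = variance_per_qtl,
                             window = window)),
            class = "null_calibration")
}

#' Contiguous scan region around a locus
#'
#' Returns up to `window` consecutive marker indices centered on `locus`,
#' clipped to the locus's chromosome.
#'
#' @param map Marker map with a `chr` column.
#' @param locus Central marker index.
#' @param window Region width in loci.
#' @export
region_around <- function(map, locus, window = 10) {
  same <- which(map$chr == map$chr[locus])
  k <- match(locus, same)
  lo <- max(1, k - floor((window - 1) / 2))
  hi <- min(length(same), lo + window - 1)
  lo <- max(1, hi - window + 1)
  same[lo:hi]
}

#' Call imprinted QTLs against a simulated null at a target FDR
#'
#' For a threshold `t`, the estimated false discovery rate is the expected
#' number of null regions at or above `t` — the null tail fraction times the
#' number of regions tested — divided by the observed count at or above `t`,
#' clipped to \[0, 1\] and made monotone non-increasing in `t`.  Regions
#' whose `DeltaLogP` has estimated FDR at or below `fdr_threshold` are
#' called.
#'
#' @param observed Numeric vector of per-region `DeltaLogP` values.
#' @param null A `null_calibration`.
#' @param fdr_threshold Target FDR (e.g. 0.2).
#' @return Data frame `region`, `delta_logp`, `fdr`, `called`.
#' @export
call_iqtls <- function(observed, null, fdr_threshold = 0.2) {
  if (!inherits(null, "null_calibration"))
    stop("a null_calibration from calibrate_null() is required to call iQTLs")
  if (length(null$delta_logp) == 0) stop("null sample is empty")
  nr <- length(observed)
  raw <- vapply(observed, function(t)
    (mean(null$delta_logp >= t) * nr) / max(sum(observed >= t), 1), numeric(1))
  raw <- pmin(pmax(raw, 0), 1)
  ord <- order(observed, decreasing = TRUE)
  fdr <- raw
  fdr[ord] <- cummax(raw[ord])   # monotone non-increasing in the threshold
  data.frame(region = seq_len(nr), delta_logp = observed, fdr = fdr,
             called = fdr <= fdr_threshold)
}

#' Apply the cis imprinted-eQTL calling rule
#'
#' A probe is called only when the peak of its parent-of-origin logP curve
#' exceeds 5 *and* lies within 5 Mb of the cognate gene.
#'
#' @param logp Per-locus logP values of the parent-of-origin comparison.
#' @param bp Physical positions of those loci.
#' @param gene_bp Position of the cognate gene.
#' @param threshold logP calling threshold (default 5).
#' @param window_bp Maximum peak-to-gene distance (default 5 Mb).
#' @return List: `called`, `peak_logp`, `peak_bp`, `distance_bp`.
#' @export
call_ieqtl <- function(logp, bp, gene_bp, threshold = 5, window_bp = 5e6) {
  k <- which.max(logp)   # leftmost on ties
  dist <- abs(bp[k] - gene_bp)
  list(called = logp[k] > threshold && dist <= window_bp,
       peak_logp = logp[k], peak_bp = bp[k], distance_bp = dist)
}

#' Scan a chromosome for a cis imprinted expression QTL
#'
#' For an expression trait, scans every locus on the chromosome carrying the
#' cognate gene and, at each, tests the parent-of-origin model *against* the
#' additive model directly (partial F-test between the two nested locus
#' models on whitened data).  The probe is called by [call_ieqtl()].
#'
#' @param y Expression phenotype.
#' @param gene_chr,gene_bp Location of the cognate gene.
#' @param phased A `phased_population`.
#' @param kin A `kinship_set` (used to whiten).
#' @param covariates Optional fixed covariates.
#' @param threshold,window_bp Calling rule parameters.
#' @return Object of class `ieqtl_scan`: `table` (locus, bp, logp), the
#'   [call_ieqtl()] fields, and `gene_bp`.
#' @export
ieqtl_scan <- function(y, gene_chr, gene_bp, phased, kin, covariates = NULL,
                       threshold = 5, window_bp = 5e6) {
  loci <- which(phased$map$chr == gene_chr)
  if (length(loci) == 0) stop("no markers on chromosome ", gene_chr)
  wd <- whiten(y, covariates, K_pm = kin$K_pm)
  y_w <- wd$y_w; X0 <- wd$X_w
  logp <- vapply(loci, function(L) {
    dz <- .locus_designs(phased, L)
    Xa <- cbind(X0, wd$Wi %*% dz$add)
    fa <- .rss(Xa, y_w)
    .partial_f_logp(y_w, Xa, wd$Wi %*% dz$poe, fa$rss, fa$rank)$logp
  }, numeric(1))
  bp <- phased$map$bp[loci]
  call <- call_ieqtl(logp, bp, gene_bp, threshold, window_bp)
  structure(c(list(table = data.frame(locus = loci, bp = bp, logp = logp),
                   gene_bp = gene_bp), call),
            class = "ieqtl_scan")
}
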