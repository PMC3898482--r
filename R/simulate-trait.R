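#' Simulate a complex trait on a founder-mosaic population
#'
#' Builds a phenotype from `n_qtls` marker loci, each explaining a fixed
#' fraction of the total variance (defaults follow the standard benchmark of
#' seven QTLs at 5% each).  Per-founder haplotype effects are drawn
#' independently for each QTL and the per-QTL genetic values are rescaled so
#' their realized in-sample variance matches the requested fraction exactly;
#' residual noise brings the total phenotypic variance to ~1.
#'
#' Modes:
#' \describe{
#'   \item{`none`}{maternal and paternal copies of a founder haplotype have
#'     the same effect (no parent-of-origin effect).}
#'   \item{`additive_poe`}{a maternally inherited founder haplotype `s` has
#'     effect `alpha[s]`, a paternally inherited one `gamma[s]`, drawn
#'     independently (or supplied).}
#'   \item{`parental_effect`}{the phenotype depends on the *dam's own*
#'     diplotype at the QTL, not on what she transmitted (a purely parental,
#'     e.g. maternal-environment, effect).}
#' }
#'
#' @param pop An `hs_population` from [drop_haplotypes()].
#' @param n_qtls Number of QTLs (0 gives pure noise).
#' @param variance_per_qtl Fraction of total variance per QTL; the sum over
#'   QTLs must be < 1.
#' @param poe_mode One of `"none"`, `"additive_poe"`, `"parental_effect"`.
#' @param alpha,gamma Optional matrices (`n_founders` x `n_qtls`) of maternal
#'   and paternal per-founder effects; drawn N(0,1) when NULL.  Under
#'   `poe_mode = "none"`, `gamma` is forced equal to `alpha`.
#' @param individuals Ids to phenotype; default, the final generation.
#' @param qtl_loci Optional marker indices for the QTLs; sampled when NULL.
#' @param seed Optional integer seed.
#'
#' @return List of class `sim_trait`: `y` (named phenotype vector),
#'   `truth` (QTL marker indices, effect matrices, realized per-QTL variance
#'   fractions, noise variance, mode).
#' @export
simulate_trait <- function(pop, n_qtls = 7, variance_per_qtl = 0.05,
                           poe_mode = c("none", "additive_poe", "parental_effect"),
                           alpha = NULL, gamma = NULL, individuals = NULL,
                           qtl_loci = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  poe_mode <- match.arg(poe_mode)
  tot_g <- n_qtls * variance_per_qtl
  if (tot_g >= 1) stop("requested genetic variance fractions sum to >= 1")
  ped <- pop$ped
  if (is.null(individuals))
    individuals <- ped$id[ped$generation == max(ped$generation)]
  n <- length(individuals)
  Fn <- nrow(pop$panel$alleles)
  M <- ncol(pop$genotypes)

  if (n_qtls == 0) {
    y <- stats::rnorm(n)
    names(y) <- individuals
    return(structure(list(y = y, truth = list(qtl_loci = integer(0),
                                              alpha = NULL, gamma = NULL,
                                              realized_var = numeric(0),
                                              noise_var = 1, poe_mode = poe_mode)),
                     class = "sim_trait"))
  }

  if (is.null(qtl_loci)) qtl_loci <- sort(sample.int(M, n_qtls))
  if (is.null(alpha)) alpha <- matrix(stats::rnorm(Fn * n_qtls), Fn, n_qtls)
  if (poe_mode == "none") {
    gamma <- alpha
  } else if (is.null(gamma)) {
    gamma <- matrix(stats::rnorm(Fn * n_qtls), Fn, n_qtls)
  }

  pat_f <- t(vapply(individuals, function(id) pop$mosaics[[id]]$pat[qtl_loci],
                    integer(n_qtls)))
  mat_f <- t(vapply(individuals, function(id) pop$mosaics[[id]]$mat[qtl_loci],
                    integer(n_qtls)))
  if (n_qtls == 1) { pat_f <- matrix(pat_f, ncol = 1); mat_f <- matrix(mat_f, ncol = 1) }

  if (poe_mode == "parental_effect") {
    dams <- ped$dam[match(individuals, ped$id)]
    pat_f <- t(vapply(dams, function(id) pop$mosaics[[id]]$pat[qtl_loci], integer(n_qtls)))
    mat_f <- t(vapply(dams, function(id) pop$mosaics[[id]]$mat[qtl_loci], integer(n_qtls)))
    if (n_qtls == 1) { pat_f <- matrix(pat_f, ncol = 1); mat_f <- matrix(mat_f, ncol = 1) }
  }

  g <- matrix(0, n, n_qtls)
  realized <- numeric(n_qtls)
  for (q in seq_len(n_qtls)) {
    val <- gamma[pat_f[, q], q] + alpha[mat_f[, q], q]
    v <- stats::var(val)
    if (v < .Machine$double.eps) {
      # monomorphic draw: no scaling possible, contributes nothing
      g[, q] <- 0; realized[q] <- 0; next
    }
    g[, q] <- (val - mean(val)) * sqrt(variance_per_qtl / v)
    realized[q] <- variance_per_qtl
  }
  noise_var <- 1 - tot_g
  y <- rowSums(g) + stats::rnorm(n, sd = sqrt(noise_var))
  names(y) <- individuals
  gtot <- rowSums(g); names(gtot) <- individuals
  structure(list(y = y,
                 truth = list(qtl_loci = qtl_loci, alpha = alpha, gamma = gamma,
                              realized_var = realized, noise_var = noise_var,
                              genetic_values = gtot, poe_mode = poe_mode)),
            class = "sim_trait")
}
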