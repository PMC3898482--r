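#' Phase weights for an offspring genotype given parental genotypes
#'
#' At a biallelic marker, the parents' genotypes partly determine the phase
#' of the offspring's genotype.  The phase is encoded by the probability
#' `w(ab)` that the ordered (paternal, maternal) genotype is `ab` rather
#' than `ba`, with `w(ab) + w(ba) = 1`.  If both parents are homozygous for
#' different alleles the offspring is perfectly phased; if both are
#' heterozygous the offspring is unphased (`w = 0.5` each way); a homozygous
#' offspring is conventionally assigned `w = 0.5` for its single (duplicated)
#' ordering.  Mendelian-impossible trios fall back to `w = 0.5` and are
#' flagged.
#'
#' @param child,sire,dam Integer dosage genotypes (0/1/2 copies of allele 1,
#'   NA allowed), vectorized over markers.  Missing parents count as
#'   uninformative.
#' @return A list: `pat1` and `pat2` (paternal allele of ordering 1 and 2),
#'   `mat1`, `mat2` (maternal alleles), `w1`, `w2` (ordering probabilities,
#'   `w1 + w2 = 1`), and logical `mendel_impossible`.  For homozygous or
#'   missing child genotypes the two orderings coincide.
#' @export
phase_weights <- function(child, sire, dam) {
  m <- length(child)
  if (length(sire) == 1) sire <- rep(sire, m)
  if (length(dam) == 1) dam <- rep(dam, m)
  bad <- function(g) any(!is.na(g) & !(g %in% 0:2))
  if (bad(child) || bad(sire) || bad(dam))
    stop("genotype codes must be 0, 1, 2 or NA")
  # P(parent with dosage g transmits allele 1)
  tp <- function(g) ifelse(is.na(g), 0.5, g / 2)
  ts <- tp(sire); td <- tp(dam)

  pat1 <- integer(m); mat1 <- integer(m); pat2 <- integer(m); mat2 <- integer(m)
  w1 <- numeric(m); mendel <- logical(m)

  het <- !is.na(child) & child == 1L
  hom <- !is.na(child) & child != 1L
  mis <- is.na(child)

  # heterozygote: orderings (1,0) and (0,1)
  p10 <- ts * (1 - td); p01 <- (1 - ts) * td
  tot <- p10 + p01
  mendel[het] <- tot[het] == 0
  wh <- ifelse(tot > 0, p10 / tot, 0.5)
  pat1[het] <- 1L; mat1[het] <- 0L; pat2[het] <- 0L; mat2[het] <- 1L
  w1[het] <- wh[het]

  a <- ifelse(hom & child == 2L, 1L, 0L)
  pat1[hom] <- a[hom]; mat1[hom] <- a[hom]; pat2[hom] <- a[hom]; mat2[hom] <- a[hom]
  w1[hom] <- 0.5
  # hom child inconsistent if either parent homozygous for the other allele
  pa <- ifelse(a == 1L, ts, 1 - ts); pm <- ifelse(a == 1L, td, 1 - td)
  mendel[hom] <- (pa * pm)[hom] == 0

  pat1[mis] <- NA_integer_; mat1[mis] <- NA_integer_
  pat2[mis] <- NA_integer_; mat2[mis] <- NA_integer_
  w1[mis] <- 0.5

  list(pat1 = pat1, mat1 = mat1, pat2 = pat2, mat2 = mat2,
       w1 = w1, w2 = 1 - w1, mendel_impossible = mendel)
}

#' Parameters of the phased haplotype-mosaic HMM
#'
#' @param error Symmetric genotyping error rate used in the emission model.
#' @param lambda Founder-switch intensity per cM: the per-interval switch
#'   probability is `1 - exp(-d_cM * lambda)`, after which the new founder is
#'   uniform over the panel.  Larger values model a finer ancestral mosaic
#'   (more accumulated generations of recombination).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(error = 0.01, lambda = 0.05) {
  if (error < 0 || error >= 0.5) stop("error must lie in [0, 0.5)")
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(error = error, lambda = lambda), class = "hmm_params")
}

# transition update for one chain interval applied on both (paternal,
# maternal) axes of the F x F state matrix; the single-chain kernel is
# T = stay*I + (1-stay)/F * J, applied independently to each parent's chain
.transition_both <- function(P, stay, Fn) {
  b <- (1 - stay) / Fn
  a2 <- stay * stay; ab <- stay * b; b2 <- b * b
  rs <- rowSums(P); cs <- colSums(P); tot <- sum(P)
  a2 * P + ab * (matrix(rs, Fn, Fn) + matrix(cs, Fn, Fn, byrow = TRUE)) + b2 * tot
}

# emission matrices (F x F, rows = paternal founder) for one individual on a
# set of markers; returns a list of matrices
.emissions <- function(pw, alleles, error, loci) {
  Fn <- nrow(alleles)
  lapply(loci, function(L) {
    if (is.na(pw$pat1[L])) return(matrix(1, Fn, Fn))
    A <- alleles[, L]
    e1 <- ifelse(A == 1L, 1 - error, error)   # P(read allele 1 | founder allele)
    e0 <- 1 - e1
    ep <- function(a) if (a == 1L) e1 else e0
    pw$w1[L] * outer(ep(pw$pat1[L]), ep(pw$mat1[L])) +
      pw$w2[L] * outer(ep(pw$pat2[L]), ep(pw$mat2[L]))
  })
}

#' Phased diplotype probabilities for one individual
#'
#' Runs the phased founder-mosaic HMM for a single genotyped individual with
#' (possibly missing) parental genotypes, chromosome by chromosome.  The
#' hidden state at marker `L` is the ordered founder pair `(s, t)` with `s`
#' the paternally and `t` the maternally inherited haplotype; parental
#' genotypes enter through the phase weights of [phase_weights()], which
#' multiply the emission term of the forward recurrence.  A standard scaled
#' forward-backward pass yields the posterior `P[s, t, L]`.
#'
#' @param child,sire,dam Dosage genotype vectors over all markers of `panel`
#'   (`sire`/`dam` may be NULL for an unphased fit, which yields a posterior
#'   symmetric in `(s, t)`).
#' @param panel A `founder_panel`.
#' @param params An [hmm_params()] object.
#' @param warn_mendel Warn (once) about Mendelian-impossible markers, where
#'   the phase weight falls back to 0.5.
#' @return Object of class `phased_probs`: `P` (array F x F x M), `phi`
#'   (M x F paternal marginals), `psi` (M x F maternal marginals), `loglik`.
#' @export
phase_individual <- function(child, sire = NULL, dam = NULL, panel,
                             params = hmm_params(), warn_mendel = TRUE) {
  alleles <- panel$alleles
  Fn <- nrow(alleles); M <- ncol(alleles)
  if (length(child) != M) stop("child genotypes must cover all ", M, " markers")
  if (is.null(sire)) sire <- rep(NA_integer_, M)
  if (is.null(dam)) dam <- rep(NA_integer_, M)
  pw <- phase_weights(child, sire, dam)
  if (warn_mendel && any(pw$mendel_impossible))
    warning(sum(pw$mendel_impossible),
            " Mendelian-impossible marker(s); phase weight reset to 0.5",
            call. = FALSE)

  P <- array(NA_real_, c(Fn, Fn, M))
  loglik <- 0
  for (cc in unique(panel$map$chr)) {
    loci <- which(panel$map$chr == cc)
    E <- .emissions(pw, alleles, params$error, loci)
    nl <- length(loci)
    stay <- exp(-diff(panel$map$cM[loci]) * params$lambda)

    fwd <- vector("list", nl)
    f <- E[[1]] / (Fn * Fn)
    cst <- sum(f)
    if (cst <= 0) stop("zero likelihood: genotypes inconsistent at marker ",
                       panel$map$marker[loci[1]])
    f <- f / cst; fwd[[1]] <- f; loglik <- loglik + log(cst)
    if (nl > 1) for (k in 2:nl) {
      f <- .transition_both(f, stay[k - 1], Fn) * E[[k]]
      cst <- sum(f)
      if (cst <= 0) stop("zero likelihood: genotypes inconsistent at marker ",
                         panel$map$marker[loci[k]])
      f <- f / cst; fwd[[k]] <- f; loglik <- loglik + log(cst)
    }

    b <- matrix(1 / (Fn * Fn), Fn, Fn)
    post <- fwd[[nl]] * b
    P[, , loci[nl]] <- post / sum(post)
    if (nl > 1) for (k in (nl - 1):1) {
      b <- .transition_both(b * E[[k + 1]], stay[k], Fn)
      b <- b / sum(b)
      post <- fwd[[k]] * b
      P[, , loci[k]] <- post / sum(post)
    }
  }
  phi <- t(apply(P, 3, rowSums)); psi <- t(apply(P, 3, colSums))
  dimnames(P) <- list(rownames(alleles), rownames(alleles), panel$map$marker)
  structure(list(P = P, phi = phi, psi = psi, loglik = loglik),
            class = "phased_probs")
}

#' Paternal/maternal marginals and the symmetrized diplotype probabilities
#'
#' From the ordered diplotype posterior `P(s, t)` computes the paternal
#' marginal `phi(s) = sum_t P(s, t)`, the maternal marginal
#' `psi(t) = sum_s P(s, t)`, and the symmetrized probabilities
#' `R(s, t) = (P(s, t) + P(t, s)) / 2`.
#'
#' @param P Either a `phased_probs` object or a single F x F matrix.
#' @return List with `phi`, `psi` (each summing to 1 per locus) and `R`.
#' @export
marginals <- function(P) {
  if (inherits(P, "phased_probs")) {
    # per-locus symmetrization of the ordered posterior

    R <- array(NA_real_, dim(P$P))
    for (L in seq_len(dim(P$P)[3])) R[, , L] <- (P$P[, , L] + t(P$P[, , L])) / 2
    return(list(phi = P$phi, psi = P$psi, R = R))
  }
  list(phi = rowSums(P), psi = colSums(P), R = (P + t(P)) / 2)
}

#' Phase every individual of a generation against its parents
#'
#' Applies [phase_individual()] to each chosen animal of an `hs_population`
#' (by default the final generation, whose parents are all genotyped) and
#' collects the paternal/maternal founder-dosage tracks used by the kinship
#' and scan stages.  Full F x F posteriors are retained only at `keep_loci`
#' to bound memory.
#'
#' @param pop An `hs_population`.
#' @param params An [hmm_params()].
#' @param individuals Ids to phase (default: final generation).
#' @param keep_loci Marker indices at which the full ordered posterior is
#'   kept (list `P[[locus]]` of n x F x F arrays).
#' @return Object of class `phased_population`: `phi`, `psi` (n x M x F
#'   arrays), `P` (named list over kept loci), `ids`, `map`, `params`,
#'   `loglik` (per individual).
#' @export
phase_population <- function(pop, params = hmm_params(), individuals = NULL,
                             keep_loci = integer(0)) {
  ped <- pop$ped
  if (is.null(individuals))
    individuals <- ped$id[ped$generation == max(ped$generation)]
  n <- length(individuals)
  Fn <- nrow(pop$panel$alleles); M <- ncol(pop$genotypes)
  phi <- array(NA_real_, c(n, M, Fn), dimnames = list(individuals, NULL, NULL))
  psi <- phi
  Pkeep <- lapply(keep_loci, function(L) array(NA_real_, c(n, Fn, Fn)))
  names(Pkeep) <- as.character(keep_loci)
  loglik <- numeric(n)
  n_mendel <- 0L
  for (i in seq_len(n)) {
    id <- individuals[i]
    k <- match(id, ped$id)
    sg <- if (!is.na(ped$sire[k])) pop$genotypes[ped$sire[k], ] else NULL
    dg <- if (!is.na(ped$dam[k])) pop$genotypes[ped$dam[k], ] else NULL
    ph <- withCallingHandlers(
      phase_individual(pop$genotypes[id, ], sg, dg, pop$panel, params),
      warning = function(w) {
        n_mendel <<- n_mendel + 1L
        invokeRestart("muffleWarning")
      })
    phi[i, , ] <- ph$phi; psi[i, , ] <- ph$psi
    loglik[i] <- ph$loglik
    for (j in seq_along(keep_loci)) Pkeep[[j]][i, , ] <- ph$P[, , keep_loci[j]]
  }
  if (n_mendel > 0)
    message(n_mendel, " individual(s) had Mendelian-impossible markers (phase weight 0.5 used)")
  structure(list(phi = phi, psi = psi, P = Pkeep, ids = individuals,
                 map = pop$panel$map, params = params, loglik = loglik),
            class = "phased_population")
}

#' Point-mass phased probabilities from known simulated mosaics
#'
#' Converts the true founder mosaics of a simulated population into a
#' `phased_population` whose diplotype probabilities are point masses on the
#' truth.  Used to study the downstream statistics free of phasing
#' uncertainty, and as the truth channel in tests.
#'
#' @inheritParams phase_population
#' @export
phased_from_mosaics <- function(pop, individuals = NULL, keep_loci = integer(0)) {
  ped <- pop$ped
  if (is.null(individuals))
    individuals <- ped$id[ped$generation == max(ped$generation)]
  n <- length(individuals)
  Fn <- nrow(pop$panel$alleles); M <- ncol(pop$genotypes)
  phi <- array(0, c(n, M, Fn), dimnames = list(individuals, NULL, NULL))
  psi <- phi
  Pkeep <- lapply(keep_loci, function(L) array(0, c(n, Fn, Fn)))
  names(Pkeep) <- as.character(keep_loci)
  for (i in seq_len(n)) {
    mo <- pop$mosaics[[individuals[i]]]
    phi[cbind(i, seq_len(M), mo$pat)] <- 1
    psi[cbind(i, seq_len(M), mo$mat)] <- 1
    for (j in seq_along(keep_loci)) {
      L <- keep_loci[j]
      Pkeep[[j]][i, mo$pat[L], mo$mat[L]] <- 1
    }
  }
  structure(list(phi = phi, psi = psi, P = Pkeep, ids = individuals,
                 map = pop$panel$map, params = NULL, loglik = rep(0, n)),
            class = "phased_population")
}
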