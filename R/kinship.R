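#' Parent-of-origin allele-sharing probabilities for one pair at one locus
#'
#' For two individuals with ordered diplotype probabilities `P_i(s,t)` and
#' `P_j(s,t)` over the founder alphabet, computes the probability that they
#' share `k = 0, 1, 2` founder alleles via parents of the *same* sex, and
#' the expected shared-allele counts: `E` via same-sex parents, `F` via
#' opposite-sex parents, and their total `K = E + F`.  These follow the
#' marginal dot products
#' \eqn{E = \phi_i\cdot\phi_j + \psi_i\cdot\psi_j},
#' \eqn{F = \phi_i\cdot\psi_j + \psi_i\cdot\phi_j}, so that
#' \eqn{K = (\phi_i+\psi_i)\cdot(\phi_j+\psi_j)}.
#'
#' @param P_i,P_j F x F ordered diplotype probability matrices (rows =
#'   paternal founder), each summing to 1.
#' @return List with `pi` (length-3 vector, sharing 0/1/2 alleles same-sex),
#'   `E`, `F`, `K`.
#' @export
sharing_probs <- function(P_i, P_j) {
  if (!all(dim(P_i) == dim(P_j)))
    stop("founder alphabets differ between the two individuals")
  phi_i <- rowSums(P_i); psi_i <- colSums(P_i)
  phi_j <- rowSums(P_j); psi_j <- colSums(P_j)
  pi2 <- sum(P_i * P_j)
  Ev <- sum(phi_i * phi_j) + sum(psi_i * psi_j)
  pi1 <- Ev - 2 * pi2
  Fv <- sum(phi_i * psi_j) + sum(psi_i * phi_j)
  list(pi = c(`0` = 1 - pi1 - pi2, `1` = pi1, `2` = pi2),
       E = Ev, F = Fv, K = Ev + Fv)
}

#' Decomposed kinship matrices from phased diplotype probabilities
#'
#' Averages the per-locus sharing matrices over markers to obtain the
#' same-parental-sex kinship `K+ = (1/N) sum_L Phi_L' Phi_L + Psi_L' Psi_L`,
#' the opposite-parental-sex kinship
#' `K- = (1/N) sum_L Phi_L' Psi_L + Psi_L' Phi_L`, and their sum `K± = K+ + K-`
#' (the ordinary marker kinship).  The matrices are then jointly rescaled by
#' `K <- D K D` with `D = diag(1/sqrt(diag(K±)))`, so the diagonal of the
#' scaled `K±` is exactly 1 while the additive decomposition is preserved.
#'
#' @param phased A `phased_population`.
#' @param markers Marker indices to average over (default: all).
#' @param scale Apply the unit-diagonal rescaling (default TRUE).
#' @return Object of class `kinship_set`: `K_plus`, `K_minus`, `K_pm`
#'   (n x n, dimnames = ids), `D` (scaling vector), `n_loci`, `markers`,
#'   `scaled`, and (when scaled) `unscaled` holding the raw matrices.
#' @export
kinship_matrices <- function(phased, markers = NULL, scale = TRUE) {
  M <- dim(phased$phi)[2]
  if (is.null(markers)) markers <- seq_len(M)
  if (length(markers) < 1) stop("marker subset is empty")
  n <- dim(phased$phi)[1]; Fn <- dim(phased$phi)[3]
  N <- length(markers)
  # flatten to n x (N*F): tcrossprod then sums Phi_L' Phi_L over loci
  Bphi <- matrix(phased$phi[, markers, , drop = FALSE], n, N * Fn)
  Bpsi <- matrix(phased$psi[, markers, , drop = FALSE], n, N * Fn)
  Kp <- (tcrossprod(Bphi) + tcrossprod(Bpsi)) / N
  Km <- (tcrossprod(Bphi, Bpsi) + tcrossprod(Bpsi, Bphi)) / N
  dimnames(Kp) <- dimnames(Km) <- list(phased$ids, phased$ids)
  out <- list(K_plus = Kp, K_minus = Km, K_pm = Kp + Km,
              D = rep(1, n), n_loci = N, markers = markers, scaled = FALSE)
  if (scale) {
    D <- 1 / sqrt(diag(out$K_pm))
    S <- outer(D, D)
    out <- list(K_plus = Kp * S, K_minus = Km * S, K_pm = (Kp + Km) * S,
                D = D, n_loci = N, markers = markers, scaled = TRUE,
                unscaled = out[c("K_plus", "K_minus", "K_pm")])
  }
  class(out) <- "kinship_set"
  out
}

#' @export
print.kinship_set <- function(x, ...) {
  cat("<kinship_set> ", nrow(x$K_pm), " individuals, ", x$n_loci, " loci",
      if (x$scaled) ", unit-diagonal scaled" else "", "\n", sep = "")
  invisible(x)
}

#' Summarize kinship components for sibling vs non-sibling pairs
#'
#' @param kin A `kinship_set` over final-generation animals.
#' @param ped The pedigree identifying full sibships.
#' @param probs Quantiles to report.
#' @return List with per-class element vectors and a summary data frame
#'   (class, component, n pairs, mean, quantiles).
#' @export
sib_vs_nonsib_summary <- function(kin, ped, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  ids <- rownames(kin$K_pm)
  g <- ped[match(ids, ped$id), ]
  sp <- sib_pairs(g, generation = g$generation[1])
  if (nrow(sp$sibs) == 0) stop("no sibling pairs among these individuals")
  take <- function(K, pr) K[pr]
  vals <- list(
    K_plus_sib = take(kin$K_plus, sp$sibs), K_plus_nonsib = take(kin$K_plus, sp$nonsibs),
    K_minus_sib = take(kin$K_minus, sp$sibs), K_minus_nonsib = take(kin$K_minus, sp$nonsibs))
  smr <- do.call(rbind, lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    data.frame(component = sub("_(non)?sib$", "", nm),
               class = if (grepl("nonsib$", nm)) "nonsib" else "sib",
               n = length(v), mean = mean(v), sd = stats::sd(v),
               t(stats::quantile(v, probs)), check.names = FALSE)
  }))
  rownames(smr) <- NULL
  list(values = vals, summary = smr)
}

#' Closed-form same-parental-sex sharing at a Hardy-Weinberg SNP
#'
#' At a biallelic SNP with allele frequency `p` in Hardy-Weinberg
#' equilibrium, the expected number of alleles shared via parents of the
#' same sex is `2(p^2 + q^2 + pq)` for full siblings and `2(p^2 + q^2)` for
#' unrelated pairs; the sibling excess is `2pq`, maximal (0.5) at `p = 0.5`.
#'
#' @param p Allele frequency (vectorized, in \[0, 1\]).
#' @param relationship `"sib"` or `"nonsib"`.
#' @return Expected shared-allele count(s).
#' @export
hwe_sharing <- function(p, relationship = c("sib", "nonsib")) {
  relationship <- match.arg(relationship)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  q <- 1 - p
  if (relationship == "sib") 2 * (p^2 + q^2 + p * q) else 2 * (p^2 + q^2)
}

#' @rdname hwe_sharing
#' @export
hwe_sharing_excess <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  2 * p * (1 - p)
}

#' Select markers within a flank of annotated regions
#'
#' Region coordinates are 0-based half-open `[start, end)` intervals (BED
#' convention); a marker at physical position `bp` is selected when it falls
#' inside any region extended by `flank_bp` on both sides.
#'
#' @param map Marker map (`marker`, `chr`, `bp`).
#' @param regions Data frame with `chr`, `start`, `end` (and optionally
#'   `name`).
#' @param flank_bp Flank width in bp (default 3 Mb, the span over which
#'   linkage disequilibrium in a heterogeneous stock still tags a region).
#' @return Integer vector of marker indices into `map`.
#' @export
subset_regions <- function(map, regions, flank_bp = 3e6) {
  if (nrow(regions) == 0) return(integer(0))
  hit <- rep(FALSE, nrow(map))
  for (r in seq_len(nrow(regions))) {
    hit <- hit | (map$chr == regions$chr[r] &
                    map$bp >= regions$start[r] - flank_bp &
                    map$bp < regions$end[r] + flank_bp)
  }
  which(hit)
}

#' Circularly permute region locations along chromosomes
#'
#' Shifts every region by a single random offset modulo its chromosome
#' length, wrapping regions that run off the end (a region crossing the
#' origin is split in two).  Per-chromosome region count (up to splits) and
#' total covered length are preserved exactly, so the permuted list is an
#' exchangeable null for location-specific enrichment.
#'
#' @param regions Data frame `chr`, `start`, `end` (0-based half-open).
#' @param chrom_lengths Named (by chr) or positionally indexed lengths in bp.
#' @param offset Common shift in bp; drawn uniformly when NULL.
#' @param seed Optional integer seed (used only when `offset` is NULL).
#' @return A region data frame of the same form, plus attribute `offset`.
#' @export
circular_permute_regions <- function(regions, chrom_lengths, offset = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(offset)) offset <- floor(stats::runif(1, 0, max(chrom_lengths)))
  out <- list()
  for (r in seq_len(nrow(regions))) {
    cl <- if (!is.null(names(chrom_lengths)))
      chrom_lengths[[as.character(regions$chr[r])]] else chrom_lengths[[regions$chr[r]]]
    s <- (regions$start[r] + offset) %% cl
    e <- s + (regions$end[r] - regions$start[r])
    if (e <= cl) {
      out[[length(out) + 1L]] <- data.frame(chr = regions$chr[r], start = s, end = e)
    } else {
      out[[length(out) + 1L]] <- data.frame(chr = regions$chr[r], start = s, end = cl)
      out[[length(out) + 1L]] <- data.frame(chr = regions$chr[r], start = 0, end = e - cl)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "offset") <- offset
  res
}
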