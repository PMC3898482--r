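#' @keywords internal
#' Recombine a parent's two haplotypes into one gamete (Haldane model).
#'
#' Crossover count per chromosome is Poisson with mean equal to the map
#' length in Morgans; crossover positions are uniform on the genetic map;
#' there is no interference.  Haplotypes are founder-label vectors indexed by
#' marker.
meiosis_gamete <- function(hap1, hap2, cM) {
  len_morgan <- (max(cM) - min(cM)) / 100
  n_xo <- stats::rpois(1, len_morgan)
  start <- sample(1:2, 1)
  if (n_xo == 0) {
    gam <- if (start == 1) hap1 else hap2
    attr(gam, "n_crossovers") <- 0L
    return(gam)
  }
  xo <- sort(stats::runif(n_xo, min(cM), max(cM)))
  # current strand at each marker = start strand flipped once per crossover left of it
  flips <- vapply(cM, function(x) sum(xo < x), integer(1))
  strand <- 1L + (start - 1L + flips) %% 2L
  gam <- ifelse(strand == 1L, hap1, hap2)
  attr(gam, "n_crossovers") <- n_xo
  gam
}

#' Drop founder haplotypes through a pedigree
#'
#' Performs gene dropping: generation-0 animals are the inbred founder
#' strains (two identical copies of their own haplotype); every other
#' animal's paternal haplotype is a recombinant of its sire's two haplotypes
#' and its maternal haplotype a recombinant of its dam's, chromosome by
#' chromosome under the Haldane (no-interference) model.  Unphased genotypes
#' are the allele-1 dosage carried by the two mosaic haplotypes.
#'
#' @param ped Pedigree from [simulate_pedigree()] (generation 0 must have
#'   exactly as many animals as the panel has founders).
#' @param panel A [simulate_founders()] panel.
#' @param geno_error Per-call probability that a genotype is misread (the
#'   dosage is replaced by one of the other two values); default 0.
#' @param seed Optional integer seed.
#'
#' @return An object of class `hs_population`: list with `ped`, `panel`,
#'   `mosaics` (per id, list `pat`/`mat` of founder-index vectors over all
#'   markers), `genotypes` (n x M dosage matrix, rows named by id), and the
#'   true ordered allele matrices `allele_pat`, `allele_mat` (oracle truth
#'   channel).
#' @export
drop_haplotypes <- function(ped, panel, geno_error = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_pedigree(ped)
  Fn <- nrow(panel$alleles)
  founders <- ped$id[ped$generation == 0]
  if (length(founders) != Fn)
    stop("generation 0 size (", length(founders), ") must equal panel founders (", Fn, ")")
  map <- panel$map
  M <- nrow(map)
  chr_idx <- split(seq_len(M), map$chr)

  mosaics <- vector("list", nrow(ped))
  names(mosaics) <- ped$id
  for (k in seq_along(founders))
    mosaics[[founders[k]]] <- list(pat = rep(k, M), mat = rep(k, M))

  ord <- order(ped$generation)
  for (i in ord) {
    if (ped$generation[i] == 0) next
    sire <- ped$sire[i]; dam <- ped$dam[i]
    if (is.na(sire) || is.na(dam) || is.null(mosaics[[sire]]) || is.null(mosaics[[dam]]))
      stop("missing parent record for ", ped$id[i])
    pat <- integer(M); mat <- integer(M)
    for (ci in chr_idx) {
      pat[ci] <- meiosis_gamete(mosaics[[sire]]$pat[ci], mosaics[[sire]]$mat[ci], map$cM[ci])
      mat[ci] <- meiosis_gamete(mosaics[[dam]]$pat[ci], mosaics[[dam]]$mat[ci], map$cM[ci])
    }
    mosaics[[ped$id[i]]] <- list(pat = pat, mat = mat)
  }

  n <- nrow(ped)
  allele_pat <- matrix(0L, n, M, dimnames = list(ped$id, map$marker))
  allele_mat <- allele_pat
  for (i in seq_len(n)) {
    mo <- mosaics[[ped$id[i]]]
    allele_pat[i, ] <- panel$alleles[cbind(mo$pat, seq_len(M))]
    allele_mat[i, ] <- panel$alleles[cbind(mo$mat, seq_len(M))]
  }
  genotypes <- allele_pat + allele_mat
  if (geno_error > 0) {
    err <- matrix(stats::runif(n * M) < geno_error, n, M)
    if (any(err)) {
      shift <- matrix(sample(1:2, n * M, replace = TRUE), n, M)
      genotypes[err] <- (genotypes[err] + shift[err]) %% 3L
    }
  }
  structure(list(ped = ped, panel = panel, mosaics = mosaics,
                 genotypes = genotypes,
                 allele_pat = allele_pat, allele_mat = allele_mat),
            class = "hs_population")
}

#' Simulate a full pedigreed founder-mosaic population in one call
#'
#' Convenience wrapper chaining [simulate_founders()], [simulate_pedigree()]
#' and [drop_haplotypes()] under a single seed.
#'
#' @inheritParams simulate_founders
#' @inheritParams simulate_pedigree
#' @inheritParams drop_haplotypes
#' @param seed Integer seed governing every stage.
#' @return An `hs_population` object.
#' @export
simulate_hs_population <- function(n_families = 50, sibs_per_family = 4,
                                   n_generations = 3, n_founders = 8,
                                   markers_per_chr = 100, n_chr = 1,
                                   chr_length_bp = 160e6, chr_length_cm = 80,
                                   maf_sampler = function(n) stats::runif(n, 0.1, 0.9),
                                   geno_error = 0, n_mid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- simulate_founders(n_founders, markers_per_chr, n_chr, maf_sampler,
                             chr_length_bp, chr_length_cm)
  ped <- simulate_pedigree(n_families, sibs_per_family, n_generations, n_founders,
                           n_mid = n_mid)
  drop_haplotypes(ped, panel, geno_error = geno_error)
}

#' @export
print.hs_population <- function(x, ...) {
  cat("<hs_population> ", nrow(x$ped), " animals (",
      sum(x$ped$generation == max(x$ped$generation)), " in final generation), ",
      ncol(x$genotypes), " markers, ", nrow(x$panel$alleles), " founders\n", sep = "")
  invisible(x)
}
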