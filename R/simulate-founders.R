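#' Simulate a panel of inbred founder haplotypes
#'
#' Generates a set of fully homozygous founder strains genotyped at biallelic
#' markers on one or more chromosomes, playing the role of the progenitor
#' strains of a heterogeneous stock.  Marker positions are drawn uniformly
#' along each chromosome and the genetic map is proportional to physical
#' position.
#'
#' @param n_founders Number of inbred founder strains (>= 2; a heterogeneous
#'   stock has 8).
#' @param markers_per_chr Number of markers per chromosome (>= 2).
#' @param n_chr Number of chromosomes.
#' @param maf_sampler Either a single allele frequency in (0, 1) used for
#'   every marker, or a function of `n` returning `n` frequencies from which
#'   founder alleles are drawn independently.
#' @param chr_length_bp Physical chromosome length in bp.
#' @param chr_length_cm Genetic chromosome length in cM.
#' @param seed Optional integer seed; identical seeds give identical panels.
#'
#' @return An object of class `founder_panel`: a list with `alleles`
#'   (`n_founders` x `M` 0/1 matrix, one row per strain), and `map`
#'   (data frame with columns `marker`, `chr`, `bp`, `cM`).  Every marker is
#'   polymorphic across the panel.
#' @export
simulate_founders <- function(n_founders = 8, markers_per_chr = 100,
                              n_chr = 1, maf_sampler = function(n) stats::runif(n, 0.1, 0.9),
                              chr_length_bp = 160e6, chr_length_cm = 80,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (markers_per_chr < 2) stop("markers_per_chr must be >= 2")
  if (n_chr < 1) stop("n_chr must be >= 1")
  if (is.numeric(maf_sampler)) {
    f0 <- maf_sampler
    if (f0 <= 0 || f0 >= 1) stop("fixed allele frequency must lie in (0,1)")
    maf_sampler <- function(n) rep(f0, n)
  }

  maps <- vector("list", n_chr)
  for (cc in seq_len(n_chr)) {
    bp <- sort(sample.int(chr_length_bp, markers_per_chr))
    maps[[cc]] <- data.frame(
      marker = sprintf("c%dm%d", cc, seq_len(markers_per_chr)),
      chr = cc, bp = bp,
      cM = bp / chr_length_bp * chr_length_cm
    )
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL

  M <- nrow(map)
  freq <- maf_sampler(M)
  alleles <- matrix(0L, n_founders, M,
                    dimnames = list(paste0("F", seq_len(n_founders)), map$marker))
  for (j in seq_len(M)) {
    a <- stats::rbinom(n_founders, 1L, freq[j])
    # resample monomorphic columns so every marker segregates in the panel
    while (length(unique(a)) == 1L) a <- stats::rbinom(n_founders, 1L, freq[j])
    alleles[, j] <- a
  }

  structure(list(alleles = alleles, map = map,
                 chr_length_bp = chr_length_bp, chr_length_cm = chr_length_cm),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("<founder_panel> ", nrow(x$alleles), " founders, ",
      nrow(x$map), " markers on ", length(unique(x$map$chr)),
      " chromosome(s)\n", sep = "")
  invisible(x)
}
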