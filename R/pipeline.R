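#' Null heritability-ratio study on a simulated stock population
#'
#' Runs the full population pipeline that calibrates the parent-of-origin
#' heritability analysis: simulate a pedigreed founder-mosaic population,
#' phase the final generation against its parents with the diplotype HMM,
#' build the decomposed kinship matrices, then repeatedly simulate
#' non-imprinted complex traits (`n_qtls` additive QTLs of
#' `variance_per_qtl` each at random SNPs) and fit the two-component model
#' to each.  Because the traits carry no parent-of-origin effects, the
#' distribution of \eqn{h^2_+/h^2_-} across traits measures how far family
#' structure alone pushes the ratio from 1 — the reference against which
#' observed trait panels are judged.
#'
#' @param n_families,sibs_per_family,n_generations,n_founders,markers_per_chr,n_chr,n_mid
#'   Population design, passed to [simulate_hs_population()].
#' @param n_traits Number of simulated non-imprinted traits.
#' @param n_qtls,variance_per_qtl Architecture of each trait.
#' @param hmm [hmm_params()] for phasing.
#' @param use_true_phase Skip the HMM and use the simulated truth
#'   (mainly for fast diagnostics).
#' @param seed Integer seed governing the whole study.
#' @return List of class `null_h2_study`: the [compare_h2_across_traits()]
#'   summary (`comparison`), per-trait fit table, the `kinship_set`, and
#'   the study dimensions.
#' @export
null_h2_study <- function(n_families = 125, sibs_per_family = 4,
                          n_generations = 3, n_founders = 8,
                          markers_per_chr = 100, n_chr = 20, n_mid = 250,
                          n_traits = 200, n_qtls = 7, variance_per_qtl = 0.05,
                          hmm = hmm_params(), use_true_phase = FALSE,
                          seed = 1) {
  set.seed(seed)
  pop <- simulate_hs_population(n_families, sibs_per_family, n_generations,
                                n_founders, markers_per_chr, n_chr,
                                n_mid = n_mid)
  phased <- if (use_true_phase) phased_from_mosaics(pop)
            else phase_population(pop, hmm)
  kin <- kinship_matrices(phased)
  fits <- vector("list", n_traits)
  for (r in seq_len(n_traits)) {
    tr <- simulate_trait(pop, n_qtls = n_qtls,
                         variance_per_qtl = variance_per_qtl,
                         poe_mode = "none", individuals = phased$ids)
    y <- residualize(tr$y)
    fits[[r]] <- fit_two_component(y, kin$K_plus, kin$K_minus)
  }
  cmp <- compare_h2_across_traits(fits)
  structure(list(comparison = cmp, fits = cmp$table, kinship = kin,
                 n_animals = length(phased$ids),
                 n_markers = ncol(pop$genotypes), n_traits = n_traits),
            class = "null_h2_study")
}

#' @export
print.null_h2_study <- function(x, ...) {
  cat("<null_h2_study> ", x$n_animals, " animals, ", x$n_markers,
      " markers, ", x$n_traits, " non-imprinted traits\n", sep = "")
  cat("median h2+ =", round(x$comparison$median_h2_plus, 3),
      " median h2- =", round(x$comparison$median_h2_minus, 3),
      " median ratio =", round(x$comparison$median_ratio, 3), "\n")
  invisible(x)
}
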