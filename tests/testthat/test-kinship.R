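rand_P <- function(Fn) {
  P <- matrix(stats::rexp(Fn * Fn), Fn, Fn)
  P / sum(P)
}

test_that("pairwise sharing probabilities match the point-mass algebra", {
  P12 <- matrix(0, 3, 3); P12[1, 2] <- 1
  P21 <- matrix(0, 3, 3); P21[2, 1] <- 1
  same <- sharing_probs(P12, P12)
  expect_equal(unname(same$pi), c(0, 0, 1))
  expect_equal(same$E, 2); expect_equal(same$F, 0)
  mirr <- sharing_probs(P12, P21)
  expect_equal(mirr$E, 0); expect_equal(mirr$F, 2)
  expect_error(sharing_probs(P12, matrix(0.25, 2, 2)), "alphabet")
})

test_that("sharing identities hold for random diplotype distributions", {
  set.seed(12)
  for (r in 1:20) {
    Fn <- sample(2:8, 1)
    Pi <- rand_P(Fn); Pj <- rand_P(Fn)
    s <- sharing_probs(Pi, Pj)
    expect_true(all(s$pi >= -1e-12 & s$pi <= 1 + 1e-12))
    expect_equal(sum(s$pi), 1, tolerance = 1e-12)
    expect_equal(s$E, unname(s$pi["1"] + 2 * s$pi["2"]), tolerance = 1e-12)
    # E + F = (phi_i + psi_i) . (phi_j + psi_j)
    tot <- sum((rowSums(Pi) + colSums(Pi)) * (rowSums(Pj) + colSums(Pj)))
    expect_equal(s$E + s$F, tot, tolerance = 1e-12)
    # symmetry in i, j
    s2 <- sharing_probs(Pj, Pi)
    expect_equal(s$E, s2$E, tolerance = 1e-12)
    expect_equal(s$F, s2$F, tolerance = 1e-12)
  }
})

test_that("matrix-form kinship equals the per-pair sharing accumulation", {
  pop <- make_test_population(3, 2, 2, markers = 25, seed = 44)
  ph <- phase_population(pop, keep_loci = 1:25)
  n <- length(ph$ids); M <- 25
  kin <- kinship_matrices(ph, scale = FALSE)
  Kp <- matrix(0, n, n); Km <- matrix(0, n, n)
  for (L in seq_len(M)) {
    PL <- ph$P[[as.character(L)]]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- sharing_probs(PL[i, , ], PL[j, , ])
      Kp[i, j] <- Kp[i, j] + s$E
      Km[i, j] <- Km[i, j] + s$F
    }
  }
  expect_equal(kin$K_plus, Kp / M, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(kin$K_minus, Km / M, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(kinship_matrices(ph, markers = integer(0)), "empty")
})

test_that("scaling gives unit diagonal and preserves additivity and PSD", {
  pop <- make_test_population(6, 3, 3, markers = 50, seed = 45)
  ph <- phase_population(pop)
  kin <- kinship_matrices(ph)
  expect_lt(max(abs(diag(kin$K_pm) - 1)), 1e-10)
  expect_lt(max(abs(kin$K_pm - kin$K_plus - kin$K_minus)), 1e-12)
  un <- kin$unscaled
  expect_lt(max(abs(un$K_pm - un$K_plus - un$K_minus)), 1e-12)
  expect_gt(min(eigen(kin$K_pm, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_gt(min(eigen(kin$K_plus, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_equal(kin$K_plus, t(kin$K_plus))
  expect_equal(kin$K_minus, t(kin$K_minus))
})

test_that("full sibs with identical phases have unscaled K+ element 2", {
  ph <- structure(list(
    phi = array(0, c(2, 4, 3)), psi = array(0, c(2, 4, 3)),
    ids = c("a", "b"), P = list()), class = "phased_population")
  # both individuals inherit founder 1 paternally, founder 2 maternally
  ph$phi[, , 1] <- 1; ph$psi[, , 2] <- 1
  kin <- kinship_matrices(ph, scale = FALSE)
  expect_equal(kin$K_plus[1, 2], 2)
  expect_equal(kin$K_minus[1, 2], 0)
})

test_that("K+ separates siblings while K- does not, across replicates", {
  n_rep <- 20
  gap_plus <- gap_minus <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    # a roomy intermediate generation keeps sib-avoidance from making mated
    # couples systematically less related than random cross-family pairs
    pop <- make_test_population(8, 3, 3, markers = 60, seed = 300 + r,
                                n_mid = 60)
    ph <- phased_from_mosaics(pop)
    kin <- kinship_matrices(ph)
    sm <- sib_vs_nonsib_summary(kin, pop$ped)$summary
    gap_plus[r] <- sm$mean[sm$component == "K_plus" & sm$class == "sib"] -
      sm$mean[sm$component == "K_plus" & sm$class == "nonsib"]
    gap_minus[r] <- sm$mean[sm$component == "K_minus" & sm$class == "sib"] -
      sm$mean[sm$component == "K_minus" & sm$class == "nonsib"]
  }
  # same-parental-sex sharing always separates sibships ...
  expect_true(all(gap_plus > 0))
  # ... and carries essentially all of the extra sibling similarity: the
  # opposite-parental-sex gap is small relative to it and centred on zero
  expect_true(all(abs(gap_minus) < gap_plus))
  expect_lt(mean(abs(gap_minus)), mean(gap_plus) / 4)
  expect_lt(abs(mean(gap_minus)), 3 * stats::sd(gap_minus) / sqrt(n_rep) + 0.01)
})

test_that("Hardy-Weinberg closed forms match a Mendelian Monte-Carlo", {
  expect_equal(hwe_sharing_excess(0.5), 0.5)
  expect_equal(hwe_sharing_excess(0), 0)
  expect_equal(hwe_sharing_excess(1), 0)
  ps <- seq(0, 1, 0.01)
  expect_equal(max(hwe_sharing(ps, "sib") - hwe_sharing(ps, "nonsib")),
               0.5)
  expect_error(hwe_sharing(1.2), "0, 1")

  # Monte-Carlo: HWE parents, Mendelian transmission, p = 0.3
  set.seed(88)
  p <- 0.3; n <- 2e5
  draw_geno <- function(n) stats::rbinom(n, 2, p)
  transmit <- function(g, n) ifelse(g == 1, stats::rbinom(n, 1, 0.5), g / 2)
  # siblings: same mother and father, two independent transmissions each
  gm <- draw_geno(n); gf <- draw_geno(n)
  shared_sib <- (transmit(gm, n) == transmit(gm, n)) +
    (transmit(gf, n) == transmit(gf, n))
  # nonsibs: independent parents
  gm2 <- draw_geno(n); gf2 <- draw_geno(n)
  shared_non <- (transmit(gm, n) == transmit(gm2, n)) +
    (transmit(gf, n) == transmit(gf2, n))
  se <- sqrt(2 / n)  # bounded by Bernoulli variances
  expect_lt(abs(mean(shared_sib) - hwe_sharing(p, "sib")), 3 * se)
  expect_lt(abs(mean(shared_non) - hwe_sharing(p, "nonsib")), 3 * se)
})

test_that("sib-minus-nonsib K+ excess matches mean 2pq over SNPs", {
  # diallelic collapse: compute sharing on true transmitted SNP alleles
  pop <- make_test_population(12, 4, 3, markers = 80, seed = 91)
  fin <- pop$ped$id[pop$ped$generation == 3]
  sp <- sib_pairs(pop$ped)
  ap <- pop$allele_pat[fin, ]; am <- pop$allele_mat[fin, ]
  pair_vals <- function(pairs) {
    vapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      mean((ap[i, ] == ap[j, ]) + (am[i, ] == am[j, ]))
    }, numeric(1))
  }
  vs <- pair_vals(sp$sibs); vn <- pair_vals(sp$nonsibs)
  excess <- mean(vs) - mean(vn)
  se <- sqrt(stats::var(vs) / length(vs) + stats::var(vn) / length(vn))
  p_hat <- colMeans(rbind(ap, am))
  # a small absolute allowance covers the systematic part: non-sib pairs in
  # a closed finite population have related parents (drift), which the
  # independent-parent Hardy-Weinberg closed form ignores
  expect_lt(abs(excess - mean(2 * p_hat * (1 - p_hat))), 3 * se + 0.01)
})

test_that("region subsetting uses half-open flanked intervals", {
  map <- data.frame(marker = paste0("m", 1:100), chr = 1,
                    bp = seq(1e6, 100e6, by = 1e6), cM = 1:100)
  expect_length(subset_regions(map, data.frame(chr = integer(0),
                                               start = integer(0),
                                               end = integer(0))), 0)
  # gene [10 Mb, 10 Mb + 1), flank 3 Mb: markers in [7 Mb, 13 Mb)
  sel <- subset_regions(map, data.frame(chr = 1, start = 10e6, end = 10e6 + 1),
                        flank_bp = 3e6)
  expect_equal(map$bp[sel], seq(7e6, 13e6, by = 1e6))
  # coverage fraction ~ selected fraction for random regions
  set.seed(7)
  st <- sort(sample(seq(1e6, 90e6, by = 1e6), 5))
  regs <- data.frame(chr = 1, start = st, end = st + 4e6)
  sel <- subset_regions(map, regs, flank_bp = 0)
  covered <- unique(unlist(lapply(seq_len(5), function(r)
    seq(regs$start[r], regs$end[r] - 1))))
  frac_len <- sum(map$bp >= min(map$bp) & map$bp %in% covered) / nrow(map)
  expect_lt(abs(length(sel) / nrow(map) - frac_len), 0.02)
})

test_that("circular permutation preserves count and covered length", {
  regs <- data.frame(chr = c(1, 1, 2), start = c(5e6, 40e6, 10e6),
                     end = c(8e6, 45e6, 12e6))
  lens <- c(`1` = 50e6, `2` = 30e6)
  id <- circular_permute_regions(regs, lens, offset = 0)
  expect_equal(id$start, regs$start)
  tot <- sum(regs$end - regs$start)
  for (off in c(1e6, 7e6, 48e6)) {
    pm <- circular_permute_regions(regs, lens, offset = off)
    expect_equal(sum(pm$end - pm$start), tot)
    expect_true(all(pm$start >= 0))
  }
  # mean subset size over random offsets ~ covered fraction x marker count
  map <- data.frame(marker = paste0("m", 1:200), chr = 1,
                    bp = seq(0, 50e6 - 1, length.out = 200), cM = 1:200)
  regs1 <- regs[regs$chr == 1, ]
  set.seed(10)
  sizes <- replicate(200, length(subset_regions(
    map, circular_permute_regions(regs1, lens), flank_bp = 0)))
  frac <- sum(regs1$end - regs1$start) / 50e6
  expect_lt(abs(mean(sizes) - frac * 200), 3 * stats::sd(sizes) / sqrt(200) + 1)
})
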