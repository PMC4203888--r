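test_that("codon-position degeneracy follows the standard genetic code", {
  expect_equal(classify_codon_degeneracy("GGG", 3L), "fourfold")
  expect_equal(classify_codon_degeneracy("ATG", 1L), "nondegenerate")
  expect_equal(classify_codon_degeneracy("AAA", 3L), "twofold")
  # three-fold degenerate Ile third position pools with twofold
  expect_equal(classify_codon_degeneracy("ATT", 3L), "twofold")
  # stop codons and ambiguous bases yield NA
  expect_true(is.na(classify_codon_degeneracy("TAA", 1L)))
  expect_true(is.na(classify_codon_degeneracy("ANG", 2L)))

  # full agreement with enumeration over all sense codons and positions
  gc_tab <- Biostrings::GENETIC_CODE
  for (cod in names(gc_tab)[gc_tab != "*"])
    for (pos in 1:3)
      expect_equal(classify_codon_degeneracy(cod, pos),
                   oracle_degeneracy(cod, pos))
})

test_that("pairwise substitution counting matches per-codon enumeration on a toy pair", {
  # six codons; single A<->G difference at a fourfold third position
  a <- c("GGA", "ATG", "AAA", "TTT", "CCC", "GAT")
  b <- c("GGG", "ATG", "AAA", "TTT", "CCC", "GAT")
  cnt <- count_pairwise_substitutions(paste(a, collapse = ""),
                                      paste(b, collapse = ""))
  # site counts from the degeneracy oracle, averaged over the two seqs
  L_want <- c(nondegenerate = 0, twofold = 0, fourfold = 0)
  for (seqs in list(a, b)) for (cod in seqs) for (pos in 1:3) {
    cls <- oracle_degeneracy(cod, pos)
    L_want[cls] <- L_want[cls] + 0.5
  }
  expect_equal(cnt$L, L_want)
  expect_equal(unname(cnt$ts), c(0, 0, 1))
  expect_equal(unname(cnt$tv), c(0, 0, 0))
  expect_equal(unname(cnt$P["fourfold"]), 1 / cnt$L[["fourfold"]])
  expect_equal(cnt$n_codons, 6L)

  # identical sequences: no substitutions anywhere
  same <- count_pairwise_substitutions(paste(a, collapse = ""),
                                       paste(a, collapse = ""))
  expect_true(all(same$P == 0) && all(same$Q == 0))
})

test_that("site counts conserve the number of compared coding sites and skip gaps/stops", {
  set.seed(31)
  pair <- simulate_codon_pair(300L, t = 0.3, kappa = 2, omega = 1,
                              seed = 31L)
  cnt <- count_pairwise_substitutions(pair$seq_A, pair$seq_B)
  expect_equal(unname(sum(cnt$L)), 3 * cnt$n_codons)

  # gap codons and stop codons are excluded and counted
  a2 <- paste0("GGG", "---", "TAA", "AAA")
  b2 <- paste0("GGG", "AAA", "CAA", "AAA")
  cnt2 <- count_pairwise_substitutions(a2, b2)
  expect_equal(cnt2$n_codons, 2L)
  expect_equal(cnt2$n_skipped, 2L)
})

test_that("Kimura two-parameter components match the closed form and flag saturation", {
  z <- k2p_components(0, 0)
  expect_equal(z$K, 0)
  k <- k2p_components(0.1, 0.05)
  A_want <- 0.5 * log(1 / 0.75) - 0.25 * log(1 / 0.9)
  B_want <- 0.5 * log(1 / 0.9)
  expect_equal(k$A, A_want, tolerance = 1e-12)
  expect_equal(k$B, B_want, tolerance = 1e-12)
  expect_equal(k$K, 0.1702, tolerance = 5e-4)
  sat <- k2p_components(0.5, 0)
  expect_true(sat$saturated)
  expect_true(is.na(sat$K))
})

test_that("K2P distance is monotone in P and Q and linear in the small-distance limit", {
  ps <- seq(0, 0.2, by = 0.02)
  ks <- k2p_components(ps, rep(0.05, length(ps)))$K
  expect_true(all(diff(ks) > 0))
  qs <- seq(0, 0.2, by = 0.02)
  ks2 <- k2p_components(rep(0.05, length(qs)), qs)$K
  expect_true(all(diff(ks2) > 0))
  for (pq in list(c(0.004, 0.004), c(0.006, 0.002), c(0.001, 0.008))) {
    K <- k2p_components(pq[1], pq[2])$K
    expect_lt(abs(K - sum(pq)) / sum(pq), 0.05)
  }
})

test_that("the Li/Pamilo-Bianchi combination reproduces hand-evaluated rates", {
  classes <- c("nondegenerate", "twofold", "fourfold")
  # no divergence at all: Ka = Ks = 0
  zero <- list(L = stats::setNames(c(100, 60, 40), classes),
               P = stats::setNames(c(0, 0, 0), classes),
               Q = stats::setNames(c(0, 0, 0), classes))
  est0 <- li_ka_ks(zero)
  expect_equal(est0$Ka, 0)
  expect_equal(est0$Ks, 0)

  # only a fourfold transition component: A4 = 0.05 exactly when
  # P4 = (1 - exp(-0.1)) / 2; then Ks = 40 * 0.05 / (60 + 40) = 0.02
  P4 <- (1 - exp(-0.1)) / 2
  toy <- list(L = stats::setNames(c(100, 60, 40), classes),
              P = stats::setNames(c(0, 0, P4), classes),
              Q = stats::setNames(c(0, 0, 0), classes))
  est <- li_ka_ks(toy)
  expect_equal(est$A[3L], 0.05, tolerance = 1e-12)
  expect_equal(est$Ks, 0.02, tolerance = 1e-12)
  expect_equal(est$Ka, 0)

  # saturated required component flags the gene as degenerate
  satd <- list(L = stats::setNames(c(100, 60, 40), classes),
               P = stats::setNames(c(0.6, 0, 0), classes),
               Q = stats::setNames(c(0, 0, 0), classes))
  expect_true(li_ka_ks(satd)$degenerate)
})

test_that("simulated substitution events reconcile with the counted differences at low divergence", {
  set.seed(32)
  ok_runs <- 0L
  for (s in 1:8) {
    pair <- simulate_codon_pair(400L, t = 0.01, kappa = 2, omega = 1,
                                seed = 320L + s)
    ev <- pair$events
    # only runs where no site was hit twice admit exact bookkeeping
    if (anyDuplicated(ev$site)) next
    ok_runs <- ok_runs + 1L
    cnt <- count_pairwise_substitutions(pair$seq_A, pair$seq_B)
    expect_equal(unname(sum(cnt$ts)), sum(ev$type == "transition"))
    expect_equal(unname(sum(cnt$tv)), sum(ev$type == "transversion"))
  }
  expect_gt(ok_runs, 2L)
})

test_that("the rate table applies the length and degeneracy filters and summarizes", {
  short <- simulate_codon_pair(90L, t = 0.2, seed = 33L,
                               gene_id = "short")
  long1 <- simulate_codon_pair(300L, t = 0.2, seed = 34L,
                               gene_id = "long1")
  long2 <- simulate_codon_pair(300L, t = 0.2, seed = 35L,
                               gene_id = "long2")
  res <- compute_rate_table(list(short, long1, long2), min_aa = 100L)
  expect_equal(res$n_excluded_length, 1L)
  expect_equal(sort(res$table$gene_id), c("long1", "long2"))
  expect_true(all(res$table$Ks >= 0) && all(res$table$Ka >= 0))

  # identical pairs: zero rates, zero means
  ident <- list(list(gene_id = "same", seq_A = long1$seq_A,
                     seq_B = long1$seq_A),
                list(gene_id = "same2", seq_A = long2$seq_A,
                     seq_B = long2$seq_A))
  res2 <- compute_rate_table(ident, min_aa = 100L)
  expect_equal(res2$summary$mean[res2$summary$statistic == "Ks"], 0)
  expect_equal(res2$summary$mean[res2$summary$statistic == "Ka"], 0)
})

test_that("planted rate parameters are recovered across simulated genes", {
  set.seed(36)
  alns <- lapply(1:15, function(i)
    simulate_codon_pair(800L, t = 0.18, kappa = 2, omega = 0.25,
                        seed = 360L + i,
                        gene_id = sprintf("g%02d", i)))
  res <- compute_rate_table(alns, min_aa = 100L)
  s <- res$summary
  kaks <- s$mean[s$statistic == "KaKs"]
  se <- s$stderr[s$statistic == "KaKs"]
  expect_lt(abs(kaks - 0.25), max(4 * se, 0.08))
  expect_gt(s$mean[s$statistic == "Ks"], 0.05)
})

test_that("UTR K2P distances are computed over non-gap columns only", {
  a <- "AACCGGTT--AA"
  b <- "AGCCGGTA--AA"   # one transition (A>G), one transversion (T>A)
  got <- utr_k2p(a, b)
  expect_equal(got$n_sites, 10L)
  expect_equal(got$P, 0.1)
  expect_equal(got$Q, 0.1)
  expect_equal(got$K, k2p_components(0.1, 0.1)$K)
})

test_that("the Kruskal-Wallis wrapper matches the hand-computed rank-sum formula", {
  g1 <- c(1.1, 2.3, 3.1, 4.0, 5.2)
  g2 <- c(2.0, 3.3, 4.1, 5.0, 6.2)
  g3 <- c(0.5, 1.3, 2.1, 3.0, 4.2)
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), each = 5L)
  got <- kruskal_wallis_rates(vals, grp)
  r <- rank(vals)
  N <- length(vals)
  H_hand <- 12 / (N * (N + 1)) *
    sum(tapply(r, grp, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  expect_equal(got$H, H_hand, tolerance = 1e-10)  # no ties here

  # identical groups: H ~ 0 (ties everywhere), p ~ 1
  same <- kruskal_wallis_rates(rep(c(1, 2, 3), 2L),
                               rep(c("a", "b"), each = 3L))
  expect_equal(same$H, 0, tolerance = 1e-10)
  expect_gt(same$p_value, 0.99)

  # strongly shifted groups separate
  set.seed(37)
  x <- rnorm(50); y <- rnorm(50) + 2 * IQR(x)
  shift <- kruskal_wallis_rates(c(x, y), rep(c("a", "b"), each = 50L))
  expect_lt(shift$p_value, 0.001)

  expect_error(kruskal_wallis_rates(1:5, rep("a", 5L)), ">= 2 groups")
  expect_error(kruskal_wallis_rates(1:5, c("a", "a", "a", "a", "b")),
               ">= 2 values")
})
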