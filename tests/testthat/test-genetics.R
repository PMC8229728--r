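# Compatibility genetics: predicate, enumeration, fractions, cohorts.

test_that("locus and mycelium constructors enforce their invariants", {
  expect_error(locus("X", character(0)), "at least one allele")
  expect_error(locus("X", c("A1", "A1")), "unique")
  expect_error(locus("X", c("A1", "A2"), c(0.6, 0.6)), "sum to 1")
  expect_error(locus("X", c("A1", "A2"), c(1.2, -0.2)), "non-negative")
  expect_equal(uniform_locus(3)$frequencies, rep(1 / 3, 3))

  expect_error(haplotype("A1"), "named")
  expect_error(mycelium(haplotype(X = "A1"), haplotype(X = "A1"),
                        haplotype(X = "A1"), haplotype(X = "A1")),
               "1-3 nuclei")
  expect_equal(myc("A1")$stage, "homokaryon")
  expect_equal(myc("A1", "A2")$stage, "heterokaryon")
  expect_equal(myc("A1", "A1", "A2")$stage, "trikaryon")
  expect_error(is_compatible(myc("A9"), myc("A1"), L2), "not defined")
})

test_that("allele profiles deduplicate and respect the locus", {
  expect_equal(allele_profile(myc("A1", "A2"), L2), c("A1", "A2"))
  expect_equal(allele_profile(myc("A1"), L2), "A1")
  expect_equal(allele_profile(myc("A1", "A1", "A2"), L3), c("A1", "A2"))
  Ly <- locus("Y", c("B1", "B2"))
  expect_error(allele_profile(myc("A1"), Ly), "does not cover")
})

test_that("compatibility is allele-set equality, incl. common-nucleus SI", {
  expect_true(is_compatible(myc("A1", "A2"), myc("A2", "A1"), L2))
  expect_false(is_compatible(myc("A1", "A1"), myc("A1", "A2"), L2))
  # common nucleus A1: {A1,A2} vs {A1,A3} still differ
  expect_false(is_compatible(myc("A1", "A2"), myc("A1", "A3"), L3))
  m <- myc("A2", "A3")
  expect_true(is_compatible(m, m, L3))
})

test_that("compatibility is an equivalence relation on random triples", {
  set.seed(42)
  loci <- list(uniform_locus(3, "X"), locus("Y", c("B1", "B2"), c(.7, .3)))
  rand_myc <- function() mycelium(
    haplotype(X = sample(paste0("A", 1:3), 1), Y = sample(c("B1", "B2"), 1)),
    haplotype(X = sample(paste0("A", 1:3), 1), Y = sample(c("B1", "B2"), 1)))
  for (i in 1:50) {
    a <- rand_myc(); b <- rand_myc(); c <- rand_myc()
    expect_true(is_compatible(a, a, loci))
    expect_equal(is_compatible(a, b, loci), is_compatible(b, a, loci))
    if (is_compatible(a, b, loci) && is_compatible(b, c, loci))
      expect_true(is_compatible(a, c, loci))
  }
})

test_that("genotype enumeration matches the canonical table layouts", {
  e2 <- enumerate_heterokaryons(L2)
  expect_length(e2$genotypes, 4)
  expect_equal(e2$labels, c("A1/A1", "A1/A2", "A2/A1", "A2/A2"))
  expect_equal(e2$probabilities, rep(0.25, 4))

  e3 <- enumerate_heterokaryons(L3)
  expect_length(e3$genotypes, 9)
  expect_equal(e3$probabilities, rep(1 / 9, 9))
  expect_equal(e3$labels[1:3], c("A1/A1", "A1/A2", "A1/A3"))

  e1 <- enumerate_heterokaryons(locus("X", "A1"))
  expect_length(e1$genotypes, 1)
  expect_equal(e1$probabilities, 1)

  # two loci: cardinality (prod k)^2, probabilities multiply
  e <- enumerate_heterokaryons(list(uniform_locus(2, "X"),
                                    locus("Y", c("B1", "B2"), c(.8, .2))))
  expect_length(e$genotypes, 16)
  expect_equal(sum(e$probabilities), 1)
  expect_equal(e$probabilities[1], (0.5 * 0.8)^2)
  expect_error(enumerate_heterokaryons(list()), "non-empty")
})

test_that("compatibility matrices reproduce the printed tables cell-for-cell", {
  m2 <- compatibility_matrix(L2)
  expect_identical(unname(m2$matrix), unname(table1_pattern()))
  expect_equal(m2$labels, rownames(table1_pattern()))
  expect_equal(sum(m2$matrix), 6)

  m3 <- compatibility_matrix(L3)
  expect_identical(unname(m3$matrix), unname(table2_pattern()))
  expect_equal(sum(m3$matrix), 15)

  m1 <- compatibility_matrix(locus("X", "A1"))
  expect_identical(unname(m1$matrix), matrix(TRUE, 1, 1))

  expect_true(isSymmetric(m3$matrix))
  expect_true(all(diag(m3$matrix)))
})

test_that("enumerated, analytic and oracle fractions agree", {
  expect_equal(compatible_fraction_enumerate(L2)$compatible_fraction, 0.375)
  expect_equal(compatible_fraction_analytic(L2)$compatible_fraction, 0.375)
  expect_equal(compatible_fraction_enumerate(L3)$compatible_fraction,
               15 / 81)
  # skewed frequencies, value frozen from the brute-force oracle
  skew <- locus("X", c("A1", "A2"), c(0.9, 0.1))
  expect_equal(oracle_compatible_fraction(skew), 0.6886)
  expect_equal(compatible_fraction_enumerate(skew)$compatible_fraction,
               0.6886)
  expect_equal(compatible_fraction_analytic(skew)$compatible_fraction,
               0.6886)
})

test_that("uniform closed form (2k-1)/k^3 holds for k = 1..6", {
  for (k in 1:6) {
    Lk <- uniform_locus(k)
    cf <- (2 * k - 1) / k^3
    expect_equal(compatible_fraction_analytic(Lk)$compatible_fraction, cf)
    expect_equal(compatible_fraction_enumerate(Lk)$compatible_fraction, cf,
                 tolerance = 1e-12)
  }
  expect_equal(compatible_fraction_analytic(uniform_locus(4))$
                 compatible_fraction, 7 / 64)
})

test_that("analytic equals enumeration to 1e-12 over random loci", {
  set.seed(11)
  for (rep in 1:12) {
    n_loci <- sample(1:3, 1)
    loci <- lapply(seq_len(n_loci), function(i) {
      k <- sample(1:5, 1)
      locus(paste0("L", i), paste0("A", seq_len(k)), random_frequencies(k))
    })
    a <- compatible_fraction_analytic(loci)$compatible_fraction
    e <- compatible_fraction_enumerate(loci,
                                       max_pairs = Inf)$compatible_fraction
    expect_equal(a, e, tolerance = 1e-12)
  }
})

test_that("multi-locus fractions are products of per-locus fractions", {
  la <- locus("X", c("A1", "A2", "A3"), c(.5, .3, .2))
  lb <- locus("Y", c("B1", "B2"), c(.6, .4))
  both <- compatible_fraction_analytic(list(la, lb))
  expect_equal(both$compatible_fraction,
               prod(both$per_locus))
  expect_equal(both$compatible_fraction,
               compatible_fraction_analytic(la)$compatible_fraction *
                 compatible_fraction_analytic(lb)$compatible_fraction)
  expect_equal(both$compatible_fraction,
               compatible_fraction_enumerate(list(la, lb))$
                 compatible_fraction)
  # two uniform triallelic loci: 97% incompatible
  two3 <- compatible_fraction_analytic(list(uniform_locus(3, "X"),
                                            uniform_locus(3, "Y")))
  expect_equal(two3$incompatible_fraction, 1 - (15 / 81)^2)
  expect_equal(format_percent(two3$incompatible_fraction, 0), "97")
})

test_that("compatible fraction decreases with more alleles and more loci", {
  fr <- vapply(1:6, function(k)
    compatible_fraction_analytic(uniform_locus(k))$compatible_fraction, 0)
  expect_true(all(diff(fr) < 0))
  cum <- vapply(1:3, function(nl)
    compatible_fraction_analytic(lapply(seq_len(nl), function(i)
      uniform_locus(3, paste0("L", i))))$compatible_fraction, 0)
  expect_true(all(diff(cum) < 0))
})

test_that("enumeration refuses oversized genotype-pair spaces", {
  big <- lapply(1:3, function(i) uniform_locus(6, paste0("L", i)))
  expect_error(compatible_fraction_enumerate(big), "cap")
  expect_error(compatibility_matrix(uniform_locus(40)), "cap")
})

test_that("Monte-Carlo estimates are calibrated and reproducible", {
  mc <- compatible_fraction_mc(L2, 1e5, seed = 1)
  expect_lt(abs(mc$estimate - 0.375), 4 * mc$se)
  expect_identical(mc$estimate,
                   compatible_fraction_mc(L2, 1e5, seed = 1)$estimate)
  mono <- compatible_fraction_mc(locus("X", "A1"), 100, seed = 2)
  expect_identical(mono$estimate, 1)
  expect_error(compatible_fraction_mc(L2, 0), "positive")
  # within 4 SE of the analytic value over many seeds
  target <- compatible_fraction_analytic(L3)$compatible_fraction
  for (s in 1:20) {
    mc <- compatible_fraction_mc(L3, 1e4, seed = s)
    expect_lt(abs(mc$estimate - target), 4 * mc$se)
  }
})

test_that("sibling cohorts reduce to half-frequency enumeration", {
  parent <- myc("A1", "A2")
  co <- sibling_cohort(parent, L2)
  expect_length(co$genotypes, 4)
  expect_equal(co$probabilities, rep(0.25, 4))
  expect_equal(sum(co$probabilities), 1)
  # every sibling allele is parental
  for (g in co$genotypes)
    expect_true(all(allele_profile(g, L2) %in% c("A1", "A2")))
  # 62.5% of sibling heterokaryons incompatible
  expect_equal(compatible_fraction_enumerate(co$loci)$incompatible_fraction,
               0.625)

  # homozygous parent: single genotype
  co1 <- sibling_cohort(myc("A1", "A1"), L2)
  expect_length(co1$genotypes, 1)
  expect_equal(co1$probabilities, 1)

  # two unlinked biallelic loci: 16 genotypes each 1/16
  loci2 <- list(uniform_locus(2, "X"), locus("Y", c("B1", "B2"), c(.9, .1)))
  par2 <- mycelium(haplotype(X = "A1", Y = "B1"),
                   haplotype(X = "A2", Y = "B2"))
  co2 <- sibling_cohort(par2, loci2)
  expect_length(co2$genotypes, 16)
  expect_equal(co2$probabilities, rep(1 / 16, 16))

  expect_error(sibling_cohort(myc("A1"), L2), "heterokaryon")
})

test_that("population surveys recover the analytic false-clonemate rate", {
  sv <- population_si_survey(L3, 200, seed = 5)
  n_pairs <- choose(200, 2)
  se <- sqrt(sv$expected_rate * (1 - sv$expected_rate) / n_pairs)
  # pairs are not independent (shared isolates), allow a generous band
  expect_lt(abs(sv$false_clonemate_rate - 15 / 81), 12 * se)
  expect_true(isSymmetric(sv$compat))
  expect_true(all(diag(sv$compat)))

  clone <- population_si_survey(L3, 10, clonal_groups = 1, seed = 1)
  expect_equal(clone$n_groups, 1)
  expect_true(is.na(clone$false_clonemate_rate))
  expect_true(all(clone$compat))

  two <- population_si_survey(list(uniform_locus(3, "X"),
                                   uniform_locus(3, "Y")), 100, seed = 9)
  expect_equal(two$expected_rate, (15 / 81)^2)
  expect_lt(abs(two$false_clonemate_rate - two$expected_rate), 0.03)
  expect_error(population_si_survey(L2, 1), "at least 2")
})

test_that("percent formatting rounds half away from zero", {
  expect_equal(format_percent(0.375), "37.5")
  expect_equal(format_percent(0.859375, 0), "86")
  expect_equal(format_percent(0.15 / 0.81, 1), "18.5")
  expect_equal(format_percent(0.625, 0), "63")  # 62.5 -> 63, half up
})
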