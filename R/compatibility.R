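# Compatibility combinatorics: who fuses stably with whom, and what fraction
# of heterokaryon pairs in a population are somatically incompatible.

#' Allele profile of a mycelium at a locus
#'
#' The deduplicated, unordered set of alleles the mycelium carries at one
#' locus. Somatic compatibility depends only on these per-locus sets, not on
#' how alleles are distributed over nuclei.
#'
#' @param m An [mycelium()].
#' @param locus An [locus()].
#' @return Sorted character vector of distinct allele labels.
#' @export
allele_profile <- function(m, locus) {
  if (!inherits(locus, "si_locus")) stop("expected an si_locus")
  al <- vapply(m$karyotype, function(h) {
    if (!locus$id %in% names(h))
      stop("mycelium does not cover locus '", locus$id, "'")
    h[[locus$id]]
  }, "")
  sort(unique(al))
}

#' Somatic compatibility predicate
#'
#' Two mycelia are somatically compatible when they carry identical unordered
#' allele sets at every incompatibility locus. Any difference leaves some
#' target molecules unmodified from the point of view of the partner's
#' reader, triggering nonself recognition. Note that two heterokaryons
#' sharing a common nucleus (A+B vs A+C) are incompatible, since their
#' allele sets differ.
#'
#' The predicate is an equivalence relation: reflexive, symmetric and (by
#' transitivity of set equality) transitive.
#'
#' @param m1,m2 [mycelium()] objects covering all loci.
#' @param loci An [locus()] or list of loci.
#' @return `TRUE` if compatible, `FALSE` otherwise.
#' @export
is_compatible <- function(m1, m2, loci) {
  loci <- as_loci(loci)
  validate_mycelium(m1, loci)
  validate_mycelium(m2, loci)
  for (L in loci) {
    if (!identical(allele_profile(m1, L), allele_profile(m2, L)))
      return(FALSE)
  }
  TRUE
}

# Internal: all haplotypes over the given loci in lexicographic order
# (first locus most significant, allele order as declared), with their
# population probabilities.
haplotype_space <- function(loci) {
  loci <- as_loci(loci)
  grid <- expand.grid(rev(lapply(loci, function(L) seq_along(L$alleles))),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(loci)), drop = FALSE]  # first locus major
  names(grid) <- vapply(loci, `[[`, "", "id")
  haps <- lapply(seq_len(nrow(grid)), function(i) {
    h <- vapply(seq_along(loci), function(j)
      loci[[j]]$alleles[grid[i, j]], "")
    names(h) <- names(grid)
    structure(h, class = "si_haplotype")
  })
  freq <- matrix(vapply(seq_along(loci), function(j)
    loci[[j]]$frequencies[grid[, j]], numeric(nrow(grid))),
    nrow = nrow(grid))
  prob <- apply(freq, 1, prod)
  labels <- vapply(haps, function(h) paste(unclass(h), collapse = ":"), "")
  list(haplotypes = haps, probabilities = prob, labels = labels)
}

#' Enumerate heterokaryon genotypes
#'
#' All ordered pairs of haplotypes (first nucleus x second nucleus), each
#' haplotype drawn independently per locus with the locus allele
#' frequencies. Genotypes are ordered row-major, second nucleus varying
#' fastest, matching the canonical compatibility-table layout
#' (A1/A1, A1/A2, ..., A2/A1, ...); A1/A2 and A2/A1 are listed separately
#' even though their allele sets coincide.
#'
#' @param loci An [locus()] or list of loci with valid frequencies.
#' @return A list of class `si_genotypes` with elements `genotypes` (list of
#'   [mycelium()] heterokaryons), `labels` (e.g. `"A1/A2"`), `probabilities`
#'   (summing to 1), and `loci`. Cardinality is `(prod k_i)^2` for `k_i`
#'   alleles at locus i.
#' @export
enumerate_heterokaryons <- function(loci) {
  loci <- as_loci(loci)
  hs <- haplotype_space(loci)
  H <- length(hs$haplotypes)
  i1 <- rep(seq_len(H), each = H)
  i2 <- rep(seq_len(H), times = H)
  genotypes <- mapply(function(a, b)
    mycelium(hs$haplotypes[[a]], hs$haplotypes[[b]]),
    i1, i2, SIMPLIFY = FALSE)
  structure(list(
    genotypes = genotypes,
    labels = paste(hs$labels[i1], hs$labels[i2], sep = "/"),
    probabilities = hs$probabilities[i1] * hs$probabilities[i2],
    loci = loci), class = "si_genotypes")
}

# Internal: canonical compatibility signature of a genotype -- the sorted
# allele set per locus, collapsed to one string. Two genotypes are
# compatible iff their signatures are equal.
genotype_signature <- function(m, loci) {
  paste(vapply(loci, function(L)
    paste(allele_profile(m, L), collapse = ","), ""), collapse = "|")
}

new_compat_result <- function(compatible_fraction, labels = NULL,
                              matrix = NULL, per_locus = NULL,
                              method = "analytic") {
  structure(list(labels = labels, matrix = matrix,
                 compatible_fraction = compatible_fraction,
                 incompatible_fraction = 1 - compatible_fraction,
                 per_locus = per_locus, method = method),
            class = "si_compat_result")
}

#' @export
print.si_compat_result <- function(x, ...) {
  cat("<si_compat_result> (", x$method, ")\n", sep = "")
  cat(sprintf("  compatible:   %.10g  (%s%%)\n", x$compatible_fraction,
              format_percent(x$compatible_fraction)))
  cat(sprintf("  incompatible: %.10g  (%s%%)\n", x$incompatible_fraction,
              format_percent(x$incompatible_fraction)))
  if (!is.null(x$matrix))
    cat("  matrix: ", nrow(x$matrix), "x", ncol(x$matrix), " genotypes\n",
        sep = "")
  invisible(x)
}

#' Format a fraction as a percentage, rounding half away from zero
#'
#' @param x Fraction in \[0,1\].
#' @param digits Decimal digits to keep.
#' @return Character scalar, e.g. `"37.5"`.
#' @export
format_percent <- function(x, digits = 1) {
  p <- x * 100
  scale <- 10^digits
  r <- sign(p) * floor(abs(p) * scale + 0.5) / scale
  format(r, nsmall = 0, trim = TRUE)
}

#' Compatible fraction by exhaustive enumeration
#'
#' Exact probability-weighted fraction of ordered heterokaryon genotype
#' pairs that are somatically compatible, summed over the full genotype
#' space. Genotypes are grouped by their per-locus allele-set signature, so
#' the exact sum over all `G^2` ordered pairs costs only `O(G)` work; the
#' answer is identical to the naive double sum. This routine is the
#' brute-force oracle for [compatible_fraction_analytic()].
#'
#' @param loci An [locus()] or list of loci.
#' @param max_pairs Refuse (with an error) when the number of ordered
#'   genotype pairs `G^2` exceeds this cap; [compatible_fraction_mc()] is
#'   the escape hatch for larger spaces.
#' @return An `si_compat_result` (no matrix).
#' @export
compatible_fraction_enumerate <- function(loci, max_pairs = 1e6) {
  loci <- as_loci(loci)
  enum <- enumerate_heterokaryons(loci)
  G <- length(enum$genotypes)
  if (as.numeric(G)^2 > max_pairs)
    stop("genotype pair space has ", format(as.numeric(G)^2, big.mark = ","),
         " ordered pairs, above the cap of ", format(max_pairs),
         "; raise 'max_pairs' or use compatible_fraction_mc()")
  sig <- vapply(enum$genotypes, genotype_signature, "", loci = loci)
  class_mass <- tapply(enum$probabilities, sig, sum)
  cf <- sum(class_mass^2)
  new_compat_result(cf, method = "enumerate")
}

# Per-locus analytic compatible fraction for frequency vector p:
# probability that two independent ordered-pair genotypes carry equal
# allele sets = sum_i p_i^4 + sum_{i<j} 4 p_i^2 p_j^2 = 2 (sum p^2)^2 - sum p^4.
locus_compatible_fraction <- function(p) {
  2 * sum(p^2)^2 - sum(p^4)
}

#' Compatible fraction, closed form
#'
#' Per locus with allele frequencies p, the probability that two
#' independently drawn heterokaryons carry equal allele sets is
#' \deqn{\sum_i p_i^4 + \sum_{i<j} 4 p_i^2 p_j^2,}
#' the first term covering homozygous (A_i/A_i) matches and the second the
#' two-by-two ways of forming the same heterozygous set. For a uniform
#' locus with k alleles this reduces to (2k-1)/k^3, i.e. 37.5% at k = 2 and
#' 15/81 (18.5%) at k = 3. Across independently segregating loci the
#' per-locus fractions multiply.
#'
#' @param loci An [locus()] or list of loci.
#' @return An `si_compat_result`; `per_locus` holds the per-locus
#'   compatible fractions.
#' @export
compatible_fraction_analytic <- function(loci) {
  loci <- as_loci(loci)
  per <- vapply(loci, function(L) locus_compatible_fraction(L$frequencies),
                0)
  new_compat_result(prod(per), per_locus = per, method = "analytic")
}

#' Compatible fraction by Monte Carlo sampling
#'
#' Draws `n_pairs` independent ordered heterokaryon genotype pairs (four
#' haplotypes per draw) and reports the mean compatibility indicator with
#' its binomial standard error. Reproducible for a fixed seed; the caller's
#' RNG state is left untouched.
#'
#' @param loci An [locus()] or list of loci.
#' @param n_pairs Number of sampled pairs (>= 1).
#' @param seed Integer seed.
#' @return List with `estimate`, `se`, `n_pairs`, `seed`.
#' @export
compatible_fraction_mc <- function(loci, n_pairs, seed = 1L) {
  loci <- as_loci(loci)
  n_pairs <- as.numeric(n_pairs)
  if (length(n_pairs) != 1L || is.na(n_pairs) || n_pairs < 1)
    stop("'n_pairs' must be a positive integer")
  compat <- with_seed(seed, {
    ok <- rep(TRUE, n_pairs)
    for (L in loci) {
      k <- length(L$alleles)
      draws <- matrix(sample.int(k, 4 * n_pairs, replace = TRUE,
                                 prob = L$frequencies), ncol = 4)
      # allele sets {a,b} and {c,d} equal iff sorted pairs coincide
      eq <- pmin(draws[, 1], draws[, 2]) == pmin(draws[, 3], draws[, 4]) &
        pmax(draws[, 1], draws[, 2]) == pmax(draws[, 3], draws[, 4])
      ok <- ok & eq
    }
    ok
  })
  est <- mean(compat)
  list(estimate = est, se = sqrt(est * (1 - est) / n_pairs),
       n_pairs = n_pairs, seed = seed)
}

#' Sibling heterokaryon cohort from one fruiting body
#'
#' Meiotic spores of a heterokaryotic parent take either parental allele at
#' each locus with probability 1/2, independently across (unlinked) loci.
#' Sibling heterokaryons are ordered pairs of two independent spores, so the
#' cohort reduces to [enumerate_heterokaryons()] over reduced loci carrying
#' only the parental alleles at frequency 1/2 each (or a single allele at
#' frequency 1 where the parent is homozygous).
#'
#' @param parent A heterokaryotic [mycelium()].
#' @param loci An [locus()] or list of loci covering the parent.
#' @return A list of class `si_sibling_cohort`: `parent`, `genotypes`,
#'   `labels`, `probabilities`, and `loci` (the reduced segregating loci,
#'   usable directly with the `compatible_fraction_*` functions).
#' @export
sibling_cohort <- function(parent, loci) {
  loci <- as_loci(loci)
  if (!inherits(parent, "si_mycelium") || parent$stage != "heterokaryon")
    stop("'parent' must be a heterokaryon")
  validate_mycelium(parent, loci)
  reduced <- lapply(loci, function(L) {
    par_alleles <- sort(unique(vapply(parent$karyotype,
                                      function(h) h[[L$id]], "")))
    locus(L$id, par_alleles)  # uniform 1/2 each, or 1 if homozygous
  })
  enum <- enumerate_heterokaryons(reduced)
  structure(list(parent = parent, genotypes = enum$genotypes,
                 labels = enum$labels, probabilities = enum$probabilities,
                 loci = as_loci(reduced)),
            class = "si_sibling_cohort")
}

#' Pairwise compatibility matrix over all genotypes
#'
#' The full labelled boolean compatibility table over the enumerated
#' genotype space, ordered as [enumerate_heterokaryons()] (first nucleus
#' major). For a single uniform biallelic or triallelic locus this
#' reproduces the canonical 4x4 and 9x9 tables cell for cell.
#'
#' @param loci An [locus()] or list of loci.
#' @param max_pairs Cap on matrix cells `G^2` (error above it).
#' @return An `si_compat_result` with `labels`, logical `matrix`
#'   (symmetric, all-true diagonal) and the exact compatible fraction.
#' @export
compatibility_matrix <- function(loci, max_pairs = 1e6) {
  loci <- as_loci(loci)
  enum <- enumerate_heterokaryons(loci)
  G <- length(enum$genotypes)
  if (as.numeric(G)^2 > max_pairs)
    stop("matrix would have ", format(as.numeric(G)^2, big.mark = ","),
         " cells, above the cap of ", format(max_pairs))
  sig <- vapply(enum$genotypes, genotype_signature, "", loci = loci)
  mat <- outer(sig, sig, `==`)
  dimnames(mat) <- list(enum$labels, enum$labels)
  cf <- sum((enum$probabilities %o% enum$probabilities)[mat])
  new_compat_result(cf, labels = enum$labels, matrix = mat,
                    method = "enumerate")
}

#' Pairwise somatic-incompatibility survey of a sampled population
#'
#' Emulates the standard mycological practice of delimiting individuals by
#' pairing isolates and scoring somatic incompatibility: a lack of SI
#' between isolates is conventionally read as clonality. Samples
#' heterokaryotic isolates from the locus frequencies (optionally planting
#' clonal replicates), computes the full pairwise compatibility matrix, the
#' number of compatibility groups, and the false-clonemate rate -- the
#' fraction of non-clonal pairs that are nevertheless compatible, whose
#' expectation is the analytic compatible fraction.
#'
#' @param loci An [locus()] or list of loci.
#' @param n_isolates Number of isolates to sample (>= 2).
#' @param clonal_groups Optional number of distinct genotypes to plant;
#'   isolates are assigned to them round-robin, so each group is a set of
#'   clonal replicates. `NULL` (default) samples every isolate
#'   independently.
#' @param seed Integer seed.
#' @return List with `compat` (n x n logical matrix), `clone_id` (planted
#'   group per isolate), `n_groups` (compatibility groups found),
#'   `false_clonemate_rate` (`NA` if there are no non-clonal pairs) and
#'   `expected_rate` (analytic compatible fraction).
#' @export
population_si_survey <- function(loci, n_isolates, clonal_groups = NULL,
                                 seed = 1L) {
  loci <- as_loci(loci)
  if (n_isolates < 2) stop("'n_isolates' must be at least 2")
  n_genotypes <- if (is.null(clonal_groups)) n_isolates
                 else as.integer(clonal_groups)
  if (n_genotypes < 1) stop("'clonal_groups' must be >= 1")
  # sample one signature per distinct genotype, directly per locus
  sigs <- with_seed(seed, {
    s <- rep("", n_genotypes)
    for (L in loci) {
      k <- length(L$alleles)
      a <- matrix(sample.int(k, 2 * n_genotypes, replace = TRUE,
                             prob = L$frequencies), ncol = 2)
      part <- paste(L$alleles[pmin(a[, 1], a[, 2])],
                    L$alleles[pmax(a[, 1], a[, 2])], sep = ",")
      part[a[, 1] == a[, 2]] <- L$alleles[a[a[, 1] == a[, 2], 1]]
      s <- paste(s, part, sep = "|")
    }
    s
  })
  clone_id <- rep(seq_len(n_genotypes), length.out = n_isolates)
  iso_sig <- sigs[clone_id]
  compat <- outer(iso_sig, iso_sig, `==`)
  dimnames(compat) <- list(paste0("iso", seq_len(n_isolates)),
                           paste0("iso", seq_len(n_isolates)))
  nonclonal <- outer(clone_id, clone_id, `!=`) & upper.tri(compat)
  fcr <- if (any(nonclonal)) mean(compat[nonclonal]) else NA_real_
  list(compat = compat, clone_id = clone_id,
       n_groups = length(unique(iso_sig)),
       false_clonemate_rate = fcr,
       expected_rate = compatible_fraction_analytic(loci)$compatible_fraction)
}

# Run code with a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
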