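# Shared fixtures: canonical loci, mycelium shorthand, the printed
# compatibility-table patterns, and an independent brute-force oracle.

L2 <- uniform_locus(2)
L3 <- uniform_locus(3)

# single-locus mycelium from allele labels, e.g. myc("A1", "A2")
myc <- function(..., locus_id = "X") {
  mycelium(lapply(list(...), function(a)
    haplotype(stats::setNames(a, locus_id))))
}

# The canonical 4x4 biallelic compatibility table: genotypes ordered
# A1/A1, A1/A2, A2/A1, A2/A2; C cells on the diagonal plus the
# A1/A2 <-> A2/A1 pair.
table1_pattern <- function() {
  labs <- c("A1/A1", "A1/A2", "A2/A1", "A2/A2")
  m <- diag(4) == 1
  m[2, 3] <- m[3, 2] <- TRUE
  dimnames(m) <- list(labs, labs)
  m
}

# The canonical 9x9 triallelic table: diagonal plus the three
# heterozygous-order pairs (A1/A2~A2/A1, A1/A3~A3/A1, A2/A3~A3/A2).
table2_pattern <- function() {
  labs <- as.vector(outer(paste0("A", 1:3), paste0("A", 1:3),
                          function(a, b) paste(a, b, sep = "/")))
  labs <- as.vector(t(matrix(labs, 3)))  # first nucleus major
  m <- diag(9) == 1
  for (pr in list(c(2, 4), c(3, 7), c(6, 8)))
    m[pr[1], pr[2]] <- m[pr[2], pr[1]] <- TRUE
  dimnames(m) <- list(labs, labs)
  m
}

# Independent brute-force oracle: naive double loop over all ordered
# genotype pairs, comparing unordered allele sets per locus directly.
# Deliberately avoids every package code path beyond the locus fields.
oracle_compatible_fraction <- function(loci) {
  if (inherits(loci, "si_locus")) loci <- list(loci)
  hap_grid <- expand.grid(lapply(loci, function(L) seq_along(L$alleles)))
  hp <- apply(hap_grid, 1, function(row)
    prod(mapply(function(L, i) L$frequencies[i], loci, row)))
  H <- nrow(hap_grid)
  geno <- expand.grid(h1 = seq_len(H), h2 = seq_len(H))
  gp <- hp[geno$h1] * hp[geno$h2]
  gset <- lapply(seq_len(nrow(geno)), function(g)
    lapply(seq_along(loci), function(l)
      sort(unique(c(hap_grid[geno$h1[g], l], hap_grid[geno$h2[g], l])))))
  total <- 0
  for (i in seq_along(gset))
    for (j in seq_along(gset))
      if (identical(gset[[i]], gset[[j]]))
        total <- total + gp[i] * gp[j]
  total
}

random_frequencies <- function(k) {
  f <- stats::runif(k)
  f / sum(f)
}
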