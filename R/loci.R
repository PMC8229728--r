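# Domain types for incompatibility genetics: loci, haplotypes, mycelia.

#' Define an incompatibility locus
#'
#' An incompatibility (het) locus carries a set of allele labels and their
#' population frequencies. A haploid nucleus carries exactly one allele per
#' locus; compatibility between mycelia is decided by comparing the unordered
#' sets of alleles they carry at every locus.
#'
#' @param id Short character label for the locus (e.g. `"X"`).
#' @param alleles Character vector of unique allele labels (e.g.
#'   `c("A1","A2","A3")`).
#' @param frequencies Numeric vector of population allele frequencies, one per
#'   allele, non-negative and summing to 1 (tolerance 1e-12). Defaults to
#'   uniform frequencies.
#' @return An object of class `si_locus`: a list with elements `id`,
#'   `alleles`, `frequencies`.
#' @examples
#' locus("X", c("A1", "A2"))                      # uniform biallelic
#' locus("X", c("A1", "A2"), c(0.9, 0.1))
#' @export
locus <- function(id, alleles, frequencies = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  alleles <- as.character(alleles)
  if (length(alleles) < 1L)
    stop("locus '", id, "': at least one allele is required")
  if (anyDuplicated(alleles))
    stop("locus '", id, "': allele labels must be unique")
  if (is.null(frequencies))
    frequencies <- rep(1 / length(alleles), length(alleles))
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) != length(alleles))
    stop("locus '", id, "': need one frequency per allele")
  if (any(frequencies < 0))
    stop("locus '", id, "': frequencies must be non-negative")
  if (abs(sum(frequencies) - 1) > 1e-12)
    stop("locus '", id, "': frequencies must sum to 1 (got ",
         format(sum(frequencies), digits = 15), ")")
  structure(list(id = id, alleles = alleles, frequencies = frequencies),
            class = "si_locus")
}

#' Uniform-frequency locus with k alleles
#'
#' Convenience constructor for a locus with alleles `A1..Ak` at equal
#' frequencies, the configuration used for the canonical compatibility
#' tables.
#'
#' @param k Number of alleles (>= 1).
#' @param id Locus label.
#' @return An `si_locus`.
#' @export
uniform_locus <- function(k, id = "X") {
  stopifnot(k >= 1)
  locus(id, paste0("A", seq_len(k)))
}

#' @export
print.si_locus <- function(x, ...) {
  cat("<si_locus> ", x$id, ": ", length(x$alleles), " allele(s)\n", sep = "")
  cat("  ", paste0(x$alleles, " (", format(x$frequencies, digits = 4), ")",
                   collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_loci <- function(loci) {
  if (inherits(loci, "si_locus")) loci <- list(loci)
  if (!is.list(loci) || !length(loci) ||
      !all(vapply(loci, inherits, TRUE, "si_locus")))
    stop("'loci' must be an si_locus or a non-empty list of si_locus objects")
  ids <- vapply(loci, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate locus ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(loci) <- ids
  loci
}

#' Construct a haplotype
#'
#' A haplotype is the allele content of one haploid nucleus: one allele per
#' locus, stored as a named character vector (names are locus ids).
#'
#' @param ... Named allele labels, e.g. `haplotype(X = "A1", Y = "B2")`, or a
#'   single named character vector.
#' @return A named character vector of class `si_haplotype`.
#' @export
haplotype <- function(...) {
  args <- list(...)
  h <- if (length(args) == 1L && is.character(args[[1L]]) &&
           length(args[[1L]]) >= 1L && !is.null(names(args[[1L]])))
    args[[1L]] else unlist(args)
  h <- stats::setNames(vapply(h, as.character, "", USE.NAMES = FALSE),
                       names(h))
  if (is.null(names(h)) || any(!nzchar(names(h))))
    stop("every allele in a haplotype must be named by its locus id")
  if (anyDuplicated(names(h)))
    stop("a haplotype carries exactly one allele per locus")
  structure(h, class = "si_haplotype")
}

validate_haplotype <- function(h, loci) {
  loci <- as_loci(loci)
  for (L in loci) {
    if (!L$id %in% names(h))
      stop("haplotype is missing an allele at locus '", L$id, "'")
    if (!h[[L$id]] %in% L$alleles)
      stop("allele '", h[[L$id]], "' is not defined for locus '", L$id, "'")
  }
  invisible(h)
}

#' Construct a mycelium from its karyotype
#'
#' A mycelium is characterised by the haploid nuclei its cells carry: one
#' nucleus (homokaryon), two (heterokaryon, the persistent basidiomycete
#' stage) or three (the transient trikaryotic fusion cell of a Buller
#' mating). The stage label is derived from the karyotype length.
#'
#' @param ... Haplotypes (named character vectors, see [haplotype()]), or a
#'   single list of haplotypes.
#' @return An object of class `si_mycelium` with elements `karyotype` (list
#'   of haplotypes) and `stage` (one of `"homokaryon"`, `"heterokaryon"`,
#'   `"trikaryon"`).
#' @examples
#' het <- mycelium(haplotype(X = "A1"), haplotype(X = "A2"))
#' het$stage  # "heterokaryon"
#' @export
mycelium <- function(...) {
  kar <- list(...)
  if (length(kar) == 1L && is.list(kar[[1L]]) &&
      !inherits(kar[[1L]], "si_haplotype"))
    kar <- kar[[1L]]
  kar <- lapply(kar, function(h) if (inherits(h, "si_haplotype")) h
                else haplotype(h))
  n <- length(kar)
  if (!n %in% 1:3)
    stop("a mycelium carries 1-3 nuclei; got ", n)
  structure(list(karyotype = kar,
                 stage = c("homokaryon", "heterokaryon", "trikaryon")[n]),
            class = "si_mycelium")
}

#' @rdname mycelium
#' @param h,h1,h2 Haplotypes.
#' @export
homokaryon <- function(h) mycelium(h)

#' @rdname mycelium
#' @export
heterokaryon <- function(h1, h2) mycelium(h1, h2)

#' @export
print.si_mycelium <- function(x, ...) {
  lab <- vapply(x$karyotype, function(h)
    paste(unclass(h), collapse = ":"), "")
  cat("<si_mycelium> ", x$stage, ": ", paste(lab, collapse = " + "),
      "\n", sep = "")
  invisible(x)
}

validate_mycelium <- function(m, loci) {
  if (!inherits(m, "si_mycelium")) stop("expected an si_mycelium")
  for (h in m$karyotype) validate_haplotype(h, loci)
  invisible(m)
}
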