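# File formats: locus definitions (JSON/TSV), genotype tables (TSV),
# compatibility matrices (TSV), trajectories (CSV + JSON sidecar).

#' Read locus definitions
#'
#' Accepts JSON (an array of objects with fields `id`, `alleles`,
#' `frequencies`; `frequencies` optional, defaulting to uniform) or TSV
#' (columns `locus`, `allele`, `frequency`), chosen by file extension.
#'
#' @param path File path.
#' @return List of [locus()] objects (named by id).
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  loci <- if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!length(raw)) stop("no loci found in ", path)
    lapply(raw, function(x)
      locus(x$id, unlist(x$alleles),
            if (!is.null(x$frequencies)) unlist(x$frequencies)))
  } else if (ext %in% c("tsv", "txt")) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("locus", "allele", "frequency")
    if (!all(need %in% names(tab)))
      stop("TSV locus file needs columns: ", paste(need, collapse = ", "))
    if (!nrow(tab)) stop("no loci found in ", path)
    lapply(split(tab, factor(tab$locus, levels = unique(tab$locus))),
           function(d) locus(d$locus[1], d$allele, d$frequency))
  } else stop("unsupported locus file extension: '", ext, "'")
  as_loci(unname(loci))
}

#' Write locus definitions
#'
#' Inverse of [read_loci()]; `write_loci()` then [read_loci()] restores
#' the loci exactly.
#'
#' @param loci An [locus()] or list of loci.
#' @param path Output path (`.json` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  loci <- as_loci(loci)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    payload <- lapply(unname(loci), function(L)
      list(id = L$id, alleles = L$alleles, frequencies = L$frequencies))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("tsv", "txt")) {
    tab <- do.call(rbind, lapply(loci, function(L)
      data.frame(locus = L$id, allele = L$alleles,
                 frequency = L$frequencies)))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else stop("unsupported locus file extension: '", ext, "'")
  invisible(path)
}

#' Read a genotype table
#'
#' TSV with columns `isolate_id`, `locus`, `nucleus_index` (1-3),
#' `allele`; one row per nucleus per locus per isolate.
#'
#' @param path File path.
#' @param loci Loci used to validate the alleles.
#' @return Named list of [mycelium()] objects.
#' @export
read_genotypes <- function(path, loci) {
  loci <- as_loci(loci)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("isolate_id", "locus", "nucleus_index", "allele")
  if (!all(need %in% names(tab)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(tab, factor(tab$isolate_id,
                                  levels = unique(tab$isolate_id))),
                function(d) {
    haps <- lapply(sort(unique(d$nucleus_index)), function(i) {
      di <- d[d$nucleus_index == i, ]
      h <- di$allele
      names(h) <- di$locus
      haplotype(h)
    })
    m <- mycelium(haps)
    validate_mycelium(m, loci)
    m
  })
  out
}

#' Write a genotype table
#'
#' @param mycelia Named list of [mycelium()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(mycelia, path) {
  if (is.null(names(mycelia)))
    names(mycelia) <- paste0("iso", seq_along(mycelia))
  rows <- lapply(names(mycelia), function(id) {
    m <- mycelia[[id]]
    do.call(rbind, lapply(seq_along(m$karyotype), function(i)
      data.frame(isolate_id = id, locus = names(m$karyotype[[i]]),
                 nucleus_index = i,
                 allele = unname(unclass(m$karyotype[[i]])))))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a compatibility matrix to TSV
#'
#' `style = "C"` mirrors the printed compatibility tables: genotype labels
#' on the first row and column, the letter `C` marking compatible cells
#' and blanks elsewhere. `style = "binary"` writes 0/1.
#'
#' @param result An `si_compat_result` from [compatibility_matrix()].
#' @param path Output path.
#' @param style `"C"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_compat_matrix <- function(result, path, style = c("C", "binary")) {
  style <- match.arg(style)
  if (is.null(result$matrix))
    stop("result carries no matrix; use compatibility_matrix()")
  m <- result$matrix
  cells <- if (style == "C") ifelse(m, "C", "") else ifelse(m, "1", "0")
  lines <- c(paste(c("", result$labels), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(result$labels[i], cells[i, ]), collapse = "\t"), ""))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV holds columns `t`, `R_<allele>`, `U_<allele>`, `S`, `alive`;
#' the sidecar `<path>.json` records death time, peak signal and the full
#' kinetic parameter set for reproducibility.
#'
#' @param traj An `rw_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj$states, path, row.names = FALSE)
  meta <- list(death_time = if (is.na(traj$death_time)) NULL
               else traj$death_time,
               peak_signal = traj$peak_signal,
               peak_time = traj$peak_time,
               present = as.list(traj$present),
               params = unclass(traj$params),
               package_version =
                 as.character(utils::packageVersion("basidioSI")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Generate deterministic synthetic input files
#'
#' Emits small plain-text fixtures for each input kind the package
#' consumes; a fixed seed gives byte-identical files.
#' \describe{
#'   \item{loci}{three random loci with 2-4 alleles plus the canonical
#'     uniform biallelic and triallelic configurations.}
#'   \item{population}{a genotype table of heterokaryotic isolates sampled
#'     from a uniform triallelic locus, with one planted clonal pair.}
#'   \item{scenario}{four JSON pairing descriptors covering the canonical
#'     matings: homokaryon x homokaryon, Buller, distinct heterokaryons,
#'     and common-nucleus heterokaryons.}
#'   \item{params}{the shipped default kinetic parameters as JSON.}
#' }
#'
#' @param kind One of `"loci"`, `"population"`, `"scenario"`, `"params"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Character vector of file paths, invisibly.
#' @export
generate_fixtures <- function(kind = c("loci", "population", "scenario",
                                       "params"),
                              dir = ".", seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(kind,
    loci = {
      random <- with_seed(seed, lapply(1:3, function(i) {
        k <- sample(2:4, 1)
        f <- stats::runif(k)
        locus(paste0("L", i), paste0("A", seq_len(k)), f / sum(f))
      }))
      p1 <- file.path(dir, "loci-random.json")
      write_loci(random, p1)
      p2 <- file.path(dir, "locus-biallelic.json")
      write_loci(uniform_locus(2), p2)
      p3 <- file.path(dir, "locus-triallelic.json")
      write_loci(uniform_locus(3), p3)
      c(p1, p2, p3)
    },
    population = {
      L <- uniform_locus(3)
      isolates <- with_seed(seed, lapply(1:12, function(i) {
        a <- sample(L$alleles, 2, replace = TRUE, prob = L$frequencies)
        mycelium(haplotype(X = a[1]), haplotype(X = a[2]))
      }))
      isolates[[12]] <- isolates[[1]]  # planted clonal replicate
      names(isolates) <- sprintf("iso%02d", 1:12)
      p <- file.path(dir, "population-genotypes.tsv")
      write_genotypes(isolates, p)
      pl <- file.path(dir, "population-locus.json")
      write_loci(L, pl)
      c(p, pl)
    },
    scenario = {
      specs <- list(
        `pairing-hom-hom` = list(
          partner1 = list("A"), partner2 = list("B"),
          mating_compatible = TRUE),
        `pairing-buller` = list(
          partner1 = list("A", "B"), partner2 = list("C"),
          mating_compatible = TRUE),
        `pairing-het-het` = list(
          partner1 = list("A", "B"), partner2 = list("C", "D"),
          mating_compatible = TRUE),
        `pairing-common-nucleus` = list(
          partner1 = list("A", "B"), partner2 = list("A", "C"),
          mating_compatible = TRUE))
      vapply(names(specs), function(nm) {
        sc <- c(specs[[nm]],
                list(locus = list(id = "X",
                                  alleles = c("A", "B", "C", "D")),
                     migration_rate = 1, n_fusion_cells = 10,
                     seed = as.integer(seed),
                     model = "ptm_plus_migration"))
        p <- file.path(dir, paste0(nm, ".json"))
        jsonlite::write_json(sc, p, auto_unbox = TRUE, digits = NA)
        p
      }, "")
    },
    params = {
      p <- file.path(dir, "rw-params-default.json")
      jsonlite::write_json(unclass(rw_params()), p, auto_unbox = TRUE,
                           digits = NA)
      p
    })
  invisible(unname(paths))
}

#' Read a pairing scenario descriptor
#'
#' JSON with fields `partner1`/`partner2` (arrays of per-nucleus alleles at
#' the single locus), `locus` (`id`, `alleles`), `mating_compatible`,
#' `migration_rate`, `n_fusion_cells`, `seed`, and optionally `model`.
#'
#' @param path JSON file path.
#' @return List with `scenario` (a [pairing_scenario()]) and `model`.
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  L <- locus(raw$locus$id, unlist(raw$locus$alleles))
  mk <- function(p) mycelium(lapply(p, function(a)
    haplotype(stats::setNames(as.character(a), L$id))))
  sc <- pairing_scenario(mk(raw$partner1), mk(raw$partner2), L,
                         mating_compatible = isTRUE(raw$mating_compatible),
                         migration_rate = raw$migration_rate %||% 1,
                         n_fusion_cells = raw$n_fusion_cells %||% 10,
                         death_time = raw$death_time %||% 1,
                         seed = raw$seed %||% 1L)
  list(scenario = sc, model = raw$model %||% "ptm_plus_migration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
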