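# Candidate nonself-recognition mechanisms, the canonical mating pairings of
# the basidiomycete lifecycle, and the race between nuclear migration and
# fusion-cell death.

#' Candidate recognition mechanisms
#'
#' The five rule sets adjudicated against the lifecycle observations:
#' \describe{
#'   \item{allelic_interaction}{direct interaction between products of two
#'     alleles of one gene; any cell whose cytoplasm carries two alleles at
#'     a locus dies -- including the standalone heterokaryon.}
#'   \item{nonallelic_interaction}{interaction between products of linked
#'     non-homologous genes; same fate table as the allelic case.}
#'   \item{differential_expression_het_only}{an allelic system expressed
#'     only in heterokaryotic cells: death requires a heterokaryotic
#'     participant and differing allele sets, so homokaryon fusions pass
#'     unrecognized.}
#'   \item{ptm_reader_writer}{the reader/writer post-translational
#'     modification system: death whenever the partners' allele sets
#'     differ (unmodified targets meet a foreign reader), with no escape
#'     route.}
#'   \item{ptm_plus_migration}{the same recognition rule, combined with
#'     nuclear migration that lets nuclei escape the dying fusion cell
#'     into a homokaryon partner.}
#' }
#'
#' @return Character vector of model names.
#' @export
recognition_models <- function() {
  c("allelic_interaction", "nonallelic_interaction",
    "differential_expression_het_only", "ptm_reader_writer",
    "ptm_plus_migration")
}

# Does this mechanism include migration escape from a dying fusion cell?
model_has_escape <- function(model) model == "ptm_plus_migration"

#' Fate of a fusion cell under a recognition mechanism
#'
#' Applies the mechanism's rule to the anastomosis of two mycelia and
#' returns whether the fused cell lives. A mycelium's internal viability is
#' scored by fusing it with itself: under a direct allelic interaction the
#' standalone heterokaryon is already non-viable.
#'
#' @param model One of [recognition_models()].
#' @param m1,m2 [mycelium()] partners.
#' @param loci An [locus()] or list of loci.
#' @return `"survives"` or `"dies"`.
#' @export
fusion_cell_fate <- function(model, m1, m2, loci) {
  model <- match.arg(model, recognition_models())
  loci <- as_loci(loci)
  validate_mycelium(m1, loci)
  validate_mycelium(m2, loci)
  compatible <- is_compatible(m1, m2, loci)
  dies <- switch(
    model,
    allelic_interaction = ,
    nonallelic_interaction = {
      # merged cytoplasm polymorphic at any locus => interaction => death
      any(vapply(loci, function(L)
        length(union(allele_profile(m1, L), allele_profile(m2, L))) >= 2,
        TRUE))
    },
    differential_expression_het_only = {
      # recognition is expressed only by heterokaryotic participants; a
      # heterokaryotic partner recognizes any differing fusion partner
      # (incl. the homokaryon in a Buller mating), but two homokaryons
      # fuse unrecognized
      (m1$stage != "homokaryon" || m2$stage != "homokaryon") && !compatible
    },
    ptm_reader_writer = ,
    ptm_plus_migration = !compatible
  )
  if (dies) "dies" else "survives"
}

#' Probability that at least one nucleus escapes before cell death
#'
#' Migration initiation is an exponential waiting time with rate `r` per
#' fusion cell, racing an absorbing death at time `t_d`; with `N`
#' independent anastomoses the overall escape probability is
#' \deqn{P = 1 - (1 - p)^N, \quad p = 1 - e^{-r t_d}.}
#' A single escaping nucleus suffices for a successful mating, so with
#' many fusion cells even a slow race is usually won.
#'
#' @param migration_rate Per-cell migration initiation rate `r` (1/time).
#' @param death_time Fusion-cell death time `t_d`; may be `Inf` (cell
#'   survives).
#' @param n_fusion_cells Number of independent fusion cells `N` (>= 1).
#' @return Probability in \[0, 1\].
#' @export
migration_escape_probability <- function(migration_rate, death_time,
                                         n_fusion_cells = 1) {
  r <- migration_rate
  if (r < 0 || death_time < 0 || n_fusion_cells < 1)
    stop("need migration_rate >= 0, death_time >= 0, n_fusion_cells >= 1")
  p <- if (r == 0) 0 else -expm1(-r * death_time)
  1 - (1 - p)^n_fusion_cells
}

#' Expected number of successful heterokaryotic tufts
#'
#' In species with little nuclear migration, homokaryon pairings produce
#' only a few localized heterokaryotic sectors ("tufts") along the
#' interaction zone. With `N` fusion cells each won with probability
#' `1 - exp(-r t_d)`, the expected count is `E = N (1 - exp(-r t_d))`,
#' approximately `N r t_d` in the low-migration regime -- small but
#' positive.
#'
#' @inheritParams migration_escape_probability
#' @return Expected number of successful sectors.
#' @export
tuft_count_expectation <- function(n_fusion_cells, migration_rate,
                                   death_time) {
  if (migration_rate < 0 || death_time < 0 || n_fusion_cells < 0)
    stop("inputs must be non-negative")
  p <- if (migration_rate == 0) 0 else -expm1(-migration_rate * death_time)
  n_fusion_cells * p
}

#' Describe a pairing of two mycelia
#'
#' @param partner1,partner2 [mycelium()] objects.
#' @param loci An [locus()] or list of loci.
#' @param mating_compatible Do the (unmodelled) mating-type loci permit
#'   nuclear migration between these partners? Treated as a background
#'   boolean: basidiomycete mating-type systems have enough alleles that
#'   unrelated partners are almost always sexually compatible.
#' @param migration_rate Per-fusion-cell nuclear migration initiation rate
#'   (1/time).
#' @param n_fusion_cells Number of independent anastomoses along the
#'   interaction zone.
#' @param death_time Fallback fusion-cell death time used when no kinetic
#'   parameters are supplied to [simulate_pairing()].
#' @param seed Integer seed (used to pick the migrating nucleus in Buller
#'   matings).
#' @return An object of class `si_scenario`.
#' @export
pairing_scenario <- function(partner1, partner2, loci,
                             mating_compatible = TRUE, migration_rate = 1,
                             n_fusion_cells = 10, death_time = 1,
                             seed = 1L) {
  loci <- as_loci(loci)
  validate_mycelium(partner1, loci)
  validate_mycelium(partner2, loci)
  if (n_fusion_cells < 1) stop("'n_fusion_cells' must be >= 1")
  if (migration_rate < 0) stop("'migration_rate' must be >= 0")
  structure(list(partner1 = partner1, partner2 = partner2, loci = loci,
                 mating_compatible = isTRUE(mating_compatible),
                 migration_rate = migration_rate,
                 n_fusion_cells = n_fusion_cells,
                 death_time = death_time, seed = seed),
            class = "si_scenario")
}

# Migration topology of a pairing: nuclei migrate only INTO homokaryons.
migration_mode <- function(m1, m2) {
  h1 <- m1$stage == "homokaryon"
  h2 <- m2$stage == "homokaryon"
  if (h1 && h2) "reciprocal"
  else if (xor(h1, h2)) "unidirectional"
  else "none"
}

# Death time of the fused cell from the kinetics, run per locus (each
# incompatibility locus is an independent reader/writer system); the cell
# dies when the first locus's signal crosses threshold.
dynamics_death_time <- function(m1, m2, loci, rw_params, t_max = 50,
                                dt = 0.01) {
  times <- vapply(loci, function(L) {
    k1 <- allele_profile(m1, L)
    k2 <- allele_profile(m2, L)
    if (identical(k1, k2)) return(Inf)
    traj <- simulate_heterokaryon_fusion(k1, k2, rw_params,
                                         t_max = t_max, dt = dt)
    if (is.na(traj$death_time)) Inf else traj$death_time
  }, 0)
  min(times)
}

#' Simulate one mating pairing
#'
#' Combines the mechanism's fusion-cell fate, the death kinetics and the
#' migration topology into the mating outcome. Nuclear migration occurs
#' only into homokaryon partners and only when mating types permit:
#' reciprocally between two homokaryons, unidirectionally into the
#' homokaryon in a Buller (heterokaryon x homokaryon) mating, and not at
#' all between two heterokaryons -- which is why heterokaryon pairings
#' showing somatic incompatibility produce no further matings.
#'
#' @param model One of [recognition_models()].
#' @param scenario A [pairing_scenario()].
#' @param rw_params Optional [rw_params()]; when supplied, the death time
#'   of a dying fusion cell comes from the reader/writer kinetics (run per
#'   locus), otherwise from `scenario$death_time`.
#' @param escape_threshold Minimum escape probability counted as a
#'   successful mating (default: any positive probability).
#' @return An object of class `si_outcome`: `fusion_cell_fate`,
#'   `death_time` (`NA` when the cell survives), `escape_probability`,
#'   `migration` (none/reciprocal/unidirectional), `mating_result` (one of
#'   `stable_common_mycelium`, `heterokaryon_formed`, `no_mating`,
#'   `SI_barrier`) and, for successful matings, `new_heterokaryons`.
#' @export
simulate_pairing <- function(model, scenario, rw_params = NULL,
                             escape_threshold = 0) {
  model <- match.arg(model, recognition_models())
  if (!inherits(scenario, "si_scenario"))
    stop("'scenario' must be a pairing_scenario()")
  m1 <- scenario$partner1
  m2 <- scenario$partner2
  loci <- scenario$loci
  fate <- fusion_cell_fate(model, m1, m2, loci)
  compatible <- is_compatible(m1, m2, loci)
  mode <- migration_mode(m1, m2)
  path <- mode != "none" && scenario$mating_compatible

  death_time <- NA_real_
  if (fate == "dies") {
    death_time <- if (!is.null(rw_params))
      dynamics_death_time(m1, m2, loci, rw_params)
    else scenario$death_time
  }

  escape <- if (fate == "survives") {
    if (path) 1 else 0
  } else if (path && model_has_escape(model)) {
    migration_escape_probability(scenario$migration_rate, death_time,
                                 scenario$n_fusion_cells)
  } else 0

  result <- if (fate == "survives" && compatible) {
    "stable_common_mycelium"
  } else if (fate == "survives") {
    if (path) "heterokaryon_formed" else "no_mating"
  } else if (path) {
    if (escape > escape_threshold) "heterokaryon_formed" else "no_mating"
  } else {
    "SI_barrier"
  }

  new_het <- NULL
  if (result == "heterokaryon_formed") {
    new_het <- with_seed(scenario$seed, make_new_heterokaryons(m1, m2))
  }
  structure(list(model = model, fusion_cell_fate = fate,
                 death_time = death_time, escape_probability = escape,
                 migration = if (path) mode else "none",
                 mating_result = result, new_heterokaryons = new_het),
            class = "si_outcome")
}

# Heterokaryons resulting from successful migration. hom x hom: reciprocal
# fertilization gives A+B on both sides. Buller: the migrating nucleus is
# chosen uniformly from the heterokaryon's haplotypes and fertilizes the
# homokaryon.
make_new_heterokaryons <- function(m1, m2) {
  h1 <- m1$stage == "homokaryon"
  h2 <- m2$stage == "homokaryon"
  if (h1 && h2) {
    het <- mycelium(m1$karyotype[[1]], m2$karyotype[[1]])
    list(het, het)
  } else {
    hom <- if (h1) m1 else m2
    het <- if (h1) m2 else m1
    donor <- het$karyotype[[sample.int(length(het$karyotype), 1)]]
    list(mycelium(hom$karyotype[[1]], donor))
  }
}

#' @export
print.si_outcome <- function(x, ...) {
  cat("<si_outcome> [", x$model, "]\n", sep = "")
  cat("  fusion cell:", x$fusion_cell_fate,
      if (!is.na(x$death_time)) sprintf("(death at t = %.4g)", x$death_time)
      else "", "\n")
  cat("  migration:", x$migration,
      sprintf("(escape P = %.4g)", x$escape_probability), "\n")
  cat("  mating result:", x$mating_result, "\n")
  invisible(x)
}

# Canonical single-locus setting used for adjudication: four alleles A-D.
canonical_setting <- function() {
  L <- locus("X", c("A", "B", "C", "D"))
  hap <- function(a) haplotype(X = a)
  list(locus = L,
       homA = homokaryon(hap("A")), homB = homokaryon(hap("B")),
       homC = homokaryon(hap("C")),
       hetAB = heterokaryon(hap("A"), hap("B")),
       hetAC = heterokaryon(hap("A"), hap("C")),
       hetCD = heterokaryon(hap("C"), hap("D")))
}

#' Adjudicate a recognition mechanism against the lifecycle observations
#'
#' Scores a mechanism against six observations that any account of
#' basidiomycete nonself recognition must reproduce:
#' \describe{
#'   \item{C1}{the standalone heterokaryon is viable (two haplotypes
#'     coexist long-term in one cytoplasm);}
#'   \item{C2}{genetically distinct heterokaryons show somatic
#'     incompatibility on pairing;}
#'   \item{C3}{matings between unrelated homokaryons succeed (a
#'     heterokaryon is formed, and is itself viable);}
#'   \item{C4}{Buller (heterokaryon x homokaryon) matings succeed;}
#'   \item{C5}{fusion-cell death is nevertheless observed in sexually
#'     compatible homokaryon matings;}
#'   \item{C6}{heterokaryon pairs sharing a common nucleus (A+B vs A+C)
#'     still show somatic incompatibility.}
#' }
#' Only the reader/writer mechanism combined with nuclear migration
#' satisfies all six.
#'
#' @param model One of [recognition_models()].
#' @param rw_params Optional [rw_params()] forwarded to
#'   [simulate_pairing()] for kinetic death times.
#' @param migration_rate,n_fusion_cells Scenario settings for the
#'   migration race.
#' @return One-row data.frame: `model`, logical `C1`..`C6`, `consistent`.
#' @export
adjudicate <- function(model, rw_params = NULL, migration_rate = 1,
                       n_fusion_cells = 10) {
  model <- match.arg(model, recognition_models())
  s <- canonical_setting()
  L <- s$locus
  scen <- function(a, b) pairing_scenario(a, b, L,
                                          migration_rate = migration_rate,
                                          n_fusion_cells = n_fusion_cells)
  het_viable <- fusion_cell_fate(model, s$hetAB, s$hetAB, L) == "survives"
  c1 <- het_viable
  c2 <- simulate_pairing(model, scen(s$hetAB, s$hetCD),
                         rw_params)$mating_result == "SI_barrier"
  c3 <- simulate_pairing(model, scen(s$homA, s$homB),
                         rw_params)$mating_result == "heterokaryon_formed" &&
    het_viable
  c4 <- simulate_pairing(model, scen(s$hetAB, s$homC),
                         rw_params)$mating_result == "heterokaryon_formed" &&
    het_viable
  c5 <- fusion_cell_fate(model, s$homA, s$homB, L) == "dies"
  c6 <- simulate_pairing(model, scen(s$hetAB, s$hetAC),
                         rw_params)$mating_result == "SI_barrier"
  data.frame(model = model, C1 = c1, C2 = c2, C3 = c3, C4 = c4, C5 = c5,
             C6 = c6,
             consistent = c1 && c2 && c3 && c4 && c5 && c6,
             stringsAsFactors = FALSE)
}

#' Adjudicate every candidate mechanism
#'
#' @inheritParams adjudicate
#' @return Data.frame with one row per mechanism (see [adjudicate()]).
#' @export
adjudicate_all <- function(rw_params = NULL, migration_rate = 1,
                           n_fusion_cells = 10) {
  do.call(rbind, lapply(recognition_models(), adjudicate,
                        rw_params = rw_params,
                        migration_rate = migration_rate,
                        n_fusion_cells = n_fusion_cells))
}
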