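## Generative simulator of the wet-lab side of the assay: heterogeneous EV
## populations (tumor/normal mixture), stochastic conjugate labeling, and the
## bead capture / wash / elution losses that precede qPCR. Every downstream
## stage is tested against the ground truth these functions carry along.

#' Parameters of a simulated EV population
#'
#' @slot n_ev number of vesicles to simulate.
#' @slot tumor_fraction probability a vesicle is tumor-derived.
#' @slot antigen_mean mean surface-antigen copies per tumor EV.
#' @slot antigen_dispersion negative-binomial size parameter (smaller = more
#'   over-dispersed); surface-marker copy numbers on vesicles are
#'   over-dispersed, so a negative binomial rather than a Poisson.
#' @slot nonspecific_rate mean spurious (antigen-independent) conjugates per
#'   EV.
#' @seealso [evPopulationParams()], [simulatePopulation()]
#' @export
setClass("EVPopulationParams",
         representation(n_ev = "integer", tumor_fraction = "numeric",
                        antigen_mean = "numeric",
                        antigen_dispersion = "numeric",
                        nonspecific_rate = "numeric"))

setValidity("EVPopulationParams", function(object) {
  msgs <- character()
  if (object@n_ev < 0) msgs <- c(msgs, "n_ev must be >= 0")
  if (object@tumor_fraction < 0 || object@tumor_fraction > 1)
    msgs <- c(msgs, "tumor_fraction must be in [0, 1]")
  if (object@antigen_mean < 0) msgs <- c(msgs, "antigen_mean must be >= 0")
  if (object@antigen_dispersion <= 0)
    msgs <- c(msgs, "antigen_dispersion must be > 0")
  if (object@nonspecific_rate < 0)
    msgs <- c(msgs, "nonspecific_rate must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct EV population parameters
#'
#' Defaults describe a cultured-cell EV preparation enriched for an
#' EpCAM-positive tumor line: most vesicles tumor-derived, a few tens of
#' antigen copies per tumor vesicle with substantial over-dispersion, and a
#' small antigen-independent background.
#'
#' @param n_ev vesicle count (default 1e4).
#' @param tumor_fraction fraction of tumor-derived vesicles (default 0.8).
#' @param antigen_mean mean antigen copies per tumor EV (default 50).
#' @param antigen_dispersion negative-binomial size (default 5).
#' @param nonspecific_rate mean spurious conjugates per EV (default 0.05).
#' @return an [EVPopulationParams].
#' @export
evPopulationParams <- function(n_ev = 10000, tumor_fraction = 0.8,
                               antigen_mean = 50, antigen_dispersion = 5,
                               nonspecific_rate = 0.05) {
  new("EVPopulationParams", n_ev = as.integer(n_ev),
      tumor_fraction = tumor_fraction, antigen_mean = antigen_mean,
      antigen_dispersion = antigen_dispersion,
      nonspecific_rate = nonspecific_rate)
}

setMethod("show", "EVPopulationParams", function(object) {
  cat(sprintf(paste0(
    "EVPopulationParams: %d EVs, tumor fraction %.3g,\n",
    "  antigen ~ NegBinom(mean = %.3g, size = %.3g) on tumor EVs,\n",
    "  nonspecific conjugate rate %.3g per EV\n"),
    object@n_ev, object@tumor_fraction, object@antigen_mean,
    object@antigen_dispersion, object@nonspecific_rate))
})

#' Simulate an EV population
#'
#' Each vesicle is tumor-derived with probability `tumor_fraction`; tumor
#' vesicles draw surface-antigen copy numbers from a negative binomial with
#' the given mean and dispersion, normal vesicles carry none.
#'
#' @param params an [EVPopulationParams].
#' @param seed integer seed for reproducibility (NULL = use current RNG
#'   stream).
#' @return a [S4Vectors::DataFrame] with one row per EV and columns
#'   `is_tumor` (logical), `antigen_copies` (integer).
#' @examples
#' pop <- simulatePopulation(evPopulationParams(n_ev = 100), seed = 1)
#' table(pop$is_tumor)
#' @export
simulatePopulation <- function(params, seed = NULL) {
  stopifnot(is(params, "EVPopulationParams"))
  .withSeed(seed, {
    n <- params@n_ev
    is_tumor <- rbinom(n, 1L, params@tumor_fraction) == 1L
    copies <- integer(n)
    nt <- sum(is_tumor)
    if (nt > 0 && params@antigen_mean > 0)
      copies[is_tumor] <- rnbinom(nt, size = params@antigen_dispersion,
                                  mu = params@antigen_mean)
    S4Vectors::DataFrame(is_tumor = is_tumor, antigen_copies = copies)
  })
}

#' Label an EV population with antibody-DNA conjugates
#'
#' Each antigen copy independently recruits a conjugate with probability
#' `p_bind` (binomial thinning); with `dual_label = TRUE` bound conjugates
#' are split evenly and independently between the two conjugate types used
#' for proximity ligation, otherwise all are type 1. On top of specific
#' binding, each EV picks up Poisson(`nonspecific_rate`) spurious conjugates
#' (assigned to a type the same way). Each bound conjugate contributes
#' `dna_per_conjugate` reporter strands.
#'
#' @param pop population from [simulatePopulation()].
#' @param p_bind per-antigen-copy conjugate binding probability.
#' @param dual_label split conjugates between types 1 and 2 (for PLA)?
#' @param nonspecific_rate mean spurious conjugates per EV.
#' @param dna_per_conjugate reporter strands per conjugate; the nominal
#'   conjugate design carries 3 (one antibody + three DNAs on the tetramer).
#' @param seed integer seed.
#' @return a [S4Vectors::DataFrame] with columns `is_tumor`,
#'   `antigen_copies`, `bound_1`, `bound_2`, `dna_strands`.
#' @examples
#' pop <- simulatePopulation(evPopulationParams(n_ev = 100), seed = 1)
#' lab <- labelPopulation(pop, p_bind = 0.3, seed = 2)
#' head(lab)
#' @export
labelPopulation <- function(pop, p_bind, dual_label = FALSE,
                            nonspecific_rate = 0, dna_per_conjugate = 3,
                            seed = NULL) {
  .assertProb(p_bind, "p_bind")
  .assertNonneg(nonspecific_rate, "nonspecific_rate")
  .assertNonneg(dna_per_conjugate, "dna_per_conjugate")
  .withSeed(seed, {
    n <- nrow(pop)
    specific <- rbinom(n, pop$antigen_copies, p_bind)
    spurious <- if (nonspecific_rate > 0) rpois(n, nonspecific_rate)
                else integer(n)
    total <- specific + spurious
    if (dual_label) {
      bound_1 <- rbinom(n, total, 0.5)
      bound_2 <- total - bound_1
    } else {
      bound_1 <- total
      bound_2 <- integer(n)
    }
    S4Vectors::DataFrame(is_tumor = pop$is_tumor,
                         antigen_copies = pop$antigen_copies,
                         bound_1 = bound_1, bound_2 = bound_2,
                         dna_strands = dna_per_conjugate * total)
  })
}

#' Eluted assay sample with its ground truth
#'
#' The material that reaches the qPCR step: labeled EVs surviving bead
#' capture and washing, the elution volume, and the true reporter-DNA
#' concentration in the eluate (the quantity the downstream pipeline is
#' asked to recover).
#'
#' @slot ev [S4Vectors::DataFrame] of surviving labeled EVs.
#' @slot eluate_volume_ul elution volume in uL.
#' @slot dna_conc_true_nM true reporter-DNA concentration in the eluate, nM.
#' @seealso [captureWashElute()]
#' @export
setClass("AssaySample",
         representation(ev = "DataFrame", eluate_volume_ul = "numeric",
                        dna_conc_true_nM = "numeric"))

setValidity("AssaySample", function(object) {
  if (object@eluate_volume_ul <= 0) return("eluate volume must be > 0")
  expected <- .strandsToNanomolar(sum(object@ev$dna_strands),
                                  object@eluate_volume_ul)
  tol <- 1e-9 * max(1, expected)
  if (abs(object@dna_conc_true_nM - expected) > tol)
    return("dna_conc_true_nM inconsistent with strand counts and volume")
  TRUE
})

#' nM concentration of `strands` molecules in `volume_ul` microliters.
#' @noRd
.strandsToNanomolar <- function(strands, volume_ul) {
  # strands / N_A = mol; / (volume_ul * 1e-6 L) = mol/L; * 1e9 = nM
  strands / .AVOGADRO / (volume_ul * 1e-6) * 1e9
}

setMethod("show", "AssaySample", function(object) {
  cat(sprintf(paste0("AssaySample: %d EVs in %.4g uL eluate, ",
                     "true reporter DNA %.4g nM\n"),
              nrow(object@ev), object@eluate_volume_ul,
              object@dna_conc_true_nM))
})

#' @describeIn captureWashElute surviving labeled EVs of a sample.
#' @param sample an `AssaySample`.
#' @export
sampleEVs <- function(sample) sample@ev

#' @describeIn captureWashElute true reporter-DNA concentration (nM).
#' @export
trueDnaConc <- function(sample) sample@dna_conc_true_nM

#' Bead capture, washing and elution
#'
#' Each labeled EV independently survives the capture-and-wash sequence with
#' probability `capture_eff * wash_retention` (independent thinning); the
#' survivors' reporter strands define the true DNA concentration in the
#' eluate.
#'
#' @param labeled output of [labelPopulation()].
#' @param capture_eff probability a vesicle is captured on the beads.
#' @param wash_retention probability a captured vesicle survives washing.
#' @param eluate_volume_ul elution volume in uL (> 0).
#' @param seed integer seed.
#' @return an [AssaySample].
#' @examples
#' pop <- simulatePopulation(evPopulationParams(n_ev = 500), seed = 1)
#' lab <- labelPopulation(pop, p_bind = 0.3, seed = 2)
#' captureWashElute(lab, 0.9, 0.95, eluate_volume_ul = 50, seed = 3)
#' @export
captureWashElute <- function(labeled, capture_eff, wash_retention,
                             eluate_volume_ul, seed = NULL) {
  .assertProb(capture_eff, "capture_eff")
  .assertProb(wash_retention, "wash_retention")
  if (!is.numeric(eluate_volume_ul) || length(eluate_volume_ul) != 1L ||
      eluate_volume_ul <= 0)
    stop("'eluate_volume_ul' must be a single positive volume", call. = FALSE)
  .withSeed(seed, {
    p <- capture_eff * wash_retention
    keep <- rbinom(nrow(labeled), 1L, p) == 1L
    surv <- labeled[keep, , drop = FALSE]
    new("AssaySample", ev = surv, eluate_volume_ul = eluate_volume_ul,
        dna_conc_true_nM = .strandsToNanomolar(sum(surv$dna_strands),
                                               eluate_volume_ul))
  })
}
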