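## Inverse quantification chain: measured reporter-DNA concentration ->
## antibody concentration (divide by the strands-per-conjugate ratio) ->
## antigen mass concentration (multiply by molecular weight; nM x kDa =
## ng/mL), with exact linear propagation of the SD, plus the digital Poisson
## partition estimator of particle concentration. All internal arithmetic is
## full precision; rounding to the reporting convention (2 decimals for nM,
## 3 significant figures for ng/mL) happens only in show().

#' Quantification result
#'
#' DNA, antibody and antigen-mass concentrations with propagated SDs, plus
#' the conversion constants used.
#'
#' @slot dna_conc,dna_sd reporter-DNA concentration in the eluate, nM.
#' @slot ab_conc,ab_sd antibody (= antigen) concentration, nM.
#' @slot antigen_mass,antigen_mass_sd antigen mass concentration, ng/mL.
#' @slot mw antigen molecular weight used, kDa.
#' @slot dna_per_ab reporter strands per antibody used.
#' @slot particle_conc particles/mL from digital counting (`NA` unless
#'   computed).
#' @slot n_wells_used,n_censored determined / censored well counts behind
#'   the estimate.
#' @seealso [quantifyRun()]
#' @export
setClass("QuantResult",
         representation(dna_conc = "numeric", dna_sd = "numeric",
                        ab_conc = "numeric", ab_sd = "numeric",
                        antigen_mass = "numeric", antigen_mass_sd = "numeric",
                        mw = "numeric", dna_per_ab = "numeric",
                        particle_conc = "numeric",
                        n_wells_used = "integer", n_censored = "integer"))

setValidity("QuantResult", function(object) {
  msgs <- character()
  vals <- c(object@dna_conc, object@dna_sd, object@ab_conc, object@ab_sd,
            object@antigen_mass, object@antigen_mass_sd)
  if (any(vals < 0)) msgs <- c(msgs, "concentrations and SDs must be >= 0")
  tol <- 1e-9
  if (abs(object@ab_conc - object@dna_conc / object@dna_per_ab) >
      tol * max(1, object@ab_conc))
    msgs <- c(msgs, "ab_conc must equal dna_conc / dna_per_ab")
  if (abs(object@antigen_mass - object@ab_conc * object@mw) >
      tol * max(1, object@antigen_mass))
    msgs <- c(msgs, "antigen_mass must equal ab_conc * mw")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult\n")
  cat(sprintf("  reporter DNA: %.2f +/- %.2f nM\n",
              object@dna_conc, object@dna_sd))
  cat(sprintf("  antibody/antigen: %.2f +/- %.2f nM  (DNA:antibody = %g:1)\n",
              object@ab_conc, object@ab_sd, object@dna_per_ab))
  cat(sprintf("  antigen mass: %s +/- %s ng/mL  (MW %.4g kDa)\n",
              signif(object@antigen_mass, 3), signif(object@antigen_mass_sd, 3),
              object@mw))
  if (!is.na(object@particle_conc))
    cat(sprintf("  particle concentration: %.4g /mL\n", object@particle_conc))
  if (object@n_wells_used > 0 || object@n_censored > 0)
    cat(sprintf("  wells: %d used, %d undetermined\n",
                object@n_wells_used, object@n_censored))
})

#' @describeIn quantifyRun antigen mass concentration (ng/mL), full
#'   precision.
#' @param result a `QuantResult`.
#' @export
antigenMass <- function(result) result@antigen_mass

#' @describeIn quantifyRun antibody concentration (nM), full precision.
#' @export
antibodyConc <- function(result) result@ab_conc

#' Convert reporter-DNA to antibody concentration
#'
#' Each conjugate carries `dna_per_ab` reporter strands per antibody
#' (nominally 3), so the antibody concentration is the measured DNA
#' concentration divided by that ratio. Full precision is retained; rounding
#' is a display concern.
#'
#' @param dna_conc reporter-DNA concentration, nM (>= 0).
#' @param dna_per_ab strands per antibody (> 0, default 3).
#' @return antibody concentration, nM.
#' @examples
#' dnaToAntibody(2.41)   # 0.8033...
#' @export
dnaToAntibody <- function(dna_conc, dna_per_ab = 3) {
  if (any(dna_conc < 0)) stop("'dna_conc' must be >= 0", call. = FALSE)
  if (!is.numeric(dna_per_ab) || dna_per_ab <= 0)
    stop("'dna_per_ab' must be > 0", call. = FALSE)
  dna_conc / dna_per_ab
}

#' Convert antibody concentration to antigen mass concentration
#'
#' One antibody marks one antigen, so the molar antigen concentration equals
#' the antibody concentration, and mass concentration follows from the
#' dimensional identity 1 nmol/L x 1 kg/mol = 1 ng/mL.
#'
#' @param ab_conc antibody concentration, nM (>= 0).
#' @param mw antigen molecular weight, kDa (>= 0). The packaged default for
#'   EpCAM is 29.1 kDa (the value used in the assay's own conversion; the
#'   ~40 kDa figure quoted for the glycosylated protein is a documented
#'   inconsistency and can be supplied instead).
#' @return mass concentration, ng/mL.
#' @examples
#' antibodyToMass(2.41 / 3, 29.1)   # 23.377 -> prints as 23.4
#' @export
antibodyToMass <- function(ab_conc, mw = 29.1) {
  if (any(ab_conc < 0) || mw < 0)
    stop("'ab_conc' and 'mw' must be >= 0", call. = FALSE)
  ab_conc * mw
}

#' Propagate an SD through multiplicative factors
#'
#' Exact for linear maps: the SD of `c * X` is `|c| * sd(X)`.
#'
#' @param sd standard deviation (>= 0).
#' @param factors multiplicative factors applied to the quantity.
#' @return sd in the target units.
#' @examples
#' propagateSd(0.48, 1 / 3)          # 0.16
#' propagateSd(0.16, 29.1)           # 4.656
#' @export
propagateSd <- function(sd, factors) {
  if (any(sd < 0)) stop("'sd' must be >= 0", call. = FALSE)
  sd * prod(abs(factors))
}

#' Digital Poisson particle concentration from a partition count
#'
#' Standard single-molecule partition correction: with particles distributed
#' over partitions at mean occupancy lambda, the fraction of negative
#' partitions is e^(-lambda), so lambda = -ln(1 - n_pos/n_total) and the
#' concentration is lambda per partition volume.
#'
#' @param n_pos positive partitions (0 <= n_pos <= n_total).
#' @param n_total total partitions (> 0).
#' @param partition_volume_ul partition volume, uL (> 0).
#' @return particles per mL.
#' @examples
#' particlesFromPositiveFraction(5000, 10000, 1e-3)  # ln(2) per nL -> per mL
#' @export
particlesFromPositiveFraction <- function(n_pos, n_total,
                                          partition_volume_ul) {
  if (n_total <= 0 || n_pos < 0 || n_pos > n_total)
    stop("need 0 <= n_pos <= n_total with n_total > 0", call. = FALSE)
  if (partition_volume_ul <= 0)
    stop("'partition_volume_ul' must be > 0", call. = FALSE)
  if (n_pos == n_total)
    stop("all partitions positive: the estimate is infinite; ",
         "dilute the sample and repeat", call. = FALSE)
  lam <- -log1p(-n_pos / n_total)
  lam / (partition_volume_ul * 1e-3)   # uL -> mL
}

#' Quantify a qPCR run through the full conversion chain
#'
#' Inverts the determined target wells through the standard curve, anchors X
#' to absolute concentration via `conc_at_x0`, and chains the per-well
#' concentrations through [dnaToAntibody()], [antibodyToMass()] and
#' [propagateSd()]. Undetermined wells are excluded and counted, never
#' imputed. The chain is linear, so doubling the input DNA concentration
#' doubles every downstream estimate exactly.
#'
#' @param plate plate `data.frame` ([qpcrPlate()]/[readPlate()]).
#' @param curve a [StandardCurve].
#' @param target which `target` rows to quantify (default all non-standard
#'   wells, i.e. those with `NA` `dilution_x`).
#' @param conc_at_x0 reporter-DNA concentration (nM) at X = 0, the anchor
#'   tying the dilution scale to absolute concentration.
#' @param dna_per_ab reporter strands per antibody (default 3).
#' @param mw antigen molecular weight, kDa (default 29.1 for EpCAM).
#' @param digital optional list `list(n_pos =, n_total =,
#'   partition_volume_ul =)` to add a digital particle count.
#' @return a [QuantResult].
#' @examples
#' curve <- standardCurve(x_range = c(0, 4))
#' ct <- simulateCt(rep(concToX(2.41, 10), 3), curve, noise_sd = 0)
#' quantifyRun(qpcrPlate("EpCAM", ct), curve, conc_at_x0 = 10)
#' @export
quantifyRun <- function(plate, curve, target = NULL, conc_at_x0 = 10,
                        dna_per_ab = 3, mw = 29.1, digital = NULL) {
  stopifnot(is(curve, "StandardCurve"))
  rows <- if (is.null(target)) is.na(plate$dilution_x)
          else plate$target %in% target
  wells <- plate[rows, , drop = FALSE]
  if (nrow(wells) == 0L)
    stop("no target wells on the plate", call. = FALSE)
  det <- !is.na(wells$ct)
  n_censored <- sum(!det)
  if (!any(det))
    stop("quantification failed: all ", nrow(wells),
         " target wells are undetermined", call. = FALSE)
  x <- invertCt(wells$ct[det], curve, warn_extrapolation = FALSE)
  conc <- xToConc(x, conc_at_x0)
  dna_conc <- mean(conc)
  dna_sd <- if (sum(det) > 1L) stats::sd(conc) else 0
  ab_conc <- dnaToAntibody(dna_conc, dna_per_ab)
  ab_sd <- propagateSd(dna_sd, 1 / dna_per_ab)
  mass <- antibodyToMass(ab_conc, mw)
  mass_sd <- propagateSd(ab_sd, mw)
  pc <- if (!is.null(digital))
    particlesFromPositiveFraction(digital$n_pos, digital$n_total,
                                  digital$partition_volume_ul)
  else NA_real_
  new("QuantResult", dna_conc = dna_conc, dna_sd = dna_sd,
      ab_conc = ab_conc, ab_sd = ab_sd, antigen_mass = mass,
      antigen_mass_sd = mass_sd, mw = mw, dna_per_ab = dna_per_ab,
      particle_conc = pc, n_wells_used = sum(det),
      n_censored = as.integer(n_censored))
}

#' Assemble a QuantResult from a measured concentration
#'
#' Convenience wrapper for the conversion chain when the reporter-DNA
#' concentration and its SD are already in hand (for example from an
#' external instrument report) rather than from a plate of Ct values.
#'
#' @param dna_conc,dna_sd measured reporter-DNA concentration and SD, nM.
#' @param dna_per_ab,mw as in [quantifyRun()].
#' @return a [QuantResult].
#' @examples
#' quantifyConcentration(2.41, 0.48)  # 0.80 +/- 0.16 nM; 23.4 ng/mL
#' @export
quantifyConcentration <- function(dna_conc, dna_sd = 0, dna_per_ab = 3,
                                  mw = 29.1) {
  ab <- dnaToAntibody(dna_conc, dna_per_ab)
  new("QuantResult", dna_conc = dna_conc, dna_sd = dna_sd, ab_conc = ab,
      ab_sd = propagateSd(dna_sd, 1 / dna_per_ab),
      antigen_mass = antibodyToMass(ab, mw),
      antigen_mass_sd = propagateSd(dna_sd, c(1 / dna_per_ab, mw)),
      mw = mw, dna_per_ab = dna_per_ab, particle_conc = NA_real_,
      n_wells_used = 0L, n_censored = 0L)
}
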