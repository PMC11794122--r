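## Statistics of conjugate assembly: how biotinylated antibodies and reporter
## DNAs partition over the four biotin-binding sites of streptavidin. The
## Poisson antibody-count model is the lambda << 1 limit of the exact 4-site
## multinomial, which is enumerated in full here.

#' Conjugation mix composition
#'
#' Concentrations and volumes of the three components combined to assemble
#' antibody-DNA conjugates, plus the biocytin blocker used to cap leftover
#' biotin-binding sites. Moles are derived as concentration x volume.
#'
#' @slot ab_conc,dna_conc,sa_conc concentrations in uM (antibody, reporter
#'   DNA, streptavidin).
#' @slot ab_vol,dna_vol,sa_vol volumes in uL.
#' @slot blocker_pmol biocytin amount in pmol (inert site blocker).
#' @seealso [conjugationMix()], [lambdaFromMix()]
#' @export
setClass("ConjugationMix",
         representation(ab_conc = "numeric", ab_vol = "numeric",
                        dna_conc = "numeric", dna_vol = "numeric",
                        sa_conc = "numeric", sa_vol = "numeric",
                        blocker_pmol = "numeric"))

setValidity("ConjugationMix", function(object) {
  vals <- c(object@ab_conc, object@ab_vol, object@dna_conc, object@dna_vol,
            object@sa_conc, object@sa_vol, object@blocker_pmol)
  if (any(!is.finite(vals)) || any(vals < 0))
    return("all concentrations, volumes and blocker amounts must be finite and >= 0")
  TRUE
})

#' Construct a ConjugationMix
#'
#' Defaults are the assembly this package models: 10 uL of anti-EpCAM
#' antibody at ~0.06 uM, 2 uL of biotinylated DNA at 10 uM, and 3 uL of
#' streptavidin at ~1.6 uM.
#'
#' @param ab_conc,ab_vol antibody concentration (uM) and volume (uL).
#' @param dna_conc,dna_vol reporter DNA concentration (uM) and volume (uL).
#' @param sa_conc,sa_vol streptavidin concentration (uM) and volume (uL).
#' @param blocker_pmol biocytin blocker, pmol.
#' @return a [ConjugationMix].
#' @examples
#' conjugationMix()
#' @export
conjugationMix <- function(ab_conc = 0.06, ab_vol = 10, dna_conc = 10,
                           dna_vol = 2, sa_conc = 1.6, sa_vol = 3,
                           blocker_pmol = 0) {
  new("ConjugationMix", ab_conc = ab_conc, ab_vol = ab_vol,
      dna_conc = dna_conc, dna_vol = dna_vol, sa_conc = sa_conc,
      sa_vol = sa_vol, blocker_pmol = blocker_pmol)
}

setMethod("show", "ConjugationMix", function(object) {
  cat("ConjugationMix\n")
  cat(sprintf("  antibody:     %.4g uM x %.4g uL = %.4g pmol\n",
              object@ab_conc, object@ab_vol, object@ab_conc * object@ab_vol))
  cat(sprintf("  reporter DNA: %.4g uM x %.4g uL = %.4g pmol\n",
              object@dna_conc, object@dna_vol, object@dna_conc * object@dna_vol))
  cat(sprintf("  streptavidin: %.4g uM x %.4g uL = %.4g pmol\n",
              object@sa_conc, object@sa_vol, object@sa_conc * object@sa_vol))
  if (object@blocker_pmol > 0)
    cat(sprintf("  biocytin blocker: %.4g pmol\n", object@blocker_pmol))
  cat(sprintf("  antibody:streptavidin molar ratio (lambda) = %.4g\n",
              lambdaFromMix(object)))
})

#' Poisson probability mass
#'
#' P(N = n) for the number of biotinylated antibodies loaded on one
#' streptavidin molecule when binding is random at mean ratio `lam`.
#'
#' @param n non-negative integer count (vectorized).
#' @param lam mean antibodies per streptavidin (the molar ratio lambda), >= 0.
#' @return probability lam^n e^(-lam) / n!.
#' @examples
#' poissonPMF(1, 1)   # exp(-1)
#' @export
poissonPMF <- function(n, lam) {
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    stop("'n' must be a non-negative integer", call. = FALSE)
  .assertNonneg(lam, "lam")
  dpois(n, lam)
}

#' Probability a streptavidin carries more than one antibody
#'
#' Under random (Poisson) loading at antibody:streptavidin molar ratio
#' `lam`, the chance a streptavidin core ends up with two or more antibodies
#' is P(N > 1) = 1 - e^(-lam) - lam e^(-lam). Keeping this probability
#' negligible (lam << 1) is what guarantees that essentially every
#' antibody-bearing conjugate carries exactly one antibody, with the
#' remaining three sites free for reporter DNA. For small lam the value is
#' lam^2/2 + O(lam^3).
#'
#' @param lam antibody:streptavidin molar ratio, >= 0.
#' @return P(N > 1), in [0, 1).
#' @examples
#' signif(probMultivalentAntibody(1 / 80), 2)   # 7.7e-05
#' @export
probMultivalentAntibody <- function(lam) {
  .assertNonneg(lam, "lam")
  -expm1(-lam) - lam * exp(-lam)
}

#' Antibody:streptavidin molar ratio of a mix
#'
#' @param mix a [ConjugationMix].
#' @return (ab_conc x ab_vol) / (sa_conc x sa_vol), dimensionless.
#' @examples
#' lambdaFromMix(conjugationMix())   # 0.125 for the default mix
#' @export
lambdaFromMix <- function(mix) {
  stopifnot(is(mix, "ConjugationMix"))
  sa_moles <- mix@sa_conc * mix@sa_vol
  if (sa_moles <= 0)
    stop("streptavidin moles are zero; lambda is undefined", call. = FALSE)
  (mix@ab_conc * mix@ab_vol) / sa_moles
}

#' Occupancy distribution over the four streptavidin sites
#'
#' Probability table over site compositions `(n_ab, n_dna, n_free)` with
#' `n_ab + n_dna + n_free = 4`: how many of a streptavidin tetramer's four
#' biotin-binding sites hold an antibody, a reporter DNA, or nothing
#' (free or biocytin-blocked).
#'
#' @slot table data.frame with columns `n_ab`, `n_dna`, `n_free`, `prob`.
#' @slot p_ab,p_dna the per-site occupancy probabilities used.
#' @seealso [enumerateSiteOccupancy()], [meanDnaPerConjugate()]
#' @export
setClass("OccupancyDistribution",
         representation(table = "data.frame", p_ab = "numeric",
                        p_dna = "numeric"))

setValidity("OccupancyDistribution", function(object) {
  tb <- object@table
  need <- c("n_ab", "n_dna", "n_free", "prob")
  if (!all(need %in% names(tb)))
    return(paste("table needs columns", paste(need, collapse = ", ")))
  if (any(tb$prob < 0)) return("probabilities must be >= 0")
  if (abs(sum(tb$prob) - 1) > 1e-12) return("probabilities must sum to 1")
  if (any(tb$n_ab + tb$n_dna + tb$n_free != 4L))
    return("compositions must sum to 4 sites")
  TRUE
})

setMethod("show", "OccupancyDistribution", function(object) {
  cat(sprintf("OccupancyDistribution over 4 sites (p_ab = %.4g, p_dna = %.4g)\n",
              object@p_ab, object@p_dna))
  tb <- object@table[object@table$prob > 1e-12, ]
  print(tb[order(-tb$prob), ], row.names = FALSE, digits = 4)
})

#' @describeIn enumerateSiteOccupancy the composition/probability table.
#' @param dist an `OccupancyDistribution`.
#' @export
occupancyTable <- function(dist) dist@table

#' Exact occupancy distribution of the streptavidin tetramer
#'
#' Enumerates all 3^4 assignments of the four biotin-binding sites to
#' {antibody, DNA, free}, with independent per-site occupancy probabilities
#' `p_ab` and `p_dna` (remainder free/blocked). This is the no-depletion,
#' equal-affinity model: sites fill independently in proportion to free
#' ligand availability. The marginal antibody count is Binomial(4, p_ab),
#' and the Poisson model [probMultivalentAntibody()] is its lambda << 1
#' limit.
#'
#' @param p_ab,p_dna per-site probabilities of holding an antibody / a DNA;
#'   both in [0, 1] with `p_ab + p_dna <= 1`.
#' @return an [OccupancyDistribution].
#' @examples
#' d <- enumerateSiteOccupancy(p_ab = 0, p_dna = 0.5)
#' subset(occupancyTable(d), n_dna == 2)$prob   # Binomial(4, 0.5) mode, 0.375
#' @export
enumerateSiteOccupancy <- function(p_ab, p_dna) {
  .assertProb(p_ab, "p_ab")
  .assertProb(p_dna, "p_dna")
  if (p_ab + p_dna > 1 + 1e-15)
    stop("p_ab + p_dna must not exceed 1", call. = FALSE)
  p_free <- max(0, 1 - p_ab - p_dna)
  states <- c(ab = p_ab, dna = p_dna, free = p_free)
  grid <- expand.grid(s1 = 1:3, s2 = 1:3, s3 = 1:3, s4 = 1:3)
  prob <- apply(grid, 1L, function(g) prod(states[g]))
  n_ab <- rowSums(grid == 1L)
  n_dna <- rowSums(grid == 2L)
  tb <- stats::aggregate(prob,
                         by = list(n_ab = n_ab, n_dna = n_dna), FUN = sum)
  names(tb)[3L] <- "prob"
  tb$n_free <- 4L - tb$n_ab - tb$n_dna
  tb <- tb[order(tb$n_ab, tb$n_dna), c("n_ab", "n_dna", "n_free", "prob")]
  rownames(tb) <- NULL
  new("OccupancyDistribution", table = tb, p_ab = p_ab, p_dna = p_dna)
}

#' Expected DNA load of a single-antibody conjugate
#'
#' E[n_dna | n_ab = 1] under an occupancy distribution: the mean number of
#' reporter strands on a conjugate that carries exactly one antibody. With
#' rare antibody and saturating DNA this is 3, the nominal
#' one-antibody/three-DNA conjugate design.
#'
#' @param dist an [OccupancyDistribution].
#' @return expected DNA count conditional on exactly one antibody.
#' @examples
#' meanDnaPerConjugate(enumerateSiteOccupancy(1e-3, 1 - 1e-3))  # ~ 3
#' @export
meanDnaPerConjugate <- function(dist) {
  stopifnot(is(dist, "OccupancyDistribution"))
  tb <- dist@table[dist@table$n_ab == 1L, ]
  p1 <- sum(tb$prob)
  if (p1 <= 0)
    stop("P(n_ab = 1) is zero; the conditional mean is undefined",
         call. = FALSE)
  sum(tb$n_dna * tb$prob) / p1
}
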