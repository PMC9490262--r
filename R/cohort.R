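#' Generate a synthetic cohort with planted effects
#'
#' Creates a per-case clinical table and a genes x cases expression matrix
#' for validating the association stage. Each case receives a continuous
#' fibrosis score (uniform on [0, 2], emulating a slide-level mean TSR
#' score) whose median split defines the planted fibrosis group. Survival
#' times are exponential with baseline median `baselineMedian` months and
#' the hazard multiplied by `exp(plantedLogHr)` in the fibrosis-high
#' group; follow-up is administratively censored at a uniform time on
#' (0, `censorHorizon`] months, emulating staggered enrollment. Planted
#' genes depend linearly on the standardized fibrosis score plus unit
#' Gaussian noise (slope `plantedSlope`, a monotone link that Spearman
#' correlation detects); all other genes are independent N(0, 1) noise.
#' Age, stage and debulking frequencies follow a typical advanced
#' ovarian-cancer cohort (mean age 63, 75% stage III, 76% optimal
#' debulking).
#'
#' @param nCases number of cases (>= 20).
#' @param nGenes number of genes.
#' @param plantedLogHr planted log hazard ratio of fibrosis-high vs -low
#'   (0.69, i.e. HR 2, by default).
#' @param plantedGeneFrac fraction of genes with planted score
#'   dependence, in [0, 1).
#' @param seed integer RNG seed.
#' @param plantedSlope linear effect of the standardized score on planted
#'   genes (default 0.45, about rho 0.4).
#' @param baselineMedian baseline median survival in months (default 37).
#' @param censorHorizon upper bound of the uniform censoring time
#'   (default 200 months).
#' @return a [SyntheticCohort-class].
#' @examples
#' co <- generateCohort(nCases = 50, nGenes = 100, seed = 2)
#' co
#' @export
generateCohort <- function(nCases = 200L, nGenes = 1000L,
                           plantedLogHr = 0.69, plantedGeneFrac = 0.1,
                           seed = 1L, plantedSlope = 0.45,
                           baselineMedian = 37, censorHorizon = 200) {
  nCases <- as.integer(nCases)
  if (nCases < 20L) stop("nCases must be >= 20")
  if (plantedGeneFrac < 0 || plantedGeneFrac >= 1)
    stop("plantedGeneFrac must be in [0, 1)")
  withr::with_seed(seed, {
    caseId <- sprintf("case%04d", seq_len(nCases))
    score <- stats::runif(nCases, 0, 2)
    grp <- medianSplit(score)
    lambda0 <- log(2) / baselineMedian
    lambda <- lambda0 * exp(plantedLogHr * (grp == "high"))
    tEvent <- stats::rexp(nCases, rate = lambda)
    tCens <- stats::runif(nCases, 0, censorHorizon)
    time <- pmin(tEvent, tCens)
    time <- pmax(time, 1e-3)                  # strictly positive
    event <- as.integer(tEvent <= tCens)
    age <- round(pmin(pmax(stats::rnorm(nCases, 63, 11), 24), 89))
    stage <- sample(c(3L, 4L), nCases, replace = TRUE,
                    prob = c(0.75, 0.25))
    debulking <- sample(c("optimal", "suboptimal"), nCases,
                        replace = TRUE, prob = c(0.76, 0.24))
    genes <- sprintf("gene%05d", seq_len(nGenes))
    nPlanted <- round(plantedGeneFrac * nGenes)
    planted <- if (nPlanted > 0) sort(sample(genes, nPlanted))
               else character(0)
    z <- as.numeric(scale(score))
    expr <- matrix(stats::rnorm(nGenes * nCases), nGenes, nCases,
                   dimnames = list(genes, caseId))
    if (nPlanted > 0)
      expr[planted, ] <- expr[planted, ] +
        matrix(rep(plantedSlope * z, each = nPlanted), nPlanted, nCases)
    clinical <- data.frame(case_id = caseId, time = time, event = event,
                           age = age, stage = stage,
                           debulking = debulking,
                           fibrosis_score = score, fibrosis_group = grp,
                           stringsAsFactors = FALSE)
    new("SyntheticCohort", clinical = clinical, expression = expr,
        plantedGenes = planted, plantedLogHr = plantedLogHr)
  })
}
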