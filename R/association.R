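#' Median split into low/high groups
#'
#' Values less than or equal to the empirical median go to `"low"`, the
#' rest to `"high"` (the tie rule is deterministic: median ties are
#' assigned low). All-identical input cannot be split and is an error.
#'
#' @param values numeric vector with at least 2 finite values.
#' @return factor with levels `low`, `high`.
#' @examples
#' medianSplit(c(1, 2, 3, 4))
#' @export
medianSplit <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("need at least 2 finite values")
  if (length(unique(v)) == 1L)
    stop("all values identical: cannot median-split into two groups")
  med <- stats::median(values, na.rm = TRUE)
  out <- factor(ifelse(values <= med, "low", "high"),
                levels = c("low", "high"))
  if (all(out == "low", na.rm = TRUE))
    stop("median split produced a single group")
  out
}

#' Cox proportional hazards association of a TSR group
#'
#' Fits a Cox model for overall survival against a two-level TSR group,
#' either univariate or multivariable (adjusted for age, stage IV vs III,
#' and suboptimal vs optimal debulking). Hazard ratios are reported with
#' 95% confidence intervals and two-sided Wald p-values. Groups without
#' any event make the partial likelihood degenerate and raise an error.
#'
#' @param data data.frame with columns `time`, `event` and, for the
#'   multivariable mode, `age`, `stage` (3/4) and `debulking`
#'   (optimal/suboptimal).
#' @param group factor of length `nrow(data)` with two levels (first
#'   level = reference), e.g. from [medianSplit()].
#' @param mode `"univariate"` or `"multivariable"`.
#' @return data.frame with one row per model term: `term`, `hr`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
coxFit <- function(data, group, mode = c("univariate", "multivariable")) {
  mode <- match.arg(mode)
  stopifnot(length(group) == nrow(data))
  group <- droplevels(as.factor(group))
  ev <- tapply(data$event, group, sum)
  if (any(is.na(ev)) || any(ev == 0))
    stop("a group has zero events: Cox model cannot converge")
  df <- data.frame(time = data$time, event = data$event, group = group)
  if (mode == "multivariable") {
    df$age <- data$age
    df$stage4 <- factor(ifelse(data$stage == 4, "IV", "III"),
                        levels = c("III", "IV"))
    df$debulking <- factor(data$debulking,
                           levels = c("optimal", "suboptimal"))
    fml <- survival::Surv(time, event) ~ group + age + stage4 + debulking
  } else {
    fml <- survival::Surv(time, event) ~ group
  }
  fit <- survival::coxph(fml, data = df)
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             hr = s$conf.int[, "exp(coef)"],
             ci_low = s$conf.int[, "lower .95"],
             ci_high = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL)
}

#' Spearman correlation of every gene with a TSR score
#'
#' Correlates the normalized expression of each gene with the per-case
#' TSR score using Spearman rank correlation (ties handled by average
#' ranks). Two-sided p-values use the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param expression numeric matrix genes x cases with dimnames.
#' @param scores named numeric vector of per-case scores; names must
#'   match the expression columns (order-independent).
#' @param minCases minimum number of aligned cases (default 5).
#' @return data.frame: `gene`, `rho`, `p`, `direction` (sign of rho).
#' @export
spearmanGeneScan <- function(expression, scores, minCases = 5L) {
  if (is.null(names(scores)) || is.null(colnames(expression)))
    stop("expression columns and scores must be named with case ids")
  common <- intersect(colnames(expression), names(scores))
  if (length(common) < length(scores) ||
      length(common) < ncol(expression))
    stop("case ids of expression matrix and scores are misaligned")
  if (length(common) < minCases)
    stop(sprintf("need at least %d aligned cases", minCases))
  ex <- expression[, common, drop = FALSE]
  sc <- scores[common]
  rho <- as.numeric(stats::cor(t(ex), sc, method = "spearman"))
  n <- length(common)
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  data.frame(gene = rownames(ex), rho = rho, p = p,
             direction = sign(rho), row.names = NULL)
}

#' Split nominally significant genes by correlation sign
#'
#' @param rows data.frame from [spearmanGeneScan()].
#' @param alpha nominal significance threshold (default 0.05).
#' @return list with character vectors `positive` (`p < alpha, rho > 0`)
#'   and `negative` (`p < alpha, rho < 0`).
#' @export
selectCorrelatedGenes <- function(rows, alpha = 0.05) {
  if (nrow(rows) == 0L) stop("empty gene table")
  list(positive = rows$gene[rows$p < alpha & rows$rho > 0],
       negative = rows$gene[rows$p < alpha & rows$rho < 0])
}

#' Over-representation analysis of a selected gene list
#'
#' Tests each gene set for over-representation of the selected genes by
#' the one-sided hypergeometric (Fisher exact) upper tail against a
#' stated background universe, then adjusts across the collection with
#' Benjamini-Hochberg. Sets are intersected with the universe before
#' testing.
#'
#' @param selected character vector of selected genes (subset of
#'   `universe`).
#' @param geneSets named list of character vectors.
#' @param universe character vector: the measured gene background.
#' @return data.frame sorted by p: `gene_set`, `overlap`, `set_size`,
#'   `selected_size`, `universe_size`, `p`, `fdr`.
#' @export
oraEnrichment <- function(selected, geneSets, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (length(selected) == 0L) stop("empty selection")
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  selected <- unique(selected)
  universe <- unique(universe)
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, selected))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(gene_set = nm, overlap = k, set_size = K,
               selected_size = n, universe_size = N, p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$gene_set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write gene-set collections in GMT format
#'
#' GMT is tab-separated: set name, description, then member genes, one
#' set per line.
#'
#' @param path file path.
#' @return `readGmt` returns a named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname readGmt
#' @param geneSets named list of character vectors to write.
#' @export
writeGmt <- function(geneSets, path) {
  lines <- vapply(names(geneSets), function(nm)
    paste(c(nm, "na", geneSets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
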