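#' Response heterogeneity per drug
#'
#' Sample standard deviation (n - 1 denominator) of the present final scores
#' for each drug: how differently the cohort's PDOs respond to it. Drugs
#' with fewer than two present scores get NA with a warning.
#'
#' @param scores A `score_matrix` ([score_cohort()]) or a [chemogram()] fit.
#' @param drug Optional single drug name; default all drugs.
#' @return Named numeric vector of heterogeneity scores.
#' @export
heterogeneity_score <- function(scores, drug = NULL) {
  m <- final_matrix(scores)
  if (!is.null(drug)) m <- m[, drug, drop = FALSE]
  out <- apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  })
  if (anyNA(out)) {
    warning("drug(s) with fewer than 2 present scores: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

#' Drug-drug correlation of response profiles
#'
#' Pairwise Pearson correlation of final scores between drugs, across PDOs
#' present for both drugs (pairwise-complete); pairs with fewer than
#' `min_pairs` complete PDOs, or involving a constant score vector, are
#' recorded missing. Drugs are hierarchically clustered on the distance
#' 1 - r (missing r treated as distance 1).
#'
#' @param scores A `score_matrix` or [chemogram()] fit.
#' @param min_pairs Minimum complete PDO pairs for a correlation (default 3).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return A `drug_correlation`: list with `drugs`, symmetric `r`, `pair_n`
#'   (complete-pair counts), `linkage` (an `hclust` tree) and `order` (the
#'   clustering leaf order).
#' @export
drug_correlation <- function(scores, min_pairs = 3, linkage = "average") {
  m <- final_matrix(scores)
  if (ncol(m) < 2) stop("need at least 2 drugs for a correlation matrix")
  obs <- !is.na(m)
  pair_n <- crossprod(obs)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[pair_n < min_pairs] <- NA_real_
  diag(r) <- 1
  if (anyNA(r)) {
    warning("correlation undefined for ", sum(is.na(r[upper.tri(r)])),
            " drug pair(s) (constant scores or < ", min_pairs,
            " complete pairs)")
  }
  d <- 1 - r
  d[is.na(d)] <- 1
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(drugs = colnames(m), r = r, pair_n = pair_n,
                 linkage = tree, order = tree$order),
            class = "drug_correlation")
}

#' @export
print.drug_correlation <- function(x, ...) {
  cat("Drug-drug Pearson correlation:", length(x$drugs), "drugs\n")
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("  defined pairs: %d / %d; r range [%.2f, %.2f]\n",
              sum(!is.na(off)), length(off),
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Hits per PDO
#'
#' Number of drugs called a hit for each PDO; missing pairs contribute 0.
#'
#' @param scores A `score_matrix` or [chemogram()] fit.
#' @return Named integer vector, one entry per PDO.
#' @export
hits_per_pdo <- function(scores) {
  sm <- if (inherits(scores, "chemogram")) scores$scores else scores
  h <- rowSums(sm$hit, na.rm = TRUE)
  storage.mode(h) <- "integer"
  h
}

#' Welch's unpaired two-tailed t-test
#'
#' Implemented from the closed-form statistic and Welch-Satterthwaite
#' degrees of freedom (so the computation is inspectable and testable
#' against an independent oracle): t = (m1 - m2) / sqrt(v1/n1 + v2/n2),
#' df = (v1/n1 + v2/n2)^2 / ((v1/n1)^2/(n1-1) + (v2/n2)^2/(n2-1)),
#' p two-tailed from the t distribution.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return List with `t_statistic`, `df`, `p_value`, `mean_diff`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations")
  }
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    # No variance in either group: identical means give t = 0, p = 1.
    t_stat <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    return(list(t_statistic = t_stat, df = n1 + n2 - 2,
                p_value = if (t_stat == 0) 1 else 0,
                mean_diff = mean(x) - mean(y)))
  }
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t_statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df),
       mean_diff = mean(x) - mean(y))
}

#' Compare a per-PDO statistic between two groups
#'
#' Welch's unpaired two-tailed t-test between two groups of PDOs — most
#' commonly their hit counts split by tumor origin or prior treatment lines.
#' No multiple-testing correction is applied.
#'
#' @param values Numeric per-PDO statistic (e.g. [hits_per_pdo()]).
#' @param labels Group label per value; exactly two distinct labels.
#' @return A `group_comparison`: group labels, sizes, means, t statistic,
#'   Welch-Satterthwaite df, two-tailed p value.
#' @export
compare_groups <- function(values, labels) {
  if (length(values) != length(labels)) {
    stop("values and labels must have the same length")
  }
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two groups required, got ",
                                length(groups))
  x <- values[labels == groups[1]]
  y <- values[labels == groups[2]]
  w <- welch_t(x, y)
  structure(list(group_labels = groups,
                 n = c(length(x), length(y)),
                 group_means = c(mean(x), mean(y)),
                 t_statistic = w$t_statistic, df = w$df,
                 p_value = w$p_value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch two-tailed t-test: %s (n=%d, mean %.3f) vs %s (n=%d, mean %.3f)\n",
              x$group_labels[1], x$n[1], x$group_means[1],
              x$group_labels[2], x$n[2], x$group_means[2]))
  cat(sprintf("  t = %.4f, df = %.2f, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

# Final-score matrix from any score container.
final_matrix <- function(scores) {
  if (inherits(scores, "chemogram")) scores <- scores$scores
  if (inherits(scores, "score_matrix")) return(scores$final_score)
  if (is.matrix(scores)) return(scores)
  stop("expected a chemogram fit, score_matrix, or matrix")
}
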