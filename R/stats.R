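#' Rank correlation between brain state and firing rate
#'
#' Orders states along an assumed consciousness gradient (default
#' walk < wake < REM < NREM, codes 1-4) and correlates the state code with
#' a firing-rate column across unit-by-state observations. Spearman rank
#' correlation by default; Pearson available.
#'
#' @param metrics Data frame with a `state` column and the rate column,
#'   e.g. the output of [state_firing_metrics()] stacked over units.
#' @param order Character vector giving the state ordering (low code =
#'   higher consciousness); observations in other states are dropped.
#' @param rate_col Name of the rate column to correlate.
#' @param method `"spearman"` or `"pearson"`.
#' @return List: `rho`, `p`, `n`, `method`. Constant rates give `rho = NA`
#'   with a warning.
#' @export
state_correlation <- function(metrics, order = c("walk", "wake", "REM", "NREM"),
                              rate_col = "total_rate_hz",
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- metrics$state %in% order
  code <- match(metrics$state[keep], order)
  rate <- metrics[[rate_col]][keep]
  ok <- !is.na(rate)
  code <- code[ok]; rate <- rate[ok]
  if (length(rate) < 3L || length(unique(code)) < 2L) {
    stop("need >= 3 observations spanning >= 2 states", call. = FALSE)
  }
  if (stats::sd(rate) == 0) {
    warning("constant rates: correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(rate),
                method = method))
  }
  ct <- suppressWarnings(stats::cor.test(code, rate, method = method,
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(rate),
       method = method)
}

#' Two-sample Levene test for homogeneity of variance
#'
#' Classic (mean-centered) Levene test: a one-way ANOVA on the absolute
#' deviations from each group's mean, as implemented by
#' `car::leveneTest(center = mean)`.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @return List: `statistic` (F), `df`, `p`.
#' @export
variance_homogeneity <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  v <- c(x, y)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lt <- car::leveneTest(v, g, center = mean)
  list(statistic = lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
       p = lt[1, "Pr(>F)"])
}

#' Holm step-down decisions over a family of comparisons
#'
#' Applies the Holm-Bonferroni step-down rule: with p-values sorted
#' ascending, reject while `p(i) <= alpha / (m - i + 1)`, then stop.
#' Decisions are monotone (rejecting a p-value implies rejecting all
#' smaller ones). Either raw p-values or a list of sample pairs (compared
#' by rank-sum, or signed-rank when `paired = TRUE`) may be supplied.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param pairs Alternatively, a list of two-element lists/list(x, y) of
#'   samples; p-values computed with [stats::wilcox.test()].
#' @param alpha Family-wise error level.
#' @param paired Use the paired signed-rank test for `pairs`.
#' @return Data frame with `p`, `p_holm` and logical `reject`.
#' @export
group_compare_holm <- function(p = NULL, pairs = NULL, alpha = 0.05,
                               paired = FALSE) {
  if (is.null(p)) {
    if (is.null(pairs)) stop("supply p-values or sample pairs", call. = FALSE)
    p <- vapply(pairs, function(pr) {
      suppressWarnings(stats::wilcox.test(pr[[1]], pr[[2]],
                                          paired = paired)$p.value)
    }, numeric(1))
  }
  if (length(p) < 1L) stop("need at least one comparison", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p, method = "holm")
  data.frame(p = p, p_holm = adj, reject = adj <= alpha)
}

#' Two-dimensional embedding of firing features
#'
#' Projects unit-by-state firing features (tonic rate, burst spike rate,
#' burst event rate) onto the plane spanned by the first two principal
#' components of the column-standardized feature matrix. The projection is
#' deterministic (component signs are fixed by convention), so a fixed seed
#' always reproduces the same coordinates; non-numeric metadata columns are
#' carried through for grouping and plotting.
#'
#' @param features Data frame with at least 10 rows; all numeric columns
#'   are embedded and must be free of missing values and non-constant.
#' @param seed Integer seed (kept for interface stability; the projection
#'   itself is deterministic).
#' @return Data frame with `dim1`, `dim2` plus the metadata columns.
#' @export
state_space_embedding <- function(features, seed = 1) {
  features <- as.data.frame(features)
  num <- vapply(features, is.numeric, logical(1))
  x <- as.matrix(features[, num, drop = FALSE])
  if (nrow(x) < 10L) stop("need at least 10 observations to embed",
                          call. = FALSE)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pr$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {                      # fix sign: dominant loading positive
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  out <- data.frame(dim1 = pr$x[, 1], dim2 = pr$x[, 2])
  cbind(out, features[, !num, drop = FALSE])
}
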