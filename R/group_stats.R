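# Nonparametric group comparison layer: tie-corrected Kruskal-Wallis
# omnibus test and Dunn's pairwise z post-hoc on pooled mid-ranks, with
# Benjamini-Hochberg adjustment over a declared comparison family.

.rank_setup <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  N <- length(values)
  r <- rank(values)                       # pooled mid-ranks
  tie_tab <- table(values)
  list(values = values, groups = groups, N = N, r = r,
       n = as.numeric(table(groups)),
       Rbar = as.numeric(tapply(r, groups, mean)),
       levels = levels(groups),
       tie_sum = sum(tie_tab^3 - tie_tab))
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based omnibus test for location differences across k groups. The
#' statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \tfrac{N+1}{2})^2}
#' is divided by the tie correction
#' \eqn{1 - \sum_t (t^3 - t) / (N^3 - N)} and referred to a chi-square
#' distribution with k - 1 degrees of freedom. When every observation is
#' identical the test is degenerate and returns H = 0, p = 1 with a flag.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor), same length.
#' @return List: \code{statistic} (H), \code{df}, \code{p.value},
#'   \code{tie_correction}, \code{degenerate}, \code{n}, \code{k}.
#' @examples
#' kruskalWallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(letters[1:3], each = 3))
#' @export
kruskalWallis <- function(values, groups) {
  s <- .rank_setup(values, groups)
  if (s$N < 3L) stop("need at least 3 observations in total")
  k <- length(s$levels)
  H0 <- 12 / (s$N * (s$N + 1)) * sum(s$n * (s$Rbar - (s$N + 1) / 2)^2)
  C <- 1 - s$tie_sum / (s$N^3 - s$N)
  degenerate <- C <= 0                     # all observations identical
  H <- if (degenerate) 0 else H0 / C
  p <- if (degenerate) 1 else stats::pchisq(H, k - 1, lower.tail = FALSE)
  list(statistic = H, df = k - 1L, p.value = p,
       tie_correction = C, degenerate = degenerate, n = s$N, k = k)
}

#' Dunn's pairwise post-hoc test with Benjamini-Hochberg adjustment
#'
#' For each group pair the Dunn z statistic is
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t(t^3 - t)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' using mid-ranks pooled over all groups; two-sided normal p-values are
#' BH-adjusted over the declared family (all pairs by default). The
#' post-hoc is computed regardless of omnibus significance; report the
#' omnibus p alongside (see [groupStats()]).
#'
#' @inheritParams kruskalWallis
#' @param family optional list of character(2) group pairs defining the
#'   comparison family; default all pairwise comparisons.
#' @return data.frame: \code{group1}, \code{group2}, \code{z},
#'   \code{p_raw}, \code{p_adj}, \code{stars}.
#' @export
dunnBH <- function(values, groups, family = NULL) {
  s <- .rank_setup(values, groups)
  if (is.null(family)) {
    cmb <- utils::combn(s$levels, 2L)
    family <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  bad <- unlist(family)[!unlist(family) %in% s$levels]
  if (length(bad))
    stop("unknown group(s) in family: ", paste(unique(bad), collapse = ", "))
  sigma2 <- s$N * (s$N + 1) / 12 - s$tie_sum / (12 * (s$N - 1))
  res <- do.call(rbind, lapply(family, function(pr) {
    i <- match(pr[1], s$levels); j <- match(pr[2], s$levels)
    se <- sqrt(sigma2 * (1 / s$n[i] + 1 / s$n[j]))
    z <- if (se > 0) (s$Rbar[i] - s$Rbar[j]) / se else 0
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p_raw = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }))
  res$p_adj <- stats::p.adjust(res$p_raw, method = "BH")
  res$stars <- starCode(res$p_adj)
  rownames(res) <- NULL
  res
}

#' Significance star codes
#'
#' The annotation convention used throughout: \code{****} p < 0.0001,
#' \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05, otherwise
#' \code{ns}.
#'
#' @param p numeric p-values.
#' @return Character vector of star codes.
#' @export
starCode <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Omnibus plus post-hoc comparison of one metric across groups
#'
#' Runs the tie-corrected Kruskal-Wallis test and the Dunn/BH pairwise
#' table on the same samples and bundles them into a
#' [StatsResult-class].
#'
#' @inheritParams dunnBH
#' @param metric name of the compared metric (for reporting).
#' @return A [StatsResult-class].
#' @export
groupStats <- function(values, groups, metric = "metric", family = NULL) {
  kw <- kruskalWallis(values, groups)
  pw <- dunnBH(values, groups, family = family)
  new("StatsResult", metric = metric, H = kw$statistic, df = kw$df,
      p_omnibus = kw$p.value, pairwise = pw)
}
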