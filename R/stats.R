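#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Implemented directly from the sums-of-squares decomposition:
#' `SS_between = sum n_g (m_g - m)^2`, `SS_within = sum (x - m_g)^2`,
#' `F = (SS_b / (k-1)) / (SS_w / (N-k))`, with the p-value from the F
#' distribution.  Post hoc pairwise comparisons use t statistics on the
#' pooled within-group mean square (df `N - k`) with Bonferroni
#' correction over the `k (k - 1) / 2` pairs.
#'
#' @param groups named list of numeric vectors (>= 2 groups, total
#'   N > k).
#' @return object of class `anova_oneway`: list with `F`, `p`, `df_between`,
#'   `df_within`, `group_means`, and `pairwise` (data.frame `a`, `b`,
#'   `diff`, `t`, `p`, `p_adj`).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  k <- length(groups); N <- length(x)
  if (N <= k) stop("need more observations than groups")
  m <- mean(x)
  mg <- vapply(groups, mean, numeric(1))
  ng <- lengths(groups)
  ss_b <- sum(ng * (mg - m)^2)
  ss_w <- sum((x - mg[g])^2)
  df_b <- k - 1; df_w <- N - k
  if (ss_w == 0 && ss_b == 0) {
    Fv <- 0; p <- 1
  } else {
    Fv <- (ss_b / df_b) / (ss_w / df_w)
    p <- stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
  }
  mse <- ss_w / df_w
  cmb <- utils::combn(names(groups), 2)
  n_pairs <- ncol(cmb)
  pw <- data.frame(a = cmb[1, ], b = cmb[2, ], diff = NA_real_,
                   t = NA_real_, p = NA_real_, p_adj = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n_pairs)) {
    a <- cmb[1, i]; b <- cmb[2, i]
    dd <- mg[a] - mg[b]
    se <- sqrt(mse * (1 / ng[a] + 1 / ng[b]))
    tt <- if (se == 0) ifelse(dd == 0, 0, Inf) else dd / se
    pp <- 2 * stats::pt(abs(tt), df_w, lower.tail = FALSE)
    pw$diff[i] <- dd; pw$t[i] <- tt; pw$p[i] <- pp
    pw$p_adj[i] <- min(1, pp * n_pairs)
  }
  structure(list(F = Fv, p = p, df_between = df_b, df_within = df_w,
                 group_means = mg, pairwise = pw),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("<anova_oneway> F(%d, %d) = %.3f, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Unpaired two-tailed Student's t test (pooled variance)
#'
#' Classical equal-variance formulation:
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / (s_p sqrt(1/n1 + 1/n2))`, two-sided p from the t
#' distribution on `n1 + n2 - 2` df.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
t_test_unpaired <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  dd <- mean(a) - mean(b)
  if (sp2 == 0) {
    t <- ifelse(dd == 0, 0, Inf)
    p <- ifelse(dd == 0, 1, 0)
  } else {
    t <- dd / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  list(t = t, df = df, p = p, mean_a = mean(a), mean_b = mean(b))
}
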