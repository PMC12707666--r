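# Group-level inference: subject-wise sign-flip permutation testing with
# FDR correction, paired contrasts with Cohen's dz and retrospective
# power, and the three-way repeated-measures ANOVA with partial eta
# squared.

#' Subject-wise sign-flip permutation test
#'
#' The null distribution of the group-mean statistic is built by negating
#' each subject's map under every +/-1 assignment: exhaustive enumeration
#' of all 2^N assignments when N <= `exhaustive_limit` (so N = 11 gives
#' 2048 permutations), seeded Monte-Carlo otherwise (identity flip always
#' included). Two-sided p-values by the symmetry of the null.
#'
#' @param group_maps N x locations matrix (subjects in rows).
#' @param statistic Function mapping a subject x location matrix to a
#'   per-location statistic; default column means.
#' @param exhaustive_limit Largest N for exhaustive enumeration,
#'   default 12.
#' @param n_montecarlo Permutations when sampling, default 2048.
#' @param seed Seed for Monte-Carlo sampling.
#' @return List of class `permutation_result`: `observed`, `p`, `q`
#'   (Benjamini-Hochberg adjusted), `n_permutations`, `exhaustive`.
#' @export
signflip_permutation <- function(group_maps, statistic = colMeans,
                                 exhaustive_limit = 12,
                                 n_montecarlo = 2048, seed = 1) {
  group_maps <- as.matrix(group_maps)
  N <- nrow(group_maps)
  if (N < 2) stop("need at least 2 subjects")
  stopifnot_finite(group_maps, "group maps")
  observed <- statistic(group_maps)
  exhaustive <- N <= exhaustive_limit
  flips <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), N)))
  } else {
    with_seed(seed, {
      f <- matrix(sample(c(1, -1), (n_montecarlo - 1) * N, replace = TRUE),
                  n_montecarlo - 1, N)
      rbind(rep(1, N), f)  # identity assignment always included
    })
  }
  nperm <- nrow(flips)
  if (identical(statistic, colMeans)) {
    # group mean is linear in the flips: one matrix product
    null_stat <- (flips %*% group_maps) / N
  } else {
    null_stat <- matrix(0, nperm, length(observed))
    for (i in seq_len(nperm)) {
      null_stat[i, ] <- statistic(group_maps * flips[i, ])
    }
  }
  p <- colMeans(sweep(abs(null_stat), 2, abs(observed), `>=`))
  structure(list(observed = observed, p = p, q = fdr_bh(p)$q,
                 n_permutations = nperm, exhaustive = exhaustive),
            class = "permutation_result")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values: q_(i) = min_{j >= i} p_(j) * m / j, and a
#' significance mask at `q_level`.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param q_level FDR level, default 0.05.
#' @return List with `q` (adjusted values, input order) and `significant`
#'   (logical mask where q < `q_level`).
#' @export
fdr_bh <- function(p_values, q_level = 0.05) {
  m <- length(p_values)
  if (!m) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1 | !is.finite(p_values))) {
    stop("p-values must lie in (0, 1]")
  }
  o <- order(p_values)
  q_sorted <- p_values[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  list(q = q, significant = q < q_level)
}

#' Paired contrast with effect size and retrospective power
#'
#' Paired t-test on the differences a - b; Cohen's dz = |t| / sqrt(N);
#' retrospective power at two-sided alpha from the noncentral t
#' distribution with noncentrality dz * sqrt(N).
#'
#' @param a,b Paired samples of equal length >= 2.
#' @param alpha Two-sided significance level for the power computation.
#' @return List of class `paired_test`: `t`, `df`, `p`, `dz`, `power`,
#'   `mean_diff`, `degenerate` (TRUE when differences have zero variance).
#' @export
paired_contrast <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  N <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(structure(list(t = NA_real_, df = N - 1, p = NA_real_,
                          dz = NA_real_, power = NA_real_,
                          mean_diff = mean(d), degenerate = TRUE),
                     class = "paired_test"))
  }
  t <- mean(d) / (sd_d / sqrt(N))
  df <- N - 1
  p <- 2 * stats::pt(-abs(t), df)
  dz <- abs(t) / sqrt(N)
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- dz * sqrt(N)
  power <- 1 - stats::pt(tcrit, df, ncp = ncp) +
    stats::pt(-tcrit, df, ncp = ncp)
  structure(list(t = t, df = df, p = p, dz = dz, power = power,
                 mean_diff = mean(d), degenerate = FALSE),
            class = "paired_test")
}

#' Cohen's dz from a paired t statistic
#' @param t Paired t statistic.
#' @param N Number of pairs.
#' @export
cohens_dz <- function(t, N) abs(t) / sqrt(N)

#' Partial eta squared from an F statistic
#' @param F F statistic.
#' @param df1,df2 Effect and error degrees of freedom.
#' @export
partial_eta_squared <- function(F, df1, df2) F * df1 / (F * df1 + df2)

#' Three-way repeated-measures ANOVA
#'
#' Fully within-subject balanced design. Each of the 7 effects (3 main, 3
#' two-way, 1 three-way) is tested against its own subject-by-effect
#' interaction error term; partial eta squared per effect. No sphericity
#' correction is applied.
#'
#' @param values Numeric vector of cell values.
#' @param subject,f1,f2,f3 Factors (coercible), one entry per value;
#'   every subject must contribute one value per factor-level cell.
#' @return Data.frame with one row per effect: `effect`, `df1`, `df2`,
#'   `F`, `p`, `pes` (partial eta squared).
#' @export
rm_anova_3way <- function(values, subject, f1, f2, f3) {
  d <- data.frame(y = values, s = factor(subject), A = factor(f1),
                  B = factor(f2), C = factor(f3))
  counts <- table(d$s, d$A, d$B, d$C)
  if (any(counts != 1)) stop("design must be complete and balanced (one value per cell)")
  cell_mean <- function(...) {
    f <- interaction(..., drop = FALSE)
    ave(d$y, f)
  }
  mu <- mean(d$y)
  m_s <- cell_mean(d$s)
  m <- list(A = cell_mean(d$A), B = cell_mean(d$B), C = cell_mean(d$C))
  m$AB <- cell_mean(d$A, d$B); m$AC <- cell_mean(d$A, d$C)
  m$BC <- cell_mean(d$B, d$C); m$ABC <- cell_mean(d$A, d$B, d$C)
  ms <- list(A = cell_mean(d$s, d$A), B = cell_mean(d$s, d$B),
             C = cell_mean(d$s, d$C),
             AB = cell_mean(d$s, d$A, d$B), AC = cell_mean(d$s, d$A, d$C),
             BC = cell_mean(d$s, d$B, d$C),
             ABC = d$y)
  lv <- function(f) length(levels(f))
  a <- lv(d$A); b <- lv(d$B); cc <- lv(d$C); n <- lv(d$s)
  ss <- function(x) sum((x - mu)^2)
  # effect sums of squares by inclusion-exclusion over marginal means
  eff <- list(
    A = m$A - mu, B = m$B - mu, C = m$C - mu,
    `A:B` = m$AB - m$A - m$B + mu,
    `A:C` = m$AC - m$A - m$C + mu,
    `B:C` = m$BC - m$B - m$C + mu,
    `A:B:C` = m$ABC - m$AB - m$AC - m$BC + m$A + m$B + m$C - mu
  )
  # subject-by-effect interaction deviations (error terms)
  err <- list(
    A = ms$A - m$A - m_s + mu,
    B = ms$B - m$B - m_s + mu,
    C = ms$C - m$C - m_s + mu,
    `A:B` = ms$AB - ms$A - ms$B - m$AB + m_s + m$A + m$B - mu,
    `A:C` = ms$AC - ms$A - ms$C - m$AC + m_s + m$A + m$C - mu,
    `B:C` = ms$BC - ms$B - ms$C - m$BC + m_s + m$B + m$C - mu,
    `A:B:C` = ms$ABC - ms$AB - ms$AC - ms$BC - m$ABC +
      ms$A + ms$B + ms$C + m$AB + m$AC + m$BC -
      m_s - m$A - m$B - m$C + mu
  )
  df_eff <- c(A = a - 1, B = b - 1, C = cc - 1,
              `A:B` = (a - 1) * (b - 1), `A:C` = (a - 1) * (cc - 1),
              `B:C` = (b - 1) * (cc - 1),
              `A:B:C` = (a - 1) * (b - 1) * (cc - 1))
  out <- do.call(rbind, lapply(names(eff), function(e) {
    ss_e <- sum(eff[[e]]^2)
    ss_err <- sum(err[[e]]^2)
    df1 <- df_eff[[e]]
    df2 <- (n - 1) * df1
    ms_e <- ss_e / df1
    ms_err <- ss_err / df2
    F <- if (ms_err > 0) ms_e / ms_err else 0
    data.frame(effect = e, df1 = df1, df2 = df2, F = F,
               p = stats::pf(F, df1, df2, lower.tail = FALSE),
               pes = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
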