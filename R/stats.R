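# Comparison statistics for the setup study: ICC, repeated-measures ANOVA
# (+ Mauchly sphericity, Bonferroni paired-t post-hocs), Friedman (+ Wilcoxon
# signed-rank post-hocs), paired t, and McNemar for paired frequencies.
# Standard tests are delegated to stats:: wherever base R provides them.

new_test_result <- function(method, statistic, p_value, df = NA_real_,
                            n = NA_integer_, adjusted = FALSE, extra = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(
    c(list(
      method = method, statistic = statistic,
      p_value = min(1, p_value), df = df, n = n, adjusted = adjusted
    ), extra),
    class = "os_test"
  )
}

#' @export
print.os_test <- function(x, ...) {
  cat(sprintf(
    "<os_test> %s: statistic = %.4g, p = %.4g\n",
    x$method, x$statistic, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.os_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = as.numeric(x$statistic),
    df = as.numeric(x$df), n = as.integer(x$n),
    p_value = x$p_value, adjusted = x$adjusted
  )
}

as_block <- function(values) {
  m <- as.matrix(values)
  if (any(!is.finite(m))) stop("repeated-measures block has missing cells", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  m
}

#' Paired t-test
#'
#' Two-sided paired t with the conventions needed by the left/right pooling
#' gate: identical samples give p = 1, a deterministic nonzero offset
#' (zero-variance difference) gives p = 0.
#'
#' @param x,y equal-length paired numeric vectors (n >= 2).
#' @return an `os_test`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("insufficient data: need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  if (sd(d) < .Machine$double.eps^0.5 * (1 + max(abs(d)))) {
    if (abs(mean(d)) < .Machine$double.eps^0.5) {
      return(new_test_result("paired t", 0, 1, df = n - 1, n = n))
    }
    return(new_test_result("paired t", sign(mean(d)) * Inf, 0, df = n - 1, n = n))
  }
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  new_test_result("paired t", t_stat, p, df = n - 1, n = n)
}

#' Intraclass correlation for repeated measurements
#'
#' Intra-rater reliability of a repeated measurement: two-way mixed-effects,
#' single-measure, consistency ICC (often written ICC(3,1)), computed from the
#' mean squares of the subjects x sessions decomposition:
#' `(MS_subject - MS_error) / (MS_subject + (k - 1) MS_error)`.
#'
#' @param ratings numeric matrix or data frame, subjects in rows, measurement
#'   sessions in columns (>= 3 subjects, >= 2 sessions).
#' @param form currently only `"consistency"` (ICC(3,1)) is implemented; the
#'   argument exists so callers can state the intended form explicitly.
#' @return an `os_test` with the ICC as `statistic`.
#' @export
icc_agreement <- function(ratings, form = c("consistency")) {
  form <- match.arg(form)
  m <- as_block(ratings)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2) stop("ICC needs >= 3 subjects and >= 2 sessions", call. = FALSE)
  grand <- mean(m)
  if (sum((m - grand)^2) < 1e-24) {
    stop("undefined ICC: zero total variance", call. = FALSE)
  }
  ms_r <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  ss_e <- sum((m - grand)^2) - k * sum((rowMeans(m) - grand)^2) -
    n * sum((colMeans(m) - grand)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  new_test_result("ICC(3,1) consistency", icc, NA_real_, n = n,
    extra = list(ms_subject = ms_r, ms_error = ms_e, sessions = k)
  )
}

# Mauchly's W for a one-sample repeated-measures design (sphericity of the
# covariance of orthonormal within-subject contrasts), chi-square approximation.
mauchly_w <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  if (k < 3 || n <= k - 1) {
    return(list(W = NA_real_, statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  C <- contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/") # orthonormal contrasts
  S <- stats::cov(m %*% C)
  dt <- det(S)
  tr <- sum(diag(S))
  if (!is.finite(dt) || dt <= 0 || tr <= 0) {
    return(list(W = NA_real_, statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  pp <- k - 1
  ndf <- n - 1
  W <- dt / (tr / pp)^pp
  rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * ndf)
  # Box's asymptotic expansion with the second-order term, as in base R
  w2 <- (pp + 2) * (pp - 1) * (pp - 2) * (2 * pp^3 + 6 * pp^2 + 3 * k + 2) /
    (288 * (ndf * pp * rho)^2)
  z <- -ndf * rho * log(W)
  df <- pp * (pp + 1) / 2 - 1
  pr1 <- pchisq(z, df, lower.tail = FALSE)
  pr2 <- pchisq(z, df + 4, lower.tail = FALSE)
  list(W = W, statistic = z, df = df, p_value = pr1 + w2 * (pr2 - pr1))
}

posthoc_labels <- function(pairs, alpha) {
  sig <- pairs[pairs$p_adjusted < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    return("NA")
  }
  lab <- split(
    ifelse(sig$mean_diff > 0, sig$to, sig$from),
    ifelse(sig$mean_diff > 0, sig$from, sig$to)
  )
  paste(vapply(
    names(lab)[order(names(lab))],
    function(g) paste0(g, " > ", paste(sort(unique(lab[[g]])), collapse = ",")),
    character(1)
  ), collapse = "; ")
}

condition_letters <- function(cond) {
  stats::setNames(letters[seq_along(cond)], cond)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F-test across k conditions of a complete balanced block,
#' with Mauchly's test of sphericity and Bonferroni-adjusted pairwise paired
#' t-test post-hocs (adjusted p = unadjusted p times the number of pairs,
#' capped at 1). Post-hoc direction labels (letters a, b, c assigned to the
#' condition columns in order, e.g. `"a > b,c"`) are reported only when the
#' omnibus test is significant at `alpha`.
#'
#' @param values subjects x conditions numeric matrix or data frame, no
#'   missing cells; n >= 2 subjects, k >= 2 conditions.
#' @param alpha significance level gating the post-hoc labels.
#' @param gg_correction apply the Greenhouse-Geisser epsilon correction to the
#'   omnibus df (off by default).
#' @return an `os_test` with extras: `mauchly` (list with W, statistic, df,
#'   p_value), `pairwise` (tibble), `posthoc` (label string), `epsilon_gg`.
#' @export
rm_anova <- function(values, alpha = 0.05, gg_correction = FALSE) {
  m <- as_block(values)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("insufficient data: need n >= 2 subjects and k >= 2 conditions", call. = FALSE)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- max(0, ss_tot - ss_cond - ss_subj)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  scale <- max(1, grand^2)
  eps0 <- 1e-22 * scale * n * k
  C <- contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  S <- crossprod(m %*% C - rep(1, n) %*% t(colMeans(m %*% C))) / (n - 1)
  eps_gg <- sum(diag(S))^2 / (df1 * sum(S^2))
  if (ss_cond < eps0 && ss_err < eps0) {
    f <- 0
    p <- 1
  } else if (ss_err < eps0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_cond / df1) / (ss_err / df2)
    if (gg_correction && is.finite(eps_gg)) {
      p <- pf(f, df1 * eps_gg, df2 * eps_gg, lower.tail = FALSE)
    } else {
      p <- pf(f, df1, df2, lower.tail = FALSE)
    }
  }
  cond <- colnames(m)
  ltr <- condition_letters(cond)
  combos <- utils::combn(k, 2)
  npair <- ncol(combos)
  pw <- lapply(seq_len(npair), function(j) {
    i1 <- combos[1, j]
    i2 <- combos[2, j]
    tt <- paired_t(m[, i1], m[, i2])
    list(
      from = unname(ltr[cond[i1]]), to = unname(ltr[cond[i2]]),
      mean_diff = mean(m[, i1]) - mean(m[, i2]),
      statistic = as.numeric(tt$statistic), p_value = tt$p_value,
      p_adjusted = min(1, tt$p_value * npair)
    )
  })
  pairwise <- tibble::new_tibble(
    lapply(stats::setNames(nm = names(pw[[1]])), function(f) {
      unlist(lapply(pw, `[[`, f), use.names = FALSE)
    }),
    nrow = npair
  )
  posthoc <- if (is.na(p) || p >= alpha) "NA" else posthoc_labels(pairwise, alpha)
  new_test_result("repeated-measures ANOVA", f, p,
    df = df1, n = n,
    extra = list(
      df_error = df2, mauchly = mauchly_w(m), pairwise = pairwise,
      posthoc = posthoc, epsilon_gg = eps_gg, condition_letters = ltr
    )
  )
}

# exact conditional permutation p for the Friedman statistic: enumerate all
# within-row permutations of the observed values ((k!)^n states).
friedman_exact_p <- function(m, observed) {
  n <- nrow(m)
  k <- ncol(m)
  perms <- permutations_of(k)
  stat_of <- function(mm) friedman_statistic(mm)
  idx <- rep(list(seq_len(nrow(perms))), n)
  combos <- do.call(expand.grid, idx)
  stats_all <- vapply(seq_len(nrow(combos)), function(r) {
    mm <- m
    for (i in seq_len(n)) mm[i, ] <- m[i, perms[combos[r, i], ]]
    stat_of(mm)
  }, numeric(1))
  mean(stats_all >= observed - 1e-12)
}

permutations_of <- function(k) {
  if (k == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- permutations_of(k - 1)
  out <- NULL
  for (pos in k:1) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
      if (pos <= k - 1) sub[, pos:(k - 1), drop = FALSE]
    )
    out <- rbind(out, block)
  }
  matrix(as.integer(out), ncol = k)
}

# tie-corrected Friedman chi-square (matches stats::friedman.test); row
# midranks computed by column-wise comparison counts.
friedman_statistic <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- matrix(0, n, k)
  eq <- matrix(0, n, k)
  for (j in seq_len(k)) {
    less <- rowSums(m < m[, j])
    eq[, j] <- rowSums(m == m[, j])
    r[, j] <- less + (eq[, j] + 1) / 2
  }
  ties <- sum(eq^2 - 1) # per tie group of size t: t^3 - t
  denom <- n * k * (k + 1) - ties / (k - 1)
  if (denom <= 0) {
    return(0)
  }
  12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
}

#' Friedman test with Wilcoxon signed-rank post-hocs
#'
#' Friedman chi-square on within-subject ranks (midranks for ties). The p
#' value is the exact conditional permutation p (enumeration over all
#' within-row orderings) when `(k!)^n <= exact_limit`, otherwise the usual
#' tie-corrected chi-square approximation. Post-hocs are pairwise Wilcoxon
#' signed-rank tests (zero differences dropped; exact null distribution when
#' the number of nonzero pairs is at most `wilcoxon_exact_limit`, normal
#' approximation with continuity correction above), Bonferroni-adjusted.
#'
#' @inheritParams rm_anova
#' @param exact_limit maximal number of enumerated permutation states for the
#'   exact Friedman p.
#' @param wilcoxon_exact_limit sample-size bound for the exact signed-rank
#'   null distribution.
#' @return an `os_test` with extras `pairwise` (tibble) and `posthoc`.
#' @export
friedman_wilcoxon <- function(values, alpha = 0.05, exact_limit = 1e5,
                              wilcoxon_exact_limit = 25) {
  m <- as_block(values)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("insufficient data for the Friedman test", call. = FALSE)
  stat <- friedman_statistic(m)
  all_tied <- all(abs(m - m[, 1]) < 1e-12)
  if (all_tied) {
    stat <- 0
    p <- 1
    exact <- TRUE
  } else if (factorial(k)^n <= exact_limit) {
    p <- friedman_exact_p(m, stat)
    exact <- TRUE
  } else {
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
    exact <- FALSE
  }
  cond <- colnames(m)
  ltr <- condition_letters(cond)
  combos <- utils::combn(k, 2)
  npair <- ncol(combos)
  pw <- lapply(seq_len(npair), function(j) {
    x <- m[, combos[1, j]]
    y <- m[, combos[2, j]]
    d <- x - y
    d <- d[abs(d) > 1e-12] # drop zero differences before ranking
    if (length(d) == 0) {
      pv <- 1
      v <- NA_real_
    } else {
      wt <- suppressWarnings(wilcox.test(d,
        exact = length(d) <= wilcoxon_exact_limit, correct = TRUE
      ))
      pv <- wt$p.value
      v <- unname(wt$statistic)
    }
    list(
      from = unname(ltr[cond[combos[1, j]]]), to = unname(ltr[cond[combos[2, j]]]),
      mean_diff = mean(x) - mean(y),
      statistic = v, p_value = pv, p_adjusted = min(1, pv * npair)
    )
  })
  pairwise <- tibble::new_tibble(
    lapply(stats::setNames(nm = names(pw[[1]])), function(f) {
      unlist(lapply(pw, `[[`, f), use.names = FALSE)
    }),
    nrow = npair
  )
  posthoc <- if (p >= alpha) "NA" else posthoc_labels(pairwise, alpha)
  new_test_result("Friedman", stat, p,
    df = k - 1, n = n,
    extra = list(
      exact = exact, pairwise = pairwise, posthoc = posthoc,
      condition_letters = ltr
    )
  )
}

#' McNemar test for paired binary frequencies
#'
#' Compares the frequency of a binary outcome (root exposure beyond the
#' threshold) between the buccal and palatal/lingual sides of the same teeth.
#' Uses the exact two-sided binomial test on the discordant pairs
#' (`min(1, 2 P(X >= max(b, c))), X ~ Binomial(b + c, 1/2)`) when
#' `b + c <= exact_limit`, and the chi-square test with continuity correction
#' above.
#'
#' @param b,c discordant-pair counts (side 1 only / side 2 only).
#' @param exact_limit largest `b + c` for which the exact test is used.
#' @return an `os_test`.
#' @export
mcnemar_paired <- function(b, c, exact_limit = 25) {
  stopifnot(
    length(b) == 1, length(c) == 1, b >= 0, c >= 0,
    b == round(b), c == round(c)
  )
  nd <- b + c
  if (nd == 0) {
    return(new_test_result("McNemar (exact)", NA_real_, 1, n = 0L))
  }
  if (nd <= exact_limit) {
    bt <- binom.test(max(b, c), nd, p = 0.5)
    new_test_result("McNemar (exact)", max(b, c), bt$p.value, n = as.integer(nd))
  } else {
    mt <- mcnemar.test(matrix(c(0, b, c, 0), 2, 2), correct = TRUE)
    new_test_result("McNemar (chi-square, CC)", unname(mt$statistic),
      mt$p.value,
      df = unname(mt$parameter), n = as.integer(nd)
    )
  }
}
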