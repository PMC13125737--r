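# Exact nonparametric tests used by the methylation statistics.
#
# stats::wilcox.test falls back to a normal approximation whenever ties are
# present, but replicated percent-methylation data tie routinely, so the
# small-sample branches here enumerate the exact permutation distributions
# with midranks. Two-sided p-values are deviation-based:
# p = Pr(|T' - E[T]| >= |T - E[T]|) under the permutation null, which is
# symmetric for these statistics.

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. When both group sizes are
#' at most `exact_max` the p-value is computed by full enumeration of all
#' `choose(n_a + n_b, n_a)` group assignments (exact under ties, using
#' midranks); otherwise the tie-corrected normal approximation is used
#' (without continuity correction).
#'
#' @param a,b Numeric vectors.
#' @param exact_max Largest per-group size for the enumeration branch.
#' @return One-row tibble with `statistic` (U of the first group), `p`,
#'   `method`, `n_a`, `n_b`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a < 1 || n_b < 1) stop("both groups need at least one value", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2

  if (max(n_a, n_b) <= exact_max) {
    idx <- utils::combn(n_a + n_b, n_a)
    rs <- colSums(matrix(r[idx], nrow = n_a))
    u_all <- rs - n_a * (n_a + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- n_a + n_b
    ties <- table(pooled)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation, tie-corrected"
  }
  tibble::tibble(
    statistic = u_obs, p = min(p, 1), method = method, n_a = n_a, n_b = n_b
  )
}

# Exact one-sample Wilcoxon signed-rank test of x against mu, two-sided.
# Zeros dropped (standard), midranks of |differences|; the null distribution
# of W+ is built by convolution over independent sign flips on a doubled-rank
# integer grid, which stays exact under ties. Falls back to the tie-corrected
# normal approximation past `exact_max` usable values.
wilcoxon_signed_rank <- function(x, mu = 0, exact_max = 25) {
  d <- x[!is.na(x)] - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(statistic = 0, p = 1, n = 0))
  }
  rk <- rank(abs(d))
  r2 <- as.integer(round(2 * rk)) # midranks are multiples of 1/2
  w2 <- sum(r2[d > 0])
  e2 <- sum(r2) / 2
  if (n <= exact_max) {
    # distribution of sum of r2 over positive signs, each +/- with prob 1/2
    dist <- 1
    offset <- 0L
    for (s in r2) {
      padded <- c(dist, rep(0, s))
      shifted <- c(rep(0, s), dist)
      dist <- (padded + shifted) / 2
    }
    support <- seq.int(0L, sum(r2))
    p <- sum(dist[abs(support - e2) >= abs(w2 - e2) - 1e-9])
  } else {
    t_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(t_tab^3 - t_tab) / 48
    z <- (w2 / 2 - sum(rk) / 2) / sqrt(sigma2) # W+ minus E[W+] = sum(ranks)/2
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(statistic = w2 / 2, p = min(p, 1), n = n)
}

#' Compare groups with the field's standard nonparametric tests
#'
#' Dispatches to [mann_whitney()] for two groups or to the Kruskal-Wallis
#' rank-sum test (via [stats::kruskal.test()], tie-corrected H with a
#' chi-square p-value) for three or more.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @param test `"mann_whitney"` or `"kruskal_wallis"`; the default picks by
#'   the number of groups.
#' @return One-row tibble with `statistic`, `p`, `method`, `n_groups`.
#' @export
group_compare <- function(values, groups,
                          test = c("auto", "mann_whitney", "kruskal_wallis")) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  k <- length(unique(groups))
  if (test == "auto") test <- if (k <= 2) "mann_whitney" else "kruskal_wallis"
  if (test == "mann_whitney") {
    if (k != 2) {
      stop("mann_whitney requires exactly 2 groups (got ", k,
           "); use kruskal_wallis for 3 or more", call. = FALSE)
    }
    g <- unique(groups)
    res <- mann_whitney(values[groups == g[1]], values[groups == g[2]])
    return(tibble::tibble(
      statistic = res$statistic, p = res$p,
      method = paste("Mann-Whitney,", res$method), n_groups = 2L
    ))
  }
  if (k < 3) {
    stop("kruskal_wallis requires at least 3 groups (got ", k,
         "); use mann_whitney for 2", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    # all observations tied: H is 0 by convention, no evidence of difference
    return(tibble::tibble(
      statistic = 0, p = 1, method = "Kruskal-Wallis", n_groups = as.integer(k)
    ))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  tibble::tibble(
    statistic = unname(kt$statistic), p = kt$p.value,
    method = "Kruskal-Wallis", n_groups = as.integer(k)
  )
}

# All permutations of 1..n as an (n! x n) matrix, built by insertion.
# Cached per n; used by the exact Spearman permutation test (n <= 9).
perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  p <- matrix(1L, 1, 1)
  if (n > 1) {
    for (m in 2:n) {
      k <- nrow(p)
      out <- matrix(0L, k * m, m)
      for (pos in seq_len(m)) {
        rows <- seq_len(k) + (pos - 1L) * k
        if (pos > 1) out[rows, seq_len(pos - 1L)] <- p[, seq_len(pos - 1L)]
        out[rows, pos] <- m
        if (pos < m) out[rows, seq(pos + 1L, m)] <- p[, seq(pos, m - 1L)]
      }
      p <- out
    }
  }
  if (n <= 9) perm_cache[[key]] <- p
  p
}

# Spearman rho with midranks; exact two-sided permutation p for n <= exact_max,
# t-approximation otherwise.
spearman_test <- function(x, y, exact_max = 9) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "undefined (constant ranks)"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rho_all <- apply(perms, 1, function(ix) stats::cor(rx, ry[ix]))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}
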