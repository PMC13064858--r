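# Statistical tests used on pipeline outputs: two-sided
# Mann-Whitney-Wilcoxon, per-family Fisher enrichment with
# Benjamini-Hochberg correction, Spearman density-size correlation.

#' Two-sided Mann-Whitney-Wilcoxon test
#'
#' Uses the exact permutation null (computed by the standard count
#' recurrence for the U distribution) when `n1 + n2 <= mww_exact_max_n`
#' (default 16) and the data contain no ties; otherwise the normal
#' approximation with tie correction and continuity correction. The exact
#' two-sided p-value is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @param cfg [defensome_config()] (for the exact-branch size switch).
#' @return list of class `defensome_test`: `statistic` (U of `sample_a`),
#'   `p_value`, `method`, `n1`, `n2`, `adjusted_p` (NA here).
#' @examples
#' mww_test(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
mww_test <- function(sample_a, sample_b, cfg = defensome_config()) {
  if (!length(sample_a) || !length(sample_b)) {
    stop("mww_test: empty sample", call. = FALSE)
  }
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- any(duplicated(pooled))
  if (!has_ties && n1 + n2 <= cfg$mww_exact_max_n) {
    probs <- u_null_distribution(n1, n2)  # P(U = 0..n1*n2)
    p_le <- sum(probs[seq_len(u + 1)])
    p_ge <- sum(probs[(u + 1):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "Mann-Whitney-Wilcoxon (exact)"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Mann-Whitney-Wilcoxon (normal approximation)"
  }
  structure(list(statistic = u, p_value = p, method = method,
                 n1 = n1, n2 = n2, adjusted_p = NA_real_),
            class = "defensome_test")
}

# Null distribution of U for sample sizes n1, n2 without ties. The number
# of rank assignments with U = u is the coefficient of q^u in the Gaussian
# binomial [n1 + n2 choose n1]_q, computed by exact polynomial recurrence.
u_null_distribution <- function(n1, n2) {
  poly <- 1
  for (k in seq_len(n1)) {
    # multiply by (1 - q^(n2 + k)) / (1 - q^k); division is exact
    poly <- poly_mul_cyclotomic(poly, n2 + k, k, n1 * n2)
  }
  poly / sum(poly)
}

# poly * (1 - q^a) / (1 - q^b), truncated at degree maxdeg (exact for
# Gaussian binomials, where the division is exact).
poly_mul_cyclotomic <- function(poly, a, b, maxdeg) {
  p <- numeric(maxdeg + 1)
  p[seq_along(poly)] <- poly
  # multiply by (1 - q^a)
  q <- p
  if (a <= maxdeg) {
    q[(a + 1):(maxdeg + 1)] <- q[(a + 1):(maxdeg + 1)] - p[1:(maxdeg + 1 - a)]
  }
  # divide by (1 - q^b): r satisfies r - shift(r, b) = q
  r <- q
  if (b <= maxdeg) {
    for (i in (b + 1):(maxdeg + 1)) r[i] <- r[i] + r[i - b]
  }
  r
}

#' @export
print.defensome_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Per-family enrichment test with Benjamini-Hochberg correction
#'
#' For each family, a two-sided Fisher exact test on the 2x2 table
#' (this family vs all other families) x (in vs out), e.g. counts inside
#' versus outside defense islands. P-values are Benjamini-Hochberg adjusted
#' across families. The odds ratio is the sample cross-product ratio with
#' the convention `Inf` when the denominator is zero and the numerator is
#' positive.
#'
#' @param counts_in named integer vector: per-family counts in the focal
#'   compartment.
#' @param counts_out named integer vector (same families): counts outside.
#' @return data.frame: `family`, `in_focal`, `out_focal`, `odds_ratio`,
#'   `p_value`, `adjusted_p`, `method`. All-zero tables are skipped.
#' @export
enrichment_test <- function(counts_in, counts_out) {
  fams <- union(names(counts_in), names(counts_out))
  ci <- stats::setNames(rep(0L, length(fams)), fams)
  co <- ci
  ci[names(counts_in)] <- as.integer(counts_in)
  co[names(counts_out)] <- as.integer(counts_out)
  tot_in <- sum(ci)
  tot_out <- sum(co)
  rows <- lapply(fams, function(f) {
    tab <- matrix(c(ci[f], tot_in - ci[f], co[f], tot_out - co[f]),
                  nrow = 2)
    if (sum(tab) == 0) return(NULL)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    orat <- if (tab[2, 1] * tab[1, 2] == 0) {
      if (tab[1, 1] * tab[2, 2] > 0) Inf else NaN
    } else {
      (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
    }
    data.frame(family = f, in_focal = ci[f], out_focal = co[f],
               odds_ratio = orat, p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(family = character(0), in_focal = integer(0),
                      out_focal = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), adjusted_p = numeric(0),
                      method = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$method <- "Fisher exact + BH"
  rownames(out) <- NULL
  out
}

#' Correlation between density and genome size
#'
#' Spearman rank correlation (tie-aware ranks) between per-genome densities
#' and genome sizes, the robust choice for the heavy-tailed density
#' distribution.
#'
#' @param densities numeric vector of densities.
#' @param genome_sizes paired numeric vector of genome sizes.
#' @return `defensome_test` with `statistic` = rho.
#' @export
correlate_density_size <- function(densities, genome_sizes) {
  if (length(densities) != length(genome_sizes) || length(densities) < 3) {
    stop("correlate_density_size: need >= 3 paired observations",
         call. = FALSE)
  }
  if (length(unique(densities)) == 1 || length(unique(genome_sizes)) == 1) {
    stop("correlate_density_size: constant vector, correlation undefined",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(densities, genome_sizes, method = "spearman",
                    alternative = "two.sided"))
  structure(list(statistic = unname(ct$estimate), p_value = ct$p.value,
                 method = "Spearman rank correlation",
                 n1 = length(densities), n2 = length(genome_sizes),
                 adjusted_p = NA_real_),
            class = "defensome_test")
}
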