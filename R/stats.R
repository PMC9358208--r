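#' Spearman rank correlation with midranks
#'
#' Ties receive midranks and the coefficient is the Pearson correlation of
#' the two rank vectors. With tied data this differs from the
#' `1 - 6*sum(d^2)/(n^3 - n)` shortcut, and it is the convention that
#' reproduces the published per-cohort coefficients; on tie-free data the
#' two agree exactly.
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @return the rank correlation coefficient in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop_ich("x and y must have equal length", "ich_domain_error")
  if (length(x) < 3) stop_ich("need at least 3 observations", "ich_domain_error")
  if (anyNA(x) || anyNA(y)) stop_ich("missing values not allowed", "ich_domain_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ich("correlation undefined for a constant vector", "ich_domain_error")
  stats::cor(rank(x), rank(y))
}

#' P-value for a Spearman coefficient
#'
#' `t_approx`: two-sided p from `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom. `exact_perm`: the proportion of permutations of a
#' tie-free rank vector whose |r| reaches the observed value — full
#' enumeration for n <= 8, Monte Carlo (fixed internal seed, `nsim` draws)
#' above.
#'
#' @param r observed coefficient.
#' @param n sample size.
#' @param method `"t_approx"` or `"exact_perm"`.
#' @param nsim Monte Carlo permutations when n > 8.
#' @return two-sided p-value. For |r| = 1 under `t_approx` the p is the 0
#'   sentinel with attribute `"degenerate" = TRUE`.
#' @export
spearman_p <- function(r, n, method = c("t_approx", "exact_perm"), nsim = 20000L) {
  method <- match.arg(method)
  if (n < 3) stop_ich("need n >= 3", "ich_domain_error")
  if (abs(r) > 1 + 1e-12) stop_ich("|r| must be <= 1", "ich_domain_error")
  if (method == "t_approx") {
    if (abs(r) >= 1) {
      out <- 0
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    t <- r * sqrt((n - 2) / (1 - r^2))
    return(2 * stats::pt(-abs(t), df = n - 2))
  }
  base <- seq_len(n)
  if (n <= 8) {
    pm <- perms(n)
    rs <- apply(pm, 1, function(p) stats::cor(base, p))
    mean(abs(rs) >= abs(r) - 1e-12)
  } else {
    with_seed(20220725, {
      rs <- replicate(nsim, stats::cor(base, sample(base)))
      mean(abs(rs) >= abs(r) - 1e-12)
    })
  }
}

#' Bonferroni correction
#'
#' @param p_raw raw p-value(s).
#' @param m number of comparisons in the family (>= 1).
#' @return `min(1, m * p_raw)`.
#' @export
bonferroni <- function(p_raw, m) {
  if (m < 1) stop_ich("family size m must be >= 1", "ich_domain_error")
  pmin(1, m * p_raw)
}

#' Power of a correlation test (Fisher-z approximation)
#'
#' `power = pnorm(sqrt(n - 3) * atanh(|rho|) - z_(1-alpha/2))`: the normal
#' approximation on the Fisher-transformed scale with two-sided alpha,
#' ignoring the negligible opposite tail. At rho = 0 this returns alpha/2
#' (the one-tail size). An approximation to the dedicated power software
#' used for the published analysis; agrees at this study's n.
#'
#' @param rho population correlation under the alternative.
#' @param n sample size (> 3).
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
correlation_power <- function(rho, n, alpha = 0.05) {
  if (n <= 3) stop_ich("power undefined for n <= 3", "ich_domain_error")
  if (abs(rho) >= 1) stop_ich("|rho| must be < 1", "ich_domain_error")
  stats::pnorm(sqrt(n - 3) * atanh(abs(rho)) - stats::qnorm(1 - alpha / 2))
}

#' Two-tailed unpaired Mann-Whitney rank test
#'
#' U from rank sums with midranks. The two-sided p is exact (enumeration of
#' all group assignments) when `n1 + n2 <= 12` and there are no ties,
#' otherwise a normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b numeric group vectors (nonempty).
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @return a `group_comparison` list: `u_statistic` (U of the first group),
#'   `p_two_sided`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (length(a) == 0 || length(b) == 0) stop_ich("empty group", "ich_domain_error")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (method == "auto") method <- if (n1 + n2 <= 12 && !ties) "exact" else "approx"
  if (method == "exact") {
    if (ties) stop_ich("exact method requires tie-free data", "ich_domain_error")
    combs <- utils::combn(n1 + n2, n1)
    allrk <- rank(pooled)  # tie-free: a permutation of 1..n
    us <- apply(combs, 2, function(ix) sum(sort(allrk)[ix]) - n1 * (n1 + 1) / 2)
    p <- min(1, 2 * min(mean(us <= u1 + 1e-9), mean(us >= u1 - 1e-9)))
  } else {
    n <- n1 + n2
    tab <- table(pooled)
    tiesum <- sum(tab^3 - tab)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tiesum / (n * (n - 1)))
    if (sigma2 <= 0) stop_ich("zero variance: all values tied", "ich_domain_error")
    z <- (u1 - n1 * n2 / 2)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(u_statistic = u1, p_two_sided = p, n1 = n1, n2 = n2,
                 method = method), class = "group_comparison")
}

#' Hedge's g corrected effect size
#'
#' Cohen's d with pooled SD, corrected for small samples either by the
#' standard factor `J = 1 - 3/(4(n1+n2) - 9)` or by a fixed percentage
#' (the published analysis quotes a "< 4%" correction for n < 20; the
#' standard factor at that n is larger, so both modes are provided).
#'
#' @param a,b numeric group vectors.
#' @param correction `"standard_J"` or `"fixed_percent"`.
#' @param q fixed-percent correction (used only for `"fixed_percent"`).
#' @return corrected effect size g.
#' @export
hedges_g <- function(a, b, correction = c("standard_J", "fixed_percent"), q = 0.04) {
  correction <- match.arg(correction)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop_ich("need at least 2 observations per group", "ich_domain_error")
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
  if (sp == 0) stop_ich("pooled sd is zero: effect size undefined", "ich_domain_error")
  d <- (mean(a) - mean(b)) / sp
  factor <- if (correction == "standard_J") 1 - 3 / (4 * (n1 + n2) - 9) else 1 - q
  d * factor
}

#' Composite severity marker
#'
#' Per-patient arithmetic sum of the named components. Neutrophil counts
#' enter on the K/uL scale: the raw cells/uL scale cannot reproduce the
#' published combinatorial coefficients, while K/uL reproduces every row, so
#' the K/uL convention is fixed here. Count columns named `*_count` are
#' converted automatically; all other components enter raw.
#'
#' @param cohort a `cohort_table`.
#' @param components character vector of column names, e.g.
#'   `c("ich_score", "nlr", "rogue_n_count", "net_n_count")`.
#' @return numeric vector of per-patient sums.
#' @export
composite_marker <- function(cohort, components) {
  vals <- rep(0, nrow(cohort))
  for (comp in components) {
    col <- comp
    v <- cohort[[col]]
    if (is.null(v)) stop_ich(paste0("unknown component: ", comp), "ich_config_error")
    if (grepl("_count$", col)) v <- counts_to_k(v)
    if (anyNA(v))
      stop_ich(paste0("missing value in component '", comp, "' for patient id ",
                      cohort$id[which(is.na(v))[1]]), "ich_validation_error")
    vals <- vals + v
  }
  vals
}

#' Correlation report over variable pairs
#'
#' For each (x, y) pair: the midrank Spearman r, raw t-approximation p,
#' Bonferroni-corrected p for family size `m`, Fisher-z power at the
#' observed r, and a strength class: `strong` when |r| > 0.7 and
#' power > 0.8 and corrected p < alpha; `moderate` when corrected p < alpha
#' but not strong; otherwise `n.s.`.
#'
#' @param cohort a `cohort_table` (or any data frame of numeric columns).
#' @param pairs two-column character matrix (or list of length-2 vectors)
#'   naming the variables to correlate. A name may also be a composite
#'   given as components separated by `"+"`, e.g.
#'   `"ich_score+nlr"`; counts in composites follow [composite_marker()].
#' @param m Bonferroni family size.
#' @param alpha significance level.
#' @return data frame with one row per pair: x, y, r, n, p_raw, p_bonf,
#'   power, strength_class.
#' @export
correlation_report <- function(cohort, pairs, m = 1, alpha = 0.05) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  stopifnot(ncol(pairs) == 2)
  resolve <- function(name) {
    comps <- trimws(strsplit(name, "+", fixed = TRUE)[[1]])
    composite_marker(cohort, comps)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- resolve(pairs[i, 1]); y <- resolve(pairs[i, 2])
    r <- spearman(x, y)
    p <- as.numeric(spearman_p(r, length(x)))
    pb <- bonferroni(p, m)
    pw <- if (abs(r) >= 1) 1 else correlation_power(r, length(x), alpha)
    cls <- if (abs(r) > 0.7 && pw > 0.8 && pb < alpha) "strong"
           else if (pb < alpha) "moderate" else "n.s."
    data.frame(x = pairs[i, 1], y = pairs[i, 2], r = r, n = length(x),
               p_raw = p, p_bonf = pb, power = pw, strength_class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published-table reproductions from the cohort
#'
#' `severity_table2()`: correlations among radiological and clinical
#' severity measures (IPH and PHE volume rows). `severity_table3()`: the
#' three neutrophil markers against clinical and radiological measures.
#' `severity_table4()`: the combinatorial ICH-score + neutrophil-marker
#' composites against 90-day mRS.
#'
#' @param cohort a `cohort_table`, default the packaged 13-patient fixture.
#' @param m Bonferroni family size (the corrected p values depend on it;
#'   the r values do not).
#' @param alpha significance level.
#' @return a [correlation_report()] data frame.
#' @export
severity_table2 <- function(cohort = ich_cohort(), m = 1, alpha = 0.05) {
  vars <- c("ich_score", "gcs", "mrs_90d", "iph_vol", "phe_vol", "mgs")
  pairs <- rbind(
    cbind("iph_vol", setdiff(vars, "iph_vol")),
    cbind("phe_vol", setdiff(vars, "phe_vol")))
  correlation_report(cohort, pairs, m = m, alpha = alpha)
}

#' @rdname severity_table2
#' @export
severity_table3 <- function(cohort = ich_cohort(), m = 1, alpha = 0.05) {
  markers <- c("rogue_n_count", "net_n_count", "nlr")
  measures <- c("gcs", "ich_score", "mrs_90d", "iph_vol", "phe_vol")
  pairs <- as.matrix(expand.grid(markers, measures, stringsAsFactors = FALSE))
  correlation_report(cohort, pairs, m = m, alpha = alpha)
}

#' @rdname severity_table2
#' @export
severity_table4 <- function(cohort = ich_cohort(), m = 1, alpha = 0.05) {
  combos <- c("ich_score",
              "ich_score+nlr",
              "ich_score+rogue_n_count",
              "ich_score+net_n_count",
              "ich_score+nlr+rogue_n_count+net_n_count")
  pairs <- cbind(combos, "mrs_90d")
  correlation_report(cohort, pairs, m = m, alpha = alpha)
}
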