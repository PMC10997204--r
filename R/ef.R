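#' Through-origin total least squares slope
#'
#' Fits the no-intercept errors-in-variables line `y = s * x` by minimising
#' the summed squared orthogonal distances `sum((y - s x)^2) / (1 + s^2)`.
#' The minimiser solves the quadratic `s^2 Sxy + s (Sxx - Syy) - Sxy = 0`
#' (with `Sxx = sum(x^2)` etc.), and the root that minimises the objective is
#' returned in closed form. The 95% confidence interval is a nonparametric
#' percentile bootstrap over the paired observations (experiments); the
#' Pearson correlation and its two-sided p-value (t-test on r with n - 2 df)
#' are computed on the paired values, optionally after log transformation.
#'
#' @param x,y Paired positive finite numeric vectors (water- and
#'   SSA-side sodium-normalised concentrations).
#' @param n_boot Number of bootstrap resamples for the CI (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @param cor_on Compute Pearson r/p on `"raw"` (default) or `"log"`
#'   transformed values.
#' @return A one-row tibble: `slope`, `ci_low`, `ci_high`, `r`, `p_value`,
#'   `n`.
#' @examples
#' tls_slope(1:10, 3 * (1:10), n_boot = 200, seed = 1)
#' @export
tls_slope <- function(x, y, n_boot = 2000, conf = 0.95, seed = NULL,
                      cor_on = c("raw", "log")) {
  cor_on <- match.arg(cor_on)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("at least 3 paired points are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("x and y must be finite")
  }
  if (any(x <= 0)) abort("x must be > 0")
  if (sd(x) == 0) abort("degenerate input: all x identical")

  slope <- tls_slope_closed_form(x, y)

  if (cor_on == "log") {
    ok <- y > 0
    ct <- cor.test(log(x[ok]), log(y[ok]), alternative = "two.sided")
  } else {
    ct <- cor.test(x, y, alternative = "two.sided")
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  xb <- matrix(x[idx], nrow = n_boot)
  yb <- matrix(y[idx], nrow = n_boot)
  sxx <- rowSums(xb * xb)
  syy <- rowSums(yb * yb)
  sxy <- rowSums(xb * yb)
  boots <- tls_root(sxx, syy, sxy)
  alpha <- 1 - conf
  ci <- quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                 names = FALSE)

  tibble(slope = slope, ci_low = ci[1], ci_high = ci[2],
         r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' @noRd
tls_slope_closed_form <- function(x, y) {
  tls_root(sum(x * x), sum(y * y), sum(x * y))
}

# Root of s^2 Sxy + s (Sxx - Syy) - Sxy = 0 minimising the orthogonal
# objective; vectorised over the sums. Sxy == 0 gives slope 0 (flat line).
#' @noRd
tls_root <- function(sxx, syy, sxy) {
  disc <- sqrt((sxx - syy)^2 + 4 * sxy^2)
  s <- ifelse(sxy == 0, 0, (syy - sxx + disc) / (2 * sxy))
  s
}

#' Geometric mean of enrichment factors with a log-scale t-interval
#'
#' The geometric mean `exp(mean(log(ef)))` with a 95% confidence interval
#' from a t-interval on the natural-log scale, back-transformed. With a
#' single value the CI is `NA`.
#'
#' @param efs Positive numeric vector of per-experiment EFs.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `gmean`, `ci_low`, `ci_high`, `n`.
#' @examples
#' geometric_mean_ef(c(10, 1000))
#' @export
geometric_mean_ef <- function(efs, conf = 0.95) {
  efs <- efs[!is.na(efs)]
  if (!length(efs)) abort("no EF values")
  if (any(efs <= 0)) abort("all EFs must be > 0")
  lx <- log(efs)
  n <- length(lx)
  m <- mean(lx)
  if (n >= 2) {
    se <- sd(lx) / sqrt(n)
    tq <- qt(1 - (1 - conf) / 2, df = n - 1)
    ci <- exp(m + c(-1, 1) * tq * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  tibble(gmean = exp(m), ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Per-experiment enrichment factors
#'
#' Computes, for every experiment x homolog x fraction with a usable
#' (non-excluded) SSA sample, the enrichment factor
#' `EF = ([PFAA]_SSA / [Na+]_SSA) / ([PFAA]_seawater / [Na+]_seawater)`.
#' The water concentration of an experiment is the mean of its triplicate
#' cartridges after MDL substitution. Excluded SSA samples yield no EF
#' (skipped, not zero).
#'
#' @param chamber A [chamber_data()] object that has been through
#'   [substitute_censored()].
#' @return Tibble: `experiment`, `homolog`, `fraction`, `water_ratio`,
#'   `ssa_ratio`, `ef`, `water_substituted` (any replicate substituted).
#' @export
per_experiment_ef <- function(chamber) {
  stopifnot(inherits(chamber, "chamber_data"))
  if (is.null(chamber$ssa$excluded)) {
    abort("run substitute_censored() before per_experiment_ef()")
  }

  water <- chamber$water %>%
    group_by(.data$experiment, .data$homolog) %>%
    summarise(
      water_conc = mean(.data$conc),
      water_substituted = any(.data$flag == "substituted"),
      .groups = "drop"
    ) %>%
    left_join(chamber$water_na, by = "experiment") %>%
    mutate(water_ratio = .data$water_conc / .data$na_conc) %>%
    select("experiment", "homolog", "water_ratio", "water_substituted")

  chamber$ssa %>%
    filter(!.data$excluded) %>%
    left_join(chamber$ssa_na, by = c("experiment", "fraction")) %>%
    mutate(ssa_ratio = .data$conc / .data$na_conc) %>%
    inner_join(water, by = c("experiment", "homolog")) %>%
    mutate(ef = .data$ssa_ratio / .data$water_ratio) %>%
    select("experiment", "homolog", "fraction", "water_ratio", "ssa_ratio",
           "ef", "water_substituted") %>%
    arrange(.data$homolog, .data$fraction, .data$experiment)
}

#' Select the EF estimate for one homolog and size fraction
#'
#' Applies the selection rule: if the Pearson correlation between the
#' sodium-normalised water and SSA concentrations is significant
#' (p < alpha, strict), the mean EF is the slope of the through-origin total
#' least squares regression; otherwise the geometric mean of the
#' per-experiment EFs is used. Fewer than 3 points fall back to the
#' geometric mean.
#'
#' @param pairs Tibble with columns `water_ratio`, `ssa_ratio`, `ef` for one
#'   homolog x fraction (one row per experiment).
#' @param alpha Significance level for the slope method (default 0.05).
#' @inheritParams tls_slope
#' @return One-row tibble: `method` (`"slope"` or `"gmean"`), `ef`,
#'   `ci_low`, `ci_high`, `r`, `p_value`, `n`.
#' @export
select_ef <- function(pairs, alpha = 0.05, n_boot = 2000, conf = 0.95,
                      seed = NULL, cor_on = c("raw", "log")) {
  cor_on <- match.arg(cor_on)
  n <- nrow(pairs)
  if (n == 0) abort("no usable points")
  fit <- NULL
  if (n >= 3 && sd(pairs$water_ratio) > 0) {
    fit <- tls_slope(pairs$water_ratio, pairs$ssa_ratio, n_boot = n_boot,
                     conf = conf, seed = seed, cor_on = cor_on)
  }
  if (!is.null(fit) && is.finite(fit$p_value) && fit$p_value < alpha) {
    tibble(method = "slope", ef = fit$slope, ci_low = fit$ci_low,
           ci_high = fit$ci_high, r = fit$r, p_value = fit$p_value, n = n)
  } else {
    gm <- geometric_mean_ef(pairs$ef, conf = conf)
    tibble(method = "gmean", ef = gm$gmean, ci_low = gm$ci_low,
           ci_high = gm$ci_high,
           r = if (is.null(fit)) NA_real_ else fit$r,
           p_value = if (is.null(fit)) NA_real_ else fit$p_value, n = n)
  }
}

#' Fit enrichment factors for all homologs and size fractions
#'
#' The full EF-estimation pipeline for a chamber campaign: substitute
#' left-censored values, gate homologs on water detection frequency,
#' compute per-experiment EFs, and for each homolog x fraction select the
#' slope or geometric-mean estimate with its 95% CI. Homologs failing the
#' gate are reported with `method = "not_calculated"`.
#'
#' @param chamber A [chamber_data()] object (censoring handled internally).
#' @param scheme A [size_fraction_scheme()]; supplies `dp_um` per fraction.
#' @param alpha Significance level for choosing the slope method.
#' @param df_threshold Water detection-frequency threshold (strict `>`).
#' @param n_boot Bootstrap resamples for slope CIs.
#' @param seed Integer seed controlling all bootstrap resampling.
#' @param cor_on Pearson test on `"raw"` (default) or `"log"` values.
#' @return An object of class `ef_fit`: a list with `records` (the EF
#'   table), `per_experiment` (per-experiment EFs), `gate` (detection
#'   frequencies), and the call parameters. `tidy()` returns the records,
#'   `glance()` a one-row summary, and `autoplot()` an EF-vs-diameter panel.
#' @examples
#' sim <- gen_chamber_experiments(chamber_config(seed = 7))
#' fit <- ef_fit(sim$chamber, n_boot = 200, seed = 1)
#' tidy(fit)
#' @export
ef_fit <- function(chamber, scheme = size_fraction_scheme(), alpha = 0.05,
                   df_threshold = 0.30, n_boot = 2000, seed = 1L,
                   cor_on = c("raw", "log")) {
  cor_on <- match.arg(cor_on)
  chamber <- substitute_censored(chamber)
  gate <- detection_frequency_gate(chamber$water, threshold = df_threshold)
  pe <- per_experiment_ef(chamber)

  eligible <- gate$homolog[gate$eligible]
  combos <- pe %>%
    filter(.data$homolog %in% eligible) %>%
    distinct(.data$homolog, .data$fraction)

  records <- purrr::pmap_dfr(combos, function(homolog, fraction) {
    pairs <- pe[pe$homolog == homolog & pe$fraction == fraction, ]
    # derive a reproducible per-combination bootstrap seed from the master
    sub_seed <- (seed * 10007L + fraction * 101L +
                   sum(utf8ToInt(homolog))) %% .Machine$integer.max
    sel <- select_ef(pairs, alpha = alpha, n_boot = n_boot,
                     seed = sub_seed, cor_on = cor_on)
    tibble(homolog = homolog, fraction = fraction) %>% dplyr::bind_cols(sel)
  })

  gated_out <- gate %>%
    filter(!.data$eligible) %>%
    mutate(method = "not_calculated", ef = NA_real_, ci_low = NA_real_,
           ci_high = NA_real_, r = NA_real_, p_value = NA_real_,
           n = 0L) %>%
    select("homolog", "method", "ef", "ci_low", "ci_high", "r",
           "p_value", "n")

  records <- bind_rows(records, gated_out) %>%
    left_join(scheme %>% select("fraction", "dp_um"), by = "fraction") %>%
    arrange(.data$homolog, .data$fraction)

  structure(
    list(records = records, per_experiment = pe, gate = gate,
         scheme = scheme, alpha = alpha, df_threshold = df_threshold,
         n_boot = n_boot, seed = seed, cor_on = cor_on),
    class = "ef_fit"
  )
}

#' @export
print.ef_fit <- function(x, ...) {
  cat("<ef_fit>\n")
  cat("  homologs gated in:", sum(x$gate$eligible), "of", nrow(x$gate), "\n")
  cat("  EF records:", sum(!is.na(x$records$ef)), "\n")
  mt <- table(x$records$method)
  cat("  methods:", paste(names(mt), mt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ef_fit
#' @param x,object An `ef_fit` object.
#' @param ... Unused.
#' @method tidy ef_fit
#' @export
tidy.ef_fit <- function(x, ...) x$records

#' @rdname ef_fit
#' @method glance ef_fit
#' @export
glance.ef_fit <- function(x, ...) {
  tibble(
    n_homologs = nrow(x$gate),
    n_eligible = sum(x$gate$eligible),
    n_records = sum(!is.na(x$records$ef)),
    n_slope = sum(x$records$method == "slope"),
    n_gmean = sum(x$records$method == "gmean"),
    alpha = x$alpha,
    df_threshold = x$df_threshold
  )
}

#' Log-log regression of EF against particle diameter
#'
#' Ordinary least squares of `log10(EF)` on `log10(dp)` across the
#' supermicrometre size fractions of one homolog, quantifying the power-law
#' dependence of enrichment on particle size.
#'
#' @param records EF records (the `records` tibble of an [ef_fit()] or any
#'   tibble with `homolog`, `ef`, `dp_um`) for a single homolog.
#' @param dp_min_um Only fractions with `dp_um` above this value enter the
#'   fit (default 1, i.e. supermicrometre).
#' @return One-row tibble: `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
ef_vs_diameter_regression <- function(records, dp_min_um = 1) {
  d <- records %>%
    filter(!is.na(.data$ef), !is.na(.data$dp_um), .data$dp_um > dp_min_um)
  if (dplyr::n_distinct(d$homolog) > 1) {
    abort("supply records for a single homolog")
  }
  if (nrow(d) < 3) abort("at least 3 supermicrometre fractions are required")
  lx <- log10(d$dp_um)
  ly <- log10(d$ef)
  fit <- lm(ly ~ lx)
  ct <- cor.test(lx, ly, alternative = "two.sided")
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}
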