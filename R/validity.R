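# Known-groups construct validity: store-type contrasts on total score and
# availability, and healthier-vs-regular price contrasts.

#' Pooled-variance two-sample t test
#'
#' Student's t test (equal-variance, two-sided) comparing two groups of store
#' total scores, with group summaries. When the pooled variance is zero and
#' the means are equal, the groups are indistinguishable and `p = 1`.
#'
#' @param x,y Numeric samples for the two groups (each n >= 2).
#' @param labels Length-2 character vector of group labels.
#' @return A list with `statistic` (t), `df`, `p_value`, and `groups` (a
#'   tibble of label, n, mean, sd).
#' @examples
#' students_t(c(30, 32, 34), c(1, 2, 3))
#' @export
students_t <- function(x, y, labels = c("group1", "group2")) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  groups <- tibble(group = labels, n = c(length(x), length(y)),
                   mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)))
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1, groups = groups))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p_value = 0, groups = groups))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, groups = groups)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by full hypergeometric enumeration with fixed
#' margins: all tables whose point probability does not exceed the observed
#' table's (within a small relative tolerance for floating-point ties)
#' contribute to p. Rows are the two groups, columns the yes/no counts.
#'
#' @param tab A 2x2 matrix of non-negative integer counts, or the count `a`
#'   with `b`, `c`, `d` supplied separately.
#' @param b,c,d Remaining cell counts when `tab` is given as a scalar.
#' @return A list with `p_value`, `table`, and `method`.
#' @examples
#' fisher_exact_2x2(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))$p_value  # 0.023
#' fisher_exact_2x2(5, 5, 5, 5)$p_value                              # 1
#' @export
fisher_exact_2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == 2))
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  } else {
    a <- tab
    stopifnot(!is.null(b), !is.null(c), !is.null(d))
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  m <- matrix(cells, 2, 2, byrow = TRUE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(p_value = 1, table = m, method = "Fisher exact (two-sided)"))
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p), table = m, method = "Fisher exact (two-sided)")
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' For paired samples (healthier and regular price in the same store). Zero
#' differences are discarded; absolute differences are mid-ranked. With at
#' most `exact_max` informative pairs the null distribution of the
#' positive-rank sum is enumerated exhaustively over all sign assignments
#' and the two-sided p is twice the smaller tail (capped at 1); above that,
#' a normal approximation with tie correction and continuity correction is
#' used. With no nonzero differences `p = 1`.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_max Largest number of informative pairs for which the exact
#'   enumeration is used (default 15).
#' @return A list with `statistic` (V, the positive-rank sum), `n_pairs`
#'   (informative pairs), `p_value`, and `method`.
#' @examples
#' wilcoxon_signed_rank(c(6.1, 6.4, 6.0, 6.6), c(2.4, 2.5, 2.4, 2.6))
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 15L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, n_pairs = 0L, p_value = 1,
                method = "Wilcoxon signed rank (no nonzero differences)"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # all 2^n sign assignments; distribution of the positive-rank sum
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.vector(signs %*% r)
    p <- 2 * min(mean(sums <= v + 1e-9), mean(sums >= v - 1e-9))
    method <- "Wilcoxon signed rank (exact enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "Wilcoxon signed rank (normal approximation, tie-corrected)"
  }
  list(statistic = v, n_pairs = n, p_value = min(1, p), method = method)
}

#' Percent price premium of the healthier option
#'
#' `100 * (mean_healthier - mean_regular) / mean_regular`, rounded to the
#' nearest integer percent.
#'
#' @param mean_healthier,mean_regular Mean prices (same unit);
#'   `mean_regular` must be positive.
#' @return Integer percent (vectorized).
#' @examples
#' price_premium(6.19, 2.45)  # 153
#' price_premium(7.07, 6.80)  # 4
#' @export
price_premium <- function(mean_healthier, mean_regular) {
  if (any(mean_regular <= 0))
    stop("mean_regular must be positive")
  as.integer(round(100 * (mean_healthier - mean_regular) / mean_regular))
}

#' Format p-values in table style
#'
#' Three decimals, with values below 0.001 shown as `"<0.001"`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Store-type availability comparison table
#'
#' For one rater's audits: the percent of stores of each type offering each
#' measure's healthier option (beverages collapsed to any-subitem-available),
#' the underlying 2x2 counts, and the two-sided Fisher exact p-value for the
#' store-type contrast.
#'
#' @param audits Long-format audit tibble containing both store types.
#' @param instrument A `cnemss_instrument`.
#' @param rater Rater id to tabulate (default: first rater in the data).
#' @return A tibble with one row per measure: counts and percentages by
#'   store type, `p_value`, `p_formatted`.
#' @examples
#' audits <- generate_audits(default_sim_config(), seed = 1)
#' availability_table(audits, nemss_instrument(), rater = "R1")
#' @export
availability_table <- function(audits, instrument, rater = NULL) {
  audits <- as_tibble(audits)
  if (is.null(rater)) rater <- sort(unique(audits$rater_id))[1]
  aud <- audits[audits$rater_id == rater, ]
  types <- sort(unique(aud$store_type))
  if (!all(c("convenience", "large_supermarket") %in% types))
    stop("both store types (large_supermarket, convenience) must be present")
  ma <- measure_availability(aud, instrument)
  rows <- lapply(measure_ids(instrument), function(id) {
    w <- ma[ma$measure_id == id, ]
    sup <- w[w$store_type == "large_supermarket", ]
    con <- w[w$store_type == "convenience", ]
    a <- sum(sup$available); b <- nrow(sup) - a
    cc <- sum(con$available); d <- nrow(con) - cc
    ft <- fisher_exact_2x2(a, b, cc, d)
    tibble(measure_id = id,
           n_supermarket = nrow(sup), n_convenience = nrow(con),
           available_supermarket = a, available_convenience = cc,
           pct_supermarket = 100 * a / nrow(sup),
           pct_convenience = 100 * cc / nrow(con),
           p_value = ft$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_formatted <- format_p(out$p_value)
  out
}

#' Healthier-vs-regular price comparison table
#'
#' For one rater's audits and every priced scoring unit: mean and sample SD
#' (n-1 denominator) of the healthier and regular prices over the stores
#' where both were recorded, the paired two-sided Wilcoxon signed-rank
#' p-value across those stores, and the integer percent price premium.
#' Units with no complete price pair are emitted with undefined (`NA`)
#' summaries and p.
#'
#' @inheritParams availability_table
#' @return A tibble with one row per priced (measure, subitem) unit:
#'   `n_pairs`, `mean_healthier`, `sd_healthier`, `mean_regular`,
#'   `sd_regular`, `premium_pct`, `p_value`, `p_formatted`.
#' @examples
#' audits <- generate_audits(default_sim_config(), seed = 1)
#' price_comparison(audits, nemss_instrument(), rater = "R1")
#' @export
price_comparison <- function(audits, instrument, rater = NULL) {
  audits <- as_tibble(audits)
  if (is.null(rater)) rater <- sort(unique(audits$rater_id))[1]
  aud <- audits[audits$rater_id == rater, ]
  units <- scoring_units(instrument)
  units <- units[units$measure_id %in% priced_measures(instrument), ]
  rows <- lapply(seq_len(nrow(units)), function(i) {
    w <- aud[aud$measure_id == units$measure_id[i] &
               (is.na(units$subitem_id[i]) |
                  (!is.na(aud$subitem_id) &
                     aud$subitem_id == units$subitem_id[i])), ]
    ok <- !is.na(w$price_healthier) & !is.na(w$price_regular)
    w <- w[ok, ]
    np <- nrow(w)
    if (np == 0) {
      return(tibble(measure_id = units$measure_id[i],
                    subitem_id = units$subitem_id[i], n_pairs = 0L,
                    mean_healthier = NA_real_, sd_healthier = NA_real_,
                    mean_regular = NA_real_, sd_regular = NA_real_,
                    premium_pct = NA_integer_, p_value = NA_real_))
    }
    wt <- wilcoxon_signed_rank(w$price_healthier, w$price_regular)
    mh <- mean(w$price_healthier); mr <- mean(w$price_regular)
    tibble(measure_id = units$measure_id[i],
           subitem_id = units$subitem_id[i], n_pairs = np,
           mean_healthier = mh,
           sd_healthier = if (np > 1) sd(w$price_healthier) else 0,
           mean_regular = mr,
           sd_regular = if (np > 1) sd(w$price_regular) else 0,
           premium_pct = if (mr > 0) price_premium(mh, mr) else NA_integer_,
           p_value = wt$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_formatted <- format_p(out$p_value)
  out
}

#' Total-score comparison by store type
#'
#' Per rater: Student's t comparison of total C-NEMS-S scores between large
#' supermarkets and convenience stores, with group means and SDs.
#'
#' @inheritParams availability_table
#' @return A tibble with one row per rater: group summaries, `statistic`,
#'   `p_value`, `p_formatted`.
#' @export
total_score_comparison <- function(audits, instrument) {
  scores <- score_stores(audits, instrument)
  rows <- lapply(sort(unique(scores$rater_id)), function(r) {
    w <- scores[scores$rater_id == r, ]
    sup <- w$total[w$store_type == "large_supermarket"]
    con <- w$total[w$store_type == "convenience"]
    tt <- students_t(sup, con, labels = c("large_supermarket", "convenience"))
    tibble(rater_id = r,
           n_supermarket = length(sup), mean_supermarket = mean(sup),
           sd_supermarket = sd(sup),
           n_convenience = length(con), mean_convenience = mean(con),
           sd_convenience = sd(con),
           statistic = tt$statistic, p_value = tt$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_formatted <- format_p(out$p_value)
  out
}
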