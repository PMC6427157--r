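# Inter-rater reliability for paired store audits: intraclass correlation
# on availability scores, Cohen's kappa on availability flags, interpretation
# bands, and the per-measure reliability table.

#' Intraclass correlation coefficient, absolute agreement, single rater
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC --
#' ICC(A,1) in the Shrout-Fleiss/McGraw-Wong taxonomy -- computed from the
#' mean-squares decomposition of the stores x raters table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row (store), column
#' (rater) and residual mean squares, \eqn{n} stores and \eqn{k} raters.
#' Absolute agreement penalizes systematic rater offsets, the appropriate
#' choice for two raters scoring the same stores.
#'
#' @param r1,r2 Numeric rating vectors for raters 1 and 2, aligned by store;
#'   length >= 2.
#' @return The ICC (at most 1), or `NA` when the table has zero total
#'   variance so the coefficient is undefined.
#' @examples
#' icc_agreement(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))      # 1
#' icc_agreement(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6)) < 1  # offset penalized
#' @export
icc_agreement <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) >= 2)
  y <- cbind(as.numeric(r1), as.numeric(r2))
  if (anyNA(y)) stop("ratings must not contain NA")
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  if (all(y == y[1])) return(NA_real_)          # zero total variance
  row_m <- rowMeans(y); col_m <- colMeans(y)
  ss_r <- k * sum((row_m - gm)^2)
  ss_c <- n * sum((col_m - gm)^2)
  ss_e <- sum((y - outer(row_m, rep(1, k)) -
                 outer(rep(1, n), col_m) + gm)^2)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  if (denom == 0) return(NA_real_)
  (ms_r - ms_e) / denom
}

#' Cohen's kappa for two raters' yes/no availability flags
#'
#' Chance-corrected agreement \eqn{(p_o - p_e)/(1 - p_e)} with
#' marginal-product expected agreement. When observed agreement is perfect
#' the coefficient is 1 by definition, even when a marginal is degenerate
#' (all-yes or all-no), so unanimously rated measures report kappa = 1
#' rather than an indeterminate 0/0.
#'
#' @param f1,f2 Logical (or two-level) vectors aligned by store; length >= 2.
#' @return Kappa in `[-1, 1]`, or `NA` when expected agreement is 1 with
#'   imperfect observed agreement (undefined).
#' @examples
#' cohen_kappa(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))  # 1
#' cohen_kappa(rep(c(TRUE, FALSE), c(5, 5)),
#'             rep(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1, 4)))  # 0.6
#' @export
cohen_kappa <- function(f1, f2) {
  stopifnot(length(f1) == length(f2), length(f1) >= 2)
  f1 <- as.logical(f1); f2 <- as.logical(f2)
  if (anyNA(f1) || anyNA(f2)) stop("flags must not contain NA")
  n <- length(f1)
  p_o <- mean(f1 == f2)
  if (p_o == 1) return(1)
  p1 <- mean(f1); p2 <- mean(f2)
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  if (p_e == 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Percent agreement between two raters
#'
#' Descriptive fallback reported alongside ICC/kappa, and the only available
#' summary when low between-store variance makes those coefficients
#' undefined.
#'
#' @param f1,f2 Vectors aligned by store.
#' @return Percent of stores on which the raters agree exactly (0-100).
#' @export
percent_agreement <- function(f1, f2) {
  stopifnot(length(f1) == length(f2), length(f1) >= 1)
  100 * mean(f1 == f2)
}

#' Interpretation bands for ICC and kappa
#'
#' ICC: below 0.4 poor, 0.4-0.75 moderate, above 0.75 good. Kappa: below 0.4
#' poor, 0.4-0.6 middle, 0.6-0.8 good, above 0.8 excellent.
#'
#' @param x Numeric vector of coefficient values (`NA` allowed).
#' @return Character vector of band labels (`NA` where `x` is `NA`).
#' @examples
#' interpret_icc(c(0.3, 0.5, 0.98))
#' interpret_kappa(c(0.52, 0.7, 0.95))
#' @export
interpret_icc <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x < 0.4, "poor", ifelse(x > 0.75, "good", "moderate")))
}

#' @rdname interpret_icc
#' @export
interpret_kappa <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x < 0.4, "poor",
                ifelse(x <= 0.6, "middle",
                       ifelse(x <= 0.8, "good", "excellent"))))
}

# Per-store, per-rater availability score and availability flag for each
# measure (beverage subitems summed / any-available collapsed).
measure_availability <- function(audits, instrument) {
  scored <- score_measures(audits, instrument)
  scored %>%
    group_by(.data$store_id, .data$store_type, .data$rater_id,
             .data$measure_id) %>%
    summarise(availability_score = sum(.data$availability_points),
              available = any(as.logical(.data$healthier_available)),
              .groups = "drop")
}

#' Per-measure inter-rater reliability table
#'
#' For every food measure: the absolute-agreement ICC of the two raters'
#' availability scores across stores, Cohen's kappa of their yes/no
#' availability flags, percent agreement, and the interpretation bands. A
#' final `composite` row carries the ICC of the availability subtotal (or of
#' the total score, when `composite = "total"`). Undefined coefficients
#' (zero between-store variance) are reported as `NA` with percent agreement
#' as the descriptive fallback, never as a silent zero.
#'
#' @param audits Long-format audit tibble containing exactly two raters, each
#'   covering every store.
#' @param instrument A `cnemss_instrument`.
#' @param composite Which score the composite ICC row summarizes:
#'   `"availability"` (the availability subtotal, default) or `"total"`.
#' @return A tibble with one row per measure plus one composite row:
#'   `measure_id`, `icc`, `icc_band`, `kappa`, `kappa_band`,
#'   `pct_agreement`.
#' @examples
#' audits <- generate_audits(default_sim_config(), seed = 1)
#' reliability_report(audits, nemss_instrument())
#' @export
reliability_report <- function(audits, instrument,
                               composite = c("availability", "total")) {
  composite <- match.arg(composite)
  audits <- as_tibble(audits)
  raters <- sort(unique(audits$rater_id))
  if (length(raters) != 2L)
    stop(sprintf("paired reliability needs exactly 2 raters, found %d (%s)",
                 length(raters), paste(raters, collapse = ", ")))
  s1 <- sort(unique(audits$store_id[audits$rater_id == raters[1]]))
  s2 <- sort(unique(audits$store_id[audits$rater_id == raters[2]]))
  if (!identical(s1, s2)) {
    odd <- c(setdiff(s1, s2), setdiff(s2, s1))
    stop(sprintf("stores not audited by both raters: %s",
                 paste(odd, collapse = ", ")))
  }

  ma <- measure_availability(audits, instrument)
  rows <- lapply(measure_ids(instrument), function(id) {
    w <- ma[ma$measure_id == id, ]
    w <- tidyr::pivot_wider(w[, c("store_id", "rater_id",
                                  "availability_score", "available")],
                            names_from = "rater_id",
                            values_from = c("availability_score", "available"))
    sc <- as.matrix(w[, paste0("availability_score_", raters)])
    fl <- as.matrix(w[, paste0("available_", raters)])
    tibble(measure_id = id,
           icc = icc_agreement(sc[, 1], sc[, 2]),
           kappa = cohen_kappa(fl[, 1], fl[, 2]),
           pct_agreement = percent_agreement(fl[, 1], fl[, 2]))
  })
  per_measure <- dplyr::bind_rows(rows)

  scores <- score_stores(audits, instrument)
  comp_col <- if (composite == "availability") "availability_subtotal" else "total"
  wide <- tidyr::pivot_wider(scores[, c("store_id", "rater_id", comp_col)],
                             names_from = "rater_id",
                             values_from = all_of(comp_col))
  comp_icc <- icc_agreement(wide[[raters[1]]], wide[[raters[2]]])

  out <- dplyr::bind_rows(
    per_measure,
    tibble(measure_id = "composite", icc = comp_icc, kappa = NA_real_,
           pct_agreement = NA_real_))
  out$icc_band <- interpret_icc(out$icc)
  out$kappa_band <- interpret_kappa(out$kappa)
  out[, c("measure_id", "icc", "icc_band", "kappa", "kappa_band",
          "pct_agreement")]
}
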