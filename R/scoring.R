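# Scoring of store audits against the instrument: per-unit component points,
# per-measure scores, and store subtotals/total.

#' Availability points for one observation
#'
#' Base points when the healthier option is present, plus species-bracket
#' bonus points for variety. The species bonus applies only when the option
#' is present; counts below the lowest bracket earn no bonus. A missing
#' species count on a bracketed measure is an incomplete observation: the
#' bracket component scores 0 with a warning rather than failing the store.
#'
#' @param measure A measure definition from a [nemss_instrument()] (an
#'   element of `instrument$measures`).
#' @param available Logical: is the healthier option (or, for healthy-food
#'   measures, any species) present?
#' @param species_count Non-negative integer count of distinct
#'   species/varieties, or `NA`.
#' @return Integer points.
#' @examples
#' inst <- nemss_instrument()
#' score_availability(inst$measures$grains, TRUE, 4)   # 2 base + 2 bonus
#' score_availability(inst$measures$vegetables, TRUE, 12)
#' @export
score_availability <- function(measure, available, species_count = NA) {
  av <- measure$availability
  if (!isTRUE(available)) return(0L)
  if (!is.null(av$brackets) && nrow(av$brackets) && is.na(species_count))
    warning(sprintf("incomplete observation for '%s': species count missing; bracket component scored 0",
                    measure$id), call. = FALSE)
  av$base_points + bracket_points(av$brackets, as.numeric(species_count))
}

#' Price points for one observation
#'
#' Compares the healthier option's price with the regular option's: points
#' for cheaper (+2), dearer (-1), or equal (+1 for milk, 0 elsewhere). Price
#' is scored 0 (not assessed) when the healthier option is absent or either
#' price is missing, since no comparison pair exists.
#'
#' @inheritParams score_availability
#' @param price_healthier,price_regular Non-negative prices in the measure's
#'   stated unit, or `NA`.
#' @return Integer points.
#' @examples
#' inst <- nemss_instrument()
#' score_price(inst$measures$milk, 3.0, 3.5)   # cheaper: +2
#' score_price(inst$measures$milk, 3.2, 3.2)   # equal (milk only): +1
#' score_price(inst$measures$bread, 7.07, 6.80) # dearer: -1
#' @export
score_price <- function(measure, price_healthier, price_regular,
                        available = TRUE) {
  if (is.null(measure$price)) return(0L)
  if (!isTRUE(available)) return(0L)
  if (is.na(price_healthier) || is.na(price_regular)) return(0L)
  if (price_healthier < 0 || price_regular < 0)
    stop("prices must be non-negative")
  r <- measure$price
  if (price_healthier < price_regular) r$cheaper
  else if (price_healthier > price_regular) r$dearer
  else r$equal
}

#' Quality points for one observation
#'
#' Percent of stock judged acceptable maps onto the quality brackets
#' (25-49% = 1, 50-74% = 2, >=75% = 3); below 25% scores 0. Only measures
#' carrying a quality dimension (vegetables, fruits, seafood) may record a
#' percent-acceptable value.
#'
#' @inheritParams score_availability
#' @param pct_acceptable Percent of stock in acceptable condition, in
#'   `[0, 100]`, or `NA`.
#' @return Integer points.
#' @examples
#' inst <- nemss_instrument()
#' score_quality(inst$measures$fruits, 80)  # 3
#' score_quality(inst$measures$fruits, 30)  # 1
#' @export
score_quality <- function(measure, pct_acceptable) {
  if (is.null(measure$quality)) {
    if (!is.na(pct_acceptable))
      stop(sprintf("measure '%s' has no quality dimension but pct_acceptable was recorded",
                   measure$id))
    return(0L)
  }
  if (is.na(pct_acceptable)) return(0L)
  if (pct_acceptable < 0 || pct_acceptable > 100)
    stop("pct_acceptable must be in [0, 100]")
  bracket_points(measure$quality$brackets, pct_acceptable)
}

# Flat rule table for vectorized scoring: one row per scoring unit.
rules_table <- function(instrument) {
  units <- scoring_units(instrument)
  rows <- lapply(seq_len(nrow(units)), function(i) {
    m <- instrument$measures[[units$measure_id[i]]]
    tibble(
      measure_id = units$measure_id[i],
      subitem_id = units$subitem_id[i],
      base_points = m$availability$base_points,
      brackets = list(m$availability$brackets),
      has_price = !is.null(m$price),
      p_cheaper = if (!is.null(m$price)) m$price$cheaper else 0L,
      p_dearer = if (!is.null(m$price)) m$price$dearer else 0L,
      p_equal = if (!is.null(m$price)) m$price$equal else 0L,
      has_quality = !is.null(m$quality),
      q_brackets = list(if (!is.null(m$quality)) m$quality$brackets)
    )
  })
  dplyr::bind_rows(rows)
}

#' Score every audit in a long-format audit table
#'
#' Computes availability, price and quality points for every observation row
#' and returns per-(measure, subitem) component points. Each (store, rater)
#' audit must cover every scoring unit of the instrument exactly once.
#'
#' @param audits Long-format audit tibble (see [read_audits()] for the
#'   schema).
#' @param instrument A `cnemss_instrument`.
#' @return A tibble: the audit rows plus `availability_points`,
#'   `price_points`, `quality_points`.
#' @seealso [score_stores()] for subtotals and totals.
#' @export
score_measures <- function(audits, instrument) {
  audits <- check_audit_coverage(audits, instrument)
  rules <- rules_table(instrument)
  x <- dplyr::left_join(audits, rules, by = c("measure_id", "subitem_id"))

  avail <- as.logical(x$healthier_available)
  sp <- as.numeric(x$species_count)
  ap <- integer(nrow(x))
  incomplete <- logical(nrow(x))
  for (key in unique(x$measure_id)) {
    idx <- which(x$measure_id == key)
    br <- x$brackets[[idx[1]]]
    base <- x$base_points[idx[1]]
    pts <- ifelse(avail[idx], base + bracket_points(br, sp[idx]), 0L)
    ap[idx] <- as.integer(pts)
    if (!is.null(br) && nrow(br))
      incomplete[idx] <- avail[idx] & is.na(sp[idx])
  }
  if (any(incomplete))
    warning(sprintf("%d incomplete observation(s): species count missing on a bracketed measure; bracket component scored 0",
                    sum(incomplete)), call. = FALSE)

  ph <- as.numeric(x$price_healthier); pr <- as.numeric(x$price_regular)
  if (any(ph < 0, na.rm = TRUE) || any(pr < 0, na.rm = TRUE))
    stop("prices must be non-negative")
  comparable <- x$has_price & avail & !is.na(ph) & !is.na(pr)
  pp <- integer(nrow(x))
  pp[comparable & ph < pr] <- x$p_cheaper[comparable & ph < pr]
  pp[comparable & ph > pr] <- x$p_dearer[comparable & ph > pr]
  pp[comparable & ph == pr] <- x$p_equal[comparable & ph == pr]

  pct <- as.numeric(x$pct_acceptable)
  if (any(!x$has_quality & !is.na(pct)))
    stop("pct_acceptable recorded for a measure with no quality dimension")
  if (any(pct < 0 | pct > 100, na.rm = TRUE))
    stop("pct_acceptable must be in [0, 100]")
  qp <- integer(nrow(x))
  for (key in quality_measures(instrument)) {
    idx <- which(x$measure_id == key & !is.na(pct))
    if (length(idx))
      qp[idx] <- bracket_points(instrument$measures[[key]]$quality$brackets,
                                pct[idx])
  }

  out <- audits
  out$availability_points <- ap
  out$price_points <- pp
  out$quality_points <- qp
  out
}

# Every (store, rater) audit must cover all scoring units exactly once.
check_audit_coverage <- function(audits, instrument) {
  audits <- as_tibble(audits)
  units <- scoring_units(instrument)
  key <- function(m, s) paste(m, ifelse(is.na(s), "", s), sep = "\r")
  want <- key(units$measure_id, units$subitem_id)
  bad <- character(0)
  for (grp in split(audits, paste(audits$store_id, audits$rater_id, sep = "\r"))) {
    have <- key(grp$measure_id, grp$subitem_id)
    if (anyDuplicated(have))
      stop(sprintf("duplicate observation(s) for store '%s', rater '%s'",
                   grp$store_id[1], grp$rater_id[1]))
    miss <- setdiff(want, have)
    if (length(miss))
      bad <- c(bad, sprintf("store '%s' rater '%s' missing: %s",
                            grp$store_id[1], grp$rater_id[1],
                            paste(gsub("\r", "/", miss), collapse = ", ")))
  }
  if (length(bad))
    stop(paste(c("audit does not cover all instrument measures:", bad),
               collapse = "\n  "))
  audits
}

#' Store scores: subtotals and total per audit
#'
#' Sums per-unit component points into the availability, price and quality
#' subtotals and the total C-NEMS-S score, one row per (store, rater) audit.
#' Scoring is deterministic and idempotent.
#'
#' @inheritParams score_measures
#' @return A tibble with columns `store_id`, `store_type`, `rater_id`,
#'   `availability_subtotal`, `price_subtotal`, `quality_subtotal`, `total`.
#' @examples
#' audits <- generate_audits(default_sim_config(), seed = 1)
#' head(score_stores(audits, nemss_instrument()))
#' @export
score_stores <- function(audits, instrument) {
  scored <- score_measures(audits, instrument)
  scored %>%
    group_by(.data$store_id, .data$store_type, .data$rater_id) %>%
    summarise(availability_subtotal = sum(.data$availability_points),
              price_subtotal = sum(.data$price_points),
              quality_subtotal = sum(.data$quality_points),
              .groups = "drop") %>%
    mutate(total = .data$availability_subtotal + .data$price_subtotal +
             .data$quality_subtotal) %>%
    arrange(.data$store_id, .data$rater_id)
}

#' Score a single store audit
#'
#' Convenience wrapper around [score_stores()] for the rows of one store and
#' one rater.
#'
#' @inheritParams score_measures
#' @param store_id,rater_id Identify the audit to score; defaults require
#'   `audits` to contain exactly one audit.
#' @return A one-row tibble as from [score_stores()].
#' @export
score_store <- function(audits, instrument, store_id = NULL, rater_id = NULL) {
  audits <- as_tibble(audits)
  if (!is.null(store_id)) audits <- audits[audits$store_id == store_id, ]
  if (!is.null(rater_id)) audits <- audits[audits$rater_id == rater_id, ]
  if (nrow(distinct(audits[, c("store_id", "rater_id")])) != 1L)
    stop("audits must contain exactly one (store, rater) audit; use score_stores() for sets")
  score_stores(audits, instrument)
}
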