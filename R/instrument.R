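# Declarative definition of the C-NEMS-S instrument: the 12 food measures,
# their healthier options, and the availability / price / quality point rules
# of the scoring sheet, plus brute-force derivation of attainable score
# ranges from those rules.

# Canonical ids of the six beverage sub-categories scored as parallel lines
# (1 availability point and a +2/-1 price rule each).
BEVERAGE_SUBITEMS <- c("carbonated", "lactose", "juice", "tea",
                       "plant_protein", "cider_vinegar")

new_brackets <- function(lo, hi, points) {
  stopifnot(length(lo) == length(hi), length(lo) == length(points))
  data.frame(lo = as.numeric(lo), hi = as.numeric(hi),
             points = as.integer(points))
}

# Points awarded by an ordered bracket table for a vector of counts/percents.
# Values below the lowest bracket score 0.
bracket_points <- function(brackets, x) {
  pts <- integer(length(x))
  if (is.null(brackets) || nrow(brackets) == 0L) return(pts)
  for (i in seq_len(nrow(brackets))) {
    hit <- !is.na(x) & x >= brackets$lo[i] & x <= brackets$hi[i]
    pts[hit] <- brackets$points[i]
  }
  pts[is.na(x)] <- 0L
  pts
}

measure_def <- function(id, display_name, healthier_option_label = NULL,
                        base_points = 0L, brackets = NULL,
                        price = NULL, quality = NULL,
                        subitems = character(0)) {
  structure(list(
    id = id,
    display_name = display_name,
    healthier_option_label = healthier_option_label,
    subitems = subitems,
    availability = list(base_points = as.integer(base_points),
                        brackets = brackets),
    price = price,
    quality = quality
  ), class = "cnemss_measure")
}

price_rule <- function(cheaper = 2L, dearer = -1L, equal = 0L) {
  list(cheaper = as.integer(cheaper), dearer = as.integer(dearer),
       equal = as.integer(equal))
}

quality_rule <- function() {
  # 25-49% acceptable = 1 pt, 50-74% = 2 pts, >=75% = 3 pts; below 25% = 0.
  list(brackets = new_brackets(c(25, 50, 75), c(49, 74, Inf), c(1L, 2L, 3L)))
}

#' The default C-NEMS-S instrument
#'
#' Builds the Chinese Nutrition Environment Measures Survey for Stores
#' scoring sheet: 12 food measures reflecting the fan/cai structure of the
#' Chinese diet (grains, dry beans, starchy tubers, vegetables, fruits,
#' seafood, meat and poultry, dietary oils, milk, bread, instant noodles,
#' beverages), each carrying the point rules of the published scoring sheet.
#'
#' Seven measures designate a healthier option (whole grains, lean meat,
#' plant-based oils, low-fat milk, whole wheat bread, non-fried instant
#' noodles, sugar-free beverages) whose presence earns base availability
#' points; the other five are wholly "healthy foods" scored on species counts
#' alone. Species-count brackets award bonus points for variety of the
#' healthier option. Price rules compare the healthier option with the
#' regular option (+2 if cheaper, -1 if dearer; milk alone awards +1 for
#' equal prices). Quality (percent of stock in acceptable condition) is
#' scored only for vegetables, fruits and seafood. The beverages measure has
#' six sub-categories, each with one availability point and its own price
#' rule.
#'
#' Milk's extra availability line (one point when low-fat varieties make up
#' more than half the milk stock) is modelled as a 0/1 indicator recorded in
#' the `species_count` field of the audit, scored through a `{>=1 -> 1}`
#' bracket.
#'
#' The instrument also carries the score ranges printed on the original
#' sheet's footnote as metadata (`reported_ranges`); [score_range()] derives
#' the attainable ranges from the rules themselves and warns where the two
#' disagree.
#'
#' @return An object of class `cnemss_instrument`: a list with elements
#'   `version`, `measures` (named list of 12 measure definitions) and
#'   `reported_ranges`.
#' @examples
#' inst <- nemss_instrument()
#' length(inst$measures)
#' measure_ids(inst)
#' @seealso [score_range()], [score_stores()], [write_instrument()]
#' @export
nemss_instrument <- function() {
  sp3 <- function() new_brackets(c(2, 4), c(3, Inf), c(1L, 2L))     # 2-3 -> 1, >3 -> 2
  m <- list(
    measure_def("grains", "Grains", "Whole grains",
                base_points = 2L, brackets = sp3(), price = price_rule()),
    measure_def("dry_beans", "Dry beans",
                brackets = new_brackets(c(1, 2, 4), c(1, 3, Inf), 1:3)),
    measure_def("starchy_tubers", "Starchy tubers",
                brackets = new_brackets(c(1, 2, 5), c(1, 4, Inf), 1:3)),
    measure_def("vegetables", "Vegetables",
                brackets = new_brackets(c(1, 5, 10), c(4, 9, Inf), 1:3),
                quality = quality_rule()),
    measure_def("fruits", "Fruits",
                brackets = new_brackets(c(1, 5, 10), c(4, 9, Inf), 1:3),
                quality = quality_rule()),
    measure_def("seafood", "Seafood",
                brackets = new_brackets(c(1, 5, 10), c(4, 9, Inf), 1:3),
                quality = quality_rule()),
    measure_def("meat_poultry", "Meat and poultry", "Lean meat options",
                base_points = 2L, brackets = sp3(), price = price_rule()),
    measure_def("dietary_oils", "Dietary oils", "Plant-based oils",
                base_points = 2L, brackets = sp3(), price = price_rule()),
    measure_def("milk", "Milk", "Low-fat milk",
                base_points = 2L,
                brackets = new_brackets(1, Inf, 1L),   # low-fat share >50% -> 1 pt
                price = price_rule(equal = 1L)),
    measure_def("bread", "Bread", "Whole wheat bread",
                base_points = 2L, brackets = new_brackets(3, Inf, 1L),
                price = price_rule()),
    measure_def("instant_noodles", "Instant noodles", "Non-fried instant noodles",
                base_points = 2L, brackets = new_brackets(3, Inf, 1L),
                price = price_rule()),
    measure_def("beverages", "Beverages", "Sugar-free beverages",
                base_points = 1L,          # per subitem
                price = price_rule(),      # per subitem
                subitems = BEVERAGE_SUBITEMS)
  )
  names(m) <- vapply(m, `[[`, "", "id")
  structure(list(
    version = "C-NEMS-S 1.0",
    measures = m,
    reported_ranges = list(availability = c(0, 48), price = c(-14, 26),
                           quality = c(0, 9), total = c(-14, 83))
  ), class = "cnemss_instrument")
}

#' @export
print.cnemss_instrument <- function(x, ...) {
  cat(sprintf("<cnemss_instrument> %s: %d food measures\n",
              x$version, length(x$measures)))
  for (m in x$measures) {
    dims <- c("availability",
              if (!is.null(m$price)) "price",
              if (!is.null(m$quality)) "quality")
    lab <- if (is.null(m$healthier_option_label)) "healthy food"
           else m$healthier_option_label
    extra <- if (length(m$subitems)) sprintf(" [%d subitems]", length(m$subitems))
             else ""
    cat(sprintf("  %-16s %-26s %s%s\n", m$id, lab,
                paste(dims, collapse = "+"), extra))
  }
  invisible(x)
}

#' Measure ids of an instrument
#'
#' @param instrument A `cnemss_instrument`.
#' @return Character vector of measure ids, in scoring-sheet order.
#' @export
measure_ids <- function(instrument) {
  stopifnot(inherits(instrument, "cnemss_instrument"))
  names(instrument$measures)
}

# Scoring units: one row per (measure, subitem) pair that receives its own
# availability/price observation. Beverages expand to their six subitems;
# every other measure is a single unit with subitem_id NA.
scoring_units <- function(instrument) {
  rows <- lapply(instrument$measures, function(m) {
    if (length(m$subitems)) {
      tibble(measure_id = m$id, subitem_id = m$subitems)
    } else {
      tibble(measure_id = m$id, subitem_id = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}

# Ids of measures carrying a quality dimension.
quality_measures <- function(instrument) {
  ids <- measure_ids(instrument)
  ids[vapply(instrument$measures, function(m) !is.null(m$quality), TRUE)]
}

# Ids of measures carrying a price dimension (beverages count: their
# subitems are priced).
priced_measures <- function(instrument) {
  ids <- measure_ids(instrument)
  ids[vapply(instrument$measures, function(m) !is.null(m$price), TRUE)]
}

# ---------------------------------------------------------------------------
# Attainable-range enumeration

# All admissible (availability, price, quality) point outcomes for one
# measure, one row per distinct joint outcome. "Admissible" couples the
# dimensions: price and quality can only be scored when the healthier option
# (or any species) is present, and a -1 price point therefore always comes
# with at least the base availability points.
measure_outcomes <- function(m) {
  if (length(m$subitems)) {
    # per-subitem outcomes, combined over all subitems by cartesian sum
    sub <- dplyr::distinct(tibble(
      avail = c(0L, rep(m$availability$base_points, 3L)),
      price = c(0L, m$price$cheaper, m$price$dearer, m$price$equal),
      quality = 0L))
    out <- sub
    for (i in seq_len(length(m$subitems) - 1L)) out <- combine_outcomes(out, sub)
    return(out)
  }
  br <- m$availability$brackets
  # Representative species counts: one per bracket, plus a present-but-below-
  # lowest-bracket count when the lowest bracket starts above 1.
  sp <- unique(c(if (is.null(br) || br$lo[1] > 1) 1, if (!is.null(br)) br$lo))
  avail_present <- unique(m$availability$base_points + bracket_points(br, sp))
  price_opts <- if (is.null(m$price)) 0L else
    unique(c(0L, m$price$cheaper, m$price$dearer, m$price$equal))
  qual_opts <- if (is.null(m$quality)) 0L else
    unique(c(0L, m$quality$brackets$points))
  present <- tidyr::expand_grid(avail = avail_present, price = price_opts,
                                quality = qual_opts)
  dplyr::distinct(dplyr::bind_rows(
    tibble(avail = 0L, price = 0L, quality = 0L), present))
}

# Cartesian-sum combine of per-subitem beverage outcomes (used by
# measure_outcomes); kept iterative and deduplicated so the outcome set stays
# small. Defined separately for clarity.
combine_outcomes <- function(a, b) {
  g <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  dplyr::distinct(tibble(
    avail = a$avail[g$i] + b$avail[g$j],
    price = a$price[g$i] + b$price[g$j],
    quality = a$quality[g$i] + b$quality[g$j]
  ))
}

#' Every attainable quality subtotal, by exhaustive enumeration
#'
#' Enumerates the full cartesian product of per-measure quality outcomes
#' (below-minimum plus each quality bracket) across all measures carrying a
#' quality dimension, and returns the resulting store-level quality subtotals.
#'
#' @param instrument A `cnemss_instrument`.
#' @return Integer vector of quality subtotals, one per enumerated
#'   combination (not deduplicated).
#' @examples
#' range(enumerate_quality_subtotals(nemss_instrument()))
#' @export
enumerate_quality_subtotals <- function(instrument) {
  stopifnot(inherits(instrument, "cnemss_instrument"))
  qm <- quality_measures(instrument)
  opts <- lapply(qm, function(id) {
    q <- instrument$measures[[id]]$quality
    unique(c(0L, q$brackets$points))
  })
  if (!length(opts)) return(0L)
  grid <- do.call(tidyr::expand_grid, stats::setNames(opts, qm))
  as.integer(rowSums(as.matrix(grid)))
}

#' Attainable score ranges of an instrument
#'
#' Derives the minimum and maximum attainable availability, price and quality
#' subtotals and total score by brute-force enumeration of every admissible
#' per-measure outcome under the instrument's point rules (enumeration
#' couples the dimensions within a measure: price or quality points are only
#' attainable together with the availability points that presence implies).
#' Nothing is copied from the printed footnote; when the derived ranges
#' disagree with the `reported_ranges` metadata carried by the instrument, a
#' warning lists the discrepancies so they are surfaced, never silently
#' patched.
#'
#' @param instrument A `cnemss_instrument`.
#' @param quiet If `TRUE`, suppress the discrepancy warning.
#' @return A tibble of class `cnemss_score_range` with one row per component
#'   (`availability`, `price`, `quality`, `total`) and columns `derived_min`,
#'   `derived_max`, `reported_min`, `reported_max`, `agrees`.
#' @examples
#' suppressWarnings(score_range(nemss_instrument()))
#' @export
score_range <- function(instrument, quiet = FALSE) {
  stopifnot(inherits(instrument, "cnemss_instrument"))
  outs <- lapply(instrument$measures, measure_outcomes)
  per_min <- sapply(outs, function(o)
    c(avail = min(o$avail), price = min(o$price),
      total = min(o$avail + o$price + o$quality)))
  per_max <- sapply(outs, function(o)
    c(avail = max(o$avail), price = max(o$price),
      total = max(o$avail + o$price + o$quality)))
  qtot <- enumerate_quality_subtotals(instrument)
  derived <- list(
    availability = c(sum(per_min["avail", ]), sum(per_max["avail", ])),
    price        = c(sum(per_min["price", ]), sum(per_max["price", ])),
    quality      = c(min(qtot), max(qtot)),
    total        = c(sum(per_min["total", ]), sum(per_max["total", ]))
  )
  rep <- instrument$reported_ranges
  out <- tibble(
    component = names(derived),
    derived_min = vapply(derived, `[`, 0, 1),
    derived_max = vapply(derived, `[`, 0, 2),
    reported_min = vapply(names(derived), function(k)
      if (is.null(rep[[k]])) NA_real_ else rep[[k]][1], 0),
    reported_max = vapply(names(derived), function(k)
      if (is.null(rep[[k]])) NA_real_ else rep[[k]][2], 0)
  )
  out$agrees <- !is.na(out$reported_min) &
    out$derived_min == out$reported_min & out$derived_max == out$reported_max
  if (!quiet && any(!out$agrees, na.rm = TRUE)) {
    bad <- out[!out$agrees, ]
    warning(sprintf(
      paste0("Derived score ranges disagree with the ranges printed on the ",
             "scoring sheet: %s. The derived ranges follow from the itemized ",
             "point rules; the printed footnote may reflect additional items ",
             "not shown on the sheet."),
      paste(sprintf("%s derived [%g, %g] vs printed [%g, %g]",
                    bad$component, bad$derived_min, bad$derived_max,
                    bad$reported_min, bad$reported_max), collapse = "; ")),
      call. = FALSE)
  }
  class(out) <- c("cnemss_score_range", class(out))
  out
}

# ---------------------------------------------------------------------------
# Config serialization (YAML)

brackets_to_list <- function(br) {
  if (is.null(br)) return(NULL)
  lapply(seq_len(nrow(br)), function(i)
    list(lo = br$lo[i],
         hi = if (is.finite(br$hi[i])) br$hi[i] else "Inf",
         points = br$points[i]))
}

brackets_from_list <- function(x) {
  if (is.null(x) || !length(x)) return(NULL)
  new_brackets(vapply(x, function(b) as.numeric(b$lo), 0),
               vapply(x, function(b) as.numeric(b$hi), 0),
               vapply(x, function(b) as.integer(b$points), 0L))
}

#' Write an instrument definition to a YAML config file
#'
#' The instrument serializes to a nested key-value file (UTF-8) that
#' [read_instrument()] restores losslessly.
#'
#' @param instrument A `cnemss_instrument`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "cnemss_instrument"))
  ser <- list(
    version = instrument$version,
    reported_ranges = lapply(instrument$reported_ranges, as.numeric),
    measures = lapply(unname(instrument$measures), function(m) {
      out <- list(
        id = m$id,
        display_name = m$display_name,
        availability = list(
          base_points = m$availability$base_points,
          brackets = brackets_to_list(m$availability$brackets)))
      if (!is.null(m$healthier_option_label))
        out$healthier_option_label <- m$healthier_option_label
      if (length(m$subitems)) out$subitems <- as.list(m$subitems)
      if (!is.null(m$price)) out$price <- m$price
      if (!is.null(m$quality))
        out$quality <- list(brackets = brackets_to_list(m$quality$brackets))
      out
    })
  )
  writeLines(yaml::as.yaml(ser), path, useBytes = TRUE)
  invisible(path)
}

#' Read an instrument definition from a YAML config file
#'
#' @param path Path to a file written by [write_instrument()].
#' @return A `cnemss_instrument`.
#' @export
read_instrument <- function(path) {
  ser <- yaml::read_yaml(path)
  measures <- lapply(ser$measures, function(m) {
    measure_def(
      id = m$id,
      display_name = m$display_name,
      healthier_option_label = m$healthier_option_label,
      base_points = m$availability$base_points,
      brackets = brackets_from_list(m$availability$brackets),
      price = if (!is.null(m$price))
        price_rule(m$price$cheaper, m$price$dearer, m$price$equal),
      quality = if (!is.null(m$quality))
        list(brackets = brackets_from_list(m$quality$brackets)),
      subitems = as.character(unlist(m$subitems %||% character(0)))
    )
  })
  names(measures) <- vapply(measures, `[[`, "", "id")
  inst <- structure(list(
    version = ser$version,
    measures = measures,
    reported_ranges = lapply(ser$reported_ranges, as.numeric)
  ), class = "cnemss_instrument")
  validate_instrument(inst)
  inst
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structural invariants of a well-formed instrument.
validate_instrument <- function(instrument) {
  m <- instrument$measures
  for (x in m) {
    if (!is.null(x$healthier_option_label) &&
        x$availability$base_points <= 0)
      stop(sprintf("measure '%s' designates a healthier option but has no base availability points", x$id))
    br <- x$availability$brackets
    if (!is.null(br) && nrow(br) > 1) {
      if (any(diff(br$lo) <= 0) || any(br$hi[-nrow(br)] >= br$lo[-1]))
        stop(sprintf("measure '%s' has overlapping or unordered species brackets", x$id))
    }
  }
  invisible(instrument)
}
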