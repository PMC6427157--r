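# Seeded generator of paired-rater audit datasets with the statistical
# structure of a store-audit measurement study: store-type availability
# gaps, price levels/premiums, quality distributions, and a tunable
# rater-disagreement rate.

#' Default simulation configuration
#'
#' Generator defaults calibrated to the measurement study's design and
#' published summary tables: 10 large supermarkets and 10 convenience
#' stores, each audited by 2 raters; per-measure healthier-option
#' availability probabilities equal to the rater-1 store-type percentages
#' divided by 100; healthier/regular price models as truncated normals with
#' the rater-1 means/SDs for grains, meat and poultry, milk, bread and
#' instant noodles. Dietary-oil and beverage prices are not published at
#' that granularity; plausible retail values are used (documented in the
#' methods vignette). Quality (percent acceptable) is uniform 60-100 in
#' supermarkets and 20-90 in convenience stores. Rater 2's availability
#' flags equal rater 1's except for independent flips with probability
#' `rater_disagreement` (default 0.05); species counts, prices and quality
#' are shared between raters.
#'
#' The beverages measure stores its collapsed (any-subitem) availability
#' probability; per-subitem probabilities are derived internally as
#' `q = 1 - (1 - p)^(1/6)` so the collapsed flag recovers `p`.
#'
#' @param n_stores Named integer vector: stores per type.
#' @param rater_disagreement Probability a rater-2 availability flag flips
#'   relative to rater 1 (independently per store and scoring unit).
#' @param price_noise_sd SD of rater-2 price observation noise (0 = prices
#'   identical across raters).
#' @return A list of class `cnemss_sim_config`.
#' @examples
#' cfg <- default_sim_config()
#' cfg$availability[cfg$availability$measure_id == "grains", ]
#' @export
default_sim_config <- function(n_stores = c(large_supermarket = 10L,
                                            convenience = 10L),
                               rater_disagreement = 0.05,
                               price_noise_sd = 0) {
  availability <- tibble(
    measure_id = c("grains", "dry_beans", "starchy_tubers", "vegetables",
                   "fruits", "seafood", "meat_poultry", "dietary_oils",
                   "milk", "bread", "instant_noodles", "beverages"),
    large_supermarket = c(1.0, 0.9, 0.9, 1.0, 1.0, 0.8, 1.0, 1.0,
                          0.8, 0.9, 0.6, 0.8),
    convenience       = c(0.1, 0.1, 0.0, 0.0, 0.1, 0.0, 0.0, 0.2,
                          0.2, 0.3, 0.0, 0.3)
  )
  # Uniform species-count ranges spanning each measure's brackets (upper
  # bound two above the top bracket threshold); milk's species field is the
  # 0/1 low-fat-majority indicator, drawn Bernoulli(0.5).
  species_max <- c(grains = 6L, dry_beans = 6L, starchy_tubers = 7L,
                   vegetables = 12L, fruits = 12L, seafood = 12L,
                   meat_poultry = 6L, dietary_oils = 6L, milk = 1L,
                   bread = 4L, instant_noodles = 4L, beverages = 1L)
  prices <- tibble(
    measure_id = c("grains", "meat_poultry", "milk", "bread",
                   "instant_noodles", "dietary_oils",
                   rep("beverages", length(BEVERAGE_SUBITEMS))),
    subitem_id = c(rep(NA_character_, 6), BEVERAGE_SUBITEMS),
    price_unit = c("RMB/0.5kg", "RMB/0.5kg", "RMB/250mL", "RMB/loaf",
                   "RMB/packet", "RMB/0.5kg", rep("RMB/250mL", 6)),
    mean_healthier = c(6.19, 28.48, 3.28, 7.07, 3.37, 11.0, rep(4.0, 6)),
    sd_healthier   = c(2.27, 14.43, 0.27, 1.13, 0.25, 2.0, rep(0.8, 6)),
    mean_regular   = c(2.45, 14.50, 3.14, 6.80, 2.50, 9.0, rep(3.5, 6)),
    sd_regular     = c(0.09, 0.00, 0.32, 0.48, 0.15, 1.5, rep(0.7, 6))
  )
  cfg <- structure(list(
    n_stores = n_stores,
    availability = availability,
    species_max = species_max,
    prices = prices,
    quality = list(large_supermarket = c(60, 100), convenience = c(20, 90)),
    rater_disagreement = rater_disagreement,
    price_noise_sd = price_noise_sd,
    date = "2017-02-01"
  ), class = "cnemss_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(config) {
  if (!all(config$n_stores >= 1)) stop("n_stores must be >= 1 per store type")
  pr <- unlist(config$availability[, c("large_supermarket", "convenience")])
  if (any(pr < 0 | pr > 1))
    stop("availability probabilities must be in [0, 1]")
  if (config$rater_disagreement < 0 || config$rater_disagreement > 1)
    stop("rater_disagreement must be in [0, 1]")
  if (any(config$prices$mean_healthier < 0) ||
      any(config$prices$mean_regular < 0) ||
      any(config$prices$sd_healthier < 0) || any(config$prices$sd_regular < 0))
    stop("price means and SDs must be non-negative")
  invisible(config)
}

#' Read / write a simulation configuration (YAML)
#'
#' The generator configuration round-trips through the same structured
#' key-value format as the instrument definition.
#'
#' @param config A `cnemss_sim_config`.
#' @param path File path.
#' @return `write_sim_config()`: `path`, invisibly. `read_sim_config()`:
#'   a `cnemss_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "cnemss_sim_config"))
  ser <- list(
    n_stores = as.list(config$n_stores),
    availability = lapply(seq_len(nrow(config$availability)), function(i)
      as.list(config$availability[i, ])),
    species_max = as.list(config$species_max),
    prices = lapply(seq_len(nrow(config$prices)), function(i) {
      r <- as.list(config$prices[i, ])
      if (is.na(r$subitem_id)) r$subitem_id <- NULL
      r
    }),
    quality = config$quality,
    rater_disagreement = config$rater_disagreement,
    price_noise_sd = config$price_noise_sd,
    date = config$date
  )
  writeLines(yaml::as.yaml(ser), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  ser <- yaml::read_yaml(path)
  cfg <- structure(list(
    n_stores = unlist(ser$n_stores),
    availability = dplyr::bind_rows(lapply(ser$availability, as_tibble)),
    species_max = unlist(ser$species_max),
    prices = dplyr::bind_rows(lapply(ser$prices, function(r) {
      r$subitem_id <- r$subitem_id %||% NA_character_
      as_tibble(r)
    }))[, c("measure_id", "subitem_id", "price_unit", "mean_healthier",
            "sd_healthier", "mean_regular", "sd_regular")],
    quality = ser$quality,
    rater_disagreement = ser$rater_disagreement,
    price_noise_sd = ser$price_noise_sd,
    date = ser$date
  ), class = "cnemss_sim_config")
  validate_sim_config(cfg)
  cfg
}

# Truncated-normal draw, lower bound `lo`; sd = 0 gives a point mass.
rtnorm <- function(n, mean, sd, lo = 0.01) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    plo <- pnorm(lo, mean[pos], sd[pos])
    u <- runif(sum(pos), plo, 1)
    out[pos] <- qnorm(u, mean[pos], sd[pos])
  }
  pmax(out, lo)
}

#' Generate a paired-rater synthetic audit dataset
#'
#' Simulates a full measurement study under `config`: for each store,
#' latent per-unit availability, species counts, prices and quality are
#' drawn, rater 1 observes them directly, and rater 2's availability flags
#' are independently flipped with probability `config$rater_disagreement`
#' (species, prices and quality are shared, with optional rater-2 price
#' noise). Output is deterministic for a fixed seed.
#'
#' @param config A `cnemss_sim_config` (see [default_sim_config()]).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A long-format audit tibble (one row per store, rater and scoring
#'   unit) with the schema documented in [read_audits()].
#' @examples
#' audits <- generate_audits(default_sim_config(), seed = 7)
#' dplyr::count(audits, store_type, rater_id)
#' @export
generate_audits <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cnemss_sim_config"))
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  inst <- nemss_instrument()
  units <- scoring_units(inst)
  n_units <- nrow(units)
  qm <- quality_measures(inst)

  stores <- dplyr::bind_rows(
    tibble(store_id = sprintf("S%03d", seq_len(config$n_stores[["large_supermarket"]])),
           store_type = "large_supermarket"),
    tibble(store_id = sprintf("C%03d", seq_len(config$n_stores[["convenience"]])),
           store_type = "convenience"))
  n_stores <- nrow(stores)

  # one latent frame: store x scoring unit
  lat <- tidyr::expand_grid(stores, units)
  # per-unit availability probability (beverage subitems get the derived q)
  pmap <- config$availability
  p_meas <- pmap[[1]]
  lat <- dplyr::left_join(lat, pmap, by = "measure_id")
  p <- ifelse(lat$store_type == "large_supermarket",
              lat$large_supermarket, lat$convenience)
  is_bev <- !is.na(lat$subitem_id)
  p[is_bev] <- 1 - (1 - p[is_bev])^(1 / sum(is_bev[seq_len(n_units)]))
  avail1 <- runif(nrow(lat)) < p

  # latent species counts (>=1 given availability); milk/beverage indicator
  smax <- config$species_max[lat$measure_id]
  species <- 1L + as.integer(floor(runif(nrow(lat)) * smax))
  species[lat$measure_id == "milk"] <- rbinom(sum(lat$measure_id == "milk"), 1L, 0.5)
  species[is_bev] <- 1L

  # latent prices for priced units
  lat_pr <- dplyr::left_join(lat, config$prices,
                             by = c("measure_id", "subitem_id"))
  has_price <- !is.na(lat_pr$mean_healthier)
  ph <- pr <- rep(NA_real_, nrow(lat))
  ph[has_price] <- rtnorm(sum(has_price), lat_pr$mean_healthier[has_price],
                          lat_pr$sd_healthier[has_price])
  pr[has_price] <- rtnorm(sum(has_price), lat_pr$mean_regular[has_price],
                          lat_pr$sd_regular[has_price])

  # latent quality
  qr <- config$quality
  is_q <- lat$measure_id %in% qm
  pct <- rep(NA_real_, nrow(lat))
  rng <- ifelse(lat$store_type == "large_supermarket", 1, 2)
  lo <- ifelse(rng == 1, qr$large_supermarket[1], qr$convenience[1])
  hi <- ifelse(rng == 1, qr$large_supermarket[2], qr$convenience[2])
  pct[is_q] <- round(runif(sum(is_q), lo[is_q], hi[is_q]), 1)

  # rater 2: independent availability flips
  flips <- runif(nrow(lat)) < config$rater_disagreement
  avail2 <- xor(avail1, flips)

  build_rater <- function(rater_id, avail, price_noise) {
    ph_obs <- ph; pr_obs <- pr
    if (price_noise > 0) {
      ph_obs <- ph_obs + rnorm(length(ph), 0, price_noise)
      pr_obs <- pr_obs + rnorm(length(pr), 0, price_noise)
      ph_obs <- pmax(ph_obs, 0.01); pr_obs <- pmax(pr_obs, 0.01)
    }
    tibble(
      store_id = lat$store_id,
      store_type = lat$store_type,
      rater_id = rater_id,
      date = config$date,
      measure_id = lat$measure_id,
      subitem_id = lat$subitem_id,
      healthier_available = as.integer(avail),
      species_count = ifelse(avail, species, 0L),
      price_healthier = ifelse(avail & has_price, ph_obs, NA_real_),
      price_regular = ifelse(avail & has_price, pr_obs, NA_real_),
      price_unit = ifelse(has_price, lat_pr$price_unit, NA_character_),
      pct_acceptable = ifelse(avail & is_q, pct, NA_real_)
    )
  }
  out <- dplyr::bind_rows(build_rater("R1", avail1, 0),
                          build_rater("R2", avail2, config$price_noise_sd))
  out <- out %>% arrange(.data$store_id, .data$rater_id, .data$measure_id,
                         .data$subitem_id)
  out
}
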