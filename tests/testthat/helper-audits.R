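# Fixture builders: complete audits constructed in code.

default_inst <- nemss_instrument()

# A complete all-absent audit for one (store, rater).
blank_audit <- function(store_id = "S1", store_type = "large_supermarket",
                        rater_id = "R1", instrument = default_inst) {
  units <- cnemss:::scoring_units(instrument)
  tibble::tibble(
    store_id = store_id, store_type = store_type, rater_id = rater_id,
    date = "2017-02-01",
    measure_id = units$measure_id, subitem_id = units$subitem_id,
    healthier_available = 0L, species_count = 0L,
    price_healthier = NA_real_, price_regular = NA_real_,
    price_unit = NA_character_, pct_acceptable = NA_real_)
}

# Override one observation row of an audit.
set_obs <- function(audit, measure_id, subitem_id = NA, available = NULL,
                    species = NULL, ph = NULL, pr = NULL, pct = NULL) {
  i <- if (all(is.na(subitem_id))) which(audit$measure_id == measure_id)
       else which(audit$measure_id == measure_id &
                    audit$subitem_id %in% subitem_id)
  stopifnot(length(i) >= 1)
  if (!is.null(available)) audit$healthier_available[i] <- as.integer(available)
  if (!is.null(species)) audit$species_count[i] <- as.integer(species)
  if (!is.null(ph)) audit$price_healthier[i] <- ph
  if (!is.null(pr)) audit$price_regular[i] <- pr
  if (!is.null(pct)) audit$pct_acceptable[i] <- pct
  audit
}

# A maximal audit: every healthier option present, top species bracket,
# healthier always cheaper, all quality >= 75%.
maximal_audit <- function(store_id = "S1", rater_id = "R1",
                          instrument = default_inst) {
  a <- blank_audit(store_id = store_id, rater_id = rater_id,
                   instrument = instrument)
  a$healthier_available <- 1L
  a$species_count <- 20L
  a$species_count[a$measure_id == "milk"] <- 1L
  priced <- a$measure_id %in% cnemss:::priced_measures(instrument)
  a$price_healthier[priced] <- 1
  a$price_regular[priced] <- 2
  qm <- cnemss:::quality_measures(instrument)
  a$pct_acceptable[a$measure_id %in% qm] <- 90
  a
}

# Random valid audits spanning the rule space: availability 0.5 everywhere,
# prices drawn so cheaper/dearer/equal all occur.
random_audit_config <- function(n_per_type = 10L) {
  cfg <- default_sim_config(n_stores = c(large_supermarket = n_per_type,
                                         convenience = n_per_type))
  cfg$availability$large_supermarket <- rep(0.5, 12)
  cfg$availability$convenience <- rep(0.5, 12)
  cfg$prices$mean_healthier <- rep(5, nrow(cfg$prices))
  cfg$prices$sd_healthier <- rep(2, nrow(cfg$prices))
  cfg$prices$mean_regular <- rep(5, nrow(cfg$prices))
  cfg$prices$sd_regular <- rep(2, nrow(cfg$prices))
  cfg$quality$large_supermarket <- c(0, 100)
  cfg$quality$convenience <- c(0, 100)
  cfg
}
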