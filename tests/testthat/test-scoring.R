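test_that("availability points follow base + species brackets", {
  inst <- nemss_instrument()
  expect_equal(score_availability(inst$measures$grains, TRUE, 4), 4)
  expect_equal(score_availability(inst$measures$grains, TRUE, 2), 3)
  expect_equal(score_availability(inst$measures$grains, TRUE, 1), 2)
  expect_equal(score_availability(inst$measures$grains, FALSE), 0)
  expect_equal(score_availability(inst$measures$vegetables, TRUE, 12), 3)
  expect_equal(score_availability(inst$measures$vegetables, TRUE, 7), 2)
  expect_equal(score_availability(inst$measures$starchy_tubers, TRUE, 5), 3)
  expect_equal(score_availability(inst$measures$starchy_tubers, TRUE, 8), 3)
  expect_equal(score_availability(inst$measures$bread, TRUE, 3), 3)
  # milk's second line: low-fat majority indicator
  expect_equal(score_availability(inst$measures$milk, TRUE, 1), 3)
  expect_equal(score_availability(inst$measures$milk, TRUE, 0), 2)
  # missing species count: incomplete observation, bracket component 0
  expect_warning(p <- score_availability(inst$measures$grains, TRUE, NA),
                 "incomplete")
  expect_equal(p, 2)
})

test_that("price points compare healthier with regular options", {
  inst <- nemss_instrument()
  expect_equal(score_price(inst$measures$milk, 3.0, 3.5), 2)
  expect_equal(score_price(inst$measures$milk, 3.2, 3.2), 1)   # milk only
  expect_equal(score_price(inst$measures$bread, 7.07, 6.80), -1)
  expect_equal(score_price(inst$measures$bread, 6.8, 6.8), 0)
  expect_equal(score_price(inst$measures$bread, 5, 6, available = FALSE), 0)
  expect_equal(score_price(inst$measures$bread, NA, 6.8), 0)
  expect_equal(score_price(inst$measures$dry_beans, NA, NA), 0)
  expect_error(score_price(inst$measures$bread, -1, 2), "non-negative")
})

test_that("quality points follow the percent-acceptable brackets", {
  inst <- nemss_instrument()
  f <- inst$measures$fruits
  expect_equal(score_quality(f, 80), 3)
  expect_equal(score_quality(f, 75), 3)
  expect_equal(score_quality(f, 74), 2)
  expect_equal(score_quality(f, 50), 2)
  expect_equal(score_quality(f, 30), 1)
  expect_equal(score_quality(f, 10), 0)
  expect_equal(score_quality(f, NA), 0)
  expect_error(score_quality(f, 120), "\\[0, 100\\]")
  expect_error(score_quality(inst$measures$milk, 80), "no quality dimension")
})

test_that("store scoring matches hand-built audits", {
  inst <- nemss_instrument()
  s <- score_store(blank_audit(), inst)
  expect_equal(s$total, 0)

  s <- score_store(maximal_audit(), inst)
  expect_equal(s$availability_subtotal, 42)
  expect_equal(s$price_subtotal, 24)
  expect_equal(s$quality_subtotal, 9)
  expect_equal(s$total, 75)

  # only sugar-free beverages present, all dearer than regular
  a <- blank_audit()
  a <- set_obs(a, "beverages", subitem_id = cnemss:::BEVERAGE_SUBITEMS,
               available = 1L, species = 1L, ph = 5, pr = 4)
  s <- score_store(a, inst)
  expect_equal(s$availability_subtotal, 6)
  expect_equal(s$price_subtotal, -6)
})

test_that("score_stores is the sum of per-rule component scorers", {
  inst <- nemss_instrument()
  audits <- generate_audits(random_audit_config(), seed = 42)
  scored <- score_measures(audits, inst)
  # independent route: scalar rule scorers applied row by row
  for (i in seq_len(nrow(scored))) {
    m <- inst$measures[[scored$measure_id[i]]]
    avail <- scored$healthier_available[i] == 1L
    expect_equal(scored$availability_points[i],
                 as.integer(score_availability(m, avail,
                                               scored$species_count[i])))
    expect_equal(scored$price_points[i],
                 as.integer(score_price(m, scored$price_healthier[i],
                                        scored$price_regular[i], avail)))
    expect_equal(scored$quality_points[i],
                 as.integer(score_quality(m, scored$pct_acceptable[i])))
  }
  stores <- score_stores(audits, inst)
  agg <- aggregate(cbind(availability_points, price_points, quality_points)
                   ~ store_id + rater_id, data = scored, FUN = sum)
  agg <- agg[order(agg$store_id, agg$rater_id), ]
  expect_equal(stores$availability_subtotal, agg$availability_points)
  expect_equal(stores$price_subtotal, agg$price_points)
  expect_equal(stores$quality_subtotal, agg$quality_points)
  expect_equal(stores$total,
               stores$availability_subtotal + stores$price_subtotal +
                 stores$quality_subtotal)
  expect_true(all(vapply(stores[4:7], is.integer, TRUE)))
})

test_that("improving an observation never decreases the total", {
  inst <- nemss_instrument()
  base <- blank_audit()
  base <- set_obs(base, "grains", available = 1L, species = 2L, ph = 3, pr = 3)
  base <- set_obs(base, "fruits", available = 1L, species = 3L, pct = 40)
  t0 <- score_store(base, inst)$total

  t_avail <- score_store(set_obs(base, "milk", available = 1L, species = 0L),
                         inst)$total
  t_species <- score_store(set_obs(base, "grains", species = 6L), inst)$total
  t_quality <- score_store(set_obs(base, "fruits", pct = 90), inst)$total
  expect_gte(t_avail, t0)
  expect_gte(t_species, t0)
  expect_gte(t_quality, t0)
})

test_that("incomplete or non-covering audits are reported", {
  inst <- nemss_instrument()
  a <- blank_audit()
  expect_error(score_store(a[a$measure_id != "milk", ], inst),
               "missing: milk")
  expect_error(score_stores(rbind(a, a[1, ]), inst), "duplicate")
  incomplete <- set_obs(a, "grains", available = 1L)
  incomplete$species_count[incomplete$measure_id == "grains"] <- NA_integer_
  expect_warning(s <- score_store(incomplete, inst), "incomplete")
  expect_equal(s$availability_subtotal, 2)  # base points only
})
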