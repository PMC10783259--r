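pfas_prfs <- list(PFOA = prf_triple("PFOA", 0.93, 0.8955, 0.9645),
                  PFOS = prf_triple("PFOS", 0.317, 0.158, 0.475))

test_that("the PFAS envelope spans the minimum low and maximum high", {
  row <- list(chemical_class = "PFAS", outcome = "Low birth weight",
              exposure_chemical = "PFOA")
  got <- resolve_prf(row, default_rules(), pfas_prfs)
  expect_prf_equal(got, 0.93, 0.158, 0.9645)
})

test_that("a single-chemical rule passes the triple through unchanged", {
  row <- list(chemical_class = "BPA", outcome = "Childhood obesity",
              exposure_chemical = "BPA")
  prfs <- list(BPA = prf_triple("BPA", 0.975, 0.9625, 0.9875))
  expect_prf_equal(resolve_prf(row, default_rules(), prfs),
                   0.975, 0.9625, 0.9875)
})

test_that("the most specific rule wins and overrides apply verbatim", {
  prfs <- list(DEHP = prf_triple("DEHP", 0.985, 0.9775, 0.9925))
  infertility <- list(chemical_class = "PHTHALATE",
                      outcome = "Male infertility",
                      exposure_chemical = "BBP_DBP")
  expect_prf_equal(resolve_prf(infertility, default_rules(), prfs),
                   1.00, 0.71, 1.00)
  other <- list(chemical_class = "PHTHALATE", outcome = "Endometriosis",
                exposure_chemical = "DEHP")
  expect_prf_equal(resolve_prf(other, default_rules(), prfs),
                   0.985, 0.9775, 0.9925)
})

test_that("unmatched rows and missing PRFs raise configuration errors", {
  no_catchall <- list(attribution_rule("PBDE", base_prf_chemical = "PBDE47"))
  row <- list(chemical_class = "BPA", outcome = "x", exposure_chemical = "BPA")
  expect_error(resolve_prf(row, no_catchall, pfas_prfs), "no attribution rule")
  pfas_row <- list(chemical_class = "PFAS", outcome = "x",
                   exposure_chemical = "PFOA")
  expect_error(resolve_prf(pfas_row, default_rules(), pfas_prfs["PFOA"]),
               "no PRF available.*PFOS")
})

test_that("the shipped rules file resolves like the built-in rule set", {
  rules <- read_rules(system.file("extdata", "rules_default.json",
                                  package = "plastattr"))
  prfs <- c(pfas_prfs, list(DEHP = prf_triple("DEHP", 0.985, 0.9775, 0.9925)))
  for (row in list(list(chemical_class = "PFAS", outcome = "Obesity",
                        exposure_chemical = "PFOA"),
                   list(chemical_class = "PHTHALATE",
                        outcome = "Male infertility",
                        exposure_chemical = "BBP_DBP"))) {
    a <- resolve_prf(row, rules, prfs)
    b <- resolve_prf(row, default_rules(), prfs)
    expect_prf_equal(a, b$base, b$low, b$high)
  }
})

test_that("envelope resolution matches a brute-force min/max scan", {
  for (seed in 1:100) {
    set.seed(seed)
    ids <- paste0("C", 1:5)
    prfs <- lapply(ids, function(id) {
      v <- sort(runif(3))
      prf_triple(id, v[2], v[1], v[3])
    })
    names(prfs) <- ids
    envelope <- sample(ids, sample(1:5, 1))
    base_chem <- sample(envelope, 1)
    # brute-force scan over the envelope, one element at a time
    lo <- Inf; hi <- -Inf
    for (id in envelope) {
      if (prfs[[id]]$low < lo) lo <- prfs[[id]]$low
      if (prfs[[id]]$high > hi) hi <- prfs[[id]]$high
    }
    rules <- list(attribution_rule("X", base_prf_chemical = base_chem,
                                   envelope_prf_chemicals = envelope))
    row <- list(chemical_class = "X", outcome = "y", exposure_chemical = "C1")
    expect_prf_equal(resolve_prf(row, rules, prfs),
                     prfs[[base_chem]]$base, lo, hi)
  }
})

test_that("attribution multiplies cost and case triples componentwise", {
  row <- list(chemical_class = "BPA", exposure_chemical = "BPA",
              life_stage = "Prenatal", outcome = "Childhood obesity",
              cost_base = 1.04, cost_low = 1.00, cost_high = 1.08,
              cases_base = 7300, cases_low = 7100, cases_high = 7400)
  prf <- prf_triple("BPA", 0.98, 0.96, 0.99)
  r <- attribute_row(row, prf)
  expect_equal(r$attributable_cost[["base"]], 1.04 * 0.98, tolerance = 1e-15)
  expect_equal(r$attributable_cost[["low"]], 1.00 * 0.96, tolerance = 1e-15)
  expect_equal(r$attributable_cost[["high"]], 1.08 * 0.99, tolerance = 1e-15)
  expect_equal(r$attributable_cases,
               c(base = 7300 * 0.98, low = 7100 * 0.96, high = 7400 * 0.99),
               tolerance = 1e-15)
  # zero PRF extinguishes the burden; missing cases stay missing
  r0 <- attribute_row(row, prf_triple("BPA", 0, 0, 0))
  expect_identical(unname(r0$attributable_cost), c(0, 0, 0))
  row$cases_base <- NA_real_
  expect_null(attribute_row(row, prf)$attributable_cases)
})

test_that("attribution is linear and never exceeds the input burden", {
  for (seed in 1:50) {
    set.seed(seed)
    v <- sort(runif(3))
    prf <- prf_triple("X", v[2], v[1], v[3])
    cost <- sort(rlnorm(3))
    row <- list(chemical_class = "X", exposure_chemical = "X",
                life_stage = "", outcome = "o",
                cost_base = cost[2], cost_low = cost[1], cost_high = cost[3])
    r1 <- attribute_row(row, prf)
    row2 <- row
    row2$cost_base <- 2 * row$cost_base
    row2$cost_low <- 2 * row$cost_low
    row2$cost_high <- 2 * row$cost_high
    r2 <- attribute_row(row2, prf)
    expect_equal(r2$attributable_cost, 2 * r1$attributable_cost,
                 tolerance = 1e-12)
    expect_true(all(r1$attributable_cost <=
                      c(cost[2], cost[1], cost[3]) + 1e-15))
    expect_true(r1$attributable_cost[["low"]] <=
                  r1$attributable_cost[["base"]] + 1e-15)
    expect_true(r1$attributable_cost[["base"]] <=
                  r1$attributable_cost[["high"]] + 1e-15)
  }
})

test_that("aggregation is permutation-invariant and matches a loop oracle", {
  for (seed in 1:40) {
    spec <- generator_spec(seed, n_outcomes = 2 + seed %% 10)
    prfs <- list(A = prf_triple("A", 0.9, 0.8, 0.95),
                 B = prf_triple("B", 0.5, 0.25, 0.75),
                 C = prf_triple("C", 1, 1, 1))
    g <- gen_burden_table(spec, prfs)
    results <- lapply(seq_len(nrow(g$burden)), function(i) {
      row <- as.list(g$burden[i, ])
      attribute_row(row, prfs[[row$exposure_chemical]])
    })
    agg <- aggregate_results(results)
    expect_equal(agg$grand_total, g$true_attributable$grand_total,
                 tolerance = 1e-12)
    perm <- sample(length(results))
    agg2 <- aggregate_results(results[perm])
    expect_equal(agg2$grand_total, agg$grand_total, tolerance = 1e-12)
    # associativity: aggregating per-class partial sums gives the same grand
    classes <- unique(agg$outcomes$chemical_class)
    partial <- sapply(classes, function(cl) {
      sub <- results[vapply(results, function(r) r$chemical_class == cl,
                            logical(1))]
      aggregate_results(sub)$grand_total
    })
    expect_equal(unname(rowSums(partial)), unname(agg$grand_total),
                 tolerance = 1e-12)
  }
})

test_that("a single result aggregates to itself", {
  r <- attribute_row(list(chemical_class = "X", exposure_chemical = "X",
                          life_stage = "", outcome = "o", cost_base = 2,
                          cost_low = 1, cost_high = 4),
                     prf_triple("X", 0.5, 0.25, 0.75))
  agg <- aggregate_results(list(r))
  expect_equal(unname(agg$grand_total), c(1.0, 0.25, 3.0), tolerance = 1e-15)
  expect_identical(nrow(agg$class_totals), 1L)
  expect_error(aggregate_results(list()), "no attributable results")
})

test_that("the shipped burden table reproduces the published class totals", {
  prfs <- published_prfs()
  tab <- attribute_burden(published_burden(), prfs)
  ct <- tab$class_totals
  pbde <- ct[ct$chemical_class == "PBDE", ]
  expect_equal(pbde$cost_base, (162 + 0.0357 + 0.081) * 0.9825,
               tolerance = 1e-12)
  expect_identical(format_cost(pbde$cost_base), "$159 billion")
  bpa <- ct[ct$chemical_class == "BPA", ]
  expect_equal(bpa$cost_base, 1.04 * 0.975, tolerance = 1e-12)
  pfas <- ct[ct$chemical_class == "PFAS", ]
  expect_equal(pfas$cost_base, sum(published_burden()$cost_base[10:22]) * 0.930,
               tolerance = 1e-12)
  expect_identical(format_cost(pfas$cost_base), "$22.4 billion")

  # rounded-PRF mode applies the whole-percent PRFs the source table prints
  tabr <- attribute_burden(published_burden(), prfs,
                           use_printed_prf_rounding = TRUE)
  ctr <- tabr$class_totals
  pfas_low <- ctr[ctr$chemical_class == "PFAS", "cost_low"]
  expect_equal(pfas_low, sum(published_burden()$cost_base[10:22]) * 0.16,
               tolerance = 1e-12)
  expect_identical(format_cost(pfas_low), "$3.85 billion")

  # attributable never exceeds input costs; ordering holds end to end
  o <- tab$outcomes
  b <- published_burden()
  expect_true(all(o$cost_base <= b$cost_base + 1e-12))
  expect_true(all(o$cost_low <= o$cost_base & o$cost_base <= o$cost_high))
  expect_true(all(ct$cost_low <= ct$cost_base & ct$cost_base <= ct$cost_high))
})
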