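test_that("odor value is concentration over threshold", {
  reg <- toy_registry()
  ap <- get_compound(reg, "α-Pinene")
  bc <- get_compound(reg, "β-Caryophyllene")
  expect_equal(odor_value(0.240, ap), 1)
  expect_equal(odor_value(0, ap), 0)
  expect_equal(odor_value(3.0, bc), 2)

  # absent threshold signals exclusion (a message, not an error) and NA
  lin <- get_compound(reg, "Linalool")
  expect_message(ov <- odor_value(5, lin),
                 class = "nanoaroma_excluded_compound")
  expect_true(is.na(suppressMessages(odor_value(5, lin))))
  expect_error(odor_value(-1, ap), class = "nanoaroma_invalid_value")
})

test_that("family rank weights follow the 100/70-30/60-30-10 scheme", {
  expect_equal(family_weights(1), 1.00)
  expect_equal(family_weights(2), c(0.70, 0.30))
  expect_equal(family_weights(3), c(0.60, 0.30, 0.10))
  expect_error(family_weights(0), class = "nanoaroma_invalid_count")
  expect_error(family_weights(4), class = "nanoaroma_invalid_count")
})

test_that("family odor values distribute per-compound values by rank", {
  reg <- toy_registry()
  fov <- family_odor_values("β-Caryophyllene", 10, reg)
  expect_equal(unname(fov["woody"]), 7)
  expect_equal(unname(fov["oriental"]), 3)
  expect_equal(sum(fov), 10)
  expect_equal(sort(names(fov)), sort(OLFACTORY_FAMILIES))

  fov1 <- family_odor_values("α-Pinene", 10, reg)
  expect_equal(unname(fov1["woody"]), 10)

  # additive superposition over compounds
  reg2 <- fixture_registry()
  fov2 <- family_odor_values(c("β-Caryophyllene", "Limonene"), c(10, 5),
                             reg2)
  expect_equal(unname(fov2[c("woody", "oriental", "citrus")]), c(7, 3, 5))
  expect_equal(unname(fov2["musk"]), 0)

  expect_error(family_odor_values("Unknownene", 1, reg),
               class = "nanoaroma_not_found")
})

test_that("weight conservation holds for random compound sets", {
  reg <- fixture_registry()
  set.seed(11)
  for (i in 1:25) {
    idx <- sample(nrow(reg$compounds), sample(1:10, 1), replace = FALSE)
    nms <- reg$compounds$name[idx]
    ov <- stats::rexp(length(nms), rate = 0.1)
    fov <- family_odor_values(nms, ov, reg)
    expect_equal(sum(fov), sum(ov), tolerance = 1e-9)
  }
})

test_that("profile normalization sums to one and flags the zero case", {
  fov <- stats::setNames(numeric(8), OLFACTORY_FAMILIES)
  fov["woody"] <- 7
  fov["oriental"] <- 3
  prof <- normalize_profile(fov)
  expect_false(prof$degenerate)
  expect_equal(unname(prof$values["woody"]), 0.7)
  expect_equal(unname(prof$values["oriental"]), 0.3)
  expect_equal(sum(prof$values), 1, tolerance = 1e-9)

  zero <- normalize_profile(stats::setNames(numeric(8),
                                            OLFACTORY_FAMILIES))
  expect_true(zero$degenerate)
  expect_equal(sum(zero$values), 0)

  even <- stats::setNames(numeric(8), OLFACTORY_FAMILIES)
  even[c("woody", "herbal")] <- 2
  expect_equal(unname(normalize_profile(even)$values[c("woody",
                                                       "herbal")]),
               c(0.5, 0.5))
})

test_that("radar coordinates lay out 8 fixed axes clockwise from 90", {
  fov <- stats::setNames(rep(1, 8), OLFACTORY_FAMILIES)
  coords <- radar_coordinates(normalize_profile(fov))
  expect_equal(coords$family, OLFACTORY_FAMILIES)
  expect_equal(coords$radius, rep(0.125, 8))
  expect_equal(coords$angle_deg, c(90, 45, 0, 315, 270, 225, 180, 135))

  solo <- stats::setNames(numeric(8), OLFACTORY_FAMILIES)
  solo["woody"] <- 4
  sc <- radar_coordinates(normalize_profile(solo))
  expect_equal(sc$radius[sc$family == "woody"], 1)
  expect_equal(sum(sc$radius), 1)

  two <- stats::setNames(numeric(8), OLFACTORY_FAMILIES)
  two["woody"] <- 7
  two["oriental"] <- 3
  tc <- radar_coordinates(normalize_profile(two))
  expect_equal(tc$radius[tc$family == "woody"], 0.7)

  zero <- normalize_profile(stats::setNames(numeric(8),
                                            OLFACTORY_FAMILIES))
  expect_error(radar_coordinates(zero),
               class = "nanoaroma_degenerate_profile")
})

test_that("the full chain on the packaged tables gives a woody profile", {
  res <- radar_from_composition(fixture_composition(), fixture_registry())
  expect_false(res$profile$degenerate)
  expect_equal(dominant_family(res$profile), "woody")
  expect_equal(sum(res$profile$values), 1, tolerance = 1e-9)
  # compounds without a threshold are logged, not silently dropped
  expect_true(all(c("Camphene", "α-Copaene", "α-Humulene", "β-Selinene",
                    "δ-Cadinene") %in% res$exclusions$compound))
})

test_that("the radar profile is invariant to overall concentration scale", {
  reg <- fixture_registry()
  tab <- fixture_composition()
  base <- radar_from_composition(tab, reg)
  for (lambda in c(0.2, 5, 40)) {
    hotter <- radar_from_composition(tab, reg,
                                     temperature = 298.15 / lambda)
    # scaling T scales every predicted concentration by lambda uniformly
    expect_equal(hotter$profile$values, base$profile$values,
                 tolerance = 1e-9)
  }
  # and directly at the family-value level
  fov <- base$family_odor_values
  expect_equal(normalize_profile(fov * 17)$values,
               normalize_profile(fov)$values, tolerance = 1e-12)
})

test_that("degenerate and tie cases are reported, not broken silently", {
  fov <- stats::setNames(numeric(8), OLFACTORY_FAMILIES)
  fov[c("woody", "citrus")] <- 3
  tie <- normalize_profile(fov)
  expect_setequal(dominant_family(tie), c("woody", "citrus"))
  zero <- normalize_profile(stats::setNames(numeric(8),
                                            OLFACTORY_FAMILIES))
  expect_error(dominant_family(zero),
               class = "nanoaroma_degenerate_profile")
})
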