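# Derived-phenotype rules: BP averaging, categories, Devereux LVM, BSA,
# LVMI/LVH, waist-to-height, CSV round-trip.

test_that("BP triplet averaging uses readings 2 and 3 only", {
  expect_equal(average_bp(rbind(c(130, 80), c(120, 74), c(124, 78))),
               c(sbp = 122, dbp = 76))
  expect_equal(average_bp(rbind(c(110, 70), c(110, 70), c(110, 70))),
               c(sbp = 110, dbp = 70))
  expect_equal(average_bp(rbind(c(100, 60), c(101, 61), c(102, 63))),
               c(sbp = 101.5, dbp = 62))
  expect_error(average_bp(rbind(c(130, 80), c(120, 74))), "three")
  expect_error(average_bp(rbind(c(130, 80), c(NA, 74), c(124, 78))),
               "present")
})

test_that("adult BMI categories respect the stated interval boundaries", {
  expect_equal(as.character(classify_bmi_adult(18.4)), "underweight")
  expect_equal(as.character(classify_bmi_adult(25.0)), "overweight")
  expect_equal(as.character(classify_bmi_adult(30.0)), "obese")
  expect_equal(as.character(classify_bmi_adult(24.95)), "normal")
  # total on a dense grid, monotone in BMI
  grid <- seq(10, 45, by = 0.01)
  cats <- classify_bmi_adult(grid)
  expect_false(anyNA(cats))
  expect_true(all(diff(as.integer(cats)) >= 0))
  expect_error(classify_bmi_adult(0), "positive")
})

test_that("adult BP status uses thresholds and the medication override", {
  expect_equal(as.character(classify_bp_adult(118, 76, FALSE)), "normal")
  expect_equal(as.character(classify_bp_adult(135, 78, FALSE)),
               "prehypertension")
  expect_equal(as.character(classify_bp_adult(118, 76, TRUE)), "hypertension")
  expect_equal(as.character(classify_bp_adult(140, 70, FALSE)), "hypertension")
  expect_equal(as.character(classify_bp_adult(119, 90, FALSE)), "hypertension")
  expect_equal(as.character(classify_bp_adult(NA, NA, TRUE)), "hypertension")
  expect_error(classify_bp_adult(NA, 80, FALSE), "missing")
})

test_that("child categories come from the supplied reference tables", {
  tabs <- reference_tables(
    iotf_bmi = data.frame(sex = "female", age = 7, underweight = 14,
                          overweight = 18, obese = 20),
    aap_bp = data.frame(sex = "female", age = 7, height = 120,
                        sbp_p90 = 110, dbp_p90 = 72,
                        sbp_p95 = 114, dbp_p95 = 75))
  expect_equal(as.character(classify_bmi_child("female", 7, 19, tabs)),
               "overweight")
  expect_equal(as.character(classify_bmi_child("female", 7, 13.9, tabs)),
               "underweight")
  # a value at the cut-off enters the higher category
  expect_equal(as.character(classify_bmi_child("female", 7, 18, tabs)),
               "overweight")
  expect_equal(as.character(classify_bmi_child("female", 7, 20, tabs)),
               "obese")
  expect_error(classify_bmi_child("female", 12, 17, tabs), "cover")
  expect_error(classify_bmi_child("male", 7, 17, tabs), "sex")

  expect_equal(as.character(classify_bp_child("female", 7, 120, 112, 70, tabs)),
               "elevated")
  expect_equal(as.character(classify_bp_child("female", 7, 120, 114, 70, tabs)),
               "hypertension")
  expect_equal(as.character(classify_bp_child("female", 7, 120, 105, 60, tabs)),
               "normal")
  expect_error(classify_bp_child("female", 12, 120, 105, 60, tabs), "cover")
})

test_that("hazardous alcohol use follows the AUDIT rule", {
  expect_true(audit_hazardous(3, 5))
  expect_true(audit_hazardous(2, 8))
  expect_false(audit_hazardous(2, 7))
  expect_true(audit_hazardous(NA, 9))
  expect_false(audit_hazardous(NA, 3))
  expect_error(audit_hazardous(NA, NA), "missing")
})

test_that("Devereux LVM evaluates the corrected cube formula", {
  expect_equal(devereux_lvm(0.9, 4.8, 0.9),
               0.8 * 1.04 * (6.6^3 - 4.8^3) + 0.6, tolerance = 1e-12)
  expect_equal(devereux_lvm(0.9, 4.8, 0.9), 147.784128, tolerance = 1e-9)
  # cubic homogeneity: doubling all dimensions multiplies (LVM - 0.6) by 8
  base <- devereux_lvm(0.8, 4.5, 0.85) - 0.6
  expect_equal(devereux_lvm(1.6, 9.0, 1.7) - 0.6, 8 * base,
               tolerance = 1e-10)
  expect_error(devereux_lvm(0, 4.8, 0), "positive")
})

test_that("body surface area formulas are correct and monotone", {
  expect_equal(body_surface_area(160, 57.6), 1.6, tolerance = 1e-12)
  expect_equal(body_surface_area(170, 70, "dubois"),
               0.007184 * 170^0.725 * 70^0.425, tolerance = 1e-12)
  h <- seq(100, 200, by = 10); w <- seq(20, 120, by = 10)
  for (wt in w) {
    expect_true(all(diff(body_surface_area(h, wt)) > 0))
  }
  for (ht in h) {
    expect_true(all(diff(body_surface_area(ht, w)) > 0))
  }
  # product-rule consistency on a grid: BSA^2 * 3600 = h * w
  gr <- expand.grid(h = h, w = w)
  expect_equal(body_surface_area(gr$h, gr$w)^2 * 3600, gr$h * gr$w,
               tolerance = 1e-10)
  expect_error(body_surface_area(-1, 60), "positive")
})

test_that("LVMI indexing and LVH thresholds are strict inequalities", {
  expect_equal(lvmi_and_lvh(160, 1.6, "parent")$lvmi, 100)
  expect_false(lvmi_and_lvh(95 * 1.6, 1.6, "grandparent")$lvh)
  expect_true(lvmi_and_lvh(95.1 * 1.6, 1.6, "grandparent")$lvh)
  tabs <- reference_tables()
  expect_true(lvmi_and_lvh(110 * 1.2, 1.2, "child", tabs)$lvh)
  expect_false(lvmi_and_lvh(109.4 * 1.2, 1.2, "child", tabs)$lvh)
  expect_error(lvmi_and_lvh(100, 0, "parent"), "positive")
})

test_that("waist-to-height ratio is a scale-invariant quotient", {
  expect_equal(waist_to_height(80, 160), 0.5)
  expect_equal(waist_to_height(104.4, 157.3), 0.6637, tolerance = 5e-5)
  for (k in c(0.5, 1, 2, 7.3)) {
    expect_equal(waist_to_height(54.8 * k, 122.5 * k),
                 waist_to_height(54.8, 122.5), tolerance = 1e-12)
  }
  expect_error(waist_to_height(80, 0), "positive")
})

test_that("phenotype tables round-trip through CSV with missing cells", {
  sim <- generate_dataset(synthetic_config(n_families = 12, seed = 4))
  path <- tempfile(fileext = ".csv")
  write_phenotypes(sim$data, path)
  back <- read_phenotypes(path)
  expect_equal(names(back), names(sim$data))
  for (cl in names(back)) {
    expect_equal(back[[cl]], sim$data[[cl]], tolerance = 1e-9, info = cl)
  }
  unlink(path)
})

test_that("derived phenotypes propagate missingness, never impute", {
  sim <- generate_dataset(synthetic_config(n_families = 10, seed = 8))
  d <- sim$data
  d$height[1] <- NA
  d$ivsd[2] <- 1.0; d$lvidd[2] <- 4.6; d$pwd[2] <- 0.95
  d$lvmi_bsa[2] <- NA
  out <- derive_phenotypes(d)
  expect_true(is.na(out$bmi[1]))
  expect_true(is.na(out$bsa[1]))
  expect_true(is.na(out$bmi_category[1]))
  # echo dimensions fill LVM and LVMI via Devereux + BSA
  expect_equal(out$lvm[2], devereux_lvm(1.0, 4.6, 0.95))
  expect_equal(out$lvmi_bsa[2], out$lvm[2] / out$bsa[2])
  expect_equal(out$lvh[2], out$lvmi_bsa[2] > 95)
})
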