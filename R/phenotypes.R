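# family_data: domain types and derived-phenotype rules for the
# three-generation cardiovascular phenotype table.

PHENO_COLUMNS <- c(
  "individual_id", "family_id", "generation", "sex", "mother_id",
  "age", "height", "weight", "waist", "muac",
  "brachial_sbp", "brachial_dbp", "central_sbp", "central_dbp",
  "pulse_pressure", "mean_arterial_pressure", "resting_hr",
  "pwv", "cimt_left", "ivsd", "lvidd", "pwd", "lvm", "lvmi_bsa",
  "on_antihypertensives", "tobacco_user", "audit_c", "audit_total"
)

GENERATIONS <- c("grandparent", "parent", "child")

#' Read a phenotype table
#'
#' One row per individual; missing values are empty cells.  Column names
#' follow the package schema (`individual_id`, `family_id`, `generation`
#' in `grandparent/parent/child`, `sex` in `female/male`, `mother_id`,
#' anthropometry, vascular measures, behaviour flags).
#'
#' @param path CSV file path.
#' @return data.frame with validated columns.
#' @seealso [write_phenotypes()], [generate_dataset()]
#' @export
read_phenotypes <- function(path) {
  dat <- utils::read.csv(path, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  # all-NA columns read as logical; coerce schema-numeric columns back
  num_cols <- setdiff(PHENO_COLUMNS,
                      c("individual_id", "family_id", "generation", "sex",
                        "mother_id", "on_antihypertensives", "tobacco_user"))
  for (cl in intersect(num_cols, names(dat))) {
    dat[[cl]] <- as.numeric(dat[[cl]])
  }
  validate_phenotypes(dat)
}

#' Write a phenotype table (missing = empty cell)
#' @param data phenotype data.frame.
#' @param path output CSV path.
#' @export
write_phenotypes <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a phenotype table against the package schema
#'
#' Checks required identity columns, generation/sex levels, positivity of
#' present measurements, and maternal links (every parent's mother is a
#' grandparent of the same family; every child's mother is a parent).
#'
#' @param data data.frame to validate.
#' @return the data, invisibly coerced (logical flags, numeric measures).
#' @export
validate_phenotypes <- function(data) {
  need <- c("individual_id", "family_id", "generation", "sex", "age")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(data$individual_id)) {
    stop("duplicate individual_id in phenotype table")
  }
  bad <- setdiff(unique(data$generation), GENERATIONS)
  if (length(bad)) {
    stop("unknown generation value(s): ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(data$sex), c("female", "male"))
  if (length(bad)) {
    stop("unknown sex value(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.na(data$age) & data$age <= 0)) stop("age must be > 0")
  for (col in c("height", "weight", "brachial_sbp", "brachial_dbp",
                "central_sbp", "central_dbp", "pwv", "cimt_left")) {
    if (col %in% names(data)) {
      check_positive(data[[col]], col, allow_na = TRUE)
    }
  }
  # adults are female by study design
  adult <- data$generation %in% c("grandparent", "parent")
  if (any(data$sex[adult] != "female")) {
    stop("grandparents and parents must be female in this study design")
  }
  # maternal links resolve within family, one generation up
  if ("mother_id" %in% names(data)) {
    idx <- match(data$mother_id, data$individual_id)
    has <- !is.na(data$mother_id)
    if (any(has & is.na(idx))) {
      stop("mother_id does not resolve for: ",
           paste(data$individual_id[has & is.na(idx)], collapse = ", "))
    }
    same_fam <- data$family_id[idx[has]] == data$family_id[has]
    if (any(!same_fam)) {
      stop("mother_id points outside the family for: ",
           paste(data$individual_id[has][!same_fam], collapse = ", "))
    }
    up <- c(parent = "grandparent", child = "parent")
    expect_gen <- up[data$generation[has]]
    ok <- is.na(expect_gen) | data$generation[idx[has]] == expect_gen
    if (any(!ok)) {
      stop("mother_id generation mismatch for: ",
           paste(data$individual_id[has][!ok], collapse = ", "))
    }
  }
  for (col in c("on_antihypertensives", "tobacco_user")) {
    if (col %in% names(data)) data[[col]] <- as.logical(data[[col]])
  }
  invisible(data)
}

#' Average a triplet of blood-pressure readings
#'
#' Three sequential readings are taken; the first accommodates the
#' white-coat response and is discarded, and the second and third are
#' averaged component-wise.
#'
#' @param readings 3-row matrix or data.frame with columns `sbp`, `dbp`
#'   (mm Hg), rows in measurement order.
#' @return named numeric vector `c(sbp =, dbp =)`.
#' @examples
#' average_bp(rbind(c(130, 80), c(120, 74), c(124, 78)))  # 122, 76
#' @export
average_bp <- function(readings) {
  readings <- as.matrix(readings)
  if (nrow(readings) != 3L || ncol(readings) != 2L) {
    stop("exactly three (sbp, dbp) readings are required")
  }
  if (anyNA(readings[2:3, ])) {
    stop("readings 2 and 3 must be present to average")
  }
  out <- colMeans(readings[2:3, , drop = FALSE])
  names(out) <- c("sbp", "dbp")
  out
}

#' Adult BMI category
#'
#' `<18.5` underweight, `[18.5, 25)` normal, `[25, 30)` overweight,
#' `>= 30` obese (half-open intervals so 24.95 is classified).
#'
#' @param bmi kg/m^2, vectorised.
#' @return factor with levels underweight/normal/overweight/obese.
#' @export
classify_bmi_adult <- function(bmi) {
  check_positive(bmi, "bmi")
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

#' Reference tables for child classifications
#'
#' Child BMI and blood-pressure categories require external age/sex(/height)
#' specific cut-offs.  These ship as replaceable CSV resources; the bundled
#' files are small synthetic fixtures illustrating the schema, not the
#' published reference values, and should be replaced for substantive use.
#'
#' Schemas: BMI table columns `sex, age, underweight, overweight, obese`
#' (cut-offs; a value at or above a cut-off enters the higher category);
#' BP table columns `sex, age, height, sbp_p90, dbp_p90, sbp_p95, dbp_p95`.
#'
#' @param iotf_bmi path or data.frame with child BMI cut-offs.
#' @param aap_bp path or data.frame with child BP percentile thresholds.
#' @param child_lvmi_p95 LVMI threshold (g/m^2) for child LVH; default the
#'   cohort's 95th percentile, 109.4 g/m^2.
#' @return object of class `reference_tables`.
#' @export
reference_tables <- function(
    iotf_bmi = system.file("extdata", "iotf_bmi_cutoffs_synthetic.csv",
                           package = "famh2"),
    aap_bp = system.file("extdata", "aap_bp_thresholds_synthetic.csv",
                         package = "famh2"),
    child_lvmi_p95 = 109.4) {
  load_tab <- function(x) {
    if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  }
  out <- list(iotf_bmi = load_tab(iotf_bmi), aap_bp = load_tab(aap_bp),
              child_lvmi_p95 = child_lvmi_p95)
  stopifnot(all(c("sex", "age", "underweight", "overweight", "obese") %in%
                  names(out$iotf_bmi)),
            all(c("sex", "age", "height", "sbp_p90", "dbp_p90",
                  "sbp_p95", "dbp_p95") %in% names(out$aap_bp)))
  class(out) <- "reference_tables"
  out
}

# nearest-age row for (sex, age); error if no row within 1 year.
nearest_age_row <- function(tab, sex, age, what) {
  rows <- tab[tab$sex == sex, , drop = FALSE]
  if (!nrow(rows)) stop(what, " table has no rows for sex '", sex, "'")
  d <- abs(rows$age - age)
  if (min(d) > 1) {
    stop(what, " table does not cover age ", age, " for sex '", sex, "'")
  }
  rows[which.min(d), , drop = FALSE]
}

#' Child BMI category from age/sex-specific cut-offs
#'
#' @param sex `"female"` or `"male"`.
#' @param age years.
#' @param bmi kg/m^2.
#' @param tables [reference_tables()].
#' @return factor level among underweight/normal/overweight/obese.  A BMI
#'   at a cut-off enters the higher category.
#' @export
classify_bmi_child <- function(sex, age, bmi, tables) {
  check_positive(bmi, "bmi")
  row <- nearest_age_row(tables$iotf_bmi, sex, age, "child BMI")
  lev <- c("underweight", "normal", "overweight", "obese")
  out <- if (bmi >= row$obese) "obese"
  else if (bmi >= row$overweight) "overweight"
  else if (bmi >= row$underweight) "normal"
  else "underweight"
  factor(out, levels = lev)
}

#' Adult blood-pressure status
#'
#' Hypertension: SBP >= 140 or DBP >= 90 mm Hg or current antihypertensive
#' medication; prehypertension: SBP 120-139 or DBP 80-89 and not on
#' medication; otherwise normal.
#'
#' @param sbp,dbp mm Hg.
#' @param on_meds logical, current antihypertensive medication.
#' @return factor with levels normal/prehypertension/hypertension.
#' @export
classify_bp_adult <- function(sbp, dbp, on_meds) {
  lev <- c("normal", "prehypertension", "hypertension")
  if (isTRUE(on_meds)) {
    return(factor("hypertension", levels = lev))  # medication alone suffices
  }
  if (is.na(sbp) || is.na(dbp)) {
    stop("blood pressure missing and not on antihypertensive medication")
  }
  out <- if (sbp >= 140 || dbp >= 90) "hypertension"
  else if (sbp >= 120 || dbp >= 80) "prehypertension"
  else "normal"
  factor(out, levels = lev)
}

#' Child blood-pressure status from percentile thresholds
#'
#' Compares readings with age/sex/height-specific 90th and 95th percentile
#' thresholds: at or above the 95th (either component) is hypertension, at
#' or above the 90th is elevated, else normal.
#'
#' @param sex,age,height child stratum (years, cm).
#' @param sbp,dbp mm Hg.
#' @param tables [reference_tables()].
#' @return factor with levels normal/elevated/hypertension.
#' @export
classify_bp_child <- function(sex, age, height, sbp, dbp, tables) {
  if (is.na(sbp) || is.na(dbp)) stop("blood pressure missing")
  rows <- tables$aap_bp[tables$aap_bp$sex == sex, , drop = FALSE]
  if (!nrow(rows)) stop("child BP table has no rows for sex '", sex, "'")
  d <- abs(rows$age - age)
  if (min(d) > 1) {
    stop("child BP table does not cover age ", age, " for sex '", sex, "'")
  }
  rows <- rows[d == min(d), , drop = FALSE]
  row <- rows[which.min(abs(rows$height - height)), , drop = FALSE]
  lev <- c("normal", "elevated", "hypertension")
  out <- if (sbp >= row$sbp_p95 || dbp >= row$dbp_p95) "hypertension"
  else if (sbp >= row$sbp_p90 || dbp >= row$dbp_p90) "elevated"
  else "normal"
  factor(out, levels = lev)
}

#' Hazardous or harmful alcohol use from AUDIT scores
#'
#' True iff AUDIT-C (three-question short form) >= 3 and/or total AUDIT
#' >= 8.  A missing score does not trigger the flag; both missing is an
#' error.
#'
#' @param audit_c AUDIT-C score.
#' @param audit_total total AUDIT score.
#' @return logical.
#' @export
audit_hazardous <- function(audit_c, audit_total) {
  if (is.na(audit_c) && is.na(audit_total)) {
    stop("both AUDIT scores missing")
  }
  (!is.na(audit_c) && audit_c >= 3) ||
    (!is.na(audit_total) && audit_total >= 8)
}

#' Left ventricular mass by the corrected Devereux formula
#'
#' `LVM = 0.8 * 1.04 * ((IVSd + LVIDd + PWd)^3 - LVIDd^3) + 0.6` grams,
#' with end-diastolic interventricular septal thickness, LV internal
#' diameter and posterior wall thickness in cm (ASE-convention cube
#' formula with the Devereux-Reichek correction).
#'
#' @param ivsd,lvidd,pwd echocardiographic dimensions, cm.
#' @return LV mass in grams, vectorised.
#' @examples
#' devereux_lvm(0.9, 4.8, 0.9)  # 147.78 g
#' @export
devereux_lvm <- function(ivsd, lvidd, pwd) {
  check_positive(ivsd, "ivsd"); check_positive(lvidd, "lvidd")
  check_positive(pwd, "pwd")
  0.8 * 1.04 * ((ivsd + lvidd + pwd)^3 - lvidd^3) + 0.6
}

#' Body surface area
#'
#' Mosteller (default): `sqrt(height * weight / 3600)`.
#' Du Bois: `0.007184 * height^0.725 * weight^0.425`.
#' The LVMI threshold of 95 g/m^2 is sensitive to the BSA formula, so the
#' choice is explicit.
#'
#' @param height cm.
#' @param weight kg.
#' @param method `"mosteller"` or `"dubois"`.
#' @return BSA in m^2, vectorised.
#' @export
body_surface_area <- function(height, weight,
                              method = c("mosteller", "dubois")) {
  method <- match.arg(method)
  check_positive(height, "height"); check_positive(weight, "weight")
  switch(method,
         mosteller = sqrt(height * weight / 3600),
         dubois = 0.007184 * height^0.725 * weight^0.425)
}

#' LVM indexing and left ventricular hypertrophy flag
#'
#' `LVMI = LVM / BSA`.  LVH: adults (grandparent/parent, all women here)
#' iff LVMI > 95 g/m^2; children iff LVMI > the supplied child 95th
#' percentile threshold (default 109.4 g/m^2).  Strict inequalities.
#'
#' @param lvm grams.
#' @param bsa m^2.
#' @param generation `"grandparent"`, `"parent"` or `"child"`.
#' @param tables [reference_tables()] supplying `child_lvmi_p95`.
#' @return list with `lvmi` (g/m^2) and `lvh` (logical).
#' @export
lvmi_and_lvh <- function(lvm, bsa, generation, tables = reference_tables()) {
  check_positive(lvm, "lvm"); check_positive(bsa, "bsa")
  generation <- match.arg(generation, GENERATIONS)
  lvmi <- lvm / bsa
  thr <- if (generation == "child") tables$child_lvmi_p95 else 95
  list(lvmi = lvmi, lvh = lvmi > thr)
}

#' Waist-to-height ratio
#' @param waist,height cm.
#' @return dimensionless ratio, vectorised.
#' @export
waist_to_height <- function(waist, height) {
  check_positive(waist, "waist"); check_positive(height, "height")
  waist / height
}

#' Derive secondary phenotypes for a whole table
#'
#' Adds BMI + category, waist-to-height ratio, BSA, Devereux LVM and
#' LVMI/LVH (where echo dimensions are present and `lvm`/`lvmi_bsa` are
#' not already filled), blood-pressure status, and the hazardous-alcohol
#' flag.  Missingness propagates: a derived value is `NA` whenever any
#' input is.
#'
#' @param data phenotype data.frame.
#' @param tables [reference_tables()].
#' @param bsa_method passed to [body_surface_area()].
#' @return the data with derived columns appended.
#' @export
derive_phenotypes <- function(data, tables = reference_tables(),
                              bsa_method = "mosteller") {
  data <- validate_phenotypes(data)
  n <- nrow(data)
  data$bmi <- ifelse(!is.na(data$height) & !is.na(data$weight),
                     data$weight / (data$height / 100)^2, NA_real_)
  data$whtr <- ifelse(!is.na(data$waist) & !is.na(data$height),
                      data$waist / data$height, NA_real_)
  data$bsa <- NA_real_
  hw <- !is.na(data$height) & !is.na(data$weight)
  if (any(hw)) {
    data$bsa[hw] <- body_surface_area(data$height[hw], data$weight[hw],
                                      bsa_method)
  }
  bmi_cat <- rep(NA_character_, n)
  bp_cat <- rep(NA_character_, n)
  lvh <- rep(NA, n)
  for (i in seq_len(n)) {
    child <- data$generation[i] == "child"
    if (!is.na(data$bmi[i])) {
      bmi_cat[i] <- as.character(
        if (child) classify_bmi_child(data$sex[i], data$age[i],
                                      data$bmi[i], tables)
        else classify_bmi_adult(data$bmi[i]))
    }
    sbp <- data$brachial_sbp[i]; dbp <- data$brachial_dbp[i]
    if (child) {
      if (!is.na(sbp) && !is.na(dbp) && !is.na(data$height[i])) {
        bp_cat[i] <- as.character(classify_bp_child(
          data$sex[i], data$age[i], data$height[i], sbp, dbp, tables))
      }
    } else {
      meds <- isTRUE(data$on_antihypertensives[i])
      if (meds || (!is.na(sbp) && !is.na(dbp))) {
        bp_cat[i] <- as.character(classify_bp_adult(sbp, dbp, meds))
      }
    }
  }
  # LVM from echo dimensions where needed
  if (!"lvm" %in% names(data)) data$lvm <- NA_real_
  if (all(c("ivsd", "lvidd", "pwd") %in% names(data))) {
    can <- !is.na(data$ivsd) & !is.na(data$lvidd) & !is.na(data$pwd)
    need <- is.na(data$lvm)
    data$lvm[can & need] <- devereux_lvm(data$ivsd[can & need],
                                         data$lvidd[can & need],
                                         data$pwd[can & need])
  }
  if (!"lvmi_bsa" %in% names(data)) data$lvmi_bsa <- NA_real_
  fill <- is.na(data$lvmi_bsa) & !is.na(data$lvm) & !is.na(data$bsa)
  data$lvmi_bsa[fill] <- data$lvm[fill] / data$bsa[fill]
  for (i in seq_len(n)) {
    if (!is.na(data$lvmi_bsa[i])) {
      thr <- if (data$generation[i] == "child") tables$child_lvmi_p95 else 95
      lvh[i] <- data$lvmi_bsa[i] > thr
    }
  }
  data$bmi_category <- bmi_cat
  data$bp_status <- bp_cat
  data$lvh <- lvh
  if (all(c("audit_c", "audit_total") %in% names(data))) {
    data$alcohol_hazardous <- mapply(function(a, b) {
      if (is.na(a) && is.na(b)) NA else audit_hazardous(a, b)
    }, data$audit_c, data$audit_total)
  }
  data
}
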