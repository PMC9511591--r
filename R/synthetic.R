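# synthetic_data: three-generation family datasets with known genetic
# architecture, for end-to-end testing of both analysis stages.

#' Default per-trait generative parameters
#'
#' One row per vascular trait: true heritability `h2`, phenotypic
#' variance `sigma_p2` (trait units squared), intercept at age 30, an age
#' slope per year (which creates the generation gradient), and a
#' male-offset sex effect.  Locations and spreads are loosely matched to
#' the cohort's descriptive medians/IQRs; exact marginal matching is a
#' non-goal — the two analysis stages only need the dependence structure.
#'
#' @return data.frame, one row per trait.
#' @export
default_trait_params <- function() {
  data.frame(
    trait = c("brachial_sbp", "brachial_dbp", "central_sbp", "central_dbp",
              "pwv", "cimt_left", "lvmi_bsa"),
    h2 = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.35, 0.30),
    sigma_p2 = c(150, 80, 130, 70, 1.2, 0.012, 480),
    intercept = c(115, 72, 105, 73, 6.3, 0.50, 78),
    beta_age = c(0.60, 0.25, 0.70, 0.30, 0.085, 0.0045, 0.60),
    beta_sex = c(-2, -1, -2, -1, 0, 0, -4),
    stringsAsFactors = FALSE
  )
}

#' Default per-measure missingness rates
#'
#' Fractions of individuals with a failed measurement, per generation
#' (grandparent, parent, child), chosen to match the cohort's completed
#' measurement counts (e.g. PWV successful in 57/61/56 of 65).
#'
#' @return data.frame with columns `trait`, `grandparent`, `parent`, `child`.
#' @export
default_missingness <- function() {
  data.frame(
    trait = c("brachial_sbp", "brachial_dbp", "central_sbp", "central_dbp",
              "pwv", "cimt_left", "lvmi_bsa"),
    grandparent = c(0, 0, 0, 0, 8 / 65, 2 / 65, 7 / 65),
    parent = c(0, 0, 0, 0, 4 / 65, 2 / 65, 2 / 65),
    child = c(3 / 65, 3 / 65, 3 / 65, 3 / 65, 9 / 65, 2 / 65, 2 / 65),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic family-trait generator
#'
#' Defaults emulate the study conditions: 65 maternal-line trios
#' (195 individuals), all-female adult generations, child sex female with
#' probability 36/65, generation age medians 56/29/7 years, and
#' per-measure missingness matching the completed counts.
#'
#' @param n_families number of trios.
#' @param traits data.frame as [default_trait_params()].
#' @param missingness data.frame as [default_missingness()], or `NULL`
#'   for complete data.
#' @param p_female_child probability a child is female.
#' @param seed master seed; all generator randomness flows from it via
#'   [derive_seeds()].
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_families = 65,
                             traits = default_trait_params(),
                             missingness = default_missingness(),
                             p_female_child = 36 / 65,
                             seed = 1) {
  stopifnot(n_families >= 1,
            all(traits$h2 >= 0 & traits$h2 <= 1),
            all(traits$sigma_p2 > 0))
  if (!is.null(missingness)) {
    rates <- as.matrix(missingness[c("grandparent", "parent", "child")])
    stopifnot(all(rates >= 0 & rates <= 1))
  }
  structure(list(n_families = n_families, traits = traits,
                 missingness = missingness,
                 p_female_child = p_female_child, seed = seed),
            class = "synthetic_config")
}

#' Generate a maternal-line trio pedigree
#'
#' `n_families` disjoint grandmother-mother-child trios; adults female,
#' child sex Bernoulli.
#'
#' @param n_families trio count.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param p_female_child probability a child is female.
#' @return a [build_pedigree()] object with `3 * n_families` individuals.
#' @export
generate_pedigree <- function(n_families, seed = NULL,
                              p_female_child = 36 / 65) {
  stopifnot(n_families >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fam <- sprintf("F%04d", seq_len(n_families))
  ids <- c(paste0(fam, "_GM"), paste0(fam, "_M"), paste0(fam, "_C"))
  d <- data.frame(
    individual_id = ids,
    family_id = rep(fam, 3),
    mother_id = c(rep(NA_character_, n_families), paste0(fam, "_GM"),
                  paste0(fam, "_M")),
    father_id = NA_character_,
    sex = c(rep("female", 2 * n_families),
            ifelse(stats::runif(n_families) < p_female_child,
                   "female", "male")),
    stringsAsFactors = FALSE
  )
  build_pedigree(d)
}

#' Sample breeding values down a pedigree
#'
#' Founders receive `g ~ N(0, sigma_g2)`.  An individual with one known
#' (maternal) parent receives `g = g_mother / 2 + N(0, 3/4 sigma_g2)` —
#' the unobserved father contributes an independent half-genome — so each
#' marginal variance is `sigma_g2` and `Cov(g) = sigma_g2 * G` for the
#' pedigree GRM `G`.  With both parents known the Mendelian segregation
#' variance is `sigma_g2 / 2`.
#'
#' @param ped a [build_pedigree()] object (topologically ordered).
#' @param sigma_g2 additive genetic variance (0 gives all-zero values).
#' @param seed RNG seed.
#' @return named numeric vector of breeding values.
#' @export
sample_breeding_values <- function(ped, sigma_g2, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), sigma_g2 >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(ped)
  g <- numeric(n)
  names(g) <- ped$individual_id
  if (sigma_g2 == 0) return(g)
  mi <- match(ped$mother_id, ped$individual_id)
  fi <- match(ped$father_id, ped$individual_id)
  # process in waves: all parents of wave k live in waves < k
  done <- logical(n)
  while (!all(done)) {
    ready <- !done & (is.na(mi) | done[pmax(mi, 1L)]) &
      (is.na(fi) | done[pmax(fi, 1L)])
    idx <- which(ready)
    founder <- is.na(mi[idx]) & is.na(fi[idx])
    g[idx[founder]] <- stats::rnorm(sum(founder), sd = sqrt(sigma_g2))
    nb <- idx[!founder]
    if (length(nb)) {
      one <- xor(is.na(mi[nb]), is.na(fi[nb]))
      mid <- ifelse(is.na(mi[nb]), 0, g[pmax(mi[nb], 1L)]) +
        ifelse(is.na(fi[nb]), 0, g[pmax(fi[nb], 1L)])
      segvar <- ifelse(one, 0.75, 0.5) * sigma_g2
      g[nb] <- mid / 2 + stats::rnorm(length(nb), sd = sqrt(segvar))
    }
    done[idx] <- TRUE
  }
  g
}

# generation role from the maternal chain depth
pedigree_roles <- function(ped) {
  mi <- match(ped$mother_id, ped$individual_id)
  depth <- integer(nrow(ped))
  for (i in seq_len(nrow(ped))) {           # topological order
    depth[i] <- if (is.na(mi[i])) 0L else depth[mi[i]] + 1L
  }
  c("grandparent", "parent", "child")[depth + 1L]
}

#' Generate phenotype records for a pedigree
#'
#' Covariates are drawn from generation-specific distributions (ages
#' centred near 56/29/7 years; anthropometry from generation-typical
#' ranges) and each trait follows
#' `y = b0 + b_age * (age - 30) + b_sex * male + g + e`,
#' `e ~ N(0, (1 - h2) sigma_p2)` i.i.d., with `g` the supplied breeding
#' values (variance `h2 * sigma_p2`).  Missingness is applied per measure
#' and generation, independently.
#'
#' @param ped a [build_pedigree()] object.
#' @param g matrix of breeding values, rows aligned with `ped`, one
#'   column per trait in `config$traits`.
#' @param config a [synthetic_config()] object.
#' @param seed RNG seed.
#' @return phenotype data.frame in the package schema.
#' @export
generate_traits <- function(ped, g, config, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(ped)
  role <- pedigree_roles(ped)
  gp <- role == "grandparent"; pa <- role == "parent"; ch <- role == "child"

  age <- numeric(n)
  age[gp] <- pmin(pmax(round(stats::rnorm(sum(gp), 56, 7.4)), 42), 82)
  age[pa] <- 29 + sample(c(-1L, 0L, 1L), sum(pa), TRUE, c(0.2, 0.6, 0.2))
  age[ch] <- pmin(pmax(round(stats::rnorm(sum(ch), 7, 2.2)), 4), 10)

  height <- numeric(n)
  height[gp] <- stats::rnorm(sum(gp), 157.3, 6)
  height[pa] <- stats::rnorm(sum(pa), 159.5, 6)
  height[ch] <- 85 + 5.5 * age[ch] + stats::rnorm(sum(ch), 0, 5)
  bmi <- numeric(n)
  bmi[gp] <- stats::rnorm(sum(gp), 34.5, 6.5)
  bmi[pa] <- stats::rnorm(sum(pa), 30, 6.5)
  bmi[ch] <- stats::rnorm(sum(ch), 15.9, 1.8)
  bmi <- pmax(bmi, 12)
  weight <- bmi * (height / 100)^2
  waist <- height * c(0.66, 0.56, 0.45)[match(role, GENERATIONS)] +
    stats::rnorm(n, 0, 6)
  muac <- c(36, 33, 18)[match(role, GENERATIONS)] + stats::rnorm(n, 0, 3)

  male <- as.numeric(ped$sex == "male")
  out <- data.frame(
    individual_id = ped$individual_id,
    family_id = ped$family_id,
    generation = role,
    sex = ped$sex,
    mother_id = ped$mother_id,
    age = age, height = round(height, 1), weight = round(weight, 1),
    waist = round(waist, 1), muac = round(muac, 1),
    stringsAsFactors = FALSE
  )

  tp <- config$traits
  for (k in seq_len(nrow(tp))) {
    tr <- tp$trait[k]
    se2 <- (1 - tp$h2[k]) * tp$sigma_p2[k]
    gk <- if (is.matrix(g)) g[, tr] else g[[tr]]
    y <- tp$intercept[k] + tp$beta_age[k] * (age - 30) +
      tp$beta_sex[k] * male + gk + stats::rnorm(n, sd = sqrt(se2))
    # physical floor for positive-valued measurements; the event is far in
    # the Gaussian tail so the truncation is negligible for the moments
    out[[tr]] <- if (tp$intercept[k] > 0) pmax(y, 0.01 * tp$intercept[k]) else y
  }
  # derived pressure summaries + behaviour flags (descriptive realism only)
  has_central <- all(c("central_sbp", "central_dbp") %in% names(out))
  if (has_central) {
    out$pulse_pressure <- out$central_sbp - out$central_dbp
    out$mean_arterial_pressure <- out$central_dbp +
      (out$central_sbp - out$central_dbp) / 3
  }
  out$resting_hr <- round(c(65, 69, 80)[match(role, GENERATIONS)] +
                            stats::rnorm(n, 0, 8))
  out$ivsd <- NA_real_; out$lvidd <- NA_real_; out$pwd <- NA_real_
  out$lvm <- NA_real_
  out$on_antihypertensives <- stats::runif(n) <
    c(0.62, 0.03, 0)[match(role, GENERATIONS)]
  out$tobacco_user <- stats::runif(n) <
    c(0.28, 0.17, 0)[match(role, GENERATIONS)]
  out$audit_c <- pmax(0, round(stats::rnorm(n, 1.5, 1.5)))
  out$audit_total <- out$audit_c + pmax(0, round(stats::rnorm(n, 1, 2)))
  out$audit_c[ch] <- NA_integer_; out$audit_total[ch] <- NA_integer_

  if (!is.null(config$missingness)) {
    mm <- config$missingness
    for (k in seq_len(nrow(mm))) {
      tr <- mm$trait[k]
      if (!tr %in% names(out)) next
      rate <- as.numeric(mm[k, GENERATIONS])[match(role, GENERATIONS)]
      drop <- stats::runif(n) < rate
      out[[tr]][drop] <- NA_real_
    }
    # central summaries inherit central pressure missingness
    if (has_central) {
      out$pulse_pressure <- out$central_sbp - out$central_dbp
      out$mean_arterial_pressure <- out$central_dbp +
        (out$central_sbp - out$central_dbp) / 3
    }
  }
  validate_phenotypes(out)
  out
}

#' Generate a complete synthetic family dataset
#'
#' Composes [generate_pedigree()], [sample_breeding_values()] (one column
#' per trait, variance `h2 * sigma_p2`) and [generate_traits()], using
#' sub-seeds derived from `config$seed`.  Optionally writes
#' `phenotypes.csv`, `pedigree.fam`, `truth.json` (generative parameters)
#' and `breeding_values.csv` to a directory.
#'
#' @param config a [synthetic_config()] object.
#' @param out_dir optional output directory.
#' @return object of class `synthetic_dataset`: list with `data`
#'   (phenotype data.frame), `pedigree`, and `truth` (config parameters +
#'   breeding-value matrix).
#' @export
generate_dataset <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- derive_seeds(config$seed, 2 + nrow(config$traits))
  ped <- generate_pedigree(config$n_families, seeds[1], config$p_female_child)
  tp <- config$traits
  g <- matrix(0, nrow(ped), nrow(tp),
              dimnames = list(ped$individual_id, tp$trait))
  for (k in seq_len(nrow(tp))) {
    g[, k] <- sample_breeding_values(ped, tp$h2[k] * tp$sigma_p2[k],
                                     seeds[1 + k])
  }
  data <- generate_traits(ped, g, config, seeds[2 + nrow(tp)])
  out <- structure(list(data = data, pedigree = ped,
                        truth = list(config = config, breeding_values = g)),
                   class = "synthetic_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phenotypes(data, file.path(out_dir, "phenotypes.csv"))
    write_fam(ped, file.path(out_dir, "pedigree.fam"))
    truth <- list(n_families = config$n_families,
                  p_female_child = config$p_female_child,
                  seed = config$seed, traits = tp,
                  missingness = config$missingness)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(data.frame(individual_id = rownames(g), g,
                                check.names = FALSE),
                     file.path(out_dir, "breeding_values.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic three-generation dataset:",
      length(unique(x$data$family_id)), "families,",
      nrow(x$data), "individuals,",
      nrow(x$truth$config$traits), "traits\n")
  invisible(x)
}
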