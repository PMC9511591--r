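# Fixtures built in code at test time.

# Minimal single-trait trio cohort for variance-component tests:
# y = beta_age * age_std + g + e with var(g) = h2, var(e) = 1 - h2.
fixture_cohort <- function(n_families, h2, seed, beta_age = 0.3) {
  set.seed(seed)
  ped <- generate_pedigree(n_families, seed = seed + 1, p_female_child = 0.5)
  g <- sample_breeding_values(ped, h2, seed = seed + 2)
  role <- famh2:::pedigree_roles(ped)
  age <- c(grandparent = 56, parent = 29, child = 7)[role] +
    round(rnorm(nrow(ped), 0, 3))
  y <- beta_age * as.numeric(scale(age)) + g +
    rnorm(nrow(ped), sd = sqrt(1 - h2))
  data <- data.frame(individual_id = ped$individual_id,
                     family_id = ped$family_id,
                     generation = role, sex = ped$sex,
                     mother_id = ped$mother_id,
                     age = age, trait = y,
                     stringsAsFactors = FALSE)
  list(data = data, pedigree = ped, g = g)
}

# Three-member chain pedigree table (one family).
trio_table <- function(fid = "F1") {
  data.frame(
    individual_id = paste0(fid, c("_GM", "_M", "_C")),
    family_id = fid,
    mother_id = c(NA, paste0(fid, "_GM"), paste0(fid, "_M")),
    father_id = NA_character_,
    sex = c("female", "female", "female"),
    stringsAsFactors = FALSE
  )
}

trio_grm_expected <- rbind(c(1, .5, .25), c(.5, 1, .5), c(.25, .5, 1))
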