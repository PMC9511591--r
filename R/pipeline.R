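# pipeline_cli: end-to-end orchestration — descriptives, Stage-1 scan,
# Stage-2 heritability for traits passing Stage 1, reproducible reports.

#' Generation-wise descriptive summary
#'
#' Median (IQR) for continuous measures and n (%) for flags, per
#' generation, with the number of successful measurements per measure.
#'
#' @param data phenotype data.frame.
#' @return data.frame with one row per variable and one formatted column
#'   per generation, plus per-measure Ns.
#' @export
descriptives <- function(data) {
  gens <- GENERATIONS
  num_vars <- intersect(c("age", "height", "weight", "waist", "muac",
                          "brachial_sbp", "brachial_dbp", "resting_hr",
                          "central_sbp", "central_dbp", "pulse_pressure",
                          "mean_arterial_pressure", "pwv", "cimt_left",
                          "lvmi_bsa"), names(data))
  flag_vars <- intersect(c("on_antihypertensives", "tobacco_user"),
                         names(data))
  rows <- list()
  med_iqr <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return("–")
    sprintf("%.2f (%.2f)", stats::median(v), stats::IQR(v))
  }
  for (v in num_vars) {
    cells <- vapply(gens, function(g) med_iqr(data[[v]][data$generation == g]),
                    character(1))
    ns <- vapply(gens, function(g) sum(!is.na(data[[v]][data$generation == g])),
                 integer(1))
    rows[[v]] <- c(variable = v, stat = "median (IQR)", cells,
                   setNames(as.character(ns), paste0("n_", gens)))
  }
  for (v in flag_vars) {
    cells <- vapply(gens, function(g) {
      x <- data[[v]][data$generation == g]
      x <- x[!is.na(x)]
      if (!length(x)) return("–")
      sprintf("%d (%.0f%%)", sum(x), 100 * mean(x))
    }, character(1))
    ns <- vapply(gens, function(g) sum(!is.na(data[[v]][data$generation == g])),
                 integer(1))
    rows[[v]] <- c(variable = v, stat = "n (%)", cells,
                   setNames(as.character(ns), paste0("n_", gens)))
  }
  # female counts
  cells <- vapply(gens, function(g) {
    x <- data$sex[data$generation == g]
    sprintf("%d (%.0f%%)", sum(x == "female"), 100 * mean(x == "female"))
  }, character(1))
  rows[["female"]] <- c(variable = "female", stat = "n (%)", cells,
                        setNames(as.character(table(factor(data$generation,
                                                           gens))),
                                 paste0("n_", gens)))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Table-3-style layout: 5 estimate rows x (method x trait) columns.
format_stage2_table <- function(fits) {
  rows <- c("Phylogenetic variance", "Error variance", "Phenotypic variance",
            "Heritability (h2)", "beta (age)")
  out <- data.frame(Quantity = rows, stringsAsFactors = FALSE)
  for (f in fits) {
    b_age <- if ("age" %in% names(f$beta)) {
      fmt_est_sd(f$beta[["age"]], f$beta_sd[["age"]])
    } else "–"
    col <- c(fmt_est_sd(f$sigma_g2, f$sigma_g2_sd),
             fmt_est_sd(f$sigma_e2, f$sigma_e2_sd),
             fmt_est_sd(f$sigma_p2, f$sigma_p2_sd),
             fmt_est_sd(f$h2, f$h2_sd),
             b_age)
    out[[paste0(f$trait, ".", f$method)]] <- col
  }
  out
}

#' Write a Stage-2 table as TSV
#' @param fits list of `heritability` fits.
#' @param path output path.
#' @export
write_stage2_table <- function(fits, path) {
  utils::write.table(format_stage2_table(fits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full two-stage analysis
#'
#' Derives descriptives, runs the Stage-1 random family scan over every
#' registry trait and generation pairing, and estimates heritability
#' (Stage 2) for exactly those traits with at least one Stage-1 pairing
#' significant at `alpha`.  Deterministic given `seed`; when `out_dir` is
#' given, writes `table1.tsv`, `table2.tsv`, `table3.tsv` and a JSON
#' manifest (seeds, settings, file checksums) sufficient to reproduce
#' every output.
#'
#' @param data phenotype data.frame.
#' @param pedigree a [build_pedigree()] object (default: extracted from
#'   `data`'s identity columns).
#' @param n_resamples Stage-1 re-pairings per row.
#' @param alpha Stage-1 significance gate.
#' @param methods Stage-2 estimators to run.
#' @param niter,burnin sampler lengths for the Bayesian methods.
#' @param seed master seed.
#' @param registry trait registry (see [trait_registry()]).
#' @param out_dir optional output directory.
#' @param p_adjust optional multiplicity adjustment (`"none"` default —
#'   the empirical p-values are reported unadjusted; `"bonferroni"` or
#'   `"BH"` adjust the gate only).
#' @return object of class `famh2_report`: list with `table1`, `stage1`,
#'   `stage2_fits`, `table3`, `selected_traits`, `manifest`.
#' @export
run_pipeline <- function(data, pedigree = pedigree_from_phenotypes(data),
                         n_resamples = 5000, alpha = 0.05,
                         methods = c("reml", "gibbs", "hmc"),
                         niter = 100000, burnin = 10000, seed = NULL,
                         registry = trait_registry(), out_dir = NULL,
                         p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  methods <- match.arg(methods, c("reml", "gibbs", "hmc"),
                       several.ok = TRUE)
  data <- validate_phenotypes(data)
  seeds <- derive_seeds(seed, 2)
  tab1 <- descriptives(data)
  s1 <- run_stage1(data, n_resamples = n_resamples, seed = seeds[1],
                   registry = registry, alpha = alpha)
  pvals <- s1$p
  gate_p <- if (p_adjust == "none") pvals else stats::p.adjust(pvals, p_adjust)
  sel <- unique(s1$trait[!is.na(gate_p) & gate_p < alpha])
  fits <- list()
  errors <- character()
  m_seeds <- derive_seeds(seeds[2], max(1, length(sel) * length(methods)))
  k <- 0
  for (tr in sel) {
    for (m in methods) {
      k <- k + 1
      f <- tryCatch(
        heritability(stats::as.formula(paste(tr, "~ age")), data, pedigree,
                     method = m, niter = niter, burnin = burnin,
                     seed = m_seeds[k]),
        error = function(e) e)
      if (inherits(f, "error")) {
        errors <- c(errors, paste0(tr, "/", m, ": ", conditionMessage(f)))
      } else {
        fits[[paste0(tr, ".", m)]] <- f
      }
    }
  }
  tab3 <- if (length(fits)) format_stage2_table(fits) else NULL
  manifest <- list(
    package = "famh2",
    version = as.character(utils::packageVersion("famh2")),
    r_version = R.version.string,
    seed = seed, stage_seeds = seeds,
    n_resamples = n_resamples, alpha = alpha, p_adjust = p_adjust,
    methods = methods, niter = niter, burnin = burnin,
    n_individuals = nrow(data),
    n_families = length(unique(data$family_id)),
    selected_traits = sel,
    errors = errors
  )
  report <- structure(list(table1 = tab1, stage1 = s1, stage2_fits = fits,
                           table3 = tab3, selected_traits = sel,
                           manifest = manifest),
                      class = "famh2_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab1, file.path(out_dir, "table1.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_stage1_table(s1, file.path(out_dir, "table2.tsv"))
    if (!is.null(tab3)) {
      utils::write.table(tab3, file.path(out_dir, "table3.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$manifest <- manifest
  }
  report
}

#' @export
print.famh2_report <- function(x, ...) {
  cat("Two-stage family heritability report\n")
  cat("====================================\n\n")
  cat("Stage 1 (", sum(x$stage1$status == "ok"), "rows fitted ):\n")
  print(x$stage1)
  cat("\nTraits passing the Stage-1 gate:",
      if (length(x$selected_traits)) paste(x$selected_traits, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$table3)) {
    cat("\nStage 2 variance components:\n")
    print(x$table3, row.names = FALSE)
  }
  invisible(x)
}
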