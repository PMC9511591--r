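# stage1_random_family: covariate-adjusted parent->offspring regression
# with a derangement-resampling null and exact empirical p = c/n.

#' Registry of vascular traits and their Stage-1 covariate rules
#'
#' Brachial and central pressures, PWV and cIMT are adjusted for age,
#' height, weight and sex; LVMI for age and sex only (it is already
#' indexed to body surface area).
#'
#' @return data.frame with columns `trait`, `label` and a list-column
#'   `covariates`.
#' @export
trait_registry <- function() {
  full <- c("age", "height", "weight", "sex")
  d <- data.frame(
    trait = c("brachial_sbp", "brachial_dbp", "central_sbp", "central_dbp",
              "pwv", "cimt_left", "lvmi_bsa"),
    label = c("Brachial SBP", "Brachial DBP", "Central SBP", "Central DBP",
              "PWV", "cIMT", "LVMI_BSA"),
    stringsAsFactors = FALSE
  )
  d$covariates <- c(rep(list(full), 6), list(c("age", "sex")))
  d
}

GENERATION_PAIRS <- c("GC_on_GP", "GC_on_P", "P_on_GP")

pair_labels <- function(pairing) {
  switch(pairing,
         GC_on_GP = c(offspring = "GC", parental = "GP"),
         GC_on_P = c(offspring = "GC", parental = "P"),
         P_on_GP = c(offspring = "P", parental = "GP"))
}

#' Extract biological pairs for one trait and generation pairing
#'
#' Builds one row per biological pair (grandparent-parent,
#' parent-child or grandparent-grandchild via the maternal line) with the
#' parental trait value `z`, the offspring trait value `y`, and the
#' offspring-side covariates.  Rows with any required value missing are
#' dropped (pairwise-complete); a family contributes to a pairing iff it
#' has that pair with valid measurements.
#'
#' @param data phenotype data.frame (see [read_phenotypes()]).
#' @param trait trait column name.
#' @param pairing one of `"GC_on_GP"`, `"GC_on_P"`, `"P_on_GP"`.
#' @param covariates character vector of offspring covariate columns
#'   (default from [trait_registry()]).
#' @return data.frame with columns `family_id`, `offspring_id`,
#'   `parental_id`, `z`, `y` and the covariates (sex coded 0/1 female/male).
#' @export
extract_pairs <- function(data, trait,
                          pairing = c("GC_on_GP", "GC_on_P", "P_on_GP"),
                          covariates = NULL) {
  pairing <- match.arg(pairing)
  if (!trait %in% names(data)) stop("no column '", trait, "' in data")
  if (is.null(covariates)) {
    reg <- trait_registry()
    covariates <- if (trait %in% reg$trait) {
      reg$covariates[[match(trait, reg$trait)]]
    } else {
      c("age", "height", "weight", "sex")
    }
  }
  idx <- function(ids) match(ids, data$individual_id)
  off_rows <- switch(pairing,
                     GC_on_GP = ,
                     GC_on_P = which(data$generation == "child"),
                     P_on_GP = which(data$generation == "parent"))
  par_rows <- switch(pairing,
                     GC_on_P = ,
                     P_on_GP = idx(data$mother_id[off_rows]),
                     GC_on_GP = idx(data$mother_id[idx(data$mother_id[off_rows])]))
  keep <- !is.na(par_rows)
  off_rows <- off_rows[keep]; par_rows <- par_rows[keep]
  out <- data.frame(
    family_id = data$family_id[off_rows],
    offspring_id = data$individual_id[off_rows],
    parental_id = data$individual_id[par_rows],
    z = data[[trait]][par_rows],
    y = data[[trait]][off_rows],
    stringsAsFactors = FALSE
  )
  for (cv in covariates) {
    if (!cv %in% names(data)) stop("covariate column '", cv, "' not in data")
    v <- data[[cv]][off_rows]
    if (cv == "sex") v <- as.numeric(v == "male")
    out[[cv]] <- v
  }
  cc <- stats::complete.cases(out)
  out <- out[cc, , drop = FALSE]
  if (nrow(out) < 3L) {
    stop("insufficient data: fewer than 3 complete pairs for '", trait,
         "' (", pairing, ")")
  }
  rownames(out) <- NULL
  # a covariate constant on the offspring side (sex for all-female adult
  # generations) carries no information and would make the design singular
  dropped <- covariates[vapply(covariates,
                               function(cv) stats::var(out[[cv]]) == 0,
                               logical(1))]
  if (length(dropped)) {
    out <- out[setdiff(names(out), dropped)]
    covariates <- setdiff(covariates, dropped)
  }
  attr(out, "dropped_covariates") <- dropped
  attr(out, "trait") <- trait
  attr(out, "pairing") <- pairing
  attr(out, "covariates") <- covariates
  out
}

# Design matrix for the pair regression; errors name the aliased column.
pair_design <- function(pairs, covariates) {
  X <- cbind(`(Intercept)` = 1, z = pairs$z)
  for (cv in covariates) X <- cbind(X, pairs[[cv]])
  colnames(X) <- c("(Intercept)", "z", covariates)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design is rank deficient; offending column(s): ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Ordinary least-squares slope of the parental trait
#'
#' Fits `y = b0 + tau * z + beta' X + eps` by OLS on a pair table and
#' returns the coefficient on the parental trait `z` together with the
#' full coefficient vector.
#'
#' @param pairs a pair table from [extract_pairs()] (or any data.frame
#'   with columns `z`, `y` and the covariates).
#' @param covariates covariate columns to adjust for; default the
#'   attribute stored by [extract_pairs()].
#' @return list with `tau` (slope on `z`) and `beta` (named coefficients).
#' @export
fit_tau <- function(pairs, covariates = attr(pairs, "covariates") %||% character()) {
  X <- pair_design(pairs, covariates)
  fit <- stats::lm.fit(X, pairs$y)
  beta <- fit$coefficients
  list(tau = unname(beta["z"]), beta = beta)
}

#' Null distribution of the slope by restricted resampling
#'
#' Re-pairs parents and offspring `n_resamples` times and refits the
#' covariate-adjusted regression each time.  Under the default restricted
#' scheme the re-pairing is a uniformly random derangement, so no
#' resampled family unit reproduces an original biological pairing;
#' `restricted = FALSE` gives unrestricted permutations for sensitivity
#' analysis.  The parental exposure (and any parent-side columns named in
#' `permute_with`) moves with the re-pairing; offspring covariates stay
#' with the offspring.
#'
#' @param pairs pair table from [extract_pairs()].
#' @param n_resamples number of re-pairings (the study design uses 5000).
#' @param seed RNG seed; fixed seed gives bitwise-identical output.
#' @param covariates covariate columns (default from the pair table).
#' @param restricted derangement-constrained re-pairing (default) or
#'   unrestricted permutation.
#' @param permute_with extra parent-side columns permuted together with `z`.
#' @return numeric vector of `n_resamples` resampled slopes.
#' @export
resample_null <- function(pairs, n_resamples = 5000, seed = NULL,
                          covariates = attr(pairs, "covariates") %||% character(),
                          restricted = TRUE, permute_with = NULL) {
  stopifnot(n_resamples >= 1)
  n <- nrow(pairs)
  if (n < 3L) stop("resampling needs at least 3 pairs")
  X <- pair_design(pairs, covariates)
  if (!is.null(seed)) set.seed(as.integer(seed))
  zcol <- match("z", colnames(X))
  pcols <- match(permute_with, colnames(X))
  taus <- numeric(n_resamples)
  y <- pairs$y
  for (b in seq_len(n_resamples)) {
    perm <- if (restricted) rderange(n) else sample.int(n)
    Xb <- X
    Xb[, zcol] <- X[perm, zcol]
    if (length(pcols)) Xb[, pcols] <- X[perm, pcols, drop = FALSE]
    taus[b] <- stats::lm.fit(Xb, y)$coefficients["z"]
  }
  taus
}

#' Exact empirical probability from a resampling null
#'
#' `c = #\{|tau_null| >= |tau_obs|\}` (ties count as exceedances) and
#' `p = c / n` with no +1 smoothing, so `p = 0` is possible.
#'
#' @param tau_obs observed slope.
#' @param null_taus resampled slopes.
#' @return list with `c`, `n` and `p`.
#' @examples
#' # 83 of 5000 resampled slopes at least as extreme: p = 0.0166
#' empirical_p(1, c(rep(2, 83), rep(0.5, 4917)))$p
#' @export
empirical_p <- function(tau_obs, null_taus) {
  if (!length(null_taus)) stop("empty null distribution")
  cc <- sum(abs(null_taus) >= abs(tau_obs))
  list(c = cc, n = length(null_taus), p = cc / length(null_taus))
}

#' Random family test for one trait and generation pairing
#'
#' The Stage-1 fitting function: regresses the offspring trait on the
#' parental trait with covariate adjustment, builds the null distribution
#' of the slope by derangement-constrained re-pairing, and reports the
#' exact empirical p-value `c/n`.
#'
#' @param formula model formula on the pair table, `y ~ z + covariates`;
#'   the default uses the covariates stored on the pair table.
#' @param pairs pair table from [extract_pairs()], or any data.frame with
#'   the formula's columns.
#' @param exposure name of the parental-trait column (default `"z"`).
#' @param n_resamples number of re-pairings.
#' @param seed RNG seed for the resampling.
#' @param restricted derangement constraint (see [resample_null()]).
#' @param permute_with extra parent-side columns permuted with the exposure.
#' @return object of class `random_family` with components `tau_obs`,
#'   `beta`, `null_taus`, `c`, `n`, `p`, `n_pairs`.
#' @seealso [run_stage1()] for the full 21-row scan.
#' @export
random_family <- function(formula = NULL, pairs, exposure = "z",
                          n_resamples = 5000, seed = NULL,
                          restricted = TRUE, permute_with = NULL) {
  cl <- match.call()
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, pairs, na.action = stats::na.omit)
    vars <- attr(stats::terms(formula), "term.labels")
    if (!exposure %in% vars) {
      stop("exposure '", exposure, "' is not a term of the formula")
    }
    covariates <- setdiff(vars, exposure)
    pairs <- data.frame(y = mf[[1L]], z = mf[[exposure]])
    for (cv in covariates) pairs[[cv]] <- mf[[cv]]
  } else {
    covariates <- attr(pairs, "covariates") %||%
      setdiff(names(pairs), c("family_id", "offspring_id", "parental_id",
                              "z", "y"))
  }
  obs <- fit_tau(pairs, covariates)
  null_taus <- resample_null(pairs, n_resamples, seed, covariates,
                             restricted, permute_with)
  ep <- empirical_p(obs$tau, null_taus)
  structure(list(
    call = cl,
    trait = attr(pairs, "trait"),
    pairing = attr(pairs, "pairing"),
    covariates = covariates,
    tau_obs = obs$tau,
    beta = obs$beta,
    null_taus = null_taus,
    c = ep$c, n = ep$n, p = ep$p,
    n_pairs = nrow(pairs),
    restricted = restricted,
    seed = seed
  ), class = "random_family")
}

#' @export
print.random_family <- function(x, ...) {
  cat("Random family test",
      if (!is.null(x$trait)) paste0("for ", x$trait, " [", x$pairing, "]"),
      "\n")
  cat(sprintf("  pairs: %d   adjusted for: %s\n", x$n_pairs,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(none)"))
  cat(sprintf("  observed slope tau = %.4f\n", x$tau_obs))
  cat(sprintf("  c = %d of n = %d resampled |tau| >= |tau_obs|;  p = c/n = %.4f\n",
              x$c, x$n, x$p))
  invisible(x)
}

#' @export
summary.random_family <- function(object, ...) {
  out <- list(fit = object,
              beta = object$beta,
              null_quantiles = stats::quantile(
                object$null_taus, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  class(out) <- "summary.random_family"
  out
}

#' @export
print.summary.random_family <- function(x, ...) {
  print(x$fit)
  cat("  coefficients:\n")
  print(round(x$beta, 4))
  cat("  null slope quantiles:\n")
  print(round(x$null_quantiles, 4))
  invisible(x)
}

#' @export
coef.random_family <- function(object, ...) object$beta

#' Kernel density of the resampled slopes
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth; purely a
#' diagnostic display — the empirical p never depends on it.
#'
#' @param null_taus resampled slopes (>= 2 distinct values).
#' @param tau_obs optional observed slope to mark.
#' @return object of class `tau_kde` (the [stats::density()] curve plus
#'   the observed marker).
#' @export
kde_tau <- function(null_taus, tau_obs = NULL) {
  if (length(null_taus) < 2L || stats::sd(null_taus) == 0) {
    stop("degenerate null distribution: need >= 2 distinct slopes")
  }
  den <- stats::density(null_taus, bw = "nrd0", kernel = "gaussian")
  structure(list(x = den$x, y = den$y, bw = den$bw, tau_obs = tau_obs,
                 n = length(null_taus)),
            class = "tau_kde")
}

#' @export
plot.tau_kde <- function(x, main = "Null distribution of tau", ...) {
  plot(x$x, x$y, type = "l", xlab = expression(tau), ylab = "density",
       main = main, ...)
  if (!is.null(x$tau_obs)) {
    abline(v = x$tau_obs, col = "firebrick", lwd = 2)
    abline(v = -x$tau_obs, col = "firebrick", lty = 3)
  }
  invisible(x)
}

#' @export
plot.random_family <- function(x, ...) {
  plot(kde_tau(x$null_taus, x$tau_obs),
       main = paste0("Random family null",
                     if (!is.null(x$trait)) paste0(": ", x$trait,
                                                   " [", x$pairing, "]")),
       ...)
}

#' Stage-1 scan over all traits and generation pairings
#'
#' Runs the random family test for every registry trait and each of the
#' three generation pairings (grandparent-grandchild, parent-grandchild,
#' grandparent-parent), 21 rows for the default 7-trait registry.  Rows
#' with insufficient data are flagged, not fatal.  Per-row seeds are
#' derived from the master seed with [derive_seeds()].
#'
#' @param data phenotype data.frame.
#' @param n_resamples re-pairings per row.
#' @param seed master seed.
#' @param registry trait registry (see [trait_registry()]).
#' @param alpha significance level for the `significant` flag.
#' @param restricted derangement constraint (see [resample_null()]).
#' @return object of class `stage1_scan`: a data.frame with columns
#'   `trait`, `outcome`, `exposure`, `n_pairs`, `tau_obs`, `c`, `n`, `p`,
#'   `significant`, `status`, with the fitted `random_family` objects in
#'   `attr(, "fits")`.
#' @export
run_stage1 <- function(data, n_resamples = 5000, seed = NULL,
                       registry = trait_registry(), alpha = 0.05,
                       restricted = TRUE) {
  rows <- expand.grid(pairing = GENERATION_PAIRS, trait = registry$trait,
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(rows))
  fits <- vector("list", nrow(rows))
  out <- data.frame(
    trait = rows$trait,
    outcome = NA_character_, exposure = NA_character_,
    n_pairs = NA_integer_, tau_obs = NA_real_,
    c = NA_integer_, n = NA_integer_, p = NA_real_,
    significant = NA, status = "ok",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(rows))) {
    trait <- rows$trait[i]; pairing <- rows$pairing[i]
    lab <- registry$label[match(trait, registry$trait)]
    pl <- pair_labels(pairing)
    out$outcome[i] <- paste0(lab, "—", pl["offspring"])
    out$exposure[i] <- paste0(lab, "—", pl["parental"])
    res <- tryCatch({
      pairs <- extract_pairs(data, trait, pairing,
                             registry$covariates[[match(trait, registry$trait)]])
      random_family(pairs = pairs, n_resamples = n_resamples,
                    seed = seeds[i], restricted = restricted)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status[i] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      out$n_pairs[i] <- res$n_pairs
      out$tau_obs[i] <- res$tau_obs
      out$c[i] <- res$c; out$n[i] <- res$n; out$p[i] <- res$p
      out$significant[i] <- res$p < alpha
    }
  }
  attr(out, "fits") <- fits
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  class(out) <- c("stage1_scan", "data.frame")
  out
}

#' @export
print.stage1_scan <- function(x, digits = 4, ...) {
  cat("Stage 1 random family scan (", sum(x$status == "ok"), "of",
      nrow(x), "rows fitted)\n\n")
  show <- as.data.frame(x)[c("outcome", "exposure", "n_pairs", "tau_obs",
                             "c", "n", "p", "significant")]
  show$tau_obs <- round(show$tau_obs, digits)
  print(show, row.names = FALSE)
  if (any(x$status != "ok")) {
    cat("\nflagged rows:\n")
    bad <- x$status != "ok"
    cat(paste0("  ", x$outcome[bad], " ~ ", x$exposure[bad], ": ",
               x$status[bad], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a Stage-1 scan as a TSV table
#'
#' Columns: Outcome, Exposure, Observed effect, c, n, P value — one row
#' per trait x generation pairing.
#'
#' @param scan a [run_stage1()] result.
#' @param path output TSV path.
#' @export
write_stage1_table <- function(scan, path) {
  tab <- data.frame(
    Outcome = scan$outcome,
    Exposure = scan$exposure,
    `Observed effect` = round(scan$tau_obs, 3),
    c = scan$c, n = scan$n,
    `P value` = round(scan$p, 4),
    check.names = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
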