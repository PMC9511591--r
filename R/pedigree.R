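# pedigree_kinship: maternal-line pedigrees, recursive kinship, GRM.

#' Build and validate a pedigree
#'
#' Accepts a data.frame with columns `individual_id`, `family_id`,
#' `mother_id` (NA for founders), optional `father_id` (all NA in a
#' maternal-line design) and `sex` (`"female"`/`"male"`).  Validates that
#' parent links resolve within the family, that every mother is female,
#' and that the graph is acyclic; individuals are returned in topological
#' order (parents before offspring).
#'
#' @param individuals data.frame as above (a phenotype table works:
#'   extra columns are ignored).
#' @return object of class `pedigree`: the ordered data.frame plus
#'   bookkeeping attributes.
#' @export
build_pedigree <- function(individuals) {
  d <- as.data.frame(individuals)
  need <- c("individual_id", "family_id", "sex")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("pedigree lacks columns: ", paste(miss, collapse = ", "))
  if (!"mother_id" %in% names(d)) d$mother_id <- NA_character_
  if (!"father_id" %in% names(d)) d$father_id <- NA_character_
  d <- d[c("individual_id", "family_id", "mother_id", "father_id", "sex")]
  d$mother_id[d$mother_id %in% c("", "0")] <- NA_character_
  d$father_id[d$father_id %in% c("", "0")] <- NA_character_
  if (anyDuplicated(d$individual_id)) stop("duplicate individual_id")
  for (side in c("mother_id", "father_id")) {
    has <- !is.na(d[[side]])
    idx <- match(d[[side]][has], d$individual_id)
    if (anyNA(idx)) {
      stop("dangling ", side, ": ",
           paste(d[[side]][has][is.na(idx)], collapse = ", "))
    }
    if (any(d$family_id[idx] != d$family_id[has])) {
      stop(side, " points to another family for: ",
           paste(d$individual_id[has][d$family_id[idx] != d$family_id[has]],
                 collapse = ", "))
    }
    want <- if (side == "mother_id") "female" else "male"
    if (any(d$sex[idx] != want)) {
      stop(side, " refers to an individual of the wrong sex")
    }
  }
  # Kahn topological sort over parent -> child edges
  n <- nrow(d)
  mi <- match(d$mother_id, d$individual_id)
  fi <- match(d$father_id, d$individual_id)
  indeg <- (!is.na(mi)) + (!is.na(fi))
  order <- integer(0)
  ready <- which(indeg == 0L)
  indeg[ready] <- -1L
  while (length(ready)) {
    i <- ready[1L]; ready <- ready[-1L]
    order <- c(order, i)
    kids <- which((!is.na(mi) & mi == i) | (!is.na(fi) & fi == i))
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) { ready <- c(ready, k); indeg[k] <- -1L }
    }
  }
  if (length(order) < n) stop("pedigree contains a cycle")
  d <- d[order, , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("pedigree", "data.frame")
  d
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals in",
      length(unique(x$family_id)), "families\n")
  founders <- sum(is.na(x$mother_id) & is.na(x$father_id))
  cat("  founders:", founders, " non-founders:", nrow(x) - founders, "\n")
  invisible(x)
}

#' Kinship coefficient matrix by the recursive tabular method
#'
#' For individuals processed parents-first:
#' `phi(i,i) = (1 + phi(mother_i, father_i)) / 2` and, for j preceding i,
#' `phi(i,j) = (phi(mother_i, j) + phi(father_i, j)) / 2`, an unknown
#' parent contributing 0 (founder alleles are unique).  Maternal-line
#' trio pedigrees are outbred by construction; an inbred self-kinship
#' (> 1/2) raises an error rather than being silently propagated.
#'
#' @param ped a [build_pedigree()] object.
#' @return symmetric matrix of kinship coefficients with individual ids
#'   as dimnames.
#' @export
kinship_coefficients <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  ids <- ped$individual_id
  mi <- match(ped$mother_id, ids)
  fi <- match(ped$father_id, ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    pm <- mi[i]; pf <- fi[i]
    pmf <- if (!is.na(pm) && !is.na(pf)) phi[pm, pf] else 0
    phi[i, i] <- 0.5 * (1 + pmf)
    if (phi[i, i] > 0.5 + 1e-12) {
      stop("inbred individual '", ids[i], "': not supported")
    }
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (!is.na(pm)) phi[pm, j] else 0) +
                      (if (!is.na(pf)) phi[pf, j] else 0))
      phi[i, j] <- row
      phi[j, i] <- row
    }
  }
  phi
}

#' Genetic relatedness matrix from a pedigree
#'
#' `G = 2 * phi`, the expected genome-sharing matrix (numerator
#' relationship matrix): 1 on the diagonal for outbred individuals, 1/2
#' for parent-offspring, 1/4 for grandparent-grandchild, 0 across
#' families (block-diagonal).
#'
#' @param ped a [build_pedigree()] object.
#' @param check_psd verify positive semi-definiteness (smallest eigenvalue
#'   >= -1e-10).
#' @return symmetric numeric matrix with ids as dimnames.
#' @export
grm <- function(ped, check_psd = TRUE) {
  G <- 2 * kinship_coefficients(ped)
  if (check_psd) {
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      stop("GRM is not positive semi-definite (min eigenvalue ",
           format(min(ev)), ")")
    }
  }
  G
}

#' Gene-dropping Monte-Carlo kinship (simulation oracle)
#'
#' Estimates kinship coefficients by explicit allele transmission: each
#' founder (and each unobserved father) carries unique alleles; each
#' non-founder inherits one maternal allele at random per replicate.
#' The empirical identity-by-descent probability between random alleles
#' of i and j converges to `phi(i, j)`.  Intended as an independent check
#' of [kinship_coefficients()], not for production use.
#'
#' @param ped a [build_pedigree()] object.
#' @param n_rep Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return list with `phi` (empirical kinship matrix) and `mc_sd`
#'   (per-entry Monte-Carlo standard deviation of the mean).
#' @export
gene_drop_kinship <- function(ped, n_rep = 1e5, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  ids <- ped$individual_id
  mi <- match(ped$mother_id, ids)
  fi <- match(ped$father_id, ids)
  # allele id matrices: n individuals x n_rep replicates
  A1 <- matrix(0L, n, n_rep)
  A2 <- matrix(0L, n, n_rep)
  next_allele <- 1L
  fresh <- function() {
    a <- next_allele
    next_allele <<- next_allele + 1L
    a
  }
  for (i in seq_len(n)) {
    if (is.na(mi[i])) {
      A1[i, ] <- fresh()
    } else {
      pick <- runif(n_rep) < 0.5
      A1[i, ] <- ifelse(pick, A1[mi[i], ], A2[mi[i], ])
    }
    if (is.na(fi[i])) {
      A2[i, ] <- fresh()
    } else {
      pick <- runif(n_rep) < 0.5
      A2[i, ] <- ifelse(pick, A1[fi[i], ], A2[fi[i], ])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  mc_sd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- ((A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
                (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])) / 4
      phi[i, j] <- phi[j, i] <- mean(ibd)
      mc_sd[i, j] <- mc_sd[j, i] <- stats::sd(ibd) / sqrt(n_rep)
    }
  }
  list(phi = phi, mc_sd = mc_sd)
}

#' Read a FAM-style pedigree file
#'
#' Whitespace-delimited columns `family_id individual_id father_id
#' mother_id sex`, with `0` for a missing parent and sex coded 1 = male,
#' 2 = female (a PLINK .fam-compatible subset, phenotype column optional
#' and ignored).
#'
#' @param path file path.
#' @return a [build_pedigree()] object.
#' @export
read_fam <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 5) stop("FAM file needs at least 5 columns")
  names(d)[1:5] <- c("family_id", "individual_id", "father_id",
                     "mother_id", "sex_code")
  d$sex <- c("male", "female")[as.integer(d$sex_code)]
  build_pedigree(d[c("individual_id", "family_id", "mother_id",
                     "father_id", "sex")])
}

#' Write a pedigree as a FAM-style file
#' @param ped a [build_pedigree()] object.
#' @param path output path.
#' @export
write_fam <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- data.frame(
    fid = ped$family_id,
    iid = ped$individual_id,
    pid = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mid = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "male", 1L, 2L)
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Extract the pedigree from a phenotype table
#' @param data phenotype data.frame with identity columns.
#' @return a [build_pedigree()] object.
#' @export
pedigree_from_phenotypes <- function(data) {
  build_pedigree(data[intersect(names(data),
                                c("individual_id", "family_id",
                                  "mother_id", "father_id", "sex"))])
}
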