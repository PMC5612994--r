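# Cross-validated RDMs, second-order inter-ROI geometry, classical MDS, the
# RV coefficient, and the mixed-effects within/between-system contrast.

#' Enumerate split-half run partitions
#'
#' All partitions of the runs into halves of sizes `ceiling(n/2)` and
#' `floor(n/2)`. For odd n every partition is counted once (462 for 11 runs);
#' for even n duplicates are avoided by keeping the half containing the first
#' run.
#'
#' @param runs run labels.
#' @return list of lists with `a` (larger half) and `b`.
#' @export
run_partitions <- function(runs) {
  n <- length(runs)
  if (n < 2) stop("need at least 2 runs to partition")
  k <- ceiling(n / 2)
  halves <- combn(runs, k, simplify = FALSE)
  if (n %% 2 == 0) halves <- Filter(function(h) runs[1] %in% h, halves)
  lapply(halves, function(h) list(a = h, b = setdiff(runs, h)))
}

#' Cross-validated representational dissimilarity matrix for one ROI
#'
#' For every split-half partition of the runs, betas are averaged within each
#' half and the half-means are Pearson-correlated across the ROI's voxels for
#' all condition pairs, giving a (conditions x conditions) matrix whose
#' diagonal estimates pattern reliability (it need not be 1). The per-partition
#' matrices are averaged on the Fisher z scale, symmetrized by averaging with
#' the transpose (also on the z scale), and mapped back to correlations.
#'
#' @param betas a prepared [beta_pattern_set()] (z-scored, 8 conditions).
#' @param roi a resolved [roi_spec()] (see [resolve_roi_overlaps()]), or a
#'   vector of masked-voxel indices.
#' @return object of class `rdm`: the similarity matrix with attributes.
#' @export
crossvalidated_rdm <- function(betas, roi) {
  if (inherits(roi, "roi_spec")) {
    if (is.null(roi$voxels)) stop("ROI voxels are unresolved; run resolve_roi_overlaps()")
    pos <- match(ijk_to_linear(betas$grid$dims, roi$voxels), betas$mask$voxels)
    if (any(is.na(pos)))
      stop(sprintf("ROI '%s' extends outside the beta mask", roi$name))
    name <- roi$name
  } else {
    pos <- as.integer(roi)
    if (any(pos < 1 | pos > length(betas$mask$voxels)))
      stop("ROI voxel indices outside the beta mask")
    name <- "roi"
  }
  if (length(pos) < 2) stop("ROI must contain at least 2 voxels")
  parts <- run_partitions(betas$runs)
  n_cond <- nrow(betas$conditions)
  zsum <- matrix(0, n_cond, n_cond)
  for (p in parts) {
    ma <- apply(betas$betas[match(p$a, betas$runs), , pos, drop = FALSE],
                c(2, 3), mean)
    mb <- apply(betas$betas[match(p$b, betas$runs), , pos, drop = FALSE],
                c(2, 3), mean)
    r <- cor(t(ma), t(mb))
    zsum <- zsum + fisher_z(r)
  }
  zmean <- zsum / length(parts)
  zsym <- (zmean + t(zmean)) / 2
  out <- fisher_inv(zsym)
  dimnames(out) <- list(betas$conditions$condition, betas$conditions$condition)
  structure(out, class = c("rdm", "matrix"), roi = name,
            n_partitions = length(parts))
}

# Vectorize an RDM for ROI-to-ROI correlation. The cross-validated diagonal
# is informative, so it is included by default.
vectorize_rdm <- function(rdm, include_diagonal = TRUE) {
  m <- unclass(rdm)
  m[upper.tri(m, diag = include_diagonal)]
}

#' Within-subject inter-ROI geometry
#'
#' Correlation distance (1 - Pearson r between vectorized RDMs) between every
#' pair of ROIs, per subject; subject matrices are averaged on the Fisher z
#' scale of the correlations to a group distance matrix.
#'
#' @param rdms_by_subject list (one per subject) of lists of `rdm`s, all with
#'   the same ROI order and condition order.
#' @param systems character vector of system labels, one per ROI.
#' @param include_diagonal include the RDM diagonal in the vectorization
#'   (default TRUE).
#' @return object of class `inter_roi_geometry` with the group distance
#'   matrix `D`, per-subject correlation matrices `r_by_unit`, ROI names and
#'   system labels.
#' @export
inter_roi_distances <- function(rdms_by_subject, systems = NULL,
                                include_diagonal = TRUE) {
  n_roi <- length(rdms_by_subject[[1]])
  roi_names <- vapply(rdms_by_subject[[1]], function(r)
    attr(r, "roi") %||% "roi", "")
  r_by_unit <- lapply(rdms_by_subject, function(subj) {
    vecs <- vapply(subj, vectorize_rdm, include_diagonal = include_diagonal,
                   numeric(length(vectorize_rdm(subj[[1]], include_diagonal))))
    if (any(apply(vecs, 2, sd) < 1e-12)) {
      bad <- roi_names[apply(vecs, 2, sd) < 1e-12]
      stop("constant RDM (zero variance) in ROI: ", paste(bad, collapse = ", "))
    }
    r <- cor(vecs)
    dimnames(r) <- list(roi_names, roi_names)
    r
  })
  zmean <- Reduce(`+`, lapply(r_by_unit, function(r) {
    z <- atanh(clip_r(r))
    diag(z) <- 0
    z
  })) / length(r_by_unit)
  D <- 1 - fisher_inv(zmean)
  diag(D) <- 0
  structure(list(D = D, r_by_unit = r_by_unit, r_reliability = NULL,
                 roi_names = roi_names, systems = systems,
                 variant = "within-subject"),
            class = "inter_roi_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Between-subject inter-ROI geometry with reliability normalization
#'
#' For each ROI pair (a, b), the cross-subject correlation `r_ab` is the
#' Fisher-average over all unordered subject pairs of the correlations
#' between subject s1's RDM in a and subject s2's RDM in b (both directions,
#' which symmetrizes the matrix). The per-ROI reliability `r_a` is the same
#' quantity with a = b. The dissimilarity index normalizes by the geometric
#' mean of the reliabilities:
#' `D_ab = 1 - r_ab / sqrt(r_a * r_b)`.
#' Non-positive reliabilities leave D undefined and raise an error naming the
#' ROI.
#'
#' @param rdms_by_subject list (one per subject, >= 2) of lists of `rdm`s.
#' @param systems system labels, one per ROI.
#' @param include_diagonal include the RDM diagonal in vectorization.
#' @return `inter_roi_geometry` with `D`, `r_pair`, `r_reliability`, and
#'   per-subject-pair correlation matrices `r_by_unit` (units = subject
#'   pairs).
#' @export
between_subject_geometry <- function(rdms_by_subject, systems = NULL,
                                     include_diagonal = TRUE) {
  S <- length(rdms_by_subject)
  if (S < 2) stop("need at least 2 subjects")
  n_roi <- length(rdms_by_subject[[1]])
  roi_names <- vapply(rdms_by_subject[[1]], function(r)
    attr(r, "roi") %||% "roi", "")
  vecs <- lapply(rdms_by_subject, function(subj)
    vapply(subj, vectorize_rdm, include_diagonal = include_diagonal,
           numeric(length(vectorize_rdm(subj[[1]], include_diagonal)))))
  pairs <- combn(S, 2, simplify = FALSE)
  r_by_unit <- lapply(pairs, function(pr) {
    r12 <- cor(vecs[[pr[1]]], vecs[[pr[2]]]) # a from s1, b from s2
    z <- (atanh(clip_r(r12)) + atanh(clip_r(t(r12)))) / 2
    r <- fisher_inv(z)
    dimnames(r) <- list(roi_names, roi_names)
    r
  })
  zmean <- Reduce(`+`, lapply(r_by_unit, function(r) atanh(clip_r(r)))) /
    length(r_by_unit)
  r_pair <- fisher_inv(zmean)
  r_rel <- diag(r_pair)
  if (any(r_rel <= 0))
    stop("non-positive between-subject reliability for ROI: ",
         paste(roi_names[r_rel <= 0], collapse = ", "),
         " (dissimilarity index undefined)")
  D <- 1 - r_pair / sqrt(outer(r_rel, r_rel))
  dimnames(D) <- list(roi_names, roi_names)
  structure(list(D = D, r_pair = r_pair,
                 r_reliability = setNames(r_rel, roi_names),
                 r_by_unit = r_by_unit, roi_names = roi_names,
                 systems = systems, variant = "between-subject"),
            class = "inter_roi_geometry")
}

clip_r <- function(r) pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)

#' Classical (metric) multidimensional scaling
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns the top-k eigenvector
#' coordinates scaled by the square roots of the eigenvalues. Negative
#' eigenvalues are truncated; their total mass is reported as an attribute.
#'
#' @param D symmetric zero-diagonal distance matrix.
#' @param k embedding dimension (default 3).
#' @return n x k coordinate matrix with attribute `eigenvalues`.
#' @export
classical_mds <- function(D, k = 3) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix must have zero diagonal")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- sum(eig$values > 1e-10)
  if (k > pos)
    stop(sprintf("k = %d exceeds the number of positive eigenvalues (%d)", k, pos))
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k)
  rownames(coords) <- rownames(D)
  attr(coords, "eigenvalues") <- eig$values
  attr(coords, "negative_mass") <- sum(abs(eig$values[eig$values < 0]))
  coords
}

#' RV coefficient between two symmetric matrices
#'
#' Both matrices are double-centered; RV is their trace inner product
#' normalized by the product of their Frobenius norms, equal to 1 iff the
#' centered matrices are proportional.
#'
#' @param A,B symmetric matrices of the same size.
#' @export
rv_coefficient <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("matrices must have the same shape")
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  Ac <- J %*% ((A + t(A)) / 2) %*% J
  Bc <- J %*% ((B + t(B)) / 2) %*% J
  na <- sum(Ac * Ac); nb <- sum(Bc * Bc)
  if (na < 1e-24 || nb < 1e-24) stop("RV coefficient undefined for a zero matrix")
  sum(Ac * Bc) / sqrt(na * nb)
}

# Long-format response table for the system contrast: one row per unit and
# ROI pair (upper triangle), with indicators for within-core and
# within-extended pairs. "Core" pools the ventral/dorsal/anterior core
# subsystems; EV pairs count as between.
system_contrast_frame <- function(r_by_unit, systems) {
  n_roi <- nrow(r_by_unit[[1]])
  if (length(systems) != n_roi) stop("one system label per ROI required")
  core <- grepl("^core", systems)
  ext <- systems == "extended"
  ut <- which(upper.tri(matrix(0, n_roi, n_roi)), arr.ind = TRUE)
  C_ind <- as.integer(core[ut[, 1]] & core[ut[, 2]])
  E_ind <- as.integer(ext[ut[, 1]] & ext[ut[, 2]])
  do.call(rbind, lapply(seq_along(r_by_unit), function(i) {
    r <- r_by_unit[[i]]
    data.frame(unit = i, pair = seq_len(nrow(ut)),
               r = r[ut], C = C_ind, E = E_ind)
  }))
}

#' Mixed-effects contrast of within- vs between-system RDM correlations
#'
#' Fits the random-intercept model
#' `r_ij = b0 + b1 * C_ij + b2 * E_ij + z_i` by REML, where `C_ij` indicates
#' that both ROIs of pair j are in the core system, `E_ij` that both are in
#' the extended system, and `z_i` is a per-unit (subject or subject-pair)
#' random intercept. `b1` is the contrast "Within Core > Between", `b2`
#' "Within Extended > Between". 95% confidence intervals come from a seeded
#' parametric bootstrap (simulate from the fitted model, refit, take
#' 2.5/97.5 percentiles of the fixed effects).
#'
#' @param geometry an `inter_roi_geometry`, or a data.frame with columns
#'   `unit`, `r`, `C`, `E`.
#' @param systems system labels (required with an `inter_roi_geometry` whose
#'   `systems` field is empty).
#' @param n_bootstrap parametric bootstrap draws (default 1000).
#' @param seed bootstrap seed.
#' @return object of class `lme_system_contrast`: data.frame `estimates` with
#'   `estimate`, `ci_lower`, `ci_upper`, `t_value` per fixed effect, plus the
#'   fitted `lme4` model.
#' @export
lme_system_contrast <- function(geometry, systems = NULL, n_bootstrap = 1000,
                                seed = 1L) {
  if (inherits(geometry, "inter_roi_geometry")) {
    systems <- systems %||% geometry$systems
    if (is.null(systems)) stop("system labels are required")
    df <- system_contrast_frame(geometry$r_by_unit, systems)
  } else {
    df <- as.data.frame(geometry)
    if (!all(c("unit", "r", "C", "E") %in% names(df)))
      stop("data frame must have columns unit, r, C, E")
  }
  if (any(df$C * df$E != 0)) stop("C and E indicators must never both be 1")
  if (length(unique(df$unit)) < 2) stop("need at least 2 units for a random intercept")
  df$unit <- factor(df$unit)
  df <- df[order(df$unit), ]
  fit <- suppressMessages(
    lme4::lmer(r ~ C + E + (1 | unit), data = df, REML = TRUE))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  # Parametric bootstrap. When every unit has the identical fixed-effect
  # design (the usual case: same ROI pairs for all subjects), the REML fixed
  # effects coincide with OLS, so bootstrap refits reduce to OLS on simulated
  # responses -- exact and orders of magnitude faster. Unbalanced data fall
  # back to lme4::refit.
  per_unit <- split(paste(df$C, df$E), df$unit)
  balanced <- length(unique(vapply(per_unit, paste, collapse = ";", ""))) == 1
  boot <- with_seed(seed, {
    if (balanced) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      sd_z <- vc$sdcor[vc$grp == "unit"]
      sd_e <- vc$sdcor[vc$grp == "Residual"]
      X <- cbind(1, df$C, df$E)
      qr_x <- qr(X)
      mu <- as.numeric(X %*% est)
      n_per <- as.integer(table(df$unit))
      vapply(seq_len(n_bootstrap), function(b) {
        y <- mu + rep(rnorm(length(n_per), 0, sd_z), times = n_per) +
          rnorm(nrow(df), 0, sd_e)
        qr.coef(qr_x, y)
      }, numeric(3))
    } else {
      sims <- stats::simulate(fit, nsim = n_bootstrap)
      vapply(seq_len(n_bootstrap), function(b) {
        refit_b <- suppressWarnings(suppressMessages(lme4::refit(fit, sims[[b]])))
        lme4::fixef(refit_b)
      }, numeric(3))
    }
  })
  ci <- apply(boot, 1, quantile, probs = c(0.025, 0.975))
  estimates <- data.frame(
    term = c("beta0", "beta1_within_core", "beta2_within_extended"),
    estimate = unname(est),
    ci_lower = ci[1, ], ci_upper = ci[2, ],
    t_value = unname(est / se), row.names = NULL)
  structure(list(estimates = estimates, model = fit,
                 n_bootstrap = n_bootstrap), class = "lme_system_contrast")
}

#' @export
print.lme_system_contrast <- function(x, ...) {
  cat("Within/between-system mixed-effects contrast\n")
  print(x$estimates, digits = 4)
  invisible(x)
}
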