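# Shared fixtures. Everything is generated in code at test time; expensive
# objects are built once per test file via lazy accessors.

tiny_grid <- function(dims = c(8, 8, 6)) volume_grid(dims)

# A small dataset with planted familiarity + identity signal in one region.
make_signal_betas <- function(seed = 1, n_runs = 11, dims = c(8, 8, 6),
                              familiarity_amp = 1.5, identity_amp = 1.5,
                              noise_sd = 1, region_center = c(4, 4, 3),
                              region_radius_mm = 5) {
  d <- generate_design(design_spec(n_runs = n_runs), seed = seed)
  sig <- signal_spec(
    familiarity_amp = familiarity_amp, identity_amp = identity_amp,
    view_amp = 0, noise_sd = noise_sd, seed = seed + 1000,
    regions = list(list(name = "R", center = region_center,
                        radius_mm = region_radius_mm, system = "extended",
                        familiarity = 1, identity = 1, view = 0)))
  g <- volume_grid(dims)
  betas <- generate_betas(d, sig, g)
  list(design = d, betas = betas, prepared = prepare_features(betas),
       region = facegeom:::resolve_region(sig$regions[[1]],
                                          full_brain_mask(g)))
}

l2io_16 <- function(runs = 1:11)
  leave_two_identities_out_splits(paste0("F", 1:4), paste0("U", 1:4), runs)

# Orthogonal Procrustes alignment (rotation/reflection + translation) used
# as the independent oracle for MDS configuration recovery.
procrustes_rms <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sqrt(mean((Yc %*% R - Xc)^2))
}

# Random synthetic RDM-like symmetric matrix with entries in [-1, 1].
random_rdm <- function(n = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n, -0.8, 0.8), n)
  m <- (m + t(m)) / 2
  structure(m, class = c("rdm", "matrix"), roi = paste0("roi", seed))
}
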