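# Shared fixtures: material table, fiber sets, small meshes and a fake
# FieldHistory builder for post-processor unit tests.

tab1 <- builtin_table1()

rd_fibers <- make_fiber_set(tab1$RD$theta, 16L)

# a soft fiber-free material for cheap isotropic checks
iso_params <- layer_params(
  mu0 = 0.01, q = 2, m1 = 0.2, m2 = 1,
  m_fe = 0, m_4e = 0, m_fd = 0, m_4d = 0,
  theta = 0, k_fd = 0, k0 = 1, kappa = 2,
  beta0 = 1e-3, beta1 = 2, phi_s_ref = 0.3, thickness = 1)

random_F <- function(scale = 0.1) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, sd = scale), 3, 3)
    if (det(F) > 0.5) return(F)
  }
}

# single-material stack of given thickness
mono_stack <- function(params, thickness = 2) {
  p <- params; p$thickness <- thickness
  layer_stack(list(RD = p))
}

# fabricate a minimal FieldHistory for post-processor tests
fake_history <- function(mesh, U_list, stack, times = seq_along(U_list)) {
  ngp <- if (mesh$dim == 3) 27L else 9L
  nq <- nrow(mesh$elems) * ngp
  structure(list(times = times, U = U_list,
                 MU = rep(list(numeric(length(mesh$mu_node_ids))),
                          length(U_list)),
                 Jgp = rep(list(rep(1, nq)), length(U_list)),
                 Pgp = rep(list(matrix(0, nq, 9)), length(U_list)),
                 Ugp = NULL, dVgp = rep(1, nq),
                 mesh = mesh, stack = stack),
            class = "FieldHistory")
}
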