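# Shared fixtures, built once per test session. Geometry fixtures use a
# coarse subdivision so the whole suite stays fast; fit-related fixtures are
# created lazily and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

fx_mesh <- function() fixture("mesh", function()
  make_bihemispheric_mesh(c(60, 45, 40), 6, 2))

fx_parc <- function() fixture("parc", function()
  make_symmetric_parcellation(fx_mesh(), 29))

fx_basis <- function() fixture("basis", function()
  solve_eigenmodes(assemble_laplace_beltrami(fx_mesh()), 6, mesh = fx_mesh()))

fx_pm <- function() fixture("pm", function()
  parcel_mode_values(fx_basis(), fx_parc(), fx_mesh(),
                     mode_order = model_modes(fx_basis())))

# finer-resolution geometry for the fit machinery (parcel noise is lower, so
# mode weights are identifiable); built only when a fit test runs
fx_mesh3 <- function() fixture("mesh3", function()
  make_bihemispheric_mesh(c(60, 45, 40), 6, 3))

fx_parc3 <- function() fixture("parc3", function()
  make_symmetric_parcellation(fx_mesh3(), 29))

fx_pm3 <- function() fixture("pm3", function() {
  basis <- solve_eigenmodes(assemble_laplace_beltrami(fx_mesh3()), 8,
                            mesh = fx_mesh3())
  parcel_mode_values(basis, fx_parc3(), fx_mesh3(),
                     mode_order = model_modes(basis))
})

# shared fit pipeline + coarse grid at the demonstration scale (60 s
# records, 120 summary edges, 0.05 grid step); expensive, built lazily once
fx_fit_pipeline <- function() fixture("fit_pipeline", function() {
  pm <- fx_pm3()
  set.seed(99)
  sedges <- sort(sample(1653, 120))
  fit_pipeline(pm, full_edge_mask(58), summary_edges = sedges, fs = 100,
               duration = 60, noise_seed = 777)
})

fx_fit_grid <- function() fixture("fit_grid", function()
  precompute_fit_grid(fx_fit_pipeline(), seq(0, 0.5, by = 0.05)))

# small random parcel recording (independent noise channels)
fx_noise_pts <- function(n_parcels = 58, duration = 30, fs = 100, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_parcels * duration * fs), n_parcels)
}

# tiny synthetic conn_cohort built directly from edge-weight draws: the
# netstats machinery operates on weights, so tests can plant effects exactly
synthetic_conn_cohort <- function(n_parcels = 20, n_ep = 10, n_hc = 10,
                                  seed = 1, effect_edges = integer(0),
                                  effect_size = 0, effect_on = "AS",
                                  effect_group = c("EP", "HC"), sd = 1) {
  et <- sleepmodes:::edge_table(n_parcels)
  E <- nrow(et)
  groups <- factor(rep(c("EP", "HC"), c(n_ep, n_hc)), levels = c("EP", "HC"))
  set.seed(seed)
  W <- array(rnorm(E * (n_ep + n_hc) * 2, sd = sd),
             c(E, n_ep + n_hc, 2), dimnames = list(NULL, NULL, c("AS", "QS")))
  if (length(effect_edges) && effect_size != 0) {
    subj <- which(groups %in% effect_group)
    W[effect_edges, subj, effect_on] <-
      W[effect_edges, subj, effect_on] + effect_size
  }
  structure(list(W = W, edge_idx = seq_len(E),
                 edges = et, groups = groups, n_parcels = n_parcels),
            class = "conn_cohort")
}
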