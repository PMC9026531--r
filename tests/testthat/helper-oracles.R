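# shared oracles and fixtures, built in code

# numerical differentiation of the strain energy along the incompressible
# uniaxial path: the independent oracle for analytic stresses
numeric_uniaxial_stress <- function(model, lambda, h = 1e-6) {
  vapply(lambda, function(l) {
    (strain_energy(model, uniaxial_stretches(l + h)) -
       strain_energy(model, uniaxial_stretches(l - h))) / (2 * h)
  }, 0)
}

# relative error with a floor tied to the curve scale (the stress vanishes
# at the reference state, where only absolute error is meaningful)
rel_err <- function(x, ref) {
  scale <- max(abs(ref))
  max(abs(x - ref) / pmax(abs(ref), 1e-2 * scale))
}

reference_models <- function() {
  list(mooney_rivlin5 = mooney_rivlin_graft(1),
       yeoh3 = yeoh_graft(1),
       ogden = ogden_aorta(),
       hgo = hgo_aorta())
}

# minimal hand-built flow_solution for metric unit tests (steady state,
# two frames spanning exactly one "cycle")
fake_solution <- function(Q = 6.2832e-6, r = 2e-3, p = 2666, h = 0.35e-3,
                          n_frames = 11, period = 0.5) {
  A <- pi * r^2
  net <- single_tube(material = elastic_graft(), length = 0.05, radius = r,
                     thickness = h)
  net$segments$tube$h <- h
  time <- seq(0, period, length.out = n_frames)
  mat <- function(v) matrix(v, n_frames, 4)
  structure(list(
    time = time,
    A = list(tube = mat(A)), Q = list(tube = mat(Q)),
    p = list(tube = mat(p)),
    x = list(tube = seq(0, 0.05, length.out = 4)),
    network = net, fluid = fluid_properties(),
    period = period, frames_per_cycle = n_frames - 1L,
    cycles_run = 1L, converged = TRUE, cycle_residuals = 1e-9),
    class = "flow_solution")
}

# small Y-junction network built by hand (parent feeding two children)
y_junction_network <- function(material = elastic_graft(), r = 2e-3,
                               h = 3e-4, L = 0.04, p_out = 1500) {
  seg <- function(nm, rr) {
    A0 <- pi * rr^2
    list(name = nm, length = L, r0 = rr, h = h, A0 = A0, wall = "test",
         material = material, loss = 1, law = tube_law(material, A0, h))
  }
  jn <- data.frame(segment = c("parent", "c1", "c2"),
                   side = c("end", "start", "start"))
  structure(list(placement = "y_junction",
                 segments = list(parent = seg("parent", r),
                                 c1 = seg("c1", 0.8 * r),
                                 c2 = seg("c2", 0.7 * r)),
                 junctions = list(jn), inlet = "parent",
                 outlets = list(c1 = list(type = "pressure", p = p_out),
                                c2 = list(type = "pressure", p = p_out)),
                 spec = NULL),
            class = "vessel_network")
}

# cache for expensive solver runs shared between test files
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

steady_waveform <- function(v) {
  inlet_waveform(period = 0.5, systole = 0.22, t_peak = 0.09,
                 v_peak = v, v_base = v)
}
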