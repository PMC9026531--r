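#' Reduced-order pulsatile flow in a compliant vessel network
#'
#' Integrates the one-dimensional area-flow (A-Q) equations of an
#' incompressible Newtonian fluid in every segment of a compliant network:
#' \deqn{A_t + Q_x = 0}
#' \deqn{Q_t + (alpha Q^2/A)_x + (A/rho) p_x = -8 pi mu Q / (rho A)}
#' with the algebraic wall law \code{p = p(A)} of each segment's
#' \code{\link{tube_law}} (quasi-static wall: wall inertia dropped; the
#' interface displacement, no-slip and traction conditions of the full
#' coupled problem are satisfied by construction of the wall law and the
#' friction term). The momentum-flux coefficient \code{alpha = 4/3} and the
#' friction term correspond to a parabolic (Poiseuille) velocity profile.
#'
#' Space-time integration is a second-order explicit MacCormack
#' predictor-corrector with a CFL-limited adaptive step. Boundary nodes are
#' closed by characteristic compatibility: prescribed velocity at the aortic
#' root inlet, prescribed (constant or time-varying) pressure at outlets, and
#' junction systems (solved by Newton iteration each step) enforcing exact
#' mass conservation plus a total-pressure relation with configurable
#' dissipation of the incoming dynamic head (see
#' \code{\link{network_spec}}, argument \code{junction_loss}; the default
#' is the dissipative mixing-plenum closure).
#' The run integrates whole cardiac cycles until the cycle-to-cycle
#' relative L2 change of pressure and flow falls below \code{tol} or
#' \code{n_cycles} is reached.
#'
#' @param network a \code{\link{build_network}} result (or
#'   \code{\link{single_tube}}).
#' @param fluid \code{\link{fluid_properties}}.
#' @param inlet an \code{\link{inlet_waveform}}.
#' @param n_cycles maximum number of cardiac cycles.
#' @param dx target node spacing (m); short segments keep at least
#'   \code{min_nodes} nodes.
#' @param min_nodes minimum nodes per segment.
#' @param cfl CFL number (< 1).
#' @param tol cycle-to-cycle relative L2 convergence tolerance.
#' @param out_dt output sampling interval (s).
#' @param alpha momentum-flux correction coefficient.
#' @param max_dt_floor smallest admissible time step (s) before the solver
#'   aborts with a CFL error.
#' @return object of class \code{"flow_solution"}: sampled time grid,
#'   per-segment matrices (frames x nodes) of area \code{A} (m^2), flow
#'   \code{Q} (m^3/s) and pressure \code{p} (Pa), node coordinates,
#'   convergence metadata and mass-balance diagnostics.
#' @export
solve_pulsatile <- function(network, fluid = fluid_properties(),
                            inlet = default_waveform(), n_cycles = 6,
                            dx = 5e-3, min_nodes = 4, cfl = 0.8,
                            tol = 1e-3, out_dt = 2e-3, alpha = 4 / 3,
                            max_dt_floor = 1e-9, verbose = FALSE) {
  stopifnot(inherits(network, "vessel_network"),
            inherits(fluid, "fluid_properties"),
            inherits(inlet, "inlet_waveform"))
  rho <- fluid$rho
  kf <- 8 * pi * fluid$mu / rho
  period <- inlet$period
  segs <- network$segments
  snames <- names(segs)
  S <- length(segs)

  n_nodes <- integer(S); dxs <- numeric(S)
  for (i in seq_len(S)) {
    n_nodes[i] <- max(min_nodes, ceiling(segs[[i]]$length / dx) + 1L)
    dxs[i] <- segs[[i]]$length / (n_nodes[i] - 1L)
  }
  laws <- lapply(segs, `[[`, "law")
  # tabulated wall laws: p, dp/dA, wave speed c and the generalized Riemann
  # function F(A) = int c/A dA on a dense stretch grid (fast interpolation
  # inside the time loop)
  flaws <- lapply(laws, tabulate_law, rho = rho)

  # initial state: each segment at the pressure of its nearest downstream
  # outlet (evaluated at t = 0), zero flow
  p_init <- init_pressures(network, t0 = 0)
  A <- vector("list", S); Q <- vector("list", S)
  for (i in seq_len(S)) {
    A[[i]] <- rep(laws[[i]]$area_at(p_init[i]), n_nodes[i])
    Q[[i]] <- rep(0, n_nodes[i])
  }

  # junction bookkeeping: per junction, vectors over connected ends
  jinfo <- lapply(network$junctions, function(j) {
    si <- match(j$segment, snames)
    K <- vapply(si, function(k) {
      l <- segs[[k]]$loss
      if (is.null(l)) 1 else l
    }, 0)
    at_end <- j$side == "end"
    list(m = nrow(j), seg = si,
         b = ifelse(at_end, n_nodes[si], 1L),
         i = ifelse(at_end, n_nodes[si] - 1L, 2L),
         s = ifelse(at_end, 1, -1), K = K,
         Afloor = 0.05 * vapply(si, function(k) segs[[k]]$A0, 0),
         Ascale = max(vapply(si, function(k) segs[[k]]$A0, 0)))
  })
  jcache <- vector("list", length(jinfo))
  inlet_seg <- match(network$inlet, snames)
  out_info <- lapply(names(network$outlets), function(nm) {
    si <- match(nm, snames)
    c(network$outlets[[nm]], list(seg = si, b = n_nodes[si],
                                  i = n_nodes[si] - 1L))
  })

  frames_per_cycle <- max(2L, round(period / out_dt))
  out_dt <- period / frames_per_cycle
  n_frames_max <- frames_per_cycle * n_cycles + 1L
  time_out <- numeric(n_frames_max)
  Asave <- lapply(n_nodes, function(n) matrix(NA_real_, n_frames_max, n))
  Qsave <- lapply(n_nodes, function(n) matrix(NA_real_, n_frames_max, n))
  frame <- 0L
  store_frame <- function(t, Af, Qf) {
    frame <<- frame + 1L
    time_out[frame] <<- t
    for (i in seq_len(S)) {
      Asave[[i]][frame, ] <<- Af[[i]]
      Qsave[[i]][frame, ] <<- Qf[[i]]
    }
  }
  store_frame(0, A, Q)

  t <- 0
  next_sample <- out_dt
  cycles_done <- 0L
  converged <- FALSE
  cycle_residuals <- numeric(0)
  t_end <- n_cycles * period

  # characteristic variable at a segment boundary: sampled at the foot of
  # the characteristic (old time level, linear interpolation) with the
  # friction source integrated along the path; second-order closure
  bW <- function(si, side, dt) {
    a <- A[[si]]; q <- Q[[si]]; n <- n_nodes[si]
    ib <- if (side > 0) n else 1L
    ii <- if (side > 0) n - 1L else 2L
    Ab <- a[ib]; ub <- q[ib] / Ab
    cb <- flaws[[si]]$c(Ab)
    th <- min(max((cb + side * ub) * dt / dxs[si], 0), 1)
    Af <- (1 - th) * Ab + th * a[ii]
    uf <- (1 - th) * ub + th * q[ii] / a[ii]
    uf + side * flaws[[si]]$F(Af) - dt * kf * uf / Af
  }

  nstep <- 0L
  while (t < t_end - 1e-12) {
    # CFL step from wave speeds
    dt <- Inf
    lim_seg <- 1L
    for (i in seq_len(S)) {
      ci <- flaws[[i]]$c(A[[i]])
      dti <- dxs[i] / max(abs(Q[[i]] / A[[i]]) + ci)
      if (dti < dt) { dt <- dti; lim_seg <- i }
    }
    dt <- cfl * dt
    nstep <- nstep + 1L
    if (verbose && nstep %% 2000L == 0L)
      message(sprintf("step %d  t = %.4f  dt = %.3g  limited by %s",
                      nstep, t, dt, snames[lim_seg]))
    if (!is.finite(dt) || dt < max_dt_floor)
      stop("solver CFL failure: time step collapsed at t = ", signif(t, 6))
    if (t + dt > next_sample) dt <- next_sample - t
    tn <- t + dt

    Astar <- A; Qstar <- Q
    for (i in seq_len(S)) {
      a <- A[[i]]; q <- Q[[i]]; n <- n_nodes[i]; h <- dxs[i]
      p <- flaws[[i]]$p(a)
      f2 <- alpha * q^2 / a
      idx <- 1:(n - 1)
      as <- a[idx] - dt / h * (q[idx + 1] - q[idx])
      Astar[[i]][idx] <- pmax(as, 0.05 * flaws[[i]]$A0)
      Qstar[[i]][idx] <- q[idx] - dt / h * (f2[idx + 1] - f2[idx]) -
        dt * (a[idx] / rho) * (p[idx + 1] - p[idx]) / h -
        dt * kf * q[idx] / a[idx]
    }
    An <- A; Qn <- Q
    for (i in seq_len(S)) {
      a <- A[[i]]; q <- Q[[i]]; n <- n_nodes[i]; h <- dxs[i]
      as <- Astar[[i]]; qs <- Qstar[[i]]
      ps <- flaws[[i]]$p(as)
      f2s <- alpha * qs^2 / as
      idx <- 2:n
      an <- 0.5 * (a[idx] + as[idx] - dt / h * (qs[idx] - qs[idx - 1]))
      An[[i]][idx] <- pmax(an, 0.05 * flaws[[i]]$A0)
      Qn[[i]][idx] <- 0.5 * (q[idx] + qs[idx] -
        dt / h * (f2s[idx] - f2s[idx - 1]) -
        dt * (as[idx] / rho) * (ps[idx] - ps[idx - 1]) / h -
        dt * kf * qs[idx] / as[idx])
      if (anyNA(Qn[[i]]) || any(!is.finite(Qn[[i]])))
        stop("solver diverged in segment '", snames[i], "' at t = ",
             signif(tn, 6))
    }

    # --- boundary closures at t = tn ---
    # inlet: prescribed velocity, backward characteristic from interior
    vi <- inlet$velocity(tn)
    Ab <- flaws[[inlet_seg]]$Finv(vi - bW(inlet_seg, -1, dt))
    An[[inlet_seg]][1] <- Ab
    Qn[[inlet_seg]][1] <- vi * Ab

    # outlets: prescribed pressure, forward characteristic from interior
    for (o in out_info) {
      fl <- flaws[[o$seg]]
      w1 <- bW(o$seg, 1, dt)
      if (o$type == "pressure") pb <- o$p
      else if (o$type == "pressure_fun") pb <- o$p_fun(tn)
      else if (o$type == "nonreflecting") {
        # incoming characteristic held at its reference value (u - F(A) = 0)
        Ab <- fl$Finv(w1 / 2)
        An[[o$seg]][o$b] <- Ab
        Qn[[o$seg]][o$b] <- (w1 / 2) * Ab
        next
      } else stop("unknown outlet type: ", o$type)
      Ab <- fl$area_at(pb)
      An[[o$seg]][o$b] <- Ab
      Qn[[o$seg]][o$b] <- (w1 - fl$F(Ab)) * Ab
    }

    # junctions
    for (jx in seq_along(jinfo)) {
      ji <- jinfo[[jx]]
      Wj <- vapply(seq_len(ji$m), function(k) bW(ji$seg[k], ji$s[k], dt), 0)
      sol <- solve_junction(ji, flaws, A, Q, rho, Wj, jcache[[jx]])
      jcache[[jx]] <- sol
      for (k in seq_len(ji$m)) {
        An[[ji$seg[k]]][ji$b[k]] <- sol$A[k]
        Qn[[ji$seg[k]]][ji$b[k]] <- sol$A[k] * sol$u[k]
      }
    }

    A <- An; Q <- Qn; t <- tn

    if (t >= next_sample - 1e-12) {
      store_frame(t, A, Q)
      next_sample <- next_sample + out_dt
      # cycle bookkeeping
      if (frame %% frames_per_cycle == 1L && frame > frames_per_cycle) {
        cycles_done <- cycles_done + 1L
        if (cycles_done >= 2L) {
          res <- cycle_change(Asave, Qsave, laws, frames_per_cycle, frame)
          cycle_residuals <- c(cycle_residuals, res)
          if (res < tol) { converged <- TRUE; break }
        }
      }
    }
  }

  time_out <- time_out[seq_len(frame)]
  Asave <- lapply(Asave, function(m) m[seq_len(frame), , drop = FALSE])
  Qsave <- lapply(Qsave, function(m) m[seq_len(frame), , drop = FALSE])
  p_out <- lapply(seq_len(S), function(i) {
    m <- Asave[[i]]
    matrix(laws[[i]]$p(as.vector(m)), nrow = nrow(m))
  })
  x <- lapply(seq_len(S), function(i)
    seq(0, segs[[i]]$length, length.out = n_nodes[i]))
  names(Asave) <- names(Qsave) <- names(p_out) <- names(x) <- snames

  sol <- structure(list(
    time = time_out, A = Asave, Q = Qsave, p = p_out, x = x,
    network = network, fluid = fluid, inlet = inlet,
    period = period, frames_per_cycle = frames_per_cycle,
    cycles_run = (frame - 1L) %/% frames_per_cycle,
    converged = converged, cycle_residuals = cycle_residuals,
    tol = tol, dx = dx, cfl = cfl, alpha = alpha),
    class = "flow_solution")
  sol$mass_balance <- mass_balance(sol)
  sol
}

# dense tabulation of a tube law for the time loop: p(A), dp/dA(A), wave
# speed c(A), Riemann function F(A) and inverses, all by linear
# interpolation over circumferential stretch
tabulate_law <- function(law, rho, lam_lo = 0.35, lam_hi = 2.8, n = 2801) {
  lam <- seq(lam_lo, lam_hi, length.out = n)
  pg <- law$p_of_lam(lam)
  dpl <- law$dp_dlam(lam)
  cg <- sqrt(pmax(lam * dpl, 0) / (2 * rho))
  g <- 2 * cg / lam
  Fg <- c(0, cumsum(diff(lam) * (utils::head(g, -1) + utils::tail(g, -1)) / 2))
  Fg <- Fg - stats::approx(lam, Fg, xout = 1)$y
  A0 <- law$A0
  dpdAg <- dpl / (2 * A0 * lam)
  fP <- stats::approxfun(lam, pg, rule = 2)
  fD <- stats::approxfun(lam, dpdAg, rule = 2)
  fC <- stats::approxfun(lam, cg, rule = 2)
  fF <- stats::approxfun(lam, Fg, rule = 2)
  fFi <- stats::approxfun(Fg, lam, rule = 2)
  fAi <- stats::approxfun(pg, lam, rule = 2)
  list(A0 = A0,
       p = function(A) fP(sqrt(A / A0)),
       dpdA = function(A) fD(sqrt(A / A0)),
       c = function(A) fC(sqrt(A / A0)),
       F = function(A) fF(sqrt(A / A0)),
       Finv = function(w) A0 * fFi(w)^2,
       area_at = function(p) A0 * fAi(p)^2)
}

# Newton solve of one junction. Unknowns: (A_e, u_e) per connected end plus
# the junction pressure node P_J. Equations: outgoing characteristic
# compatibility per end (W from the foot interpolation), exact mass
# conservation, and a pressure relation per end: ends discharging into the
# junction (donors) satisfy p_e + (1 - K_e) rho u_e^2/2 = P_J (a fraction
# K_e of the dynamic head is dissipated; K_e = 1 is the dissipative
# mixing-plenum closure); receiving ends satisfy ideal total-pressure
# continuity p_e + rho u_e^2/2 = P_J. Donor/receiver classification is
# lagged one step for smoothness. Warm-started from the previous step.
solve_junction <- function(ji, flaws, A, Q, rho, W, cache = NULL) {
  m <- ji$m
  s <- ji$s; K <- ji$K
  if (!is.null(cache)) {
    Ae <- cache$A; ue <- cache$u; PJ <- cache$PJ
  } else {
    Ae <- numeric(m); ue <- numeric(m)
    for (k in seq_len(m)) {
      Ae[k] <- A[[ji$seg[k]]][ji$b[k]]
      ue[k] <- Q[[ji$seg[k]]][ji$b[k]] / Ae[k]
    }
    PJ <- mean(vapply(seq_len(m), function(k) flaws[[ji$seg[k]]]$p(Ae[k]), 0))
  }
  zeta <- 1 - K * (s * ue > 0)   # donor ends lose K * dynamic head
  nunk <- 2 * m + 1
  f <- numeric(nunk)
  J <- matrix(0, nunk, nunk)
  iA <- seq(1, 2 * m, by = 2)
  iu <- seq(2, 2 * m, by = 2)
  iP <- nunk
  for (iter in 1:40) {
    for (k in seq_len(m)) {
      fl <- flaws[[ji$seg[k]]]
      pk <- fl$p(Ae[k]); dpk <- fl$dpdA(Ae[k]); ck <- fl$c(Ae[k])
      f[k] <- ue[k] + s[k] * fl$F(Ae[k]) - W[k]
      J[k, iu[k]] <- 1
      J[k, iA[k]] <- s[k] * ck / Ae[k]
      f[m + 1 + k] <- (pk + zeta[k] * 0.5 * rho * ue[k]^2 - PJ) / rho
      J[m + 1 + k, iA[k]] <- dpk / rho
      J[m + 1 + k, iu[k]] <- zeta[k] * ue[k]
      J[m + 1 + k, iP] <- -1 / rho
    }
    f[m + 1] <- sum(s * Ae * ue) / ji$Ascale
    J[m + 1, iA] <- s * ue / ji$Ascale
    J[m + 1, iu] <- s * Ae / ji$Ascale
    res <- max(abs(f))
    if (res < 1e-12) break
    if (iter == 40) {
      if (res < 1e-9) break   # floating-point plateau; accept
      stop("junction Newton failed to converge (residual ",
           signif(res, 3), ")")
    }
    step <- solve(J, f)
    # damped update keeping areas positive
    lam <- 1
    repeat {
      Anew <- Ae - lam * step[iA]
      if (all(Anew > ji$Afloor) || lam < 1e-3) break
      lam <- lam / 2
    }
    Ae <- pmax(Anew, ji$Afloor)
    ue <- ue - lam * step[iu]
    PJ <- PJ - lam * step[iP]
  }
  # project the residual mass defect onto the velocities so junction mass
  # conservation holds to machine precision
  r <- sum(s * Ae * ue)
  w <- Ae^2 / sum(Ae^2)
  ue <- ue - s * r * w / Ae
  list(A = Ae, u = ue, PJ = PJ)
}


# nearest-downstream-outlet initial pressure per segment
init_pressures <- function(network, t0 = 0) {
  snames <- names(network$segments)
  p <- rep(NA_real_, length(snames)); names(p) <- snames
  for (nm in names(network$outlets)) {
    o <- network$outlets[[nm]]
    p[nm] <- if (o$type == "pressure") o$p
             else if (o$type == "pressure_fun") o$p_fun(t0) else 0
  }
  repeat {
    grew <- FALSE
    for (j in network$junctions) {
      fed <- j$segment[j$side == "start"]
      feeders <- j$segment[j$side == "end"]
      if (all(!is.na(p[fed])) && any(is.na(p[feeders]))) {
        p[feeders[is.na(p[feeders])]] <- mean(p[fed])
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  p[is.na(p)] <- mean(p, na.rm = TRUE)
  p
}

# relative L2 change between the two most recent whole cycles (p and Q)
cycle_change <- function(Asave, Qsave, laws, fpc, nf) {
  i2 <- (nf - fpc + 1):nf
  i1 <- i2 - fpc
  num <- 0; den <- 0; numq <- 0; denq <- 0
  for (i in seq_along(Asave)) {
    p2 <- laws[[i]]$p(as.vector(Asave[[i]][i2, ]))
    p1 <- laws[[i]]$p(as.vector(Asave[[i]][i1, ]))
    num <- num + sum((p2 - p1)^2); den <- den + sum(p2^2)
    q2 <- as.vector(Qsave[[i]][i2, ]); q1 <- as.vector(Qsave[[i]][i1, ])
    numq <- numq + sum((q2 - q1)^2); denq <- denq + sum(q2^2)
  }
  max(sqrt(num / max(den, 1e-300)), sqrt(numq / max(denq, 1e-300)))
}

# volume accounting over the final whole cycle
mass_balance <- function(sol) {
  fpc <- sol$frames_per_cycle
  nf <- length(sol$time)
  if (nf < fpc + 1) return(NULL)
  idx <- (nf - fpc):nf
  tt <- sol$time[idx]
  trapz <- function(y)
    sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  inlet_seg <- sol$network$inlet
  v_in <- trapz(sol$Q[[inlet_seg]][idx, 1])
  v_out <- 0
  for (nm in names(sol$network$outlets)) {
    n <- ncol(sol$Q[[nm]])
    v_out <- v_out + trapz(sol$Q[[nm]][idx, n])
  }
  dV <- 0
  for (nm in names(sol$A)) {
    x <- sol$x[[nm]]
    a1 <- sol$A[[nm]][idx[1], ]; a2 <- sol$A[[nm]][idx[length(idx)], ]
    seg_int <- function(a)
      sum(diff(x) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
    dV <- dV + seg_int(a2) - seg_int(a1)
  }
  list(inflow_m3 = v_in, outflow_m3 = v_out, storage_m3 = dV,
       closure_error = (v_in - v_out - dV) / max(abs(v_in), 1e-300),
       periodic_error = (v_in - v_out) / max(abs(v_in), 1e-300))
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution>", x$network$placement, "placement,",
      x$cycles_run, "cycles,",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (length(x$cycle_residuals))
    cat("  cycle-to-cycle residuals:",
        paste(signif(x$cycle_residuals, 3), collapse = " "), "\n")
  mb <- x$mass_balance
  if (!is.null(mb))
    cat(sprintf("  final-cycle inflow %.3g mL, closure error %.2e\n",
                mb$inflow_m3 * 1e6, mb$closure_error))
  invisible(x)
}

#' @export
summary.flow_solution <- function(object, ...) {
  fin <- final_cycle_index(object)
  rows <- lapply(names(object$A), function(nm) {
    p <- object$p[[nm]][fin, , drop = FALSE]
    q <- object$Q[[nm]][fin, , drop = FALSE]
    data.frame(segment = nm,
               p_peak_mmhg = max(p) / MMHG_PA,
               p_mean_mmhg = mean(p) / MMHG_PA,
               q_peak_ml_s = max(abs(q)) * 1e6,
               q_mean_ml_min = mean(q[, ncol(q) %/% 2 + 1]) * 6e7)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.flow_solution", "data.frame")
  out
}

final_cycle_index <- function(sol) {
  nf <- length(sol$time)
  (nf - sol$frames_per_cycle):nf
}

#' Shunt flow time series over the final cycle
#'
#' Flow rate at the shunt mid-segment node over the final simulated cycle,
#' with its cycle mean and peak.
#'
#' @param solution a converged \code{\link{solve_pulsatile}} result.
#' @param force evaluate even if the run did not reach the convergence
#'   tolerance.
#' @return list with \code{time} (s, cycle-relative), \code{q_m3_s},
#'   \code{q_ml_min}, \code{mean_ml_min}, \code{peak_ml_min}.
#' @export
shunt_flow_series <- function(solution, force = FALSE) {
  if (!inherits(solution, "flow_solution"))
    stop("solution must be a flow_solution")
  if (!solution$converged && !force)
    stop("solution did not converge (last cycle residual ",
         signif(utils::tail(solution$cycle_residuals, 1), 3),
         "); pass force = TRUE to extract anyway")
  if (!"shunt" %in% names(solution$Q))
    stop("network has no shunt segment")
  fin <- final_cycle_index(solution)
  mid <- ncol(solution$Q[["shunt"]]) %/% 2 + 1
  q <- solution$Q[["shunt"]][fin, mid]
  tt <- solution$time[fin] - solution$time[fin[1]]
  list(time = tt, q_m3_s = q, q_ml_min = q * 6e7,
       mean_ml_min = mean(q) * 6e7, peak_ml_min = max(q) * 6e7)
}

#' Single-tube network for validation runs
#'
#' One straight compliant segment named \code{"tube"} from inlet to a single
#' outlet; used for classical verification limits (steady Poiseuille flow,
#' Moens-Korteweg pulse-wave speed, grid-convergence studies).
#'
#' @param material wall material.
#' @param length,radius,thickness geometry (m).
#' @param outlet outlet descriptor: \code{list(type = "pressure", p = Pa)},
#'   \code{list(type = "pressure_fun", p_fun = function(t))} or
#'   \code{list(type = "nonreflecting")}.
#' @return a \code{vessel_network} with a single segment.
#' @export
single_tube <- function(material = elastic_graft(), length = 0.1,
                        radius = 2e-3, thickness = 0.3e-3,
                        outlet = list(type = "pressure", p = 0)) {
  A0 <- pi * radius^2
  seg <- list(name = "tube", length = length, r0 = radius, h = thickness,
              A0 = A0, wall = "tube", material = material,
              law = tube_law(material, A0, thickness))
  structure(list(placement = "single_tube",
                 segments = list(tube = seg), junctions = list(),
                 inlet = "tube", outlets = list(tube = outlet),
                 spec = NULL),
            class = "vessel_network")
}
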