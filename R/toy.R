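#' Quartic double-well toy potential
#'
#' A two-dimensional surrogate for molecular dynamics: a quartic double well
#' along `x` coupled to a harmonic coordinate `y`,
#' \deqn{V(x, y) = h\,\big((x/a)^2 - 1\big)^2 + \tfrac{1}{2} k_y y^2,}
#' with `a = well_separation / 2`.  The two minima sit at `(+-a, 0)` with
#' `V = 0` and the saddle at the origin with `V = barrier_height`, so barrier
#' heights, minima and curvatures are all available in closed form for
#' analytic tests.  Units: unit mass, `kB = 1`, temperature in energy units.
#'
#' @param barrier_height saddle energy relative to the minima (energy units).
#' @param well_separation distance between the two minima (length units).
#' @param coupling stiffness of the orthogonal harmonic coordinate.
#' @return An object of class `toy_potential`.
#' @examples
#' pot <- toy_potential(barrier_height = 5)
#' toy_energy_force(pot, c(0, 0))$energy  # the saddle energy
#' @export
toy_potential <- function(barrier_height = 5, well_separation = 2,
                          coupling = 1) {
  stopifnot(barrier_height > 0, well_separation > 0, coupling > 0)
  structure(
    list(barrier_height = barrier_height,
         well_separation = well_separation,
         coupling = coupling,
         a = well_separation / 2),
    class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("Quartic double-well potential\n",
      "  barrier height : ", x$barrier_height, "\n",
      "  minima         : x = +-", x$a, "\n",
      "  y stiffness    : ", x$coupling, "\n", sep = "")
  invisible(x)
}

#' Energy and force of the toy potential
#'
#' @param potential a [toy_potential()].
#' @param position numeric 2-vector `(x, y)`.
#' @return A list with `energy` (scalar) and `force` (2-vector, the negative
#'   gradient of the energy).
#' @export
toy_energy_force <- function(potential, position) {
  stopifnot(inherits(potential, "toy_potential"),
            length(position) == 2, all(is.finite(position)))
  toy_energy_force_cpp(as.numeric(position), potential$barrier_height,
                       potential$a, potential$coupling)
}

#' Single Langevin (BAOAB) integration step
#'
#' BAOAB splitting of underdamped Langevin dynamics.  With `friction = 0`
#' the O block is the identity and the step reduces to symplectic velocity
#' Verlet.  Randomness flows through R's global RNG, so runs are reproducible
#' under [set.seed()].
#'
#' @param potential a [toy_potential()].
#' @param position,velocity numeric 2-vectors.
#' @param dt time step (> 0).
#' @param friction friction coefficient (>= 0, inverse time).
#' @param temperature temperature in energy units (> 0).
#' @return A list with updated `position` and `velocity`.
#' @export
langevin_step <- function(potential, position, velocity, dt, friction,
                          temperature) {
  stopifnot(dt > 0, friction >= 0, temperature > 0,
            all(is.finite(position)), all(is.finite(velocity)))
  out <- baoab_run_cpp(c(position, velocity), 1L, 1L, dt, friction,
                       temperature, potential$barrier_height, potential$a,
                       potential$coupling)
  list(position = out[2, 1:2], velocity = out[2, 3:4])
}

#' Run Langevin dynamics for a fixed number of steps
#'
#' @inheritParams langevin_step
#' @param state numeric 4-vector `(x, y, vx, vy)`.
#' @param n_steps number of integration steps.
#' @param save_every store every `save_every`-th state (the initial state is
#'   always stored).
#' @return A matrix with columns `x`, `y`, `vx`, `vy`.
#' @export
langevin_run <- function(potential, state, n_steps, dt, friction,
                         temperature, save_every = 1L) {
  stopifnot(length(state) == 4, all(is.finite(state)), n_steps >= 1)
  out <- baoab_run_cpp(as.numeric(state), as.integer(n_steps),
                       as.integer(save_every), dt, friction, temperature,
                       potential$barrier_height, potential$a,
                       potential$coupling)
  colnames(out) <- c("x", "y", "vx", "vy")
  out
}

#' Toy dynamics backend for the path sampler
#'
#' Wraps the Langevin toy engine in the pluggable backend interface used by
#' the sampling engine ([run_sampler()], [run_inf_init()]).  A backend is a
#' list providing: `propagate(phase, stop_low, stop_high, max_steps)` which
#' integrates until the order parameter leaves the open interval
#' `(stop_low, stop_high)` and returns `frames`, `lambdas`, `n_steps` and
#' `terminal`; `draw_velocities(phase)`; `flip(phase)` (time reversal);
#' `lambda(frames)`; and `timestep`, the physical duration of one frame
#' interval.  The toy order parameter is the `x` coordinate.
#'
#' @inheritParams langevin_step
#' @return A list of class `dynamics_backend`.
#' @export
toy_dynamics <- function(potential, dt = 0.02, friction = 1,
                         temperature = 1) {
  stopifnot(inherits(potential, "toy_potential"), dt > 0, friction >= 0,
            temperature > 0)
  backend <- list(
    kind = "toy",
    potential = potential,
    dt = dt,
    friction = friction,
    temperature = temperature,
    timestep = dt,
    propagate = function(phase, stop_low, stop_high, max_steps) {
      out <- propagate_toy_cpp(as.numeric(phase), dt, friction, temperature,
                               potential$barrier_height, potential$a,
                               potential$coupling, stop_low, stop_high,
                               as.integer(max_steps))
      list(frames = out$frames, lambdas = out$frames[, 1],
           n_steps = out$n_steps, terminal = out$terminal)
    },
    draw_velocities = function(phase) {
      phase[3:4] <- stats::rnorm(2, sd = sqrt(temperature))
      phase
    },
    flip = function(phase) {
      phase[3:4] <- -phase[3:4]
      phase
    },
    lambda = function(frames) {
      if (is.matrix(frames)) frames[, 1] else frames[1]
    })
  class(backend) <- "dynamics_backend"
  backend
}

#' One-dimensional overdamped surrogate backend
#'
#' Brownian dynamics on a collective variable treated directly as the
#' coordinate, for exercising the sampler and the initialisation protocol on
#' CV-level surrogates of membrane processes (for example a local
#' translocation distance relaxing in a double well).  The potential is a
#' quartic double well with minima at `minimum_a` and `minimum_b` and the
#' stated barrier at their midpoint.  `direction = -1` declares an
#' order-reversing mapping, so progress toward state B means a *decreasing*
#' coordinate (as for a translocation distance shrinking to zero); internally
#' the order parameter is `direction * coordinate`.
#'
#' Overdamped dynamics carry no velocities: `draw_velocities` and `flip` are
#' identities and time reversal holds in distribution.
#'
#' @param minimum_a,minimum_b coordinate values of the two metastable states.
#' @param barrier_height barrier at the midpoint (energy units, kB = 1).
#' @param dt time step; `friction` the Brownian friction; `temperature` in
#'   energy units.
#' @param direction `+1` (order parameter = coordinate) or `-1` (reversed).
#' @return A list of class `dynamics_backend`.
#' @export
surrogate_cv_dynamics <- function(minimum_a, minimum_b, barrier_height = 5,
                                  dt = 0.005, friction = 1, temperature = 1,
                                  direction = 1) {
  stopifnot(minimum_a != minimum_b, barrier_height > 0, dt > 0,
            friction > 0, temperature > 0, direction %in% c(-1, 1))
  mid <- (minimum_a + minimum_b) / 2
  half <- abs(minimum_b - minimum_a) / 2
  grad <- function(z) {
    u <- ((z - mid) / half)^2 - 1
    4 * barrier_height * u * (z - mid) / half^2
  }
  sigma <- sqrt(2 * temperature * dt / friction)
  backend <- list(
    kind = "surrogate_cv",
    dt = dt,
    timestep = dt,
    direction = direction,
    propagate = function(phase, stop_low, stop_high, max_steps) {
      z <- phase[1]
      lam <- direction * z
      zs <- numeric(min(max_steps + 1L, 1e6L))
      zs[1] <- z
      n <- 1L
      terminal <- if (lam < stop_low) 1L else if (lam > stop_high) 2L else 0L
      while (terminal == 0L && n <= max_steps) {
        z <- z - grad(z) * dt / friction + sigma * stats::rnorm(1)
        n <- n + 1L
        zs[n] <- z
        lam <- direction * z
        if (lam < stop_low) terminal <- 1L
        else if (lam > stop_high) terminal <- 2L
      }
      frames <- matrix(zs[seq_len(n)], ncol = 1)
      list(frames = frames, lambdas = direction * frames[, 1],
           n_steps = n - 1L, terminal = terminal)
    },
    draw_velocities = function(phase) phase,
    flip = function(phase) phase,
    lambda = function(frames) {
      if (is.matrix(frames)) direction * frames[, 1] else direction * frames[1]
    })
  class(backend) <- "dynamics_backend"
  backend
}

#' Deterministic downhill backend (degenerate-limit testing)
#'
#' Moves the order parameter toward state B by a fixed increment every
#' step, in both time directions (the landscape is imagined monotonically
#' downhill toward B).  Used to check degenerate limits of the
#' initialisation protocol: with this mover any shot is immediately
#' reactive, so the protocol must terminate in its first round.
#'
#' @param step increment of the order parameter per step.
#' @return A list of class `dynamics_backend`.
#' @export
downhill_dynamics <- function(step = 0.1) {
  stopifnot(step > 0)
  backend <- list(
    kind = "downhill",
    dt = 1,
    timestep = 1,
    propagate = function(phase, stop_low, stop_high, max_steps) {
      lam <- phase[1]
      out <- lam
      terminal <- if (lam < stop_low) 1L else if (lam > stop_high) 2L
                  else 0L
      n <- 0L
      while (terminal == 0L && n < max_steps) {
        lam <- lam + step
        out <- c(out, lam)
        n <- n + 1L
        if (lam < stop_low) terminal <- 1L
        else if (lam > stop_high) terminal <- 2L
      }
      frames <- matrix(out, ncol = 1)
      list(frames = frames, lambdas = frames[, 1], n_steps = n,
           terminal = terminal)
    },
    draw_velocities = function(phase) phase,
    flip = function(phase) phase,
    lambda = function(frames) {
      if (is.matrix(frames)) frames[, 1] else frames[1]
    })
  class(backend) <- "dynamics_backend"
  backend
}

#' Brute-force rate from direct Langevin simulation
#'
#' Counts A -> B transitions in one long trajectory with hysteresis state
#' assignment (in A until the order parameter exceeds `lambda_b`, then in B
#' until it drops below `lambda_a`) and reports the A -> B rate as events per
#' unit time spent in A, with a Poisson-style standard error.
#'
#' @inheritParams langevin_step
#' @param state initial 4-vector; place it in the A basin.
#' @param n_steps total number of integration steps.
#' @param lambda_a,lambda_b terminal interfaces defining states A and B.
#' @return A list with `rate`, `se`, `n_ab`, `n_ba`, `time_a`, `time_b`.
#' @export
brute_force_rate <- function(potential, state, n_steps, dt, friction,
                             temperature, lambda_a, lambda_b) {
  stopifnot(lambda_a < lambda_b, n_steps > 0)
  out <- mfpt_run_cpp(as.numeric(state), as.numeric(n_steps), dt, friction,
                      temperature, potential$barrier_height, potential$a,
                      potential$coupling, lambda_a, lambda_b)
  if (out$n_ab < 1) stop("no A->B transitions observed; increase n_steps")
  rate <- out$n_ab / out$time_a
  list(rate = rate, se = rate / sqrt(out$n_ab), n_ab = out$n_ab,
       n_ba = out$n_ba, time_a = out$time_a, time_b = out$time_b,
       ab_times = out$ab_times)
}
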