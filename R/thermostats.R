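# Nose-Hoover chain thermostats on centre-of-mass (nuclear) and relative
# (shell) coordinates, with conserved-quantity bookkeeping.

#' Create a Nose-Hoover chain thermostat
#'
#' One chain of `n_links >= 2` thermostat variables coupled to a set of
#' degrees of freedom. Thermostat masses follow the standard prescription
#' q_1 = D k_B T tau^2 and q_j = k_B T tau^2 for j > 1, where D is the
#' number of coupled degrees of freedom and tau the coupling timescale.
#'
#' @param target_T target temperature (K).
#' @param dof number of coupled degrees of freedom (N_f for the nuclear
#'   chain, 3 n_s for the shell chain).
#' @param tau coupling timescale (fs).
#' @param n_links chain length, default 4 (must be > 1).
#' @return An object of class `nhc_chain` with positions `eta`, momenta
#'   `p_eta` (eV fs) and masses `q` (eV fs^2).
#' @seealso [nhc_propagate()], [conserved_quantity()]
#' @export
nhc_chain <- function(target_T, dof, tau, n_links = 4) {
  if (target_T <= 0) stop("target temperature must be positive")
  if (n_links < 2) stop("chain length must be > 1")
  if (dof < 1) stop("chain must couple at least one degree of freedom")
  kT <- .KB * target_T
  q <- rep(kT * tau^2, n_links)
  q[1] <- dof * kT * tau^2
  structure(list(eta = numeric(n_links), p_eta = numeric(n_links), q = q,
                 target_T = target_T, dof = dof, tau = tau,
                 n_links = as.integer(n_links)),
            class = "nhc_chain")
}

#' Propagate a Nose-Hoover chain over a half step
#'
#' Reversible update of the chain variables using a 7-point Suzuki-Yoshida
#' factorization, returning the accumulated velocity scale factor for the
#' coupled degrees of freedom. `twoK` is twice the kinetic energy of the
#' coupled subsystem in its own representation (eV): sum Mbar |Sdot|^2 for
#' the nuclear chain, sum mbar |sdot|^2 for the shell chain.
#'
#' @param chain an `nhc_chain`.
#' @param twoK twice the coupled kinetic energy (eV).
#' @param dt interval to propagate over (fs); the integrator calls this with
#'   half the MD timestep on either side of the velocity-Verlet update.
#' @param n_inner number of inner cycles of the factorization (default 2).
#' @return list with `scale` (multiply coupled velocities by this) and the
#'   updated `chain`.
#' @export
nhc_propagate <- function(chain, twoK, dt, n_inner = 2) {
  w1 <- 0.784513610477560
  w2 <- 0.235573213359357
  w3 <- -1.17767998417887
  w <- c(w1, w2, w3, 1 - 2 * (w1 + w2 + w3), w3, w2, w1)
  kT <- .KB * chain$target_T
  D <- chain$dof
  nc <- chain$n_links
  p <- chain$p_eta; q <- chain$q; eta <- chain$eta
  scale <- 1
  akin <- twoK
  for (cyc in seq_len(n_inner)) for (iw in seq_along(w)) {
    delta <- w[iw] * dt / n_inner
    # chain forces: G_1 = 2K - D kT, G_j = p_{j-1}^2/q_{j-1} - kT
    p[nc] <- p[nc] + 0.5 * delta * (p[nc - 1]^2 / q[nc - 1] - kT)
    for (j in (nc - 1):1) {
      fac <- exp(-0.25 * delta * p[j + 1] / q[j + 1])
      Gj <- if (j == 1) akin - D * kT else p[j - 1]^2 / q[j - 1] - kT
      p[j] <- p[j] * fac * fac + 0.5 * delta * Gj * fac
    }
    s <- exp(-delta * p[1] / q[1])
    if (!is.finite(s)) stop("thermostat divergence: non-finite scale factor")
    scale <- scale * s
    akin <- akin * s * s
    eta <- eta + delta * p / q
    for (j in 1:(nc - 1)) {
      fac <- exp(-0.25 * delta * p[j + 1] / q[j + 1])
      Gj <- if (j == 1) akin - D * kT else p[j - 1]^2 / q[j - 1] - kT
      p[j] <- p[j] * fac * fac + 0.5 * delta * Gj * fac
    }
    p[nc] <- p[nc] + 0.5 * delta * (p[nc - 1]^2 / q[nc - 1] - kT)
  }
  chain$p_eta <- p; chain$eta <- eta
  list(scale = scale, chain = chain)
}

#' Thermostat contribution to the conserved quantity
#'
#' Each chain contributes sum_j p_eta_j^2 / (2 q_j) + D k_B T eta_1 +
#' k_B T sum_{j>1} eta_j to the NVT conserved quantity.
#'
#' @param chain an `nhc_chain`.
#' @return energy (eV).
#' @export
nhc_energy <- function(chain) {
  kT <- .KB * chain$target_T
  sum(chain$p_eta^2 / (2 * chain$q)) +
    chain$dof * kT * chain$eta[1] +
    if (chain$n_links > 1) kT * sum(chain$eta[-1]) else 0
}

#' Conserved quantity of an NVT run
#'
#' The total extended-system energy (potential + all kinetic terms) plus the
#' thermostat contributions of every active chain. With no chains this
#' reduces to the NVE total energy.
#'
#' @param total_energy NVE total energy (eV).
#' @param chains list of `nhc_chain` objects (may be empty).
#' @return energy (eV).
#' @export
conserved_quantity <- function(total_energy, chains = list()) {
  total_energy + sum(vapply(chains, nhc_energy, 0))
}

#' Default thermostat pair for a core-shell system
#'
#' Nuclear chain coupled to the centre-of-mass velocities at
#' `T_phys_target` with D = N_f, and shell chain coupled to the relative
#' core-shell velocities at `T_s_target` (default 1 K, keeping the shell
#' subsystem cold) with D = 3 n_s.
#'
#' @param sys a `particle_system` with shells.
#' @param T_phys_target nuclear target (K), default 300.
#' @param T_s_target shell target (K), default 1.
#' @param tau_phys,tau_shell coupling timescales (fs).
#' @param n_links chain length.
#' @return list with elements `nuclear` and `shell`.
#' @export
make_default_chains <- function(sys, T_phys_target = 300, T_s_target = 1,
                                tau_phys = 50, tau_shell = 10, n_links = 4) {
  if (n_shells(sys) == 0)
    stop("shell chain requested for a system without shells")
  list(nuclear = nhc_chain(T_phys_target, dof_count(sys), tau_phys, n_links),
       shell = nhc_chain(T_s_target, 3L * n_shells(sys), tau_shell, n_links))
}

#' Convert a kinetic-energy target to a chain temperature
#'
#' For thermostatting fictitious subsystems whose control variable is a
#' kinetic energy rather than a temperature (e.g. a target of 0.0007 Hartree
#' for surrogate internal variables): at stationarity 2 KE = D k_B T, so the
#' equivalent chain temperature is T = 2 KE / (D k_B).
#'
#' @param ke_target kinetic energy target (eV).
#' @param dof coupled degrees of freedom.
#' @return temperature (K).
#' @export
ke_target_temperature <- function(ke_target, dof) {
  2 * ke_target / (dof * .KB)
}
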