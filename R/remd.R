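# Temperature replica exchange: ladder construction, Metropolis swaps with
# velocity rescaling, replica bookkeeping and mixing diagnostics.

#' Geometric temperature ladder
#'
#' \eqn{T_k = T_{min} (T_{max}/T_{min})^{k/(n-1)}}, endpoints exact.
#' Geometric spacing gives near-uniform neighbour acceptance for systems
#' whose heat capacity varies slowly with temperature.  Defaults: 28 rungs
#' from 180 K to 540 K.
#'
#' @param tmin,tmax Ladder endpoints, Kelvin.
#' @param n Number of rungs (>= 2).
#' @return Ascending numeric vector of temperatures.
#' @export
#' @examples
#' geometric_ladder(180, 540, 3)  # middle rung = 180 * sqrt(3)
geometric_ladder <- function(tmin = 180, tmax = 540, n = 28) {
  if (n < 2) stop("ladder needs at least 2 rungs")
  if (!(tmax > tmin && tmin > 0)) stop("need tmax > tmin > 0")
  tmin * (tmax / tmin)^((seq_len(n) - 1) / (n - 1))
}

#' Metropolis replica-exchange acceptance
#'
#' Swap between neighbour rungs is accepted with probability
#' \eqn{\min(1, \exp[(\beta_i - \beta_j)(E_i - E_j)])}, \eqn{\beta = 1/k_B T}.
#'
#' @param e_i,e_j Potential energies of the two replicas, kcal/mol.
#' @param t_i,t_j Their current temperatures, Kelvin.
#' @param u Uniform(0,1) draw deciding acceptance.
#' @return List with `prob` and logical `accept`.
#' @export
exchange_attempt <- function(e_i, e_j, t_i, t_j, u = runif(1)) {
  delta <- (1 / (.kB * t_i) - 1 / (.kB * t_j)) * (e_i - e_j)
  prob <- min(1, exp(delta))
  list(prob = prob, accept = u < prob)
}

#' Run temperature replica-exchange MD
#'
#' All replicas share one topology and force field (pair strengths are
#' temperature independent).  Dynamics advances `exchange_interval` steps
#' between swap sweeps; sweeps alternate even (1-2, 3-4, ...) and odd
#' (2-3, 4-5, ...) neighbour pairings.  On acceptance the two replicas
#' exchange temperatures and their velocities are rescaled by
#' \eqn{\sqrt{T_{new}/T_{old}}}.  Each replica draws dynamics noise from its
#' own RNG stream; swap decisions use a dedicated stream, so results do not
#' depend on the order replicas are advanced in.  One frame per replica is
#' recorded at the end of every sweep.
#'
#' @param topology A `kh_topology`.
#' @param nsweeps Number of exchange sweeps.
#' @param ladder Temperature ladder, Kelvin ([geometric_ladder()]).
#' @param exchange_interval Steps between swap attempts (default 100).
#' @param integrator Base [integrator_params()]; temperature/replica/seed
#'   fields are managed per replica.
#' @param forcefield [kh_forcefield()].
#' @param seed Master seed (dynamics streams and swap stream derive from it).
#' @param init_positions Optional starting coordinates shared by replicas.
#' @return A `kh_remd`: `ladder`; `frames` (n x 3 x nsweeps x nreplicas
#'   array); `frame_temp` (nsweeps x nreplicas matrix of the temperature each
#'   replica had when the frame was recorded); `energy` tibble; `swaps`
#'   tibble (sweep, rung pair, acceptance); `trace` (nsweeps x nreplicas rung
#'   indices); final `states`.
#' @export
run_remd <- function(topology, nsweeps, ladder = geometric_ladder(),
                     exchange_interval = 100,
                     integrator = integrator_params(),
                     forcefield = kh_forcefield(), seed = 1,
                     init_positions = NULL) {
  nrep <- length(ladder)
  if (nrep < 1) stop("replica exchange needs at least one rung")
  n <- nrow(topology$beads)
  sys <- .pack_system(topology, forcefield)   # shared potential, packed once
  states <- lapply(seq_len(nrep), function(r) {
    st <- init_state(topology, positions = init_positions,
                     temperature = ladder[r], seed = seed * 1000 + r)
    list(pos = st$pos, vel = st$vel, groups = unname(st$groups),
         step = as.double(st$step))
  })
  group_names <- names(topology$groups)
  temp_of <- ladder                 # temperature currently held by replica r
  energy_of <- numeric(nrep)
  frames <- array(NA_real_, c(n, 3, nsweeps, nrep))
  frame_temp <- matrix(NA_real_, nsweeps, nrep)
  trace <- matrix(NA_integer_, nsweeps, nrep)
  nrec_max <- nsweeps * max(1, nrep %/% 2)
  sw_sweep <- integer(nrec_max); sw_lo <- integer(nrec_max)
  sw_prob <- numeric(nrec_max); sw_acc <- logical(nrec_max)
  nrec <- 0
  elog <- matrix(NA_real_, nsweeps, nrep)
  set.seed(seed)                    # dedicated swap stream
  swap_u <- matrix(runif(nsweeps * nrep), nsweeps, nrep)

  for (s in seq_len(nsweeps)) {
    for (r in seq_len(nrep)) {
      it <- unclass(integrator)
      it$temperature <- temp_of[r]
      it$seed <- as.double(seed)
      it$replica <- as.double(r)
      out <- cpp_run(sys, states[[r]], it, as.integer(exchange_interval),
                     as.integer(exchange_interval))
      states[[r]] <- list(pos = out$pos, vel = out$vel, groups = out$groups,
                          step = out$step)
      frames[, , s, r] <- out$frames[, , 1]
      frame_temp[s, r] <- temp_of[r]
      energy_of[r] <- out$energy[nrow(out$energy), 6]
      elog[s, r] <- energy_of[r]
    }
    rung_of <- match(temp_of, ladder)
    first <- if (nrep < 2) integer(0) else
      if (s %% 2 == 1) seq(1, nrep - 1, by = 2) else
      if (nrep > 2) seq(2, nrep - 1, by = 2) else integer(0)
    for (klo in first) {
      i <- which(rung_of == klo); j <- which(rung_of == klo + 1)
      at <- exchange_attempt(energy_of[i], energy_of[j],
                             temp_of[i], temp_of[j], u = swap_u[s, klo])
      if (at$accept) {
        ti <- temp_of[i]; tj <- temp_of[j]
        states[[i]] <- .rescale_velocities(states[[i]], sqrt(tj / ti))
        states[[j]] <- .rescale_velocities(states[[j]], sqrt(ti / tj))
        temp_of[i] <- tj; temp_of[j] <- ti
      }
      nrec <- nrec + 1
      sw_sweep[nrec] <- s; sw_lo[nrec] <- klo
      sw_prob[nrec] <- at$prob; sw_acc[nrec] <- at$accept
    }
    trace[s, ] <- match(temp_of, ladder)
  }
  keep <- seq_len(nrec)
  structure(list(ladder = ladder, frames = frames, frame_temp = frame_temp,
                 trace = trace,
                 swaps = tibble::tibble(sweep = sw_sweep[keep],
                                        rung_lo = sw_lo[keep],
                                        rung_hi = sw_lo[keep] + 1L,
                                        prob = sw_prob[keep],
                                        accepted = sw_acc[keep]),
                 energy = tibble::tibble(
                   sweep = rep(seq_len(nsweeps), nrep),
                   replica = rep(seq_len(nrep), each = nsweeps),
                   temperature = as.vector(frame_temp),
                   total = as.vector(elog)),
                 states = lapply(states, function(st) {
                   names(st$groups) <- group_names
                   structure(st, class = "kh_state")
                 }),
                 exchange_interval = exchange_interval,
                 topology = topology),
            class = "kh_remd")
}

.rescale_velocities <- function(state, f) {
  state$vel <- state$vel * f
  state$groups <- lapply(state$groups, function(g) {
    if (!isTRUE(g$fixed)) { g$V <- g$V * f; g$omega <- g$omega * f }
    g
  })
  state
}

#' @export
print.kh_remd <- function(x, ...) {
  acc <- if (nrow(x$swaps)) mean(x$swaps$accepted) else NA
  cat("kh_remd:", length(x$ladder), "rungs (", min(x$ladder), "-",
      max(x$ladder), "K ) |", nrow(x$trace), "sweeps | mean acceptance",
      round(acc, 3), "\n")
  invisible(x)
}

#' Dwell-time distribution of a replica trace
#'
#' Lengths of consecutive runs of exchange attempts each replica spends at
#' one rung.  Dwell segments partition the trace: per replica the dwells sum
#' to the trace length.
#'
#' @param trace nsweeps x nreplicas integer matrix of rung indices (the
#'   `trace` field of a `kh_remd`), or a `kh_remd`.
#' @return Tibble with columns replica, rung, dwell.
#' @export
dwell_time_distribution <- function(trace) {
  if (inherits(trace, "kh_remd")) trace <- trace$trace
  trace <- as.matrix(trace)
  if (nrow(trace) == 0) stop("empty replica trace")
  out <- lapply(seq_len(ncol(trace)), function(r) {
    rl <- rle(trace[, r])
    tibble::tibble(replica = r, rung = rl$values, dwell = rl$lengths)
  })
  dplyr::bind_rows(out)
}
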