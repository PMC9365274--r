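# Exact stationary analysis of the binding subsystem (no Pol II, no
# residence limit) on small CRMs.  This is the brute-force oracle the
# stochastic engine is validated against: states are all 3^N occupancy
# configurations of the N functional elements, transitions mirror
# propensity_table() exactly (including cooperativity-modified off-rates).

#' Enumerate occupancy states of the functional elements
#'
#' States are base-3 encodings (element order = promoter order of the
#' *functional* elements): digit 0 empty, 1 monomer, 2 dimer.
#'
#' @param n_functional Number of functional elements.
#' @return Integer matrix, `3^n` rows, one column per functional element.
#' @keywords internal
enumerate_states <- function(n_functional) {
  n_states <- 3L^n_functional
  m <- matrix(0L, nrow = n_states, ncol = n_functional)
  idx <- 0:(n_states - 1)
  for (j in seq_len(n_functional)) {
    m[, j] <- (idx %/% 3L^(j - 1L)) %% 3L
  }
  m
}

#' Build the CME generator matrix of the binding subsystem
#'
#' Transition rates between all `3^N` occupancy configurations of the `N`
#' functional elements, taken verbatim from [propensity_table()] (with
#' Pol II recruitment excluded — it does not change occupancy — and the
#' residence limit inapplicable, as the chemical master equation cannot
#' carry molecule age).
#'
#' @param config A [crm_config()] with at most 8 functional elements.
#' @param dose WUS concentration (>= 0).
#' @return A list of class `crm_generator`: `states` (matrix from
#'   [enumerate_states()]), `labels` (e.g. `"M--D"` in functional-element
#'   order: `-` empty, `M` monomer, `D` dimer), `Q` (dense rate matrix
#'   with zero row sums), `elements` (names of the functional elements).
#' @examples
#' G <- build_generator(build_variant("970i"), dose = 1)
#' rowSums(G$Q)  # all zero
#' @export
build_generator <- function(config, dose) {
  stopifnot(inherits(config, "crm_config"))
  fun_idx <- which(config$elements$functional)
  n <- length(fun_idx)
  if (n > 8) {
    stop("state space 3^", n, " too large; at most 8 functional elements",
         call. = FALSE)
  }
  states <- enumerate_states(n)
  n_states <- nrow(states)
  Q <- matrix(0, n_states, n_states)
  # binding-only config: k_pol = 0 so propensity_table emits no pol channel
  cfg0 <- config
  cfg0$kinetics$k_pol <- 0
  full_occ <- rep(0L, nrow(config$elements))
  for (s in seq_len(n_states)) {
    full_occ[fun_idx] <- states[s, ]
    st <- cell_state(config, occupancy = full_occ)
    pt <- propensity_table(st, dose, cfg0)
    if (nrow(pt) == 0) next
    for (r in seq_len(nrow(pt))) {
      i_full <- match(pt$element[r], config$elements$name)
      j_fun <- match(i_full, fun_idx)
      delta <- switch(pt$event[r],
                      monomer_bind = +1L, dimer_bind = +1L,
                      monomer_unbind = -1L, dimer_unbind = -1L)
      target <- s + delta * 3L^(j_fun - 1L)
      Q[s, target] <- Q[s, target] + pt$propensity[r]
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  labels <- apply(states, 1, function(row) {
    paste(c("-", "M", "D")[row + 1L], collapse = "")
  })
  structure(
    list(states = states, labels = labels, Q = Q,
         elements = config$elements$name[fun_idx]),
    class = "crm_generator"
  )
}

#' Stationary distribution of a generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by a dense linear solve with the
#' normalisation constraint replacing one balance equation.  Degenerate
#' chains (e.g. dose 0, where only unbinding is possible) are handled by
#' restricting to the closed communicating class reachable in the
#' time-reversed chain; if the stationary law is not unique the function
#' stops with a report of the absorbing components.
#'
#' @param G A [build_generator()] result.
#' @return Tibble with columns `state` (label) and `probability`
#'   (non-negative, summing to 1, residual `||pi Q|| < 1e-10`).
#' @export
stationary_distribution <- function(G) {
  Q <- G$Q
  n <- nrow(Q)
  # drop states that can never be entered (no incoming rate); they carry
  # zero stationary mass (e.g. dimer states when kon_dimer = 0).  Removal
  # can expose further unreachable states, so iterate.
  keep <- rep(TRUE, n)
  repeat {
    Qk <- Q[keep, keep, drop = FALSE]
    incoming <- colSums(Qk) - diag(Qk)
    dead <- incoming <= 0 & seq_len(sum(keep)) != 1L # all-empty always kept
    if (!any(dead)) break
    keep[which(keep)[dead]] <- FALSE
  }
  Qr <- Q[keep, keep, drop = FALSE]
  diag(Qr) <- 0
  diag(Qr) <- -rowSums(Qr) # re-close rows on the retained subspace
  m <- nrow(Qr)
  A <- t(Qr)
  A[m, ] <- 1 # normalisation replaces one balance row
  b <- c(rep(0, m - 1), 1)
  pi_r <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(pi_r) || any(!is.finite(pi_r)) || any(pi_r < -1e-8)) {
    absorbing <- which(abs(diag(Q)) < 1e-14)
    stop("generator is reducible or degenerate; absorbing states: ",
         paste(G$labels[absorbing], collapse = ", "), call. = FALSE)
  }
  pi_hat <- numeric(n)
  pi_hat[keep] <- pmax(pi_r, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  residual <- max(abs(pi_hat %*% Q))
  if (residual > 1e-10) {
    stop("stationary solve residual ", format(residual), " exceeds 1e-10",
         call. = FALSE)
  }
  tibble::tibble(state = G$labels, probability = as.numeric(pi_hat))
}

#' Closed-form single-site stationary occupancy
#'
#' One cis-element in isolation is a birth-death chain
#' empty <-> monomer <-> dimer; detailed balance gives stationary weights
#' proportional to `(1, W/Kd_M, W^2 / (Kd_M * Kd_D))`.
#'
#' @param kd_m Monomer dissociation constant (> 0).
#' @param kd_d Dimer dissociation constant (> 0).
#' @param W WUS concentration (>= 0); vectorised.
#' @return Tibble with columns `W`, `p_empty`, `p_monomer`, `p_dimer`.
#' @examples
#' analytic_single_site(1, 1, W = 1)  # p_monomer = 1/3
#' @export
analytic_single_site <- function(kd_m, kd_d, W) {
  if (kd_m <= 0 || kd_d <= 0) stop("Kd values must be > 0", call. = FALSE)
  w0 <- rep(1, length(W))
  w1 <- W / kd_m
  w2 <- W^2 / (kd_m * kd_d)
  z <- w0 + w1 + w2
  tibble::tibble(W = W, p_empty = w0 / z, p_monomer = w1 / z,
                 p_dimer = w2 / z)
}

#' Discrete-time fine-grid oracle including the non-Markovian features
#'
#' A fixed-step Bernoulli-event simulation that the CME cannot replace:
#' it carries molecule age, so the residence-time limit and the Pol II
#' refractory gap are represented exactly as step-function constraints.
#' At each step of length `dt`, at most one event fires with probability
#' `a0 * dt` (requires `a0 * dt <= 0.01` for fidelity); it converges to
#' SSA statistics as `dt -> 0` and serves as the independent oracle for
#' trajectory-level features.  Pure R, deliberately simple and slow.
#'
#' @param config A [crm_config()].
#' @param dose WUS concentration.
#' @param dt Step size, seconds; must satisfy the stability bound.
#' @param t_end Simulated seconds.
#' @param seed Integer seed.
#' @param burnin Fraction of `t_end` discarded before accumulating.
#' @return A list: `initiation_rate` (initiations per second after
#'   burn-in), `mrna`, `fractions` (per-element tibble as in
#'   [occupancy_fractions()]), `initiation_times`.
#' @export
fine_grid_oracle <- function(config, dose, dt, t_end, seed, burnin = 0) {
  stopifnot(inherits(config, "crm_config"))
  el <- config$elements
  k <- config$kinetics
  n <- nrow(el)
  # stability bound: dt <= 0.01 / max total propensity (worst case: all
  # channels at their maxima, off-rates never cooperativity-inflated)
  max_a0 <- sum(ifelse(el$functional,
                       pmax(k$kon_monomer * dose * k$on_rate_boost^n,
                            koff_from_kd(el$kd_monomer, k$kon_monomer) +
                              k$kon_dimer * dose,
                            koff_from_kd(el$kd_dimer, k$kon_dimer)), 0)) +
    k$k_pol * n
  if (max_a0 > 0 && dt > 0.01 / max_a0) {
    stop("dt = ", dt, " too large; need dt <= ", format(0.01 / max_a0),
         call. = FALSE)
  }
  tau <- k$residence_limit
  withr::local_seed(as.integer(seed))
  occ <- rep(0L, n)
  bind_time <- rep(NA_real_, n)
  pol_count <- rep(0L, n)
  active <- rep(FALSE, n)
  pol_ready_at <- 0
  mrna <- 0L
  init_times <- numeric(0)
  burn_start <- burnin * t_end
  time_acc <- matrix(0, n, 4) # empty, monomer, dimer, active
  steps <- ceiling(t_end / dt)
  # inlined numeric propensities (same laws as propensity_table; the
  # tibble interface is far too slow for a fixed-step inner loop)
  koff_m <- koff_from_kd(el$kd_monomer, k$kon_monomer)
  koff_d <- koff_from_kd(el$kd_dimer, k$kon_dimer)
  d_ref <- reference_distance(config)
  co <- config$cooperativity
  eff_off <- function(i) {
    base <- if (occ[i] == 1L) koff_m[i] else koff_d[i]
    if (co$mode == "none") return(base)
    if (occ[i] == 1L) {
      c_fac <- co$c_monomer
      js <- which(if (co$monomer_neighbours == "any") occ > 0L else occ == 1L)
    } else {
      c_fac <- co$c_dimer
      js <- which(if (co$dimer_neighbours == "dimer") occ == 2L else occ > 0L)
    }
    js <- js[js != i]
    if (length(js) == 0) return(base)
    w <- if (co$mode == "equal") rep(1, length(js)) else {
      distance_weight(abs(el$position[js] - el$position[i]), d_ref)
    }
    base * prod(c_fac^w)
  }
  # per-element channels: col 1 = "on" (monomer- or dimer-bind),
  # col 2 = "off" (unbind/dissociate); last slot = Pol II
  prop <- numeric(2 * n + 1)
  event_of <- function(idx) {
    if (idx == 2 * n + 1) return(c(0L, 5L))
    i <- ((idx - 1L) %/% 2L) + 1L
    if (idx %% 2L == 1L) {
      c(i, if (occ[i] == 0L) 1L else 3L)   # monomer_bind / dimer_bind
    } else {
      c(i, if (occ[i] == 1L) 2L else 4L)   # monomer_unbind / dimer_unbind
    }
  }
  for (s in seq_len(steps)) {
    t <- (s - 1) * dt
    # time-based deactivation
    if (k$residence_mode == "time" && is.finite(tau)) {
      expired <- occ == 1L & active & (t - bind_time >= tau)
      active[expired] <- FALSE
    }
    if (t >= burn_start) {
      sel <- cbind(seq_len(n), occ + 1L)
      time_acc[sel] <- time_acc[sel] + dt
      act <- which(occ == 1L & active)
      time_acc[act, 4] <- time_acc[act, 4] + dt
    }
    for (i in seq_len(n)) {
      if (!el$functional[i]) {
        prop[2 * i - 1L] <- 0
        prop[2 * i] <- 0
      } else if (occ[i] == 0L) {
        boost <- 1
        if (k$on_rate_boost > 1 && co$mode != "none") {
          js <- which(occ > 0L)
          js <- js[js != i]
          if (length(js) > 0) {
            w <- if (co$mode == "equal") rep(1, length(js)) else {
              distance_weight(abs(el$position[js] - el$position[i]), d_ref)
            }
            boost <- k$on_rate_boost^sum(w)
          }
        }
        prop[2 * i - 1L] <- k$kon_monomer * dose * boost
        prop[2 * i] <- 0
      } else if (occ[i] == 1L) {
        prop[2 * i - 1L] <- k$kon_dimer * dose
        prop[2 * i] <- eff_off(i)
      } else {
        prop[2 * i - 1L] <- 0
        prop[2 * i] <- eff_off(i)
      }
    }
    n_act <- sum(occ == 1L & active)
    prop[2 * n + 1L] <- if (k$k_pol > 0 && n_act > 0 && t >= pol_ready_at) {
      k$k_pol * n_act
    } else 0
    a0 <- sum(prop)
    if (a0 <= 0) next
    if (stats::runif(1) >= a0 * dt) next
    idx <- sample.int(2L * n + 1L, 1, prob = prop)
    ei <- event_of(idx)
    i <- ei[1]
    ev <- c("monomer_bind", "monomer_unbind", "dimer_bind", "dimer_unbind",
            "pol_recruit")[ei[2]]
    if (ev == "monomer_bind") {
      occ[i] <- 1L; bind_time[i] <- t; active[i] <- TRUE; pol_count[i] <- 0L
    } else if (ev == "monomer_unbind") {
      occ[i] <- 0L; bind_time[i] <- NA_real_; active[i] <- FALSE
    } else if (ev == "dimer_bind") {
      occ[i] <- 2L
    } else if (ev == "dimer_unbind") {
      occ[i] <- 1L
      if (k$dimer_bind_time == "reset") {
        bind_time[i] <- t; pol_count[i] <- 0L; active[i] <- TRUE
      } else {
        active[i] <- if (k$residence_mode == "time") {
          !is.finite(tau) || (t - bind_time[i]) < tau
        } else pol_count[i] < k$residence_count
      }
    } else { # pol_recruit
      mrna <- mrna + 1L
      if (t >= burn_start) init_times <- c(init_times, t)
      pol_ready_at <- t + k$pol_gap
      if (k$residence_mode == "count") {
        cand <- which(occ == 1L & active)
        j <- cand[sample.int(length(cand), 1)]
        pol_count[j] <- pol_count[j] + 1L
        if (pol_count[j] >= k$residence_count) active[j] <- FALSE
      }
    }
  }
  window <- t_end - burn_start
  fractions <- tibble::tibble(
    element = el$name,
    frac_empty = time_acc[, 1] / window,
    frac_monomer = time_acc[, 2] / window,
    frac_dimer = time_acc[, 3] / window,
    frac_active = time_acc[, 4] / window
  )
  list(initiation_rate = length(init_times) / window, mrna = mrna,
       fractions = fractions, initiation_times = init_times)
}

#' Stationary occupancy fractions per element from the CME
#'
#' Marginalises the joint stationary distribution onto each functional
#' element; non-functional elements are reported as always empty.
#'
#' @param config A [crm_config()].
#' @param dose WUS concentration.
#' @return Tibble: `element`, `p_empty`, `p_monomer`, `p_dimer`.
#' @export
stationary_occupancy <- function(config, dose) {
  fun_idx <- which(config$elements$functional)
  if (dose == 0) {
    return(tibble::tibble(element = config$elements$name,
                          p_empty = 1, p_monomer = 0, p_dimer = 0))
  }
  G <- build_generator(config, dose)
  pi_hat <- stationary_distribution(G)$probability
  out <- purrr::map_dfr(seq_along(fun_idx), function(j) {
    tibble::tibble(
      element = G$elements[j],
      p_empty = sum(pi_hat[G$states[, j] == 0L]),
      p_monomer = sum(pi_hat[G$states[, j] == 1L]),
      p_dimer = sum(pi_hat[G$states[, j] == 2L])
    )
  })
  all_el <- tibble::tibble(element = config$elements$name)
  dplyr::left_join(all_el, out, by = "element") |>
    tidyr::replace_na(list(p_empty = 1, p_monomer = 0, p_dimer = 0))
}
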