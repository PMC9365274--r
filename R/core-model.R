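#' Describe one WUS-binding cis-element
#'
#' A cis-element is a TAAT-core binding site in the CLV3 cis-regulatory
#' module (CRM), characterised by its promoter coordinate and its
#' dissociation constants for the first (monomer) and second (dimer) WUS
#' molecule.  Loss-of-binding mutants are represented by `functional = FALSE`:
#' a non-functional element contributes no binding propensities at all.
#'
#' @param name Element label, conventionally its promoter coordinate
#'   (e.g. `"970"`).
#' @param position Promoter coordinate in bp (integer-valued).
#' @param kd_monomer Dissociation constant of the WUS monomer, in WUS
#'   arbitrary concentration units.  Must be positive.
#' @param kd_dimer Dissociation constant of the second WUS molecule joining
#'   a bound monomer, same units.  Defaults to `kd_monomer` (the model's
#'   convention when no independent dimer affinity is available).
#' @param functional Logical; `FALSE` marks a loss-of-binding mutation.
#' @return A one-row tibble with columns `name`, `position`, `kd_monomer`,
#'   `kd_dimer`, `functional`.
#' @examples
#' cis_element("970", 970, kd_monomer = 1)
#' @export
cis_element <- function(name, position, kd_monomer, kd_dimer = kd_monomer,
                        functional = TRUE) {
  if (!is.numeric(kd_monomer) || kd_monomer <= 0) {
    stop("`kd_monomer` must be > 0 (element ", name, ")", call. = FALSE)
  }
  if (!is.numeric(kd_dimer) || kd_dimer <= 0) {
    stop("`kd_dimer` must be > 0 (element ", name, ")", call. = FALSE)
  }
  tibble::tibble(
    name = as.character(name),
    position = as.numeric(position),
    kd_monomer = as.numeric(kd_monomer),
    kd_dimer = as.numeric(kd_dimer),
    functional = isTRUE(functional)
  )
}

#' Kinetic parameters of the single-cell model
#'
#' Association rates are per WUS-concentration-unit per second; binding
#' propensities are linear in the WUS concentration (`kon * [WUS]`).
#' Off-rates are derived from dissociation constants via [koff_from_kd()].
#'
#' @param kon_monomer Association rate of a WUS monomer to an empty element.
#' @param kon_dimer Association rate of a second WUS molecule to a bound
#'   monomer.
#' @param k_pol Pol II recruitment rate per transcriptionally active
#'   monomer, per second.
#' @param pol_gap Refractory time between successive transcription
#'   initiations, seconds.  Default 4 s, the delay implied by an 80-bp
#'   polymerase footprint clearing at 1.2 kb/min.
#' @param residence_limit Residence-time limit tau_res: the bound age
#'   (seconds) beyond which a WUS monomer remains bound but can no longer
#'   recruit Pol II.  `Inf` disables the limit.  Default 10 s, the value
#'   that equalises the intrinsic (single-element) variants.
#' @param residence_mode `"time"` (default) deactivates a monomer when its
#'   bound age reaches `residence_limit`; `"count"` instead deactivates it
#'   after `residence_count` successful Pol II recruitments.
#' @param residence_count Initiation count for `residence_mode = "count"`.
#' @param dimer_bind_time What the surviving monomer's age clock does when
#'   a dimer loses one molecule: `"inherit"` (default) keeps the original
#'   arrival time (oldest molecule stays), `"reset"` restarts the clock.
#' @param on_rate_boost Optional cooperativity on the *binding* side:
#'   monomer-bind propensities are multiplied by `on_rate_boost^w` per
#'   occupied neighbour (distance weight `w`).  Default 1 (off-rate-only
#'   cooperativity, the model default).
#' @return A list of class `crm_kinetics`.
#' @export
crm_kinetics <- function(kon_monomer = 0.15, kon_dimer = 0.15,
                         k_pol = 0.1, pol_gap = 4,
                         residence_limit = 10,
                         residence_mode = c("time", "count"),
                         residence_count = 1L,
                         dimer_bind_time = c("inherit", "reset"),
                         on_rate_boost = 1) {
  residence_mode <- match.arg(residence_mode)
  dimer_bind_time <- match.arg(dimer_bind_time)
  rates <- c(kon_monomer = kon_monomer, kon_dimer = kon_dimer, k_pol = k_pol)
  if (any(rates < 0)) {
    stop("association and Pol II rates must be >= 0", call. = FALSE)
  }
  if (pol_gap < 0) stop("`pol_gap` must be >= 0", call. = FALSE)
  if (!(residence_limit > 0)) {
    stop("`residence_limit` must be > 0 (use Inf to disable)", call. = FALSE)
  }
  if (on_rate_boost < 1) stop("`on_rate_boost` must be >= 1", call. = FALSE)
  structure(
    list(
      kon_monomer = kon_monomer, kon_dimer = kon_dimer,
      k_pol = k_pol, pol_gap = pol_gap,
      residence_limit = residence_limit,
      residence_mode = residence_mode,
      residence_count = as.integer(residence_count),
      dimer_bind_time = dimer_bind_time,
      on_rate_boost = on_rate_boost
    ),
    class = "crm_kinetics"
  )
}

#' Cooperativity model among cis-elements
#'
#' Cooperativity acts on the *off*-rate of a bound species: each occupied
#' neighbouring element contributes a multiplicative stabilisation factor
#' `c^w` with `c <= 1` and distance weight `w` from [distance_weight()].
#' Smaller factors mean stronger cooperativity (10x the cooperativity of
#' `c = 0.01` is `c = 0.001`).  Monomer cooperativity (activation side) and
#' dimer cooperativity (repression side) are independent channels.
#'
#' @param mode `"none"`, `"equal"` (distance-independent, weight 1 for all
#'   pairs) or `"distance"` (weight `min(1, d_ref/d)`).
#' @param c_monomer Monomer cooperativity factor in (0, 1].  Default 0.01.
#' @param c_dimer Dimer cooperativity factor in (0, 1].  Default 0.2.
#' @param reference_distance Gap (bp) at which the factor applies at full
#'   strength; `NULL` (default) uses the smallest inter-element gap of the
#'   CRM it is applied to.
#' @param monomer_neighbours Which occupied neighbours stabilise a bound
#'   monomer: `"any"` (default; monomer or dimer) or `"monomer"`.
#' @param dimer_neighbours Which neighbours stabilise a bound dimer:
#'   `"dimer"` (default) or `"any"`.
#' @return A list of class `crm_cooperativity`.
#' @export
cooperativity <- function(mode = c("none", "equal", "distance"),
                          c_monomer = 0.01, c_dimer = 0.2,
                          reference_distance = NULL,
                          monomer_neighbours = c("any", "monomer"),
                          dimer_neighbours = c("dimer", "any")) {
  mode <- match.arg(mode)
  monomer_neighbours <- match.arg(monomer_neighbours)
  dimer_neighbours <- match.arg(dimer_neighbours)
  for (f in c(c_monomer, c_dimer)) {
    if (!(f > 0 && f <= 1)) {
      stop("cooperativity factors must lie in (0, 1]", call. = FALSE)
    }
  }
  if (!is.null(reference_distance) && reference_distance <= 0) {
    stop("`reference_distance` must be > 0", call. = FALSE)
  }
  structure(
    list(
      mode = mode, c_monomer = c_monomer, c_dimer = c_dimer,
      reference_distance = reference_distance,
      monomer_neighbours = monomer_neighbours,
      dimer_neighbours = dimer_neighbours
    ),
    class = "crm_cooperativity"
  )
}

#' Assemble a complete promoter genotype
#'
#' A `crm_config` is the full description of one promoter variant: its
#' ordered cis-elements, the kinetic parameters, and the cooperativity
#' model.  It is the unit every simulation and oracle function consumes.
#'
#' @param elements A tibble of cis-elements (rows from [cis_element()],
#'   `dplyr::bind_rows()`-ed), positions strictly increasing.
#' @param kinetics A [crm_kinetics()] object.
#' @param coop A [cooperativity()] object.
#' @param label Genotype name.
#' @return A list of class `crm_config`.
#' @examples
#' crm_config(cis_element("970", 970, 1), label = "970 only")
#' @export
crm_config <- function(elements, kinetics = crm_kinetics(),
                       coop = cooperativity(), label = "custom") {
  elements <- tibble::as_tibble(elements)
  needed <- c("name", "position", "kd_monomer", "kd_dimer", "functional")
  if (!all(needed %in% names(elements))) {
    stop("`elements` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(elements$name)) {
    stop("element names must be unique", call. = FALSE)
  }
  if (is.unsorted(elements$position, strictly = TRUE)) {
    stop("element positions must be strictly increasing", call. = FALSE)
  }
  if (any(elements$kd_monomer <= 0) || any(elements$kd_dimer <= 0)) {
    stop("dissociation constants must be > 0", call. = FALSE)
  }
  if (!any(elements$functional)) {
    stop("at least one functional element is required", call. = FALSE)
  }
  stopifnot(inherits(kinetics, "crm_kinetics"),
            inherits(coop, "crm_cooperativity"))
  # Resolve the distance kernel's reference gap once, from the geometry the
  # config is built with; spacing mutations later must not silently rescale
  # the kernel (they pass the resolved value through).
  if (is.null(coop$reference_distance) && nrow(elements) >= 2) {
    coop$reference_distance <- min(diff(elements$position))
  }
  structure(
    list(elements = elements, kinetics = kinetics, cooperativity = coop,
         label = label),
    class = "crm_config"
  )
}

#' @export
print.crm_config <- function(x, ...) {
  cat("<crm_config> ", x$label, "\n", sep = "")
  cat(sprintf("  %d elements (%d functional): %s\n",
              nrow(x$elements), sum(x$elements$functional),
              paste(ifelse(x$elements$functional, x$elements$name,
                           paste0("(", x$elements$name, ")")),
                    collapse = " ")))
  k <- x$kinetics
  cat(sprintf(
    "  kon_M=%g kon_D=%g k_pol=%g pol_gap=%gs residence_limit=%gs (%s)\n",
    k$kon_monomer, k$kon_dimer, k$k_pol, k$pol_gap, k$residence_limit,
    k$residence_mode))
  co <- x$cooperativity
  cat(sprintf("  cooperativity: %s (c_mono=%g, c_dimer=%g)\n",
              co$mode, co$c_monomer, co$c_dimer))
  invisible(x)
}

#' Resolve the reference distance of a config's cooperativity kernel
#'
#' `NULL` resolves to the smallest inter-element gap among all elements
#' (functional or not — geometry is a property of the sequence).
#' @param config A [crm_config()].
#' @return Reference distance in bp.
#' @keywords internal
reference_distance <- function(config) {
  d_ref <- config$cooperativity$reference_distance
  if (!is.null(d_ref)) return(d_ref)
  pos <- config$elements$position
  if (length(pos) < 2) return(1)
  min(diff(pos))
}

#' Off-rate from a dissociation constant
#'
#' The unbinding propensity of a bound WUS species is `koff = Kd * kon`,
#' so that the stationary ratio bound/unbound equals `[WUS]/Kd`.
#'
#' @param kd Dissociation constant (> 0).
#' @param kon Association rate (>= 0), per concentration unit per second.
#' @return Off-rate in 1/s.
#' @examples
#' koff_from_kd(2.5, 0.4)  # 1
#' @export
koff_from_kd <- function(kd, kon) {
  if (any(kd <= 0)) stop("`kd` must be > 0", call. = FALSE)
  if (any(kon < 0)) stop("`kon` must be >= 0", call. = FALSE)
  kd * kon
}

#' Distance weight of the cooperativity kernel
#'
#' Cooperativity between two elements applies at full strength up to the
#' reference gap and decays inversely beyond it:
#' `w(d) = min(1, d_ref / d)`.  A cooperativity factor `c` then enters the
#' off-rate as `c^w`, so far-apart pairs interact weakly (`w -> 0`,
#' `c^w -> 1`).
#'
#' @param d Gap between the two elements, bp (> 0).
#' @param d_ref Reference gap, bp (> 0).
#' @return Weight in (0, 1], non-increasing in `d`.
#' @examples
#' distance_weight(20, 10)  # 0.5
#' @export
distance_weight <- function(d, d_ref) {
  if (any(d <= 0)) stop("element gap `d` must be > 0", call. = FALSE)
  if (any(d_ref <= 0)) stop("`d_ref` must be > 0", call. = FALSE)
  pmin(1, d_ref / d)
}

# Occupancy codes shared with the C++ engine.
OCC_EMPTY <- 0L
OCC_MONOMER <- 1L
OCC_DIMER <- 2L

#' Create an instantaneous cell state
#'
#' @param config A [crm_config()]; determines the number of elements.
#' @param occupancy Integer vector, one entry per element: 0 empty,
#'   1 monomer, 2 dimer.
#' @param bind_time Arrival time of the current monomer per element
#'   (`NA` where empty).
#' @param active Logical per element; a monomer that can still recruit
#'   Pol II.  Defaults to `occupancy == 1`.
#' @param pol_ready_at Earliest time the next initiation is allowed.
#' @param t Current time.
#' @param mrna Cumulative initiation count.
#' @return A list of class `cell_state`.
#' @export
cell_state <- function(config, occupancy = NULL, bind_time = NULL,
                       active = NULL, pol_ready_at = 0, t = 0, mrna = 0L) {
  n <- nrow(config$elements)
  if (is.null(occupancy)) occupancy <- rep(OCC_EMPTY, n)
  occupancy <- as.integer(occupancy)
  stopifnot(length(occupancy) == n, all(occupancy %in% 0:2))
  if (is.null(bind_time)) bind_time <- ifelse(occupancy > 0, t, NA_real_)
  if (is.null(active)) active <- occupancy == OCC_MONOMER
  structure(
    list(occupancy = occupancy, bind_time = as.numeric(bind_time),
         active = as.logical(active), pol_ready_at = pol_ready_at,
         t = t, mrna = as.integer(mrna)),
    class = "cell_state"
  )
}

#' Cooperativity-modified off-rate of the species bound at one element
#'
#' The base off-rate (`Kd * kon` for the occupied species) is multiplied by
#' `c^w(d_ij)` for every qualifying occupied neighbour `j`: a bound
#' *monomer* is stabilised by any occupied neighbour with the monomer
#' factor; a bound *dimer* is stabilised only by dimer-occupied neighbours
#' with the dimer factor (both neighbour rules configurable via
#' [cooperativity()]).  Non-functional neighbours never contribute (they
#' are never occupied).
#'
#' @param state A [cell_state()].
#' @param i Element index (promoter order).
#' @param config A [crm_config()].
#' @return Off-rate in 1/s for the species currently bound at element `i`.
#' @export
effective_off_rate <- function(state, i, config) {
  occ <- state$occupancy
  if (occ[i] == OCC_EMPTY) {
    stop("element ", config$elements$name[i], " is unoccupied", call. = FALSE)
  }
  el <- config$elements
  k <- config$kinetics
  co <- config$cooperativity
  base <- if (occ[i] == OCC_MONOMER) {
    koff_from_kd(el$kd_monomer[i], k$kon_monomer)
  } else {
    koff_from_kd(el$kd_dimer[i], k$kon_dimer)
  }
  if (co$mode == "none") return(base)
  if (occ[i] == OCC_MONOMER) {
    c_fac <- co$c_monomer
    qualifies <- if (co$monomer_neighbours == "any") occ > 0 else occ == OCC_MONOMER
  } else {
    c_fac <- co$c_dimer
    qualifies <- if (co$dimer_neighbours == "dimer") occ == OCC_DIMER else occ > 0
  }
  js <- setdiff(which(qualifies), i)
  if (length(js) == 0) return(base)
  w <- if (co$mode == "equal") {
    rep(1, length(js))
  } else {
    distance_weight(abs(el$position[js] - el$position[i]),
                    reference_distance(config))
  }
  base * prod(c_fac^w)
}

# On-rate boost factor for monomer binding at empty element i (>= 1).
on_rate_factor <- function(state, i, config) {
  boost <- config$kinetics$on_rate_boost
  if (boost == 1) return(1)
  co <- config$cooperativity
  if (co$mode == "none") return(1)
  occ <- state$occupancy
  js <- setdiff(which(occ > 0), i)
  if (length(js) == 0) return(1)
  el <- config$elements
  w <- if (co$mode == "equal") rep(1, length(js)) else {
    distance_weight(abs(el$position[js] - el$position[i]),
                    reference_distance(config))
  }
  boost^sum(w)
}

#' Enumerate all enabled stochastic events and their propensities
#'
#' One row per enabled reaction channel of the single-cell model:
#' monomer binding (`kon_M * [WUS]`, empty functional elements), monomer
#' unbinding ([effective_off_rate()]), dimer formation (`kon_D * [WUS]`,
#' monomer-occupied elements), dimer dissociation, and — when the
#' refractory clock allows (`t >= pol_ready_at`) — Pol II recruitment at
#' `k_pol` times the number of active monomers.  A total propensity of 0
#' is a valid quiescent state, not an error.
#'
#' @param state A [cell_state()].
#' @param dose WUS concentration (arbitrary units, >= 0).
#' @param config A [crm_config()].
#' @return Tibble with columns `event` (one of `monomer_bind`,
#'   `monomer_unbind`, `dimer_bind`, `dimer_unbind`, `pol_recruit`),
#'   `element` (name, `NA` for `pol_recruit`) and `propensity`.
#' @export
propensity_table <- function(state, dose, config) {
  if (dose < 0) stop("`dose` must be >= 0", call. = FALSE)
  el <- config$elements
  k <- config$kinetics
  occ <- state$occupancy
  rows <- list()
  for (i in seq_len(nrow(el))) {
    if (!el$functional[i]) next
    if (occ[i] == OCC_EMPTY) {
      rows[[length(rows) + 1L]] <- list(
        event = "monomer_bind", element = el$name[i],
        propensity = k$kon_monomer * dose * on_rate_factor(state, i, config))
    } else if (occ[i] == OCC_MONOMER) {
      rows[[length(rows) + 1L]] <- list(
        event = "monomer_unbind", element = el$name[i],
        propensity = effective_off_rate(state, i, config))
      rows[[length(rows) + 1L]] <- list(
        event = "dimer_bind", element = el$name[i],
        propensity = k$kon_dimer * dose)
    } else {
      rows[[length(rows) + 1L]] <- list(
        event = "dimer_unbind", element = el$name[i],
        propensity = effective_off_rate(state, i, config))
    }
  }
  n_active <- sum(state$active & occ == OCC_MONOMER)
  if (k$k_pol > 0 && state$t >= state$pol_ready_at && n_active > 0) {
    rows[[length(rows) + 1L]] <- list(
      event = "pol_recruit", element = NA_character_,
      propensity = k$k_pol * n_active)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(event = character(), element = character(),
                          propensity = numeric()))
  }
  dplyr::bind_rows(rows)
}
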