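# Promoter-variant grammar.  The wild-type CRM is the five-element
# cluster 950, 970, 997, 1007, 1060 (element names double as bp
# coordinates, giving inter-element gaps 20, 27, 10, 53).  All variants
# are expressed in the mutant-1080 background, so element 1080 is absent
# from the model entirely.  Default dissociation constants are anchored
# to the measured affinity ratios: Kd(970) = 1 (arbitrary units),
# Kd(970M4) = 1/3 (three-fold tighter binding), Kd(1060) = 21.4 * Kd(970M4)
# (the highest/lowest intrinsic affinity ratio), and the three
# intermediate-affinity elements at Kd = 3; Kd_dimer = Kd_monomer per
# element.

wt_element_table <- function() {
  kd_970m4 <- 1 / 3
  dplyr::bind_rows(
    cis_element("950", 950, kd_monomer = 3),
    cis_element("970", 970, kd_monomer = 1),
    cis_element("997", 997, kd_monomer = 3),
    cis_element("1007", 1007, kd_monomer = 3),
    cis_element("1060", 1060, kd_monomer = 21.4 * kd_970m4)
  )
}

# catalogue: name -> list(loss = elements, affinity = list(element = factor),
# spacing = list(anchor =, factor =), description)
variant_catalogue <- function() {
  lower4 <- function(keep) setdiff(c("950", "970", "997", "1007", "1060"), keep)
  list(
    WT = list(description = "wild-type CRM, five functional elements"),
    `950M` = list(loss = "950",
                  description = "loss-of-binding mutation in 950"),
    `970M` = list(loss = "970",
                  description = "loss-of-binding mutation in 970"),
    `997M` = list(loss = "997",
                  description = "loss-of-binding mutation in 997"),
    `1007M` = list(loss = "1007",
                   description = "loss-of-binding mutation in 1007"),
    `1060M` = list(loss = "1060",
                   description = "loss-of-binding mutation in 1060"),
    DM = list(loss = c("970", "997"),
              description = "double mutant: 970M + 997M"),
    QM = list(loss = c("950", "970", "997", "1060"),
              description = "quadruple mutant: 950M + 970M + 997M + 1060M"),
    `950i` = list(loss = lower4("950"),
                  description = "950 intrinsic: only 950 functional"),
    `970i` = list(loss = lower4("970"),
                  description = "970 intrinsic: only 970 functional"),
    `997i` = list(loss = lower4("997"),
                  description = "997 intrinsic: only 997 functional"),
    `1007i` = list(loss = lower4("1007"),
                   description = "1007 intrinsic: only 1007 functional"),
    `1060i` = list(loss = lower4("1060"),
                   description = "1060 intrinsic: only 1060 functional"),
    `970M4` = list(affinity = list(`970` = 3),
                   description = "affinity-raising mutation: 970 binds 3x tighter"),
    `970M4i` = list(affinity = list(`970` = 3), loss = lower4("970"),
                    description = "970M4 intrinsic: tightened 970, others lost"),
    `DS-997` = list(spacing = list(anchor = "997", factor = 2),
                    description = "duplicated intervening sequence flanking 997 (gaps 970-997 and 997-1007 doubled)")
  )
}

#' Catalogue of named promoter variants
#'
#' @return Tibble with columns `name`, `description`, `mutations`
#'   (a compact mutation-list string).
#' @examples
#' list_named_variants()
#' @export
list_named_variants <- function() {
  cat_ <- variant_catalogue()
  purrr::imap_dfr(cat_, function(v, nm) {
    muts <- c(
      if (!is.null(v$loss)) paste0("loss(", v$loss, ")"),
      if (!is.null(v$affinity)) {
        purrr::imap_chr(v$affinity, ~ paste0("affinity(", .y, ", x", .x, ")"))
      },
      if (!is.null(v$spacing)) {
        paste0("spacing(", v$spacing$anchor, ", x", v$spacing$factor, ")")
      }
    )
    tibble::tibble(name = nm, description = v$description,
                   mutations = paste(muts, collapse = " + "))
  })
}

#' Build a named promoter variant
#'
#' Constructs the full [crm_config()] of any promoter variant in the
#' catalogue (see [list_named_variants()]).  Loss mutations set
#' `functional = FALSE`; affinity mutations divide both dissociation
#' constants by the factor (tighter binding); spacing mutations rescale
#' the gaps flanking the anchor element without touching any Kd.
#'
#' @param name Variant name, e.g. `"WT"`, `"970i"`, `"970M4"`, `"DS-997"`.
#' @param kinetics,coop Optional kinetic/cooperativity overrides.  By
#'   default, multi-element variants run with distance-dependent
#'   cooperativity and no residence limit, while intrinsic (single
#'   functional element) variants run without cooperativity and with the
#'   10-s residence limit — the regimes the two halves of the analysis
#'   use.
#' @return A [crm_config()] labelled `name`.
#' @examples
#' build_variant("970i")
#' build_variant("DS-997")$elements
#' @export
build_variant <- function(name, kinetics = NULL, coop = NULL) {
  cat_ <- variant_catalogue()
  if (!name %in% names(cat_)) {
    stop("unknown variant \"", name, "\"; valid names: ",
         paste(names(cat_), collapse = ", "), call. = FALSE)
  }
  v <- cat_[[name]]
  el <- wt_element_table()
  if (!is.null(v$loss)) {
    el$functional[el$name %in% v$loss] <- FALSE
  }
  if (!is.null(v$affinity)) {
    for (nm in names(v$affinity)) {
      i <- match(nm, el$name)
      el$kd_monomer[i] <- el$kd_monomer[i] / v$affinity[[nm]]
      el$kd_dimer[i] <- el$kd_dimer[i] / v$affinity[[nm]]
    }
  }
  n_functional <- sum(el$functional)
  if (is.null(coop)) {
    coop <- if (n_functional >= 2) {
      cooperativity(mode = "distance")
    } else {
      cooperativity(mode = "none")
    }
  }
  if (is.null(kinetics)) {
    kinetics <- if (coop$mode == "none" && n_functional == 1) {
      crm_kinetics(residence_limit = 10)
    } else {
      crm_kinetics(residence_limit = Inf)
    }
  }
  cfg <- crm_config(el, kinetics = kinetics, coop = coop, label = name)
  if (!is.null(v$spacing)) {
    cfg <- apply_spacing_mutation(cfg, v$spacing$anchor, v$spacing$factor)
    cfg$label <- name
  }
  cfg
}

#' Rescale the gaps flanking one element
#'
#' Models spacing mutations that duplicate (or multiply) the intervening
#' sequence on both sides of an anchor element: the two flanking gaps are
#' scaled by `factor`, downstream positions shift consistently, element
#' order is preserved, and no dissociation constant changes.
#'
#' @param config A [crm_config()].
#' @param anchor Name of an interior element (not first or last).
#' @param factor Gap multiplier (>= 1; deletions are not modelled).
#' @return A new [crm_config()] with rewritten positions, labelled
#'   `"<label> spacing(<anchor> x<factor>)"` unless `factor == 1`.
#' @examples
#' apply_spacing_mutation(build_variant("WT"), "997", 2)$elements$position
#' @export
apply_spacing_mutation <- function(config, anchor, factor) {
  stopifnot(inherits(config, "crm_config"))
  if (factor < 1) {
    stop("`factor` must be >= 1 (deletions are not modelled)", call. = FALSE)
  }
  el <- config$elements
  i <- match(as.character(anchor), el$name)
  if (is.na(i)) stop("unknown element \"", anchor, "\"", call. = FALSE)
  if (i == 1 || i == nrow(el)) {
    stop("anchor must be interior to the CRM", call. = FALSE)
  }
  gaps <- diff(el$position)
  gaps[i - 1] <- gaps[i - 1] * factor # gap upstream of anchor
  gaps[i] <- gaps[i] * factor         # gap downstream of anchor
  el$position <- el$position[1] + c(0, cumsum(gaps))
  label <- if (factor == 1) config$label else {
    paste0(config$label, " spacing(", anchor, " x", factor, ")")
  }
  crm_config(el, kinetics = config$kinetics, coop = config$cooperativity,
             label = label)
}
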