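# YAML config documents: a complete, standalone description of a promoter
# genotype plus optional gradient and run settings.  Unknown keys are a
# hard error so typos never silently fall back to defaults.

config_schema <- list(
  top = c("label", "elements", "kinetics", "cooperativity", "gradient",
          "run", "seed"),
  element = c("name", "position", "kd_monomer", "kd_dimer", "functional"),
  kinetics = c("kon_monomer", "kon_dimer", "k_pol", "pol_gap",
               "residence_limit", "residence_mode", "residence_count",
               "dimer_bind_time", "on_rate_boost"),
  cooperativity = c("mode", "c_monomer", "c_dimer", "reference_distance",
                    "monomer_neighbours", "dimer_neighbours"),
  run = c("t_end", "replicates", "burnin", "doses")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop("unknown key", if (length(extra) > 1) "s", " in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
}

#' Read a CRM configuration document
#'
#' Parses and validates a YAML config (see [default_config()] for the
#' schema), resolving all defaults.  Validation failures name the
#' offending field; unknown keys are a hard error.  A missing
#' `cooperativity` block defaults to `mode: none` with a notice.
#'
#' @param path Path to a YAML file.
#' @return A list: `config` (a [crm_config()]), `gradient` (numeric or
#'   `NULL`), `run` (run settings or `NULL`), `seed` (or `NULL`).
#' @export
read_crm_config <- function(path) {
  doc <- yaml::read_yaml(path)
  check_keys(doc, config_schema$top, "config")
  if (is.null(doc$elements) || length(doc$elements) == 0) {
    stop("config must define `elements`", call. = FALSE)
  }
  el_rows <- purrr::imap(doc$elements, function(e, i) {
    check_keys(e, config_schema$element, paste0("elements[", i, "]"))
    for (f in c("name", "position", "kd_monomer")) {
      if (is.null(e[[f]])) {
        stop("elements[", i, "]: missing required field `", f, "`",
             call. = FALSE)
      }
    }
    if (e$kd_monomer <= 0) {
      stop("elements[", i, "].kd_monomer must be > 0, got ", e$kd_monomer,
           call. = FALSE)
    }
    if (!is.null(e$kd_dimer) && e$kd_dimer <= 0) {
      stop("elements[", i, "].kd_dimer must be > 0, got ", e$kd_dimer,
           call. = FALSE)
    }
    cis_element(e$name, e$position, e$kd_monomer,
                kd_dimer = e$kd_dimer %||% e$kd_monomer,
                functional = e$functional %||% TRUE)
  })
  kin_args <- doc$kinetics %||% list()
  check_keys(kin_args, config_schema$kinetics, "kinetics")
  if (!is.null(kin_args$residence_limit) &&
      identical(kin_args$residence_limit, "Inf")) {
    kin_args$residence_limit <- Inf
  }
  kinetics <- do.call(crm_kinetics, kin_args)
  if (is.null(doc$cooperativity)) {
    message("config has no `cooperativity` block; defaulting to mode: none")
    coop <- cooperativity(mode = "none")
  } else {
    check_keys(doc$cooperativity, config_schema$cooperativity, "cooperativity")
    coop <- do.call(cooperativity, doc$cooperativity)
  }
  if (!is.null(doc$run)) check_keys(doc$run, config_schema$run, "run")
  config <- crm_config(dplyr::bind_rows(el_rows), kinetics = kinetics,
                       coop = coop, label = doc$label %||% "unnamed")
  list(config = config,
       gradient = if (!is.null(doc$gradient)) as.numeric(doc$gradient),
       run = doc$run, seed = doc$seed)
}

#' Write a configuration document
#'
#' Emits a complete YAML document (all defaults resolved) that
#' [read_crm_config()] parses back losslessly.
#'
#' @param config A [crm_config()].
#' @param path Output path.
#' @param gradient,run,seed Optional extra blocks.
#' @return `path`, invisibly.
#' @export
write_crm_config <- function(config, path, gradient = NULL, run = NULL,
                             seed = NULL) {
  stopifnot(inherits(config, "crm_config"))
  kin <- unclass(config$kinetics)
  if (is.infinite(kin$residence_limit)) kin$residence_limit <- "Inf"
  coop <- unclass(config$cooperativity)
  coop <- coop[!vapply(coop, is.null, logical(1))]
  doc <- list(
    label = config$label,
    elements = purrr::pmap(config$elements, function(name, position,
                                                     kd_monomer, kd_dimer,
                                                     functional) {
      list(name = name, position = position, kd_monomer = kd_monomer,
           kd_dimer = kd_dimer, functional = functional)
    }),
    kinetics = kin,
    cooperativity = coop
  )
  if (!is.null(gradient)) doc$gradient <- as.numeric(gradient)
  if (!is.null(run)) doc$run <- run
  if (!is.null(seed)) doc$seed <- seed
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Default wild-type configuration document
#'
#' Writes (or returns) the fully resolved default configuration — the
#' wild-type five-element CRM with distance-dependent cooperativity and
#' the default gradient — for bit-exact reproducibility of the defaults.
#'
#' @param path Optional output path; if `NULL` the document is returned
#'   as a list.
#' @return The config list (invisibly if written to `path`).
#' @export
default_config <- function(path = NULL) {
  cfg <- build_variant("WT")
  if (is.null(path)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    write_crm_config(cfg, tmp, gradient = as.numeric(synth_gradient()),
                     seed = 1)
    return(yaml::read_yaml(tmp))
  }
  write_crm_config(cfg, path, gradient = as.numeric(synth_gradient()),
                   seed = 1)
  invisible(path)
}

#' Stable content hash of a configuration
#'
#' Changes iff the configuration content (elements, kinetics,
#' cooperativity, label) changes.
#'
#' @param config A [crm_config()].
#' @return A character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "crm_config"))
  digest::digest(list(elements = as.list(config$elements),
                      kinetics = unclass(config$kinetics),
                      cooperativity = unclass(config$cooperativity),
                      label = config$label), algo = "sha1")
}

#' Write a tabular result with a metadata sidecar
#'
#' CSV output keeps stable column order and full float precision; JSON
#' output nests the table under `$data`.  Both get a metadata block
#' (package version, seed and config hash when the result carries them)
#' — as a `.meta.json` sidecar for CSV, inline under `$meta` for JSON.
#'
#' @param result A data frame (any of the package's tibble results).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  meta <- list(
    package = "crmswitch",
    version = as.character(utils::packageVersion("crmswitch")),
    seed = attr(result, "seed"),
    config_hash = if (!is.null(attr(result, "config"))) {
      config_hash(attr(result, "config"))
    }
  )
  meta <- meta[!vapply(meta, is.null, logical(1))]
  df <- as.data.frame(result)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(list(meta = meta, data = df), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
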