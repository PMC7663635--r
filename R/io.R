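#' Read a model parameter file (YAML or JSON)
#'
#' Reads a configuration file with top-level keys `costs`, `utilities`,
#' `schedules`, `cohort`, `config` (all optional) and returns a fully
#' validated [model_params()]. Missing fields are filled from the bundled
#' canonical fixture ([paper_fixture()]), so an empty file yields the fixture
#' itself. Every cost component is a `{base, low, high}` mapping.
#'
#' @param config_path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated [model_params()].
#' @export
load_params <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("load_params: file not found: ", config_path)
  }
  raw <- if (grepl("\\.json$", config_path, ignore.case = TRUE)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config_path)
  }
  if (is.null(raw)) raw <- list()
  params_from_list(raw)
}

#' Build model parameters from a plain list, fixture-filling missing fields
#'
#' @param raw a list as produced by parsing a params YAML/JSON file.
#' @return a validated [model_params()].
#' @keywords internal
params_from_list <- function(raw) {
  def <- paper_fixture()

  costs <- def$costs
  for (nm in names(raw$costs)) {
    if (!nm %in% names(costs)) {
      stop("load_params: unknown cost component '", nm, "'")
    }
    trip <- raw$costs[[nm]]
    if (is.list(trip)) trip <- unlist(trip)
    if (is.null(names(trip))) names(trip) <- c("base", "low", "high")[seq_along(trip)]
    cur <- costs[[nm]]
    cur[names(trip)] <- trip
    costs[[nm]] <- cur
  }
  costs <- do.call(cost_inputs, costs)

  u <- def$utilities
  util_fields <- c("utility_survivor", "discount_rate", "median_age",
                   "life_expectancy")
  for (nm in names(raw$utilities)) {
    if (!nm %in% util_fields) {
      stop("load_params: unknown utility field '", nm, "'")
    }
    u[[nm]] <- raw$utilities[[nm]]
  }
  utilities <- utility_inputs(u$utility_survivor, u$discount_rate,
                              u$median_age, u$life_expectancy)

  co <- raw$cohort
  cycle_hours <- co$cycle_hours %||% def$cycle_hours
  schedules <- def$schedules
  if (!is.null(raw$schedules)) {
    schedules <- lapply(raw$schedules, function(a) {
      list(
        rescue = rescue_schedule(
          a$arm_label, a$improvement %||% 0, a$time_points_h,
          a$cumulative_rescued
        ),
        survival = survival_schedule(
          a$time_points_h, a$rescued_survival, a$trapped_survival
        )
      )
    })
    names(schedules) <- vapply(raw$schedules, function(a) a$arm_label, "")
  }

  cfg <- def$config
  if (!is.null(raw$config)) {
    known <- names(formals(model_config))
    bad <- setdiff(names(raw$config), known)
    if (length(bad)) stop("load_params: unknown config switch: ",
                          paste(bad, collapse = ", "))
    args <- utils::modifyList(unclass(cfg), raw$config)
    cfg <- do.call(model_config, args)
  }

  model_params(
    costs = costs, utilities = utilities, schedules = schedules,
    cycle_hours = cycle_hours,
    cohort_size = co$cohort_size %||% def$cohort_size,
    distance_to_hospital_miles =
      co$distance_to_hospital_miles %||% def$distance_to_hospital_miles,
    seats_per_vehicle = co$seats_per_vehicle %||% def$seats_per_vehicle,
    config = cfg
  )
}

#' Write model parameters to YAML
#'
#' Inverse of [load_params()]: `load_params(write_params(p, f))` returns a
#' parameter set equal to `p` field by field.
#'
#' @param params a [model_params()] object.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  out <- list(
    costs = lapply(params$costs, as.list),
    utilities = params$utilities[c("utility_survivor", "discount_rate",
                                   "median_age", "life_expectancy")],
    cohort = list(
      cycle_hours = params$cycle_hours,
      cohort_size = params$cohort_size,
      distance_to_hospital_miles = params$distance_to_hospital_miles,
      seats_per_vehicle = params$seats_per_vehicle
    ),
    schedules = unname(lapply(params$schedules, function(a) {
      list(
        arm_label = a$rescue$arm_label,
        improvement = a$rescue$improvement,
        time_points_h = a$rescue$time_points_h,
        cumulative_rescued = a$rescue$cumulative_rescued,
        rescued_survival = a$survival$rescued_survival,
        trapped_survival = a$survival$trapped_survival
      )
    })),
    config = unclass(params$config)
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Export arm schedules as tidy CSV
#'
#' Columns: `time_h, cumulative_rescued, rescued_survival, trapped_survival,
#' arm`, one row per arm and time point.
#'
#' @param params a [model_params()] object.
#' @param path output CSV path; if `NULL`, the data frame is returned only.
#' @return the tidy data frame, invisibly when written.
#' @export
schedules_to_csv <- function(params, path = NULL) {
  rows <- lapply(params$schedules, function(a) {
    data.frame(
      time_h = a$rescue$time_points_h,
      cumulative_rescued = a$rescue$cumulative_rescued,
      rescued_survival = a$survival$rescued_survival,
      trapped_survival = a$survival$trapped_survival,
      arm = a$rescue$arm_label
    )
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
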