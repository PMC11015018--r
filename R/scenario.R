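# Scenario runner: ties the stages (water window -> f_oc -> f_pt ->
# Drake / COPT; tectonic and speciation independent; population feeding
# f_oc) into reproducible, file-driven runs.  Every reported quantity
# carries both its raw value and a display value rounded under the named
# convention, because the published headline numbers mix significant-
# figure and decimal conventions.

#' Round a value for display under a named convention
#'
#' Round-half-away-from-zero under one of: `sig1`/`sig2` (1 or 2
#' significant figures), `dec1`/`dec2` (1 or 2 decimals), `int`
#' (nearest integer).  Science code keeps full precision; this utility
#' exists only to reproduce headline display values.
#'
#' @param value Numeric value(s).
#' @param convention One of `"sig1"`, `"sig2"`, `"dec1"`, `"dec2"`,
#'   `"int"`.
#' @return Rounded value(s).
#' @examples
#' round_display(0.010526, "sig2")   # 0.011
#' round_display(91.67, "int")       # 92
#' round_display(0.165, "dec2")      # 0.17
#' @export
round_display <- function(value,
                          convention = c("sig2", "sig1", "dec1", "dec2",
                                         "int")) {
  convention <- match.arg(convention)
  half_away <- function(x, d) {
    # small relative nudge so binary representations of exact halves
    # (e.g. 0.165) round away from zero as intended
    sign(x) * floor(abs(x) * 10^d + 0.5 + 1e-9) / 10^d
  }
  unname(vapply(value, function(x) {
    if (!is.finite(x)) return(x)
    if (x == 0) return(0)
    switch(convention,
           int = half_away(x, 0),
           dec1 = half_away(x, 1),
           dec2 = half_away(x, 2),
           sig1 = half_away(x, -floor(log10(abs(x)))),
           sig2 = half_away(x, 1 - floor(log10(abs(x)))))
  }, numeric(1)))
}

row_df <- function(quantity, raw, convention, bound = FALSE) {
  data.frame(quantity = quantity, raw = raw,
             display = round_display(raw, convention),
             convention = convention, bound = bound,
             stringsAsFactors = FALSE)
}

STAGES <- c("water", "foc", "fpt", "drake", "copt", "tectonic",
            "speciation", "population")

# ---- stage handlers -------------------------------------------------------

stage_water <- function(cfg, state) {
  radii <- cfg$radii %||% c(0.5, 1, 2.35)
  mode <- cfg$freeboard_mode %||% "conservative"
  rows <- lapply(radii, function(r) {
    win <- permitted_window(r, mode)
    if (isTRUE(all.equal(r, 0.5)))
      message("window for R = 0.5: computed 0.014-0.054% from exact 1/R ",
              "scaling (per-bound 2 s.f. rounding would print 0.015-0.055%)")
    rbind(row_df(sprintf("fmin_pct_R%g", r), win$fmin, "sig2"),
          row_df(sprintf("fmax_pct_R%g", r), win$fmax, "sig2"),
          row_df(sprintf("oceans_min_R%g", r), win$oceans_min,
                 if (win$oceans_min >= 1.5) "int" else "dec1"),
          row_df(sprintf("oceans_max_R%g", r), win$oceans_max,
                 if (win$oceans_max >= 1.5) "int" else "dec1"),
          row_df(sprintf("width_pct_R%g", r), window_width(win), "sig1"))
  })
  list(rows = do.call(rbind, rows), state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_foc <- function(cfg, state) {
  method <- cfg$method %||% "ratio"
  mode <- cfg$freeboard_mode %||% "conservative"
  if (method == "ratio") {
    r_small <- cfg$radius_small %||% 0.5
    r_large <- cfg$radius_large %||% 2.35
    vv <- unlist(cfg$variability) %||% c(3.8, 55)
    v <- variability_range(vv[1], vv[2])
    # narrowest window on the largest planet, widest on the smallest;
    # the downstream ratio uses 1-s.f. display widths, mirroring the
    # published arithmetic chain (raw widths reported alongside)
    w_narrow_raw <- window_width(permitted_window(r_large, mode))
    w_wide_raw <- window_width(permitted_window(r_small, mode))
    w_narrow <- round_display(w_narrow_raw, "sig1")
    w_wide <- round_display(w_wide_raw, "sig1")
    b <- foc_ratio_bounds(w_narrow, w_wide, v)
    state$foc <- round_display(b, "sig2")
    rows <- rbind(row_df("width_low_pct", w_narrow_raw, "sig1"),
                  row_df("width_high_pct", w_wide_raw, "sig1"),
                  row_df("foc_low", b[["low"]], "sig2"),
                  row_df("foc_high", b[["high"]], "sig2"))
  } else if (method == "population") {
    if (is.null(state$population))
      stop("foc method 'population' requires the population stage first",
           call. = FALSE)
    est <- foc_from_population(state$population, mode)
    state$foc <- rep(est$estimate, 2)
    rows <- rbind(row_df("foc_estimate", est$estimate, "sig2"),
                  row_df("foc_se", est$se, "sig2"))
  } else stop("unknown foc method: ", method, call. = FALSE)
  list(rows = rows, state = state)
}

stage_fpt <- function(cfg, state) {
  fpt <- fpt_estimate(cfg$stellar_fraction %||% 0.33,
                      cfg$large_enough_fraction %||% 0.5,
                      unlist(cfg$extra_factors) %||% numeric())
  state$fpt <- round_display(as.numeric(fpt), "dec2")
  list(rows = row_df("fpt_upper", as.numeric(fpt), "dec2", bound = TRUE),
       state = state)
}

stage_drake <- function(cfg, state, mode = "acc") {
  dmode <- cfg$mode %||% if (mode == "copt") "copt" else "acc_scaled"
  rows <- NULL
  if (dmode == "acc_scaled") {
    foc <- state$foc %||% c(0.00016, 0.011)
    fpt <- state$fpt %||% 0.17
    fi <- fi_product(foc, fpt)
    fi_disp <- round_display(fi, "sig1")
    base <- c(cfg$base_low %||% 200, cfg$base_high %||% 5e7)
    acc <- scale_acc_range(base, fi_disp)
    rows <- rbind(row_df("fi_low", fi[[1]], "sig1", TRUE),
                  row_df("fi_high", fi[[2]], "sig1", TRUE),
                  row_df("acc_low", acc[["low"]], "sig1", TRUE),
                  row_df("acc_high", acc[["high"]], "sig1", TRUE))
  } else if (dmode %in% c("interval", "copt")) {
    params <- scenario_drake_params(cfg, state, dmode)
    res <- drake_interval(params)
    rows <- rbind(row_df("n_low", res$low, "sig2", res$bound),
                  row_df("n_high", res$high, "sig2", res$bound))
  } else stop("unknown drake mode: ", dmode, call. = FALSE)
  if (!is.null(cfg$monte_carlo)) {
    mc_cfg <- cfg$monte_carlo
    if (is.null(state$seed))
      stop("scenario field `seed` is required for monte_carlo evaluation",
           call. = FALSE)
    params <- scenario_drake_params(cfg, state,
                                    if (dmode == "copt") "copt"
                                    else "interval")
    mc <- drake_monte_carlo(params, mc_cfg$n_samples %||% 1e4L, state$seed)
    rows <- rbind(rows,
                  row_df("mc_mean", mc$mean, "sig2", mc$bound),
                  row_df("mc_median", mc$median, "sig2", mc$bound),
                  row_df("mc_q025", mc$q025, "sig2", mc$bound),
                  row_df("mc_q975", mc$q975, "sig2", mc$bound),
                  row_df("mc_p_ge_1", mc$p_ge_1, "dec2", mc$bound))
  }
  list(rows = rows, state = state)
}

scenario_drake_params <- function(cfg, state, dmode) {
  if (!is.null(cfg$scenario)) return(drake_scenario(cfg$scenario))
  term <- function(x, default) {
    v <- x %||% default
    drake_term(unlist(v))
  }
  drake_params(
    r_star = term(cfg$r_star, 1),
    f_p = term(cfg$f_p, c(0.2, 0.5)),
    n_e = term(cfg$n_e, c(1, 5)),
    f_l = term(cfg$f_l, 1),
    f_c = term(cfg$f_c, c(0.1, 0.2)),
    lifetime = term(cfg$lifetime,
                    if (dmode == "copt") 5e8 else c(1e3, 1e8)),
    f_oc = if (!is.null(cfg$f_oc)) drake_term(unlist(cfg$f_oc))
           else if (is.null(cfg$f_i)) drake_term(state$foc %||%
                                                   c(0.00016, 0.011)),
    f_pt = if (!is.null(cfg$f_pt)) drake_term(unlist(cfg$f_pt))
           else if (is.null(cfg$f_i)) drake_term(state$fpt %||% 0.17),
    f_i = if (!is.null(cfg$f_i)) drake_term(unlist(cfg$f_i)),
    mode = if (dmode == "copt") "copt" else "acc")
}

stage_tectonic <- function(cfg, state) {
  len <- cfg$target_length_km %||% 55000
  rng <- assembly_time_range(len, cfg$rate_low %||% 100,
                             cfg$rate_high %||% 600)
  rows <- rbind(row_df("assembly_min_myr", rng[["low"]], "int"),
                row_df("assembly_max_myr", rng[["high"]], "int"))
  for (br in cfg$brackets %||% list()) {
    d <- bracket_duration(event_bracket(br$first, br$last,
                                        br$label %||% ""))
    rows <- rbind(rows,
                  row_df(paste0("transition_", br$label, "_myr"), d, "int"))
  }
  list(rows = rows, state = state)
}

stage_speciation <- function(cfg, state) {
  params <- birth_death_params(cfg$lambda %||% 1, cfg$mu %||% 0,
                               cfg$horizon %||% 500)
  rows <- row_df("expected_chain_length", expected_chain_length(params),
                 "int")
  n_reps <- cfg$n_reps %||% 0
  if (n_reps > 0) {
    if (is.null(state$seed))
      stop("scenario field `seed` is required for speciation replicates",
           call. = FALSE)
    q <- chain_length_quantiles(params, n_reps, state$seed)
    rows <- rbind(rows,
                  row_df("chain_q05", q[[1]], "int"),
                  row_df("chain_median", q[[2]], "int"),
                  row_df("chain_q95", q[[3]], "int"))
  }
  list(rows = rows, state = state)
}

stage_population <- function(cfg, state) {
  if (is.null(state$seed))
    stop("scenario field `seed` is required for the population stage",
         call. = FALSE)
  comps <- if (is.null(cfg$components)) default_mixture()
  else lapply(cfg$components, function(c)
    mixture_component(c$weight, c$family, min = c$min, max = c$max,
                      at = c$at %||% 0))
  config <- population_config(cfg$n %||% 1e5,
                              cfg$radius_low %||% 0.5,
                              cfg$radius_high %||% 2.35,
                              comps, cfg$water_max %||% 56,
                              seed = state$seed)
  pop <- generate_population(config)
  state$population <- pop
  est <- foc_from_population(pop, cfg$freeboard_mode %||% "conservative")
  rows <- rbind(row_df("population_n", config$n, "int"),
                row_df("foc_population", est$estimate, "sig2"),
                row_df("foc_population_se", est$se, "sig2"),
                row_df("in_window_mass_analytic", in_window_mass(config),
                       "sig2"))
  list(rows = rows, state = state)
}

# ---- scenario driver ------------------------------------------------------

validate_scenario <- function(sc) {
  if (is.null(sc$name)) stop("scenario field `name` is missing",
                             call. = FALSE)
  stages <- unlist(sc$stages)
  if (!length(stages)) stop("scenario field `stages` is empty",
                            call. = FALSE)
  bad <- setdiff(stages, STAGES)
  if (length(bad))
    stop("scenario field `stages` names unknown stage(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  stochastic <- any(stages %in% c("population", "speciation")) ||
    (!is.null(sc$drake$monte_carlo)) || (!is.null(sc$copt$monte_carlo))
  if (stochastic && is.null(sc$seed))
    stop("scenario field `seed` is required when a stochastic stage is ",
         "selected", call. = FALSE)
  stages
}

#' Run a scenario
#'
#' Executes the selected stages in dependency order (water; population;
#' f_oc; f_pt; Drake/COPT; tectonic and speciation independently) and
#' returns — optionally writes — a report in which every display-rounded
#' value is accompanied by its raw value.
#'
#' @param scenario Path to a YAML scenario file (see
#'   [list_scenarios()]), or an equivalent named list.
#' @param seed Optional integer overriding the scenario's seed.
#' @param out_dir If given, the report is written there as
#'   `<name>.csv` and/or `<name>.json`.
#' @param format Output format(s) when `out_dir` is given.
#' @return Object of class `run_report`: list with `name`, `seed`,
#'   `package_version` and `table` (stage, quantity, raw, display,
#'   convention, bound).
#' @examples
#' run_scenario(scenario_path("tectonic"))
#' @export
run_scenario <- function(scenario, seed = NULL, out_dir = NULL,
                         format = c("csv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  sc <- if (is.character(scenario)) yaml::read_yaml(scenario) else scenario
  stages <- validate_scenario(sc)
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  state <- list(seed = sc$seed)
  order <- intersect(c("water", "population", "foc", "fpt", "drake",
                       "copt", "tectonic", "speciation"), stages)
  tabs <- list()
  for (st in order) {
    res <- switch(st,
                  water = stage_water(sc$water, state),
                  population = stage_population(sc$population, state),
                  foc = stage_foc(sc$foc, state),
                  fpt = stage_fpt(sc$fpt, state),
                  drake = stage_drake(sc$drake, state, "acc"),
                  copt = stage_drake(sc$copt, state, "copt"),
                  tectonic = stage_tectonic(sc$tectonic, state),
                  speciation = stage_speciation(sc$speciation, state))
    state <- res$state
    if (!is.null(res$rows)) {
      res$rows <- cbind(stage = st, res$rows)
      tabs[[st]] <- res$rows
    }
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  report <- structure(
    list(name = sc$name, seed = sc$seed,
         package_version = as.character(utils::packageVersion("copt")),
         table = tab),
    class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir, format)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Scenario '%s' (copt %s%s)\n", x$name, x$package_version,
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  tab <- x$table
  tab$raw <- formatC(tab$raw, digits = 6, format = "g")
  disp <- formatC(tab$display, digits = 8, format = "g")
  tab$display <- ifelse(tab$bound, paste0("< ", disp), disp)
  print(tab[c("stage", "quantity", "raw", "display")], row.names = FALSE)
  invisible(x)
}

write_report <- function(report, out_dir, format = c("csv", "json")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if ("csv" %in% format) {
    tab <- report$table
    tab$raw <- formatC(tab$raw, digits = 6, format = "g")
    tab$display <- formatC(tab$display, digits = 8, format = "g")
    path <- file.path(out_dir, paste0(report$name, ".csv"))
    utils::write.table(tab, path, sep = ",", row.names = FALSE,
                       quote = FALSE, eol = "\n")
  }
  if ("json" %in% format) {
    path <- file.path(out_dir, paste0(report$name, ".json"))
    jsonlite::write_json(
      list(name = report$name, seed = report$seed,
           package_version = report$package_version,
           results = report$table),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Bundled scenarios
#'
#' @return `list_scenarios()` returns the names of the YAML scenario
#'   files shipped with the package; `scenario_path(name)` the full path
#'   of one.
#' @param name Scenario name, without extension.
#' @examples
#' list_scenarios()
#' @export
list_scenarios <- function() {
  sub("\\.yaml$", "",
      list.files(system.file("scenarios", package = "copt"),
                 pattern = "\\.yaml$"))
}

#' @rdname list_scenarios
#' @export
scenario_path <- function(name) {
  path <- system.file("scenarios", paste0(name, ".yaml"), package = "copt")
  if (path == "")
    stop("no bundled scenario named '", name, "'; see list_scenarios()",
         call. = FALSE)
  path
}
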