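# Serialization (CSV with '#' metadata headers, JSON reports) and the
# command-line interface. Scalar reports are JSON; tabular artifacts are
# plain CSV. Numbers are serialized with 12 significant digits so that a
# write/read round trip is lossless at test tolerances.

#' Write / read a trial table as CSV with metadata header
#'
#' The metadata attribute (model, parameters, seed) is stored as
#' `# key=value` comment lines before the header row, so a written file is
#' self-describing and `read_trials_csv()` restores both data and metadata.
#'
#' @param trials A `trial_table` from [simulate_trials()].
#' @param path File path.
#' @return `write_trials_csv()` returns `path` invisibly;
#'   `read_trials_csv()` returns the `trial_table`.
#' @export
write_trials_csv <- function(trials, path) {
  meta <- attr(trials, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 12)), con)
  utils::write.csv(as.data.frame(trials), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^# ", "", ln), "=", fixed = TRUE)[[1]]
    val <- kv[2]
    num <- suppressWarnings(as.numeric(val))
    meta[[kv[1]]] <- if (is.na(num)) val else num
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE)
  df$correct <- as.logical(df$correct)
  attr(df, "meta") <- meta
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Write / read a confidence count table as CSV
#'
#' @param counts A [confidence_counts()] table.
#' @param path File path.
#' @export
write_counts_csv <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  confidence_counts(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an outcome curve as CSV
#'
#' Columns: `c2`, `value`, `response`, `context`.
#'
#' @param curve An [outcome_curve()] object.
#' @param path File path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(c2 = curve$grid, value = curve$values,
               response = curve$response, context = curve$context),
    path, row.names = FALSE)
  invisible(path)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12, null = "null")
  invisible(path)
}

# ---- CLI ------------------------------------------------------------------

cli_stop <- function(...) {
  stop(structure(class = c("metacrit_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

cli_parse_flags <- function(args) {
  flags <- list()
  for (a in args) {
    if (!startsWith(a, "--"))
      cli_stop("unrecognized argument: ", a)
    kv <- sub("^--", "", a)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq == -1) { flags[[kv]] <- TRUE; next }
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    num <- suppressWarnings(as.numeric(val))
    flags[[key]] <- if (is.na(num)) val else num
  }
  flags
}

cli_config <- function(flags) {
  cfg <- list()
  if (!is.null(flags$config)) {
    cfg <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
    flags$config <- NULL
  }
  utils::modifyList(cfg, flags)   # flags override the config file
}

cli_params <- function(cfg) {
  for (k in c("d_prime")) if (is.null(cfg[[k]]))
    cli_stop("missing required option --", k)
  sdt_params(d_prime = cfg$d_prime,
             c1 = if (is.null(cfg$c1)) 0 else cfg$c1,
             p_S2 = if (is.null(cfg$p_S2)) 0.5 else cfg$p_S2)
}

cli_pm <- function(cfg) {
  model <- if (!is.null(cfg$model)) cfg$model
           else if (!is.null(cfg$k) && cfg$k > 0) "loss"
           else if (!is.null(cfg$sigma2) && cfg$sigma2 > 0) "noise"
           else "standard"
  process_model(model, sigma2 = cfg$sigma2,
                k = if (is.null(cfg$k)) 0 else cfg$k)
}

cli_extras <- function(cfg, context) {
  switch(context,
    reward = {
      if (!is.null(cfg$Q2)) reward_matrix2(1, 0, cfg$Q2, 0)
      else if (!is.null(cfg$R_hit2))
        reward_matrix2(cfg$R_hit2, cfg$R_miss2, cfg$R_CR2, cfg$R_FA2)
      else cli_stop("reward context requires --Q2 or the four --R_*2 payoffs")
    },
    calibration = {
      if (is.null(cfg$p_correct_T))
        cli_stop("calibration context requires --p_correct_T")
      calibration_target(cfg$p_correct_T)
    },
    NULL)
}

cli_cmd_optimal <- function(cfg) {
  params <- cli_params(cfg)
  context <- cfg$context
  if (is.null(context))
    cli_stop("--context is required (accuracy, reward, calibration, hf)")
  extras <- cli_extras(cfg, context)
  opt <- switch(context,
    accuracy = c2_opt_accuracy(params),
    reward = c2_opt_reward(params, rm = extras),
    calibration = c2_opt_calibration(params, extras),
    hf = c2_opt_hf(params),
    cli_stop("unknown context: ", context))
  rep <- list(context = opt$context, d_prime = params$d_prime,
              c1 = params$c1, p_S2 = params$p_S2,
              c1_star = opt$c1_star,
              c2_S1_star = opt$c2_S1_star, c2_S2_star = opt$c2_S2_star,
              clipped_S1 = opt$clipped_S1, clipped_S2 = opt$clipped_S2)
  # the reward <-> calibration equivalence: restate the context strength as
  # both a reward quotient and a threshold-accuracy odds
  if (context == "reward") {
    Q2 <- reward_quotient(extras)
    rep$Q2 <- Q2
    rep$equivalent_O_T <- Q2
    rep$equivalent_p_correct_T <- Q2 / (1 + Q2)
  }
  if (context == "calibration") {
    rep$O_T <- extras$O_T
    rep$equivalent_Q2 <- extras$O_T
  }
  rep
}

cli_cmd_curve <- function(cfg) {
  params <- cli_params(cfg)
  context <- cfg$context
  if (is.null(context)) cli_stop("--context is required")
  extras <- cli_extras(cfg, context)
  pm <- cli_pm(cfg)
  response <- if (is.null(cfg$response)) "S2" else cfg$response
  step <- if (is.null(cfg$step)) 1e-3 else cfg$step
  grid <- c2_grid(params, response, step = step,
                  width = if (is.null(cfg$width)) 6 else cfg$width)
  engine <- if (is.null(cfg$engine)) "exact" else cfg$engine
  outcome_curve(context, params, extras, response, grid, pm,
                engine = engine,
                n = if (is.null(cfg$n)) 1e6 else cfg$n, seed = cfg$seed)
}

cli_cmd_simulate <- function(cfg) {
  params <- cli_params(cfg)
  pm <- cli_pm(cfg)
  if (is.null(cfg$c2_S1) || is.null(cfg$c2_S2))
    cli_stop("simulate requires --c2_S1 and --c2_S2")
  if (is.null(cfg$seed)) cli_stop("simulate requires --seed")
  crit <- type2_criteria(cfg$c2_S1, cfg$c2_S2)
  simulate_trials(pm, params, crit,
                  n = if (is.null(cfg$n)) 1e4 else cfg$n, seed = cfg$seed)
}

cli_cmd_fit_metad <- function(cfg) {
  if (is.null(cfg$counts) && is.null(cfg$trials))
    cli_stop("fit-metad requires --counts=<csv> or --trials=<csv>")
  counts <- if (!is.null(cfg$counts)) read_counts_csv(cfg$counts)
            else counts_from_trials(read_trials_csv(cfg$trials))
  fit <- fit_metad(counts)
  unclass(fit)
}

cli_cmd_sweep <- function(cfg) {
  params <- cli_params(cfg)
  vals <- as.numeric(strsplit(as.character(cfg$values), ",")[[1]])
  if (anyNA(vals)) cli_stop("--values must be a comma-separated numeric list")
  param <- if (is.null(cfg$parameter)) "sigma2" else cfg$parameter
  pm_list <- lapply(vals, function(v) {
    if (param == "sigma2") {
      if (v == 0) process_model("standard") else process_model("noise", sigma2 = v)
    } else if (param == "k") {
      s2 <- if (is.null(cfg$sigma2)) 0.1 else cfg$sigma2
      if (v == 0 && s2 == 0) process_model("standard")
      else process_model("loss", sigma2 = s2, k = v)
    } else cli_stop("--parameter must be sigma2 or k")
  })
  sweep_mratio(pm_list, params,
               n = if (is.null(cfg$n)) 1e5 else cfg$n,
               seed = cfg$seed,
               engine = if (is.null(cfg$engine)) "exact" else cfg$engine)
}

#' Command-line interface dispatcher
#'
#' Subcommands: `optimal` (closed-form optimal criteria, JSON report),
#' `curve` (outcome curve, CSV), `simulate` (trial table, CSV),
#' `fit-metad` (meta-d' fit from a counts or trials CSV, JSON),
#' `sweep` (M-ratio across a sigma2 or k grid, CSV). Options are
#' `--key=value` flags; a JSON config file (`--config=file.json`) supplies
#' defaults which flags override. `--out=path` writes the result; without it
#' the result is printed to standard output.
#'
#' @param args Character vector of command-line arguments (the subcommand
#'   followed by flags); defaults to the process arguments.
#' @return The computed object, invisibly. Validation errors signal
#'   condition class `metacrit_usage_error` (the wrapper script maps these
#'   to exit code 2, other failures to 3).
#' @export
metacrit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: metacrit <optimal|curve|simulate|fit-metad|sweep> [--key=value ...]",
    "  common: --d_prime= --c1= --p_S2= --config=file.json --out=path --seed=",
    sep = "\n")
  fail_usage <- function(msg)
    stop(structure(class = c("metacrit_usage_error", "error", "condition"),
                   list(message = paste0(msg, "\n", usage), call = NULL)))
  if (length(args) == 0) fail_usage("no subcommand given")
  cmd <- args[1]
  cfg <- tryCatch(cli_config(cli_parse_flags(args[-1])),
                  error = function(e) fail_usage(conditionMessage(e)))
  run <- switch(cmd,
    "optimal" = cli_cmd_optimal,
    "curve" = cli_cmd_curve,
    "simulate" = cli_cmd_simulate,
    "fit-metad" = cli_cmd_fit_metad,
    "sweep" = cli_cmd_sweep,
    fail_usage(paste0("unknown subcommand: ", cmd)))
  res <- run(cfg)   # validation raises metacrit_usage_error via the cli_*
                    # helpers; numerical failures propagate as plain errors
  out <- cfg$out
  if (inherits(res, "trial_table")) {
    if (is.null(out)) print(utils::head(as.data.frame(res)))
    else write_trials_csv(res, out)
  } else if (inherits(res, "outcome_curve")) {
    if (is.null(out)) print(res) else write_curve_csv(res, out)
  } else if (is.data.frame(res)) {
    if (is.null(out)) print(res)
    else utils::write.csv(res, out, row.names = FALSE)
  } else {
    if (is.null(out)) cat(jsonlite::toJSON(res, auto_unbox = TRUE,
                                           digits = 12, pretty = TRUE), "\n")
    else write_report_json(res, out)
  }
  invisible(res)
}
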