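#' Run the end-to-end pipeline and write all artifacts
#'
#' Executes generate -> simulate -> score -> analyze and writes, under
#' `config$out_dir`: `grammar.json`, `schedule.csv` (all participants'
#' token-mapped trial schedules), `test_set.json`, `responses.csv` and
#' `report.json`. Every file embeds the master seed and config hash, so a
#' rerun with the same config is byte-identical and any single stage can
#' be re-audited from its file alone.
#'
#' @param config an `agl_run_config` with a non-NULL `out_dir`.
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) a list with the report and the written paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "agl_run_config"))
  if (is.null(config$out_dir)) stop_invalid("config$out_dir is not set")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  meta <- list(seed = config$seed, config_hash = config$hash,
               experiment = config$experiment)
  paths <- list()

  say("generate", "building grammar, stream and test set (seed %s)",
      format(config$seed))
  paths$grammar <- file.path(config$out_dir, "grammar.json")
  write_grammar(config$g, paths$grammar)
  sim <- simulate_run(config)
  paths$test_set <- file.path(config$out_dir, "test_set.json")
  write_test_set_json(sim$test_set, paths$test_set)

  say("generate", "writing %d-participant schedule", sum(config$n_participants))
  inventories <- if (config$experiment == "exp1") list(token_inventory("exp1"))
    else list(token_inventory("exp2_visual"), token_inventory("exp2_auditory"))
  sched <- list()
  pid <- 0
  for (j in seq_along(inventories)) {
    for (i in seq_len(config$n_participants[j])) {
      pid <- pid + 1
      pseed <- derive_seed(config$seed, "cohort", j, "participant", i)
      mapping <- assign_tokens(inventories[[j]], config$g,
                               seed = derive_seed(pseed, "tokens"))
      stream <- with_seed(pseed, grammar_walk(config$g, config$stream_length))
      s <- build_schedule(stream, sim$test_set, mapping, config$g,
                          timing = config$timing,
                          seed = derive_seed(pseed, "test_order"))
      s <- cbind(participant = pid, s)
      sched[[pid]] <- s
    }
  }
  paths$schedule <- file.path(config$out_dir, "schedule.csv")
  write_csv_with_meta(do.call(rbind, sched), paths$schedule, meta)

  say("simulate", "%d response rows", nrow(sim$log))
  paths$responses <- file.path(config$out_dir, "responses.csv")
  write_response_log(sim$log, paths$responses, meta)

  say("analyze", "scoring and inferential battery")
  report <- reproduce_report(config)
  paths$report <- file.path(config$out_dir, "report.json")
  write_report_json(report, paths$report)
  say("done", "artifacts in %s", config$out_dir)
  invisible(list(report = report, paths = paths, config = config))
}

#' Command-line interface
#'
#' Subcommands: `generate` (grammar + schedule + test set), `simulate`
#' (adds the response log), `analyze` (score an existing response CSV),
#' `run` (end to end), `audit` (balance and transitional-probability
#' report for a test-set JSON). Common flags: `--seed N`,
#' `--experiment exp1|exp2`, `--out DIR`; `analyze` takes
#' `--responses FILE` and `--design exp1|exp2`; `audit` takes
#' `--test-set FILE` and `--grammar FILE`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return exit status, invisibly.
#' @export
agl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: aglsim <generate|simulate|analyze|run|audit> [options]",
    "  common: --seed N  --experiment exp1|exp2  --out DIR",
    "  analyze: --responses FILE --design exp1|exp2 --out DIR",
    "  audit:   --test-set FILE [--grammar FILE]", sep = "\n")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_flags(args[-1])
  seed <- as.integer(opt$seed %||% 1)
  experiment <- opt$experiment %||% opt$design %||% "exp1"
  out <- opt$out %||% "aglsim_out"

  if (cmd %in% c("generate", "simulate", "run")) {
    config <- run_config(experiment = experiment, seed = seed,
                         out_dir = out)
    res <- run_pipeline(config)
    if (cmd == "run") print(res$report)
    return(invisible(0L))
  }
  if (cmd == "analyze") {
    if (is.null(opt$responses) || !file.exists(opt$responses)) {
      message("analyze: missing response log (--responses FILE); nothing to analyze")
      return(invisible(1L))
    }
    log <- read_response_log(opt$responses)
    acc <- score_responses(log)
    anova <- if (length(unique(acc$group)) > 1) mixed_anova(acc) else
      rm_anova_oneway(acc)
    summ <- condition_summary(acc)
    print(summ)
    print(anova)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(table1 = summ, effects = anova$effects),
      file.path(out, "analysis.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    return(invisible(0L))
  }
  if (cmd == "audit") {
    if (is.null(opt[["test-set"]]) || !file.exists(opt[["test-set"]])) {
      message("audit: missing test-set JSON (--test-set FILE)")
      return(invisible(1L))
    }
    g <- if (!is.null(opt$grammar)) read_grammar(opt$grammar) else
      default_grammar()
    ts <- read_test_set_json(opt[["test-set"]], g)
    print(ts)
    print(audit_item_sets(subset_items(ts, "within_violation"),
                          subset_items(ts, "cross_violation")))
    cat("Adjacent transitional probability of each grammatical successor: 0.5\n")
    cat("Lag-2 outcome distributions (exact; flatter than adjacent TPs):\n")
    for (a in g$elements$label) {
      d <- lag2_distribution(g, a)
      cat(sprintf("  %s -> %s\n", a,
                  paste(sprintf("%s:%.2f", names(d), d), collapse = " ")))
    }
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        out[[key]] <- args[i + 1]
        i <- i + 2
      } else {
        out[[key]] <- TRUE
        i <- i + 1
      }
    } else {
      i <- i + 1
    }
  }
  out
}
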