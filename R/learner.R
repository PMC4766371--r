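#' Parameters of the synthetic transitional-probability learner
#'
#' The simulated participant accumulates weighted forward transition
#' counts during exposure and judges test items by their smoothed mean
#' log transitional probability. Two learning weights make within- and
#' cross-domain learning dissociable: `w_within` scales the count
#' increment for same-domain adjacent pairs, `w_cross` for cross-domain
#' pairs. Setting `w_cross = 0` yields an observer that has learned the
#' within-domain statistics but is blind to cross-domain dependencies --
#' the configuration that reproduces the behavioural signature of
#' above-chance within-domain and at-chance cross-domain violation
#' detection.
#'
#' @param w_within learning weight for same-domain transitions, in [0, 1].
#' @param w_cross learning weight for cross-domain transitions, in [0, 1].
#' @param alpha additive smoothing count (> 0) used when converting counts
#'   to transitional probabilities; default 0.5.
#' @param tau decision temperature (> 0): familiarity differences are
#'   divided by `tau` before the logistic endorsement rule, so small `tau`
#'   means near-deterministic judgments.
#' @param lapse probability in [0, 0.5] of replacing a judgment with a
#'   uniform random response.
#' @return an `agl_learner_params` list.
#' @seealso [learner_preset()], [simulate_cohort()]
#' @export
learner_params <- function(w_within = 0.9, w_cross = 0, alpha = 0.5,
                           tau = 1, lapse = 0.1) {
  if (w_within < 0 || w_within > 1) stop_invalid("w_within must be in [0,1]")
  if (w_cross < 0 || w_cross > 1) stop_invalid("w_cross must be in [0,1]")
  if (alpha <= 0) stop_invalid("alpha must be > 0")
  if (tau <= 0) stop_invalid("tau must be > 0")
  if (lapse < 0 || lapse > 0.5) stop_invalid("lapse must be in [0, 0.5]")
  structure(list(w_within = w_within, w_cross = w_cross, alpha = alpha,
                 tau = tau, lapse = lapse),
            class = "agl_learner_params")
}

#' Named learner presets
#'
#' Presets live in a package config file, not in code
#' (`inst/extdata/learner_presets.json`). `exp1`, `exp2_visual` and
#' `exp2_auditory` are calibration targets tuned so that simulated group
#' means fall within ten percentage points of the corresponding published
#' group means; `null` is a no-learning observer for calibration checks.
#'
#' @param name preset name.
#' @return an `agl_learner_params`.
#' @export
learner_preset <- function(name = c("exp1", "exp2_visual", "exp2_auditory",
                                    "null")) {
  name <- match.arg(name)
  path <- system.file("extdata", "learner_presets.json",
                      package = "aglsim", mustWork = TRUE)
  do.call(learner_params, jsonlite::read_json(path,
                                              simplifyVector = TRUE)[[name]])
}

#' Expose a learner to a stream, accumulating transition counts
#'
#' For every adjacent pair (a, b) of the stream the count c(a -> b) grows
#' by `w_within` if a and b share a domain, else by `w_cross`.
#'
#' @param params an `agl_learner_params`.
#' @param stream character vector of element labels.
#' @param g an `agl_grammar`.
#' @return an `agl_learner_state`: list with the 6 x 6 `counts` matrix.
#' @export
expose_learner <- function(params, stream, g) {
  labs <- g$elements$label
  counts <- matrix(0, length(labs), length(labs),
                   dimnames = list(labs, labs))
  if (length(stream) >= 2) {
    from <- stream[-length(stream)]
    to <- stream[-1]
    w <- ifelse(domain_relation(g, from, to) == "within",
                params$w_within, params$w_cross)
    for (i in seq_along(from)) {
      counts[from[i], to[i]] <- counts[from[i], to[i]] + w[i]
    }
  }
  structure(list(counts = counts), class = "agl_learner_state")
}

#' @export
print.agl_learner_state <- function(x, ...) {
  cat("Learner state: weighted transition counts\n")
  print(round(x$counts, 2))
  invisible(x)
}

#' Familiarity of a sequence: smoothed mean log transitional probability
#'
#' `mean over adjacent pairs of log[(c(a->b) + alpha) /
#' (sum_x c(a->x) + 6 alpha)]`. With an empty state this is `log(1/6)`
#' for any sequence; adding mass to a transition never decreases the
#' familiarity of sequences containing it.
#'
#' @param state an `agl_learner_state`.
#' @param seq character vector of element labels (length >= 2).
#' @param alpha additive smoothing count > 0.
#' @return a single numeric score.
#' @export
familiarity <- function(state, seq, alpha = 0.5) {
  if (alpha <= 0) stop_invalid("alpha must be > 0")
  if (length(seq) < 2) stop_invalid("sequence must have >= 2 elements")
  counts <- state$counts
  k <- ncol(counts)
  from <- seq[-length(seq)]
  to <- seq[-1]
  num <- counts[cbind(from, to)] + alpha
  den <- rowSums(counts)[from] + k * alpha
  mean(log(num / den))
}

#' One grammaticality judgment
#'
#' With probability `lapse` the response is a fair coin; otherwise the
#' item is endorsed with probability
#' `logistic((familiarity - criterion) / tau)`. Uses the current RNG
#' stream (seed management belongs to the cohort level).
#'
#' @param state an `agl_learner_state`.
#' @param item an `agl_test_item` or a character sequence.
#' @param criterion the decision criterion on the familiarity scale; by
#'   convention the participant's median familiarity over the full test
#'   set (see [simulate_cohort()]).
#' @param tau decision temperature > 0.
#' @param lapse lapse probability.
#' @param alpha smoothing count passed to [familiarity()].
#' @return logical: endorsed ("follows the rules") or not.
#' @export
judge <- function(state, item, criterion, tau, lapse = 0, alpha = 0.5) {
  if (tau <= 0) stop_invalid("tau must be > 0")
  seq <- if (inherits(item, "agl_test_item")) item$elements else item
  f <- familiarity(state, seq, alpha)
  p <- lapse * 0.5 + (1 - lapse) * stats::plogis((f - criterion) / tau)
  stats::runif(1) < p
}

#' Configuration of a simulated cohort
#'
#' @param n_participants number of simulated participants (>= 1).
#' @param params an `agl_learner_params` or a preset name.
#' @param g an `agl_grammar`; default [default_grammar()].
#' @param seed master seed; per-participant seeds are derived from it.
#' @param group optional between-subjects group label attached to every
#'   response row (e.g. `"visual"` / `"auditory"`).
#' @param stream_length learning-stream length, default 180.
#' @param n_items test-set sizes `c(grammatical, within, cross)`,
#'   default 20/10/10.
#' @param test_set optionally a pre-built `agl_test_set` shared with other
#'   cohorts; built from the cohort seed when NULL.
#' @return an `agl_cohort_config` list.
#' @export
cohort_config <- function(n_participants = 15, params = "exp1",
                          g = default_grammar(), seed = 1, group = NA,
                          stream_length = 180, n_items = c(20, 10, 10),
                          test_set = NULL) {
  if (n_participants < 1) stop_invalid("n_participants must be >= 1")
  if (is.character(params)) params <- learner_preset(params)
  stopifnot(inherits(params, "agl_learner_params"))
  structure(list(n_participants = n_participants, params = params, g = g,
                 seed = seed, group = group, stream_length = stream_length,
                 n_items = n_items, test_set = test_set),
            class = "agl_cohort_config")
}

#' Simulate a cohort of synthetic participants
#'
#' One test set is built per cohort (as in the modelled experiments, all
#' participants judge the same structural items). Each participant then
#' gets an independently derived seed, a fresh 180-element learning
#' stream, a fresh token mapping (recorded for the schedule stage; the
#' abstract learner is token-blind), exposure, and one judgment per test
#' item with the decision criterion placed at that participant's median
#' familiarity across the full test set.
#'
#' @param config an `agl_cohort_config`.
#' @return a `ResponseLog` data.frame with columns `participant`, `group`,
#'   `item_id`, `condition`, `endorse`, `correct`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "agl_cohort_config"))
  g <- config$g
  p <- config$params
  ts <- config$test_set
  if (is.null(ts)) {
    ref_stream <- generate_learning_stream(
      g, config$stream_length, seed = derive_seed(config$seed, "ref_stream"))
    ts <- build_test_set(g, config$n_items[1], config$n_items[2],
                         config$n_items[3],
                         seed = derive_seed(config$seed, "test_set"),
                         exclusion = ref_stream)
  }
  conditions <- set_conditions(ts)
  ids <- vapply(ts$items, function(it) it$id, "")
  logs <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    logs[[i]] <- with_seed(derive_seed(config$seed, "participant", i), {
      stream <- grammar_walk(g, config$stream_length)
      state <- expose_learner(p, stream, g)
      f <- vapply(ts$items,
                  function(it) familiarity(state, it$elements, p$alpha), 0)
      crit <- stats::median(f)
      pr <- p$lapse * 0.5 +
        (1 - p$lapse) * stats::plogis((f - crit) / p$tau)
      endorse <- stats::runif(length(pr)) < pr
      data.frame(
        participant = i, group = config$group, item_id = ids,
        condition = conditions, endorse = endorse,
        correct = ifelse(conditions == "grammatical", endorse, !endorse),
        stringsAsFactors = FALSE
      )
    })
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  attr(out, "seed") <- config$seed
  out
}

#' Read / write a response log as CSV
#'
#' @param log a response-log data.frame.
#' @param path file path.
#' @param meta optional named list written as `# key: value` header lines.
#' @return `read_response_log` returns the data.frame.
#' @export
write_response_log <- function(log, path, meta = NULL) {
  write_csv_with_meta(log, path, meta)
}

#' @rdname write_response_log
#' @export
read_response_log <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

write_csv_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (k in names(meta)) {
      writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
    }
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
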