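#' Generate a learning stream by random walk on the grammar
#'
#' Uniform random start element, then repeated 0.5/0.5 same/cross branch
#' choices. Every adjacent transition is grammatical; a fixed seed gives
#' an identical stream. The default length of 180 elements at 1000 ms
#' stimulus + 1000 ms ISI yields the standard 6-minute learning phase.
#'
#' @param g an `agl_grammar`.
#' @param length number of elements (>= 2), default 180.
#' @param seed integer seed (optional; NULL uses the current RNG stream).
#' @return character vector of element labels.
#' @export
generate_learning_stream <- function(g, length = 180, seed = NULL) {
  if (length < 2) stop_invalid("stream length must be >= 2, got %d", length)
  with_seed(seed, grammar_walk(g, length))
}

# one seeded walk; relies on caller for RNG state
grammar_walk <- function(g, length, branches = NULL) {
  labs <- g$elements$label
  if (is.null(branches)) {
    branches <- sample(c(1L, 2L), length - 1, replace = TRUE,
                       prob = g$branch_probability)
  }
  out <- character(length)
  out[1] <- labs[sample.int(length(labs), 1)]
  for (i in seq_len(length - 1)) {
    out[i + 1] <- g$successors[[out[i]]][branches[i]]
  }
  out
}

#' Label every adjacent transition of a sequence
#'
#' @param g an `agl_grammar`.
#' @param seq character vector of element labels, length >= 2.
#' @return data.frame with one row per adjacent pair: `from`, `to`,
#'   `relation` (within/cross) and `status` (grammatical/violation).
#' @export
#' @examples
#' g <- default_grammar()
#' classify_transitions(g, c("V1", "A2", "A1"))
classify_transitions <- function(g, seq) {
  if (length(seq) < 2) stop_invalid("sequence must have >= 2 elements")
  check_elements(g, seq)
  from <- seq[-length(seq)]
  to <- seq[-1]
  data.frame(
    from = from, to = to,
    relation = domain_relation(g, from, to),
    status = ifelse(is_grammatical_transition(g, from, to),
                    "grammatical", "violation"),
    stringsAsFactors = FALSE
  )
}

#' Count ungrammatical adjacent transitions in a sequence
#'
#' @inheritParams classify_transitions
#' @return integer count.
#' @export
count_violations <- function(g, seq) {
  sum(classify_transitions(g, seq)$status == "violation")
}

new_test_item <- function(g, elements, condition, id = NA_character_) {
  labels <- classify_transitions(g, elements)
  structure(
    list(id = id, elements = elements, condition = condition,
         transition_labels = labels,
         violation_count = sum(labels$status == "violation")),
    class = "agl_test_item"
  )
}

#' @export
print.agl_test_item <- function(x, ...) {
  cat(sprintf("[%s] %s (%s, %d violation%s)\n",
              x$id, paste(x$elements, collapse = "-"), x$condition,
              x$violation_count, if (x$violation_count == 1) "" else "s"))
  invisible(x)
}

#' Generate novel grammatical test items
#'
#' Grammatical length-6 walks, pairwise distinct, and -- when an exclusion
#' stream is supplied -- not equal to any contiguous 6-element window of
#' that stream ("novel" relative to the learning experience).
#'
#' @param g an `agl_grammar`.
#' @param n number of items, default 20.
#' @param length item length, default 6.
#' @param seed integer seed (optional).
#' @param exclusion optional character vector (a learning stream) whose
#'   contiguous windows the items must avoid.
#' @return list of `agl_test_item`, condition `"grammatical"`.
#' @export
generate_grammatical_items <- function(g, n = 20, length = 6, seed = NULL,
                                       exclusion = NULL) {
  if (n < 1) stop_invalid("n must be >= 1")
  excl <- character(0)
  if (!is.null(exclusion) && base::length(exclusion) >= length) {
    k <- base::length(exclusion) - length + 1
    excl <- vapply(seq_len(k), function(i) {
      paste(exclusion[i:(i + length - 1)], collapse = "-")
    }, "")
  }
  with_seed(seed, {
    items <- list()
    seen <- character(0)
    attempts <- 0
    max_attempts <- 200 * n
    while (base::length(items) < n && attempts < max_attempts) {
      attempts <- attempts + 1
      w <- grammar_walk(g, length)
      key <- paste(w, collapse = "-")
      if (key %in% seen || key %in% excl) next
      seen <- c(seen, key)
      items[[base::length(items) + 1]] <-
        new_test_item(g, w, "grammatical",
                      sprintf("G%02d", base::length(items) + 1))
    }
    if (base::length(items) < n) {
      stop_invalid(
        "could only generate %d of %d distinct novel items in %d attempts",
        base::length(items), n, max_attempts)
    }
    items
  })
}

#' Build violation test items by replacement with grammar renewal
#'
#' Each item starts as a seeded grammar walk. At every step whose sampled
#' successor matches the targeted relation (`mode = "within"`: a
#' same-domain step; `mode = "cross"`: an other-domain step) the
#' grammatical successor is replaced by an incorrect element of the same
#' target domain, after which the walk is "renewed": generation continues
#' grammatically from the emitted element. The result is an item in which
#' every targeted-relation transition violates the grammar and every other
#' transition is grammatical.
#'
#' Replacement choice: for a within-domain step the wrong element is the
#' one that is neither the grammatical successor nor an immediate repeat
#' of the predecessor (unique -- e.g. the within step A2->A3 becomes
#' A2->A1); for a cross-domain step both non-grammatical other-domain
#' elements are eligible and one is drawn at random. Walks whose sampled
#' branches contain no targeted-relation step (probability 2^-5 for
#' length 6) cannot carry a violation and are discarded and regenerated.
#'
#' @param g an `agl_grammar`.
#' @param n number of items, default 10.
#' @param length item length, default 6.
#' @param mode `"within"` or `"cross"`.
#' @param seed integer seed (optional).
#' @return list of `agl_test_item`, condition `"<mode>_violation"`.
#' @export
make_violation_items <- function(g, n = 10, length = 6,
                                 mode = c("within", "cross"), seed = NULL) {
  mode <- match.arg(mode)
  if (n < 1) stop_invalid("n must be >= 1")
  target_branch <- if (mode == "within") 1L else 2L
  labs <- g$elements$label
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        branches <- sample(c(1L, 2L), length - 1, replace = TRUE,
                           prob = g$branch_probability)
        if (any(branches == target_branch)) break
      }
      out <- character(length)
      out[1] <- labs[sample.int(base::length(labs), 1)]
      for (s in seq_len(length - 1)) {
        succ <- g$successors[[out[s]]][branches[s]]
        if (branches[s] == target_branch) {
          succ <- replace_element(g, out[s], succ, mode)
        }
        out[s + 1] <- succ
      }
      new_test_item(g, out, paste0(mode, "_violation"),
                    sprintf("%s%02d", toupper(substr(mode, 1, 1)), i))
    })
  })
}

# the incorrect stand-in for a grammatical successor `succ` after `prev`
replace_element <- function(g, prev, succ, mode) {
  pool <- g$elements$label[g$elements$domain == element_domain(g, succ)]
  if (mode == "within") {
    # unique: same domain, not the successor, no immediate repeat
    wrong <- setdiff(pool, c(succ, prev))
    stopifnot(length(wrong) == 1)
    wrong
  } else {
    # prev is in the other domain; two candidates, drawn at random
    wrong <- setdiff(pool, succ)
    wrong[sample.int(length(wrong), 1)]
  }
}

#' Build a complete 20/10/10 test set
#'
#' @param g an `agl_grammar`.
#' @param n_grammatical,n_within,n_cross set sizes (default 20/10/10).
#' @param length item length, default 6.
#' @param seed integer seed; child seeds are derived per subset.
#' @param exclusion optional learning stream for novelty checks on the
#'   grammatical items.
#' @return an `agl_test_set`: list with `items` (all items, grammatical
#'   first), `seed` and `counts`.
#' @export
build_test_set <- function(g, n_grammatical = 20, n_within = 10,
                           n_cross = 10, length = 6, seed = 1,
                           exclusion = NULL) {
  items <- c(
    generate_grammatical_items(g, n_grammatical, length,
                               seed = derive_seed(seed, "grammatical"),
                               exclusion = exclusion),
    make_violation_items(g, n_within, length, "within",
                         seed = derive_seed(seed, "within")),
    make_violation_items(g, n_cross, length, "cross",
                         seed = derive_seed(seed, "cross"))
  )
  structure(
    list(items = items, seed = seed,
         counts = c(grammatical = n_grammatical,
                    within_violation = n_within,
                    cross_violation = n_cross)),
    class = "agl_test_set"
  )
}

#' @export
print.agl_test_set <- function(x, ...) {
  cat(sprintf("Test set (seed %s): %d grammatical, %d within-violation, %d cross-violation\n",
              format(x$seed), x$counts[1], x$counts[2], x$counts[3]))
  invisible(x)
}

set_conditions <- function(ts) {
  vapply(ts$items, function(it) it$condition, "")
}

subset_items <- function(ts, condition) {
  ts$items[set_conditions(ts) == condition]
}

#' Audit the violation balance of two violation-item sets
#'
#' Reports the total and mean violations per sequence in each set and a
#' two-sample equal-variance Student's t test on the per-item violation
#' counts -- the standard check that the two ungrammatical sets are
#' matched in violation load.
#'
#' @param within_set,cross_set lists of `agl_test_item`, or bare numeric
#'   vectors of per-item violation counts.
#' @return an `agl_balance` list: `within_total`, `cross_total`,
#'   `within_mean_per_seq`, `cross_mean_per_seq`, `t_statistic`, `df`,
#'   `p_value`.
#' @export
audit_item_sets <- function(within_set, cross_set) {
  counts <- function(s) {
    if (is.numeric(s)) return(as.numeric(s))
    vapply(s, function(it) as.numeric(it$violation_count), 0)
  }
  w <- counts(within_set)
  x <- counts(cross_set)
  if (!length(w) || !length(x)) stop_invalid("item sets must be non-empty")
  tt <- if (stats::sd(c(w - mean(w), x - mean(x))) == 0) {
    # zero pooled variance: t is 0 for equal means, infinite otherwise
    list(statistic = if (mean(w) == mean(x)) 0 else Inf * sign(mean(w) - mean(x)),
         parameter = length(w) + length(x) - 2,
         p.value = if (mean(w) == mean(x)) 1 else 0)
  } else {
    stats::t.test(w, x, var.equal = TRUE)
  }
  structure(
    list(within_total = sum(w), cross_total = sum(x),
         within_mean_per_seq = mean(w), cross_mean_per_seq = mean(x),
         t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = unname(tt$p.value)),
    class = "agl_balance"
  )
}

#' @export
print.agl_balance <- function(x, ...) {
  cat(sprintf(
    "Violation balance: within %d total (%.2f/seq), cross %d total (%.2f/seq); t(%g) = %.3f, p = %.3f\n",
    x$within_total, x$within_mean_per_seq, x$cross_total,
    x$cross_mean_per_seq, x$df, x$t_statistic, x$p_value))
  invisible(x)
}

#' Token inventories for the standard experiment variants
#'
#' Tokens are abstract identifiers (no audio or image rendering): three
#' pure-tone IDs at 210/286/389 Hz and three shape IDs for the
#' audio-visual variant (`"exp1"`); three shape and three color IDs for
#' the within-vision category variant (`"exp2_visual"`); three tone and
#' three non-word IDs for the within-audition variant (`"exp2_auditory"`).
#'
#' @param variant one of `"exp1"`, `"exp2_visual"`, `"exp2_auditory"`.
#' @return named list: domain label -> character(3) token IDs.
#' @export
token_inventory <- function(variant = c("exp1", "exp2_visual",
                                        "exp2_auditory")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", "token_inventories.json",
                      package = "aglsim", mustWork = TRUE)
  inv <- jsonlite::read_json(path, simplifyVector = TRUE)[[variant]]
  lapply(inv, as.character)
}

#' Randomly map grammar elements to tokens for one participant
#'
#' Each participant gets an independent uniform random bijection between
#' the three elements of each domain and that domain's three tokens;
#' tokens never cross domain boundaries, so the structural sequences are
#' identical across participants while the surface stimuli differ.
#'
#' @param inventory named list: domain label -> character(3) tokens (see
#'   [token_inventory()]).
#' @param g an `agl_grammar`.
#' @param seed integer seed (optional).
#' @return named character vector: element label -> token ID.
#' @export
assign_tokens <- function(inventory, g, seed = NULL) {
  domains <- unique(g$elements$domain)
  if (!setequal(names(inventory), domains)) {
    stop_invalid("inventory domains {%s} do not match grammar domains {%s}",
                 paste(names(inventory), collapse = ","),
                 paste(domains, collapse = ","))
  }
  with_seed(seed, {
    out <- character(0)
    for (d in domains) {
      toks <- inventory[[d]]
      if (length(toks) != 3 || anyDuplicated(toks)) {
        stop_invalid("inventory for domain %s must hold 3 distinct tokens", d)
      }
      els <- g$elements$label[g$elements$domain == d]
      out[els] <- sample(toks)
    }
    out
  })
}

#' Build a timed, token-mapped stimulus schedule
#'
#' Learning trials follow the stream order; test items are shuffled under
#' the seed, then laid out item by item. Onsets accumulate
#' `duration + isi` continuously, so the learning phase spans
#' `length(stream) * (duration + isi)` ms (6 minutes at the defaults).
#'
#' @param stream character vector: learning stream.
#' @param test_set an `agl_test_set`.
#' @param mapping named character vector from [assign_tokens()].
#' @param g an `agl_grammar`.
#' @param timing list with `duration_ms` and `isi_ms` (default 1000/1000).
#' @param seed integer seed for the test-order shuffle.
#' @return data.frame with columns `phase`, `trial`, `item_id`, `element`,
#'   `domain`, `token`, `onset_ms`, `duration_ms`, `isi_ms`.
#' @export
build_schedule <- function(stream, test_set, mapping, g,
                           timing = list(duration_ms = 1000, isi_ms = 1000),
                           seed = NULL) {
  unmapped <- setdiff(g$elements$label, names(mapping))
  if (length(unmapped)) {
    stop_invalid("no token mapped for element(s): %s",
                 paste(unmapped, collapse = ", "))
  }
  order_idx <- with_seed(seed, sample(seq_along(test_set$items)))
  test_elements <- character(0)
  test_ids <- character(0)
  for (i in order_idx) {
    it <- test_set$items[[i]]
    test_elements <- c(test_elements, it$elements)
    test_ids <- c(test_ids, rep(it$id, length(it$elements)))
  }
  element <- c(stream, test_elements)
  phase <- c(rep("learning", length(stream)),
             rep("test", length(test_elements)))
  item_id <- c(rep("stream", length(stream)), test_ids)
  step <- timing$duration_ms + timing$isi_ms
  data.frame(
    phase = phase,
    trial = seq_along(element),
    item_id = item_id,
    element = element,
    domain = element_domain(g, element),
    token = unname(mapping[element]),
    onset_ms = (seq_along(element) - 1) * step,
    duration_ms = timing$duration_ms,
    isi_ms = timing$isi_ms,
    stringsAsFactors = FALSE
  )
}

#' Read / write a test set as JSON
#'
#' The file carries every item's elements, condition, per-transition
#' annotations and violation count plus the generating seed -- enough to
#' re-audit the set without regeneration. Round-trips exactly.
#'
#' @param ts an `agl_test_set`.
#' @param path file path.
#' @param g an `agl_grammar` (for reconstruction on read).
#' @return `read_test_set_json` returns an `agl_test_set`.
#' @export
write_test_set_json <- function(ts, path) {
  obj <- list(
    seed = ts$seed,
    counts = as.list(ts$counts),
    items = lapply(ts$items, function(it) {
      list(id = it$id, condition = it$condition,
           elements = it$elements,
           transitions = it$transition_labels,
           violation_count = it$violation_count)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_test_set_json
#' @export
read_test_set_json <- function(path, g) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- lapply(seq_len(nrow(obj$items)), function(i) {
    new_test_item(g, unlist(obj$items$elements[i]),
                  obj$items$condition[i], obj$items$id[i])
  })
  structure(
    list(items = items, seed = obj$seed, counts = unlist(obj$counts)),
    class = "agl_test_set"
  )
}
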