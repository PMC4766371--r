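#' Cross-domain artificial grammars
#'
#' An `agl_grammar` describes a finite-state grammar over six abstract
#' elements split across two domains (three elements each). Every element
#' has exactly two grammatical successors -- one in its own domain, one in
#' the other -- chosen with equal probability during generation. Domains
#' are abstract tags; an experiment binds them to sensory modalities
#' (auditory/visual) or to perceptual categories (shapes/colors,
#' tones/non-words) via token mappings, without touching the structure.
#'
#' @param elements a data.frame with columns `label`, `domain`, `index`.
#' @param successors named list mapping each element label to a character
#'   vector `c(same, cross)`: the same-domain successor first, then the
#'   cross-domain successor.
#' @param branch_probability numeric length 2, probabilities of the
#'   same-domain and cross-domain successor; default `c(0.5, 0.5)`.
#' @return an object of class `agl_grammar`.
#' @seealso [default_grammar()], [validate_grammar()]
#' @export
grammar_spec <- function(elements, successors,
                         branch_probability = c(0.5, 0.5)) {
  stopifnot(is.data.frame(elements),
            all(c("label", "domain", "index") %in% names(elements)))
  if (anyDuplicated(elements$label) > 0) {
    stop_invalid("duplicate element labels in grammar")
  }
  successors <- lapply(successors, as.character)
  if (!setequal(names(successors), elements$label)) {
    stop_invalid("successor map must have exactly one entry per element")
  }
  branch_probability <- as.numeric(branch_probability)
  if (length(branch_probability) == 1) {
    branch_probability <- rep(branch_probability, 2)
  }
  structure(
    list(elements = elements[, c("label", "domain", "index")],
         successors = successors[elements$label],
         branch_probability = stats::setNames(branch_probability,
                                              c("same", "cross"))),
    class = "agl_grammar"
  )
}

#' @export
print.agl_grammar <- function(x, ...) {
  cat(sprintf("Cross-domain artificial grammar: %d elements, domains {%s}\n",
              nrow(x$elements),
              paste(unique(x$elements$domain), collapse = ", ")))
  for (lab in x$elements$label) {
    cat(sprintf("  %s -> {%s (same, p=%.2g), %s (cross, p=%.2g)}\n",
                lab, x$successors[[lab]][1], x$branch_probability[1],
                x$successors[[lab]][2], x$branch_probability[2]))
  }
  invisible(x)
}

#' The default six-element cross-domain grammar
#'
#' Builds the grammar in which, writing the two domains as `A` and `V`
#' with indices 1..3 (mod-3 arithmetic, 3 + 1 wraps to 1):
#' `V_i -> {V_(i+1), A_(i+1)}` and `A_i -> {A_(i+1), V_i}`, each successor
#' at probability 0.5. Under this wiring the walk V1-A2-A3-V3-A1-V1 is
#' fully grammatical, each element occurs with stationary frequency 1/6,
#' and each element has exactly three distinct lag-2 (non-adjacent)
#' continuations.
#'
#' @param domains character length 2: labels of the two domains. The first
#'   plays the `A` role above, the second the `V` role.
#' @return an `agl_grammar`.
#' @export
#' @examples
#' g <- default_grammar()
#' successors(g, "V1")
default_grammar <- function(domains = c("A", "V")) {
  stopifnot(length(domains) == 2, !anyDuplicated(domains))
  dA <- domains[1]; dV <- domains[2]
  idx <- 1:3
  nxt <- function(i) i %% 3 + 1
  elements <- data.frame(
    label = c(paste0(dA, idx), paste0(dV, idx)),
    domain = rep(c(dA, dV), each = 3),
    index = c(idx, idx),
    stringsAsFactors = FALSE
  )
  successors <- stats::setNames(vector("list", 6), elements$label)
  for (i in idx) {
    successors[[paste0(dV, i)]] <- c(paste0(dV, nxt(i)), paste0(dA, nxt(i)))
    successors[[paste0(dA, i)]] <- c(paste0(dA, nxt(i)), paste0(dV, i))
  }
  grammar_spec(elements, successors)
}

#' @rdname grammar_spec
#' @param g an `agl_grammar`.
#' @param a an element label.
#' @export
successors <- function(g, a) {
  check_elements(g, a)
  g$successors[[a]]
}

check_elements <- function(g, ...) {
  labs <- unlist(list(...))
  bad <- setdiff(labs, g$elements$label)
  if (length(bad)) {
    stop_invalid("unknown element(s): %s", paste(bad, collapse = ", "))
  }
  invisible(labs)
}

element_domain <- function(g, a) {
  g$elements$domain[match(a, g$elements$label)]
}

#' Domain relation of an adjacent pair
#'
#' @param g an `agl_grammar`.
#' @param a,b element labels.
#' @return `"within"` if `a` and `b` share a domain, else `"cross"`.
#' @export
domain_relation <- function(g, a, b) {
  check_elements(g, a, b)
  ifelse(element_domain(g, a) == element_domain(g, b), "within", "cross")
}

#' Is a -> b a grammatical transition?
#'
#' @inheritParams domain_relation
#' @return logical.
#' @export
#' @examples
#' g <- default_grammar()
#' is_grammatical_transition(g, "A1", "V1") # TRUE
#' is_grammatical_transition(g, "A2", "A1") # FALSE
is_grammatical_transition <- function(g, a, b) {
  check_elements(g, a, b)
  mapply(function(x, y) y %in% g$successors[[x]], a, b, USE.NAMES = FALSE)
}

#' Forward transitional probability of a -> b
#'
#' @inheritParams domain_relation
#' @return the branch probability of the matching successor, 0 if the
#'   transition is ungrammatical.
#' @export
transition_probability <- function(g, a, b) {
  check_elements(g, a, b)
  mapply(function(x, y) {
    hit <- match(y, g$successors[[x]])
    if (is.na(hit)) 0 else unname(g$branch_probability[hit])
  }, a, b, USE.NAMES = FALSE)
}

#' Row-stochastic transition matrix of a grammar
#'
#' @param g an `agl_grammar`.
#' @return a 6 x 6 matrix with element labels as dimnames.
#' @export
transition_matrix <- function(g) {
  labs <- g$elements$label
  P <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (a in labs) {
    P[a, g$successors[[a]][1]] <- P[a, g$successors[[a]][1]] +
      g$branch_probability[["same"]]
    P[a, g$successors[[a]][2]] <- P[a, g$successors[[a]][2]] +
      g$branch_probability[["cross"]]
  }
  P
}

#' Stationary distribution of the grammar's Markov chain
#'
#' Solves the left eigenproblem of the transition matrix; for the default
#' grammar the chain is doubly stochastic and the result is uniform (1/6).
#'
#' @param g an `agl_grammar`.
#' @return named numeric vector summing to 1.
#' @export
stationary_distribution <- function(g) {
  P <- transition_matrix(g)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(P))
}

#' Exact lag-2 (non-adjacent) outcome distribution
#'
#' Enumerates the four two-step paths out of `a` (same/cross at each of
#' two steps), merging duplicate endpoints. Under the default grammar each
#' element has exactly three distinct lag-2 outcomes with probabilities
#' `{0.5, 0.25, 0.25}` -- a useful reminder that non-adjacent statistics
#' are flatter than the 0.5 adjacent transitional probabilities.
#'
#' @param g an `agl_grammar`.
#' @param a an element label.
#' @return named numeric vector of endpoint probabilities (sums to 1).
#' @export
#' @examples
#' lag2_distribution(default_grammar(), "V1")
lag2_distribution <- function(g, a) {
  check_elements(g, a)
  p <- g$branch_probability
  out <- numeric(0)
  for (i in 1:2) {
    mid <- g$successors[[a]][i]
    for (j in 1:2) {
      end <- g$successors[[mid]][j]
      out[end] <- (if (is.na(out[end])) 0 else out[end]) + p[i] * p[j]
    }
  }
  out[order(names(out))]
}

#' Enumerate every length-L walk of a grammar with its probability
#'
#' Expands the full tree of same/cross branch choices from every start
#' element (uniform start). For length L this is `6 * 2^(L-1)` walks; used
#' for exact expectations such as the mean number of cross-domain
#' transitions per test sequence.
#'
#' @param g an `agl_grammar`.
#' @param length walk length (number of elements), >= 1.
#' @return list with `walks` (character matrix, one row per walk) and
#'   `prob` (numeric, sums to 1).
#' @export
enumerate_walks <- function(g, length) {
  stopifnot(length >= 1)
  labs <- g$elements$label
  walks <- matrix(labs, ncol = 1)
  prob <- rep(1 / base::length(labs), base::length(labs))
  if (length > 1) {
    for (step in 2:length) {
      n <- nrow(walks)
      walks <- walks[rep(seq_len(n), each = 2), , drop = FALSE]
      prob <- rep(prob, each = 2)
      branch <- rep(1:2, n)
      last <- walks[, step - 1]
      nxt <- vapply(seq_along(last),
                    function(r) g$successors[[last[r]]][branch[r]], "")
      walks <- cbind(walks, nxt)
      prob <- prob * g$branch_probability[branch]
    }
  }
  dimnames(walks) <- NULL
  list(walks = walks, prob = unname(prob))
}

#' Validate a grammar against its structural invariants
#'
#' Runs the full battery of structural checks and returns a report rather
#' than throwing: two successors per element; exactly one successor per
#' domain; branch probabilities 0.5/0.5; no self-loops; irreducibility;
#' uniform stationary distribution; exactly three distinct lag-2 outcomes
#' per element. Malformed successor maps yield failed entries, not errors.
#'
#' @param g an `agl_grammar`.
#' @return a data.frame of class `agl_validation` with columns `check`,
#'   `pass`, `detail`.
#' @export
validate_grammar <- function(g) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  labs <- g$elements$label
  add("six_elements", length(labs) == 6,
      sprintf("%d elements", length(labs)))

  two_succ <- vapply(labs, function(a) {
    s <- g$successors[[a]]
    length(s) == 2 && !anyDuplicated(s) && all(s %in% labs) && !(a %in% s)
  }, TRUE)
  add("two_distinct_successors", all(two_succ),
      if (all(two_succ)) "" else paste("fails at:",
        paste(labs[!two_succ], collapse = ", ")))

  one_per_domain <- vapply(labs, function(a) {
    s <- g$successors[[a]]
    length(s) == 2 && all(s %in% labs) &&
      element_domain(g, s[1]) == element_domain(g, a) &&
      element_domain(g, s[2]) != element_domain(g, a)
  }, TRUE)
  add("one_successor_per_domain", all(one_per_domain),
      if (all(one_per_domain)) "" else paste("fails at:",
        paste(labs[!one_per_domain], collapse = ", ")))

  add("branch_probabilities_half",
      isTRUE(all.equal(unname(g$branch_probability), c(0.5, 0.5))),
      sprintf("same=%.3g cross=%.3g", g$branch_probability[1],
              g$branch_probability[2]))

  ok_matrix <- all(two_succ)
  if (ok_matrix) {
    P <- transition_matrix(g)
    reach <- (diag(length(labs)) + P) %^% length(labs)
    irreducible <- all(reach > 0)
    add("irreducible", irreducible, "")
    pi_hat <- stationary_distribution(g)
    uniform <- max(abs(pi_hat - 1 / length(labs))) < 1e-10
    add("uniform_stationary", irreducible && uniform,
        paste(sprintf("%.4f", pi_hat), collapse = " "))
    lag2_ok <- vapply(labs,
                      function(a) length(lag2_distribution(g, a)) == 3, TRUE)
    add("three_lag2_outcomes", all(lag2_ok),
        if (all(lag2_ok)) "" else paste("fails at:",
          paste(labs[!lag2_ok], collapse = ", ")))
  } else {
    add("irreducible", FALSE, "skipped: malformed successor map")
    add("uniform_stationary", FALSE, "skipped: malformed successor map")
    add("three_lag2_outcomes", FALSE, "skipped: malformed successor map")
  }
  out <- do.call(rbind, checks)
  class(out) <- c("agl_validation", "data.frame")
  out
}

# small matrix power helper (non-negative integer exponent)
`%^%` <- function(M, n) {
  R <- diag(nrow(M))
  while (n > 0) {
    if (n %% 2 == 1) R <- R %*% M
    M <- M %*% M
    n <- n %/% 2
  }
  R
}

#' @export
print.agl_validation <- function(x, ...) {
  cat("Grammar validation:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-26s %s\n", if (x$pass[i]) "ok" else "FAIL",
                x$check[i], x$detail[i]))
  }
  invisible(x)
}

#' Read / write a grammar as JSON
#'
#' The on-disk format has keys `elements` (array of
#' `{label, domain, index}`), `successors` (map label ->
#' `[same-domain label, cross-domain label]`) and optionally
#' `branch_probability` (defaults to 0.5/0.5). Round-trips exactly, so an
#' alternative topology can be dropped in without code changes.
#'
#' @param g an `agl_grammar`.
#' @param path file path.
#' @return `read_grammar` returns an `agl_grammar`; `write_grammar`
#'   returns `path` invisibly.
#' @export
write_grammar <- function(g, path) {
  obj <- list(
    elements = g$elements,
    successors = g$successors,
    branch_probability = unname(g$branch_probability)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_grammar
#' @export
read_grammar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bp <- if (is.null(obj$branch_probability)) c(0.5, 0.5) else
    as.numeric(obj$branch_probability)
  succ <- lapply(obj$successors, as.character)
  grammar_spec(as.data.frame(obj$elements), succ, bp)
}
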