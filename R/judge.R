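#' @name judge_backends
#' @title Pluggable pairwise judges
#'
#' @description
#' A judge backend compares two embedding images and returns a
#' `judge_decision` naming the winner (1 or 2). Three backends are
#' provided: [llm_judge()] speaks the vision-LLM protocol over a
#' user-supplied transport; [oracle_judge()] deterministically prefers the
#' candidate with the higher value of a supplied higher-is-better score
#' (used for offline testing and benchmarking); [noisy_judge()] agrees with
#' the oracle with a configurable probability `p`, emulating a judge of
#' known accuracy.
NULL

new_judge_decision <- function(winner, raw_responses, backend) {
  stopifnot(winner %in% c(1L, 2L), length(raw_responses) >= 1L)
  structure(
    list(
      winner = as.integer(winner),
      raw_responses = as.character(raw_responses),
      attempts = length(raw_responses),
      backend = backend
    ),
    class = "judge_decision"
  )
}

#' @export
print.judge_decision <- function(x, ...) {
  cat(sprintf("judge_decision [%s]: winner %d (%d attempt%s)\n",
              x$backend, x$winner, x$attempts, if (x$attempts > 1) "s" else ""))
  invisible(x)
}

new_judge_backend <- function(name, compare, deterministic) {
  structure(
    list(name = name, compare = compare, deterministic = deterministic),
    class = "judge_backend"
  )
}

#' @export
print.judge_backend <- function(x, ...) {
  cat(sprintf("judge_backend '%s' (%s)\n", x$name,
              if (x$deterministic) "deterministic" else "stochastic"))
  invisible(x)
}

#' Compare two images with a judge backend
#'
#' @param backend A `judge_backend`.
#' @param image1,image2 The two candidates (for the LLM backend,
#'   [render_embedding()] images; oracle backends only need a `config_id`).
#' @return A `judge_decision`.
#' @export
judge_compare <- function(backend, image1, image2) {
  stopifnot(inherits(backend, "judge_backend"))
  dec <- backend$compare(image1, image2)
  if (!inherits(dec, "judge_decision")) stopf("backend returned an invalid decision")
  dec
}

#' The pairwise comparison prompt sent to a vision LLM
#'
#' @param basis `"umap"` or `"pca"`; the plot-type word in the prompt is
#'   substituted accordingly.
#' @return A single string.
#' @export
judge_prompt <- function(basis = c("umap", "pca")) {
  basis <- match.arg(basis)
  word <- if (basis == "umap") "UMAP" else "PCA"
  paste0(
    "You will be shown two ", word, " plots. Please carefully examine both. ",
    "Image 1 is labeled \u20181\u2019 and Image 2 is labeled \u20182\u2019. ",
    "Based on visual accuracy (cluster separation, boundary clarity, etc.), ",
    "which one is better? Please respond with only: 1 or 2."
  )
}

#' Vision-LLM judge over a thin transport contract
#'
#' The transport is any function `(prompt, image1, image2) -> character`
#' that submits the text prompt together with both PNG images to a
#' chat-with-images model and returns the raw text reply — an OpenAI-style
#' HTTP adapter, a vendor SDK, or a scripted mock. The judge sends the
#' verbatim prompt, strips whitespace and trailing punctuation from the
#' reply, and accepts exactly `"1"` or `"2"`; any other reply triggers an
#' independent re-prompt, up to `max_retries` attempts. All raw replies are
#' recorded on the decision.
#'
#' @param transport Function `(prompt, image1, image2) -> character(1)`.
#' @param basis Embedding basis named in the prompt.
#' @param max_retries Maximum number of prompts per comparison (>= 1).
#'   Bounded because an unbounded retry loop is unacceptable in a library.
#' @param model Model identifier recorded on the backend (passed through to
#'   transports that want it via `attr(transport, "model")` conventions).
#' @return A `judge_backend`.
#' @examples
#' always2 <- function(prompt, i1, i2) "2"
#' b <- llm_judge(always2)
#' @export
llm_judge <- function(transport, basis = c("umap", "pca"), max_retries = 10L,
                      model = "gpt-4o-2024-08-06") {
  stopifnot(is.function(transport), max_retries >= 1L)
  basis <- match.arg(basis)
  prompt <- judge_prompt(basis)
  name <- paste0("llm:", model)
  compare <- function(image1, image2) {
    responses <- character(0)
    for (attempt in seq_len(max_retries)) {
      reply <- tryCatch(transport(prompt, image1, image2), error = function(e) {
        stopf("judge transport failure: %s", conditionMessage(e),
              class = "scjudge_transport_error",
              data = list(raw_responses = responses))
      })
      responses <- c(responses, as.character(reply)[1L])
      ans <- sanitize_reply(reply)
      if (ans %in% c("1", "2")) {
        return(new_judge_decision(as.integer(ans), responses, name))
      }
    }
    stopf("judge gave no valid '1'/'2' reply in %d attempts (last: %s)",
          max_retries, deparse(responses[length(responses)]),
          class = "scjudge_judge_protocol_error",
          data = list(raw_responses = responses))
  }
  new_judge_backend(name, compare, deterministic = FALSE)
}

# strip whitespace and trailing punctuation; the protocol accepts only "1"/"2"
sanitize_reply <- function(reply) {
  x <- trimws(as.character(reply)[1L])
  sub("[[:punct:]]+$", "", x)
}

#' Deterministic oracle comparison of two scores
#'
#' @param score1,score2 Finite higher-is-better scores.
#' @param tie_rule `"first"` (ties go to candidate 1) or `"error"`.
#' @return A `judge_decision`.
#' @export
oracle_compare <- function(score1, score2, tie_rule = c("first", "error")) {
  tie_rule <- match.arg(tie_rule)
  if (!is.finite(score1) || !is.finite(score2)) stopf("oracle scores must be finite")
  if (score1 == score2 && tie_rule == "error") {
    stopf("tied oracle scores (%g)", score1, class = "scjudge_tie_error")
  }
  winner <- if (score2 > score1) 2L else 1L
  new_judge_decision(winner, as.character(winner), "oracle")
}

#' Oracle judge keyed by configuration scores
#'
#' Picks the candidate whose `config_id` has the strictly higher score.
#' This is the deterministic stand-in for a visual judge used in offline
#' tests and benchmarks; scores are any higher-is-better quantity (e.g. a
#' clustering metric against ground truth).
#'
#' @param scores Named numeric vector, names are `config_id`s.
#' @param tie_rule Passed to [oracle_compare()].
#' @return A `judge_backend`.
#' @export
oracle_judge <- function(scores, tie_rule = c("first", "error")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  compare <- function(image1, image2) {
    s <- lookup_scores(scores, image1, image2)
    oracle_compare(s[1], s[2], tie_rule)
  }
  new_judge_backend("oracle", compare, deterministic = TRUE)
}

#' Noisy oracle judge with known accuracy
#'
#' Agrees with the score oracle with probability `p` and picks the other
#' candidate with probability `1 - p`, drawing from a private seeded stream
#' (the caller's RNG is untouched). `p = 1` reduces exactly to
#' [oracle_judge()]. Used to emulate a visual judge whose measured pairwise
#' accuracy is `p`.
#'
#' @param scores Named numeric vector of higher-is-better scores.
#' @param p Accuracy in `(0.5, 1]`.
#' @param seed Integer seed of the private decision stream.
#' @param tie_rule Passed to [oracle_compare()].
#' @return A `judge_backend`.
#' @export
noisy_judge <- function(scores, p, seed = 1L, tie_rule = c("first", "error")) {
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(p) || length(p) != 1L || p <= 0.5 || p > 1) {
    stopf("p must lie in (0.5, 1], got %s", deparse(p))
  }
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  state <- new.env(parent = emptyenv())
  state$rs <- with_seed(seed, get(".Random.seed", envir = globalenv()))
  compare <- function(image1, image2) {
    s <- lookup_scores(scores, image1, image2)
    truth <- oracle_compare(s[1], s[2], tie_rule)$winner
    u <- draw_private(state)
    winner <- if (u <= p) truth else 3L - truth
    new_judge_decision(winner, as.character(winner), sprintf("noisy(p=%g)", p))
  }
  new_judge_backend(sprintf("noisy(p=%g)", p), compare, deterministic = FALSE)
}

# one uniform draw from a private RNG state, preserving the caller's stream
draw_private <- function(state) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", state$rs, envir = globalenv())
  u <- stats::runif(1)
  state$rs <- get(".Random.seed", envir = globalenv())
  if (has_old) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  u
}

#' One-off noisy oracle comparison
#'
#' @inheritParams oracle_compare
#' @param p Accuracy in `(0.5, 1]`.
#' @param rng_seed Seed for the single draw.
#' @return A `judge_decision`.
#' @export
noisy_oracle_compare <- function(score1, score2, p, rng_seed,
                                 tie_rule = c("first", "error")) {
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(p) || length(p) != 1L || p <= 0.5 || p > 1) {
    stopf("p must lie in (0.5, 1], got %s", deparse(p))
  }
  truth <- oracle_compare(score1, score2, tie_rule)$winner
  u <- with_seed(rng_seed, stats::runif(1))
  winner <- if (u <= p) truth else 3L - truth
  new_judge_decision(winner, as.character(winner), sprintf("noisy(p=%g)", p))
}

lookup_scores <- function(scores, image1, image2) {
  ids <- c(image_config_id(image1), image_config_id(image2))
  if (!all(ids %in% names(scores))) {
    stopf("no oracle score for: %s",
          paste(setdiff(ids, names(scores)), collapse = ", "))
  }
  unname(scores[ids])
}

image_config_id <- function(image) {
  if (is.list(image) && !is.null(image$config_id)) image$config_id
  else stopf("image carries no config_id for score lookup")
}

#' Majority vote over repeated comparisons
#'
#' Queries the backend `k` times on the same pair (independent calls) and
#' returns the most frequent winner; `k` must be odd so that ties are
#' impossible. With `k = 1` this is a single comparison; `k = 5` is the
#' five-shot protocol.
#'
#' @param backend A `judge_backend`.
#' @param image1,image2 The two candidates.
#' @param k Odd positive number of shots.
#' @return A `judge_decision` aggregating all raw responses.
#' @export
majority_vote <- function(backend, image1, image2, k = 5L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k) || k %% 2 == 0) {
    stopf("k must be a positive odd integer, got %s", deparse(k))
  }
  decisions <- lapply(seq_len(k), function(i) judge_compare(backend, image1, image2))
  winners <- vapply(decisions, `[[`, 0L, "winner")
  winner <- if (sum(winners == 1L) > k / 2) 1L else 2L
  new_judge_decision(
    winner,
    unlist(lapply(decisions, `[[`, "raw_responses")),
    sprintf("%s x%d", backend$name, k)
  )
}
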