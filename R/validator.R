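#' The shared interaction-verb lexicon
#'
#' Verb phrases that the mock validator treats as asserting an interaction
#' when they link the two queried names inside one sentence. The synthetic
#' abstract generator draws from the same lexicon, so validator behaviour
#' on generated corpora is decidable without a language model.
#'
#' @return character vector of verb phrases.
#' @export
interaction_verbs <- function() {
  c("binds", "phosphorylates", "activates", "inhibits", "regulates",
    "interacts with", "forms a complex with")
}

#' Construct a generation backend
#'
#' A backend is the pluggable text-generation stage of the validator: a
#' callable taking a prompt string and returning generated text. The
#' shipped [mock_backend()] is a deterministic rule system; a fine-tuned
#' language model can be plugged in through the same contract.
#'
#' @param generate function(prompt) -> character(1).
#' @param name backend label.
#' @param deterministic does the backend always return the same text for
#'   the same prompt?
#' @return a list of class `kg_backend`.
#' @export
new_backend <- function(generate, name = "custom", deterministic = FALSE) {
  stopifnot(is.function(generate))
  structure(list(generate = generate, name = name,
                 deterministic = isTRUE(deterministic)),
            class = "kg_backend")
}

#' @export
print.kg_backend <- function(x, ...) {
  cat("<kg_backend> ", x$name,
      if (x$deterministic) " (deterministic)" else "", "\n", sep = "")
  invisible(x)
}

# Pull the queried names and the final context block out of a prompt built
# by build_instruction(). The few-shot blocks contain their own Context/
# Question lines, so the *last* occurrence is the real query.
parse_prompt <- function(prompt) {
  ctx_starts <- gregexpr("Context: ", prompt, fixed = TRUE)[[1]]
  q_starts <- gregexpr("Question: Using only the provided context, do ",
                       prompt, fixed = TRUE)[[1]]
  if (ctx_starts[1] == -1 || q_starts[1] == -1) {
    stop("malformed prompt: no context/question block found", call. = FALSE)
  }
  ctx_at <- max(ctx_starts)
  q_at <- max(q_starts)
  context <- substr(prompt, ctx_at + nchar("Context: "), q_at - 1)
  question <- substr(prompt, q_at, nchar(prompt))
  m <- regmatches(question,
                  regexec("do (.+) and (.+) interact\\?", question))[[1]]
  if (length(m) != 3) {
    stop("malformed prompt: queried pair not found", call. = FALSE)
  }
  list(context = trimws(context), name_a = m[2], name_b = m[3])
}

#' Deterministic rule-based validation backend
#'
#' A format-conforming stand-in for a fine-tuned generative model, used in
#' tests and offline runs. It answers YES exactly when some single
#' sentence of the context links the two queried names with a verb phrase
#' from [interaction_verbs()] (in either direction, as `A <verb> B`);
#' otherwise NO. Output always starts with the YES/NO indicator followed
#' by a confidence level and a one-sentence explanation.
#'
#' @return a deterministic `kg_backend`.
#' @examples
#' b <- mock_backend()
#' txt <- b$generate(build_instruction("KINA1 binds KINB2 in neurons.",
#'                                     "KINA1", "KINB2"))
#' substr(txt, 1, 3) # "YES"
#' @export
mock_backend <- function() {
  gen <- function(prompt) {
    q <- parse_prompt(prompt)
    if (!grepl(q$name_a, q$context, fixed = TRUE) ||
        !grepl(q$name_b, q$context, fixed = TRUE)) {
      stop("malformed prompt: queried names not present in the context",
           call. = FALSE)
    }
    sentences <- strsplit(q$context, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    verbs <- paste(gsub(" ", "\\\\s+", interaction_verbs()), collapse = "|")
    esc <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
    pat_ab <- paste0("\\b", esc(q$name_a), "\\s+(?:", verbs, ")\\s+",
                     esc(q$name_b), "\\b")
    pat_ba <- paste0("\\b", esc(q$name_b), "\\s+(?:", verbs, ")\\s+",
                     esc(q$name_a), "\\b")
    hit <- NULL
    for (s in sentences) {
      if (grepl(pat_ab, s) || grepl(pat_ba, s)) { hit <- s; break }
    }
    if (!is.null(hit)) {
      verb <- regmatches(hit, regexpr(paste0("\\b(?:", verbs, ")\\b"),
                                      hit, perl = TRUE))
      paste0("YES. Confidence: high. The context states that ", q$name_a,
             " ", verb[1], " ", q$name_b,
             ", a direct statement of interaction.")
    } else {
      paste0("NO. Confidence: high. ", q$name_a, " and ", q$name_b,
             " are mentioned in the context, but no sentence links them ",
             "with an interaction verb.")
    }
  }
  new_backend(gen, name = "mock", deterministic = TRUE)
}

#' Parse a generated verdict
#'
#' The output convention requires every generated answer to begin with the
#' indicator `YES` (interaction present in the context) or `NO`. The
#' decision is the leading token after stripping whitespace and
#' punctuation, matched case-insensitively; a confidence level is pulled
#' from a "confidence: high/medium/low" phrase when present (defaulting to
#' `"unstated"`); the remaining text is kept as the explanation.
#'
#' @param generated generated text (non-empty).
#' @return a tibble row with columns `decision` (`"YES"`/`"NO"`),
#'   `confidence`, `explanation`.
#' @examples
#' parse_verdict("NO. Confidence: medium. The proteins are only co-mentioned.")
#' @export
parse_verdict <- function(generated) {
  if (is.null(generated) || is.na(generated) || !nzchar(trimws(generated))) {
    stop("cannot parse an empty generation", call. = FALSE)
  }
  stripped <- sub("^[[:space:][:punct:]]+", "", generated)
  token <- toupper(sub("^([[:alpha:]]+).*$", "\\1", stripped))
  if (!token %in% c("YES", "NO")) {
    cond <- structure(
      class = c("kgppi_malformed_output", "error", "condition"),
      list(message = paste0("generated text does not begin with YES or NO: ",
                            substr(generated, 1, 80)),
           call = NULL, raw = generated)
    )
    stop(cond)
  }
  conf_m <- regmatches(
    generated,
    regexpr("[Cc]onfidence[: ]+\\(?(high|medium|low)", generated,
            perl = TRUE)
  )
  confidence <- if (length(conf_m) == 1) {
    tolower(sub(".*(high|medium|low)$", "\\1", conf_m))
  } else "unstated"
  rest <- sub("^[[:space:][:punct:]]*(YES|NO|yes|no|Yes|No)[[:space:][:punct:]]*",
              "", generated)
  rest <- sub("^[Cc]onfidence[: ]+\\(?(high|medium|low)\\)?[[:space:][:punct:]]*",
              "", rest)
  tibble::tibble(decision = token, confidence = confidence,
                 explanation = trimws(rest))
}

#' Validate one instruction example with a backend
#'
#' Invokes the backend on the example's prompt and parses the verdict. If
#' the generated text is malformed (no leading YES/NO) the backend is
#' retried once; if still malformed, a NO verdict with `"unstated"`
#' confidence is recorded and flagged `malformed = TRUE`, so batch runs
#' stay total.
#'
#' @param example one-row tibble (or list) with fields `prompt`, `doc_id`.
#' @param backend a `kg_backend`.
#' @return a tibble row: `doc_id`, `decision`, `confidence`, `explanation`,
#'   `malformed`, `raw_output`.
#' @export
validate_pair <- function(example, backend) {
  stopifnot(inherits(backend, "kg_backend"))
  raw <- backend$generate(example$prompt)
  v <- tryCatch(parse_verdict(raw), kgppi_malformed_output = function(e) NULL)
  if (is.null(v)) {
    raw <- backend$generate(example$prompt)
    v <- tryCatch(parse_verdict(raw), kgppi_malformed_output = function(e) NULL)
  }
  if (is.null(v)) {
    return(tibble::tibble(doc_id = example$doc_id, decision = "NO",
                          confidence = "unstated",
                          explanation = "generation malformed twice",
                          malformed = TRUE, raw_output = raw))
  }
  dplyr::bind_cols(tibble::tibble(doc_id = example$doc_id), v,
                   tibble::tibble(malformed = FALSE, raw_output = raw))
}

#' Validate a table of instruction examples
#'
#' @param examples tibble with columns `prompt`, `doc_id` (one row each).
#' @param backend a `kg_backend`.
#' @return a tibble of verdicts, one row per example, in input order.
#' @export
validate_examples <- function(examples, backend) {
  purrr::map_dfr(seq_len(nrow(examples)), function(i) {
    validate_pair(examples[i, ], backend)
  })
}
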