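# Zero-shot and few-shot chat-prompt baselines with strict label parsing.
# The chat backend is an abstract contract (prompt in, raw text out), so the
# whole module runs against deterministic mocks; no API is ever required.

ZERO_SHOT_TEMPLATE <- paste0(
  "You are a psychiatrist specialized in diagnosing and treating ",
  "Post-Traumatic Stress Disorder (PTSD). I will provide you with a ",
  "narrative written by a woman describing her birth experience. Your task ",
  "is to decide whether this woman is at high risk of PTSD (Label 1) or ",
  "lower risk of PTSD (Label 0). Do not write anything but '1' or '0'. ",
  "### < Text > : \"{text}\"")

FEW_SHOT_PREAMBLE <- paste0(
  "You are a psychiatrist specialized in diagnosing and treating ",
  "Post-Traumatic Stress Disorder (PTSD). I will provide you with a ",
  "narrative written by a woman describing her birth experience. Your task ",
  "is to decide whether this woman is at high risk of PTSD (Label 1), or ",
  "lower risk of PTSD (Label 0). Do not write anything but '1' or '0'. ",
  "Here are a few examples of text with their associated class labels as ",
  "'1' (PTSD) or '0' (No-PTSD).")

#' Specification of a prompt-based classifier
#'
#' @param mode `"zero_shot"` or `"few_shot"`.
#' @param examples for few-shot: a data.frame with columns `narrative` and
#'   `label` (1-4 rows; when 2 or more, both labels must appear). Must be
#'   empty/NULL for zero-shot.
#' @param model_name backend model tag (informational).
#' @param temperature must be 0: prompting is run deterministically
#'   (greedy decoding).
#' @return a `prompt_spec` list.
#' @export
prompt_spec <- function(mode = c("zero_shot", "few_shot"), examples = NULL,
                        model_name = "gpt-3.5-turbo-16k", temperature = 0) {
  mode <- match.arg(mode)
  if (temperature != 0)
    stop_validation("temperature must be 0 (deterministic prompting)")
  if (mode == "zero_shot") {
    if (!is.null(examples) && nrow(examples) > 0L)
      stop_validation("zero_shot prompts take no examples")
    examples <- data.frame(narrative = character(0), label = integer(0))
  } else {
    if (is.null(examples) || nrow(examples) < 1L || nrow(examples) > 4L)
      stop_validation("few_shot requires 1-4 examples")
    if (!all(c("narrative", "label") %in% names(examples)))
      stop_validation("examples need 'narrative' and 'label' columns")
    if (nrow(examples) >= 2L && length(unique(examples$label)) < 2L)
      stop_validation("few_shot examples must include both labels")
  }
  structure(list(mode = mode, examples = examples, model_name = model_name,
                 temperature = 0), class = "prompt_spec")
}

#' Render the classification prompt for one narrative
#'
#' Instantiates the prompt template for the spec's mode: the task
#' instruction, then (few-shot only) example blocks formatted as
#' `< Text > : "..." < Label > : <0|1>` separated by `###`, then the target
#' narrative last.
#'
#' @param spec a `prompt_spec`.
#' @param narrative non-empty character scalar.
#' @return the rendered prompt string.
#' @export
render_prompt <- function(spec, narrative) {
  stopifnot(inherits(spec, "prompt_spec"))
  if (!is.character(narrative) || length(narrative) != 1L || !nzchar(narrative))
    stop_validation("narrative must be a non-empty string")
  if (spec$mode == "zero_shot")
    return(sub("{text}", narrative, ZERO_SHOT_TEMPLATE, fixed = TRUE))
  blocks <- vapply(seq_len(nrow(spec$examples)), function(i) {
    sprintf("< Text > : \"%s\" < Label > : %d",
            spec$examples$narrative[i], spec$examples$label[i])
  }, character(1))
  paste0(FEW_SHOT_PREAMBLE, " ",
         paste(blocks, collapse = " ### "),
         sprintf(" ### < Text > : \"%s\"", narrative))
}

#' Parse a chat response into a class label
#'
#' The prompt instructs the model to answer only `1` or `0`. After stripping
#' whitespace, exactly `"1"`/`"0"` parse strictly; otherwise, if the first
#' non-whitespace character is a `1` or `0` the response parses leniently
#' (real backends occasionally decorate answers); anything else is
#' `unparseable` -- a reported value, never an error.
#'
#' @param raw_response character scalar.
#' @return list with `label` (integer 0/1 or `NA`), and `parse` in
#'   `"strict"`, `"lenient"`, `"unparseable"`.
#' @export
parse_label <- function(raw_response) {
  s <- trimws(raw_response %||% "")
  if (s %in% c("0", "1"))
    return(list(label = as.integer(s), parse = "strict"))
  first <- substr(s, 1L, 1L)
  if (first %in% c("0", "1"))
    return(list(label = as.integer(first), parse = "lenient"))
  list(label = NA_integer_, parse = "unparseable")
}

#' Classify narratives through a chat backend
#'
#' Renders one prompt per narrative, queries the backend (retrying failures
#' once), and parses the responses. Unparseable responses are counted and
#' carried as `NA` labels so downstream evaluation can exclude them
#' explicitly.
#'
#' @param spec a `prompt_spec`.
#' @param narratives character vector.
#' @param backend a `chat_backend`.
#' @return list with `labels` (integer, `NA` = unparseable), `transcript`
#'   data.frame (prompt, raw response, parsed label, parse mode), and
#'   `n_unparseable`.
#' @export
classify_via_chat <- function(spec, narratives, backend) {
  stopifnot(inherits(backend, "chat_backend"))
  rows <- lapply(narratives, function(txt) {
    prompt <- render_prompt(spec, txt)
    raw <- tryCatch(backend$ask(prompt),
                    error = function(e) tryCatch(backend$ask(prompt),
                                                 error = function(e2) NA_character_))
    parsed <- parse_label(raw)
    data.frame(prompt = prompt, raw_response = raw %||% NA_character_,
               label = parsed$label, parse = parsed$parse,
               stringsAsFactors = FALSE)
  })
  transcript <- do.call(rbind, rows)
  list(labels = transcript$label, transcript = transcript,
       n_unparseable = sum(transcript$parse == "unparseable"))
}

#' Write a prompt transcript as JSONL for audit
#' @param transcript the `transcript` data.frame from [classify_via_chat()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcript_jsonl <- function(transcript, path) {
  lines <- vapply(seq_len(nrow(transcript)), function(i)
    as.character(jsonlite::toJSON(as.list(transcript[i, ]), auto_unbox = TRUE,
                                  na = "null")), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- mock backends -----------------------------------------------------------

#' Construct a chat backend
#' @param name backend tag.
#' @param ask function(prompt) -> character scalar raw response.
#' @param deterministic logical.
#' @return a `chat_backend`.
#' @export
chat_backend <- function(name, ask, deterministic = TRUE) {
  structure(list(name = name, ask = ask, deterministic = isTRUE(deterministic)),
            class = "chat_backend")
}

#' Mock backend answering a constant string
#' @param answer the response returned for every prompt.
#' @return a `chat_backend`.
#' @export
chat_mock_constant <- function(answer = "1") {
  chat_backend("mock-constant", function(prompt) answer)
}

#' Extract the target narrative from a rendered prompt
#'
#' The target is always the last `< Text > : "..."` block; mocks use this to
#' look up the narrative's true label.
#'
#' @param prompt a string produced by [render_prompt()].
#' @return the target narrative text.
#' @export
extract_target_text <- function(prompt) {
  marker <- "< Text > : \""
  pos <- gregexpr(marker, prompt, fixed = TRUE)[[1L]]
  if (pos[1L] == -1L) stop_validation("prompt has no < Text > block")
  start <- pos[length(pos)] + nchar(marker)
  body <- substr(prompt, start, nchar(prompt))
  sub("\"$", "", body)
}

#' Scripted mock with a target error profile
#'
#' Answers with the narrative's true label, flipped so that positives are
#' detected with probability `sensitivity` and negatives rejected with
#' probability `specificity`. Flips are decided per narrative from a hash of
#' its text mixed with `seed`, so the mock is deterministic and independent
#' of call order.
#'
#' @param corpus a `narrative_corpus` supplying true labels by narrative text.
#' @param sensitivity,specificity target per-class accuracy probabilities.
#' @param seed integer seed.
#' @return a `chat_backend`.
#' @export
chat_mock_scripted <- function(corpus, sensitivity = 1, specificity = 1,
                               seed = 0L) {
  truth <- stats::setNames(corpus$label, corpus$narrative)
  chat_backend(sprintf("mock-scripted-se%.2f-sp%.2f", sensitivity, specificity),
               function(prompt) {
    text <- extract_target_text(prompt)
    if (!text %in% names(truth))
      stop_validation("mock backend: narrative not in its corpus")
    lab <- truth[[text]]
    u <- with_seed((fnv1a32(text) + as.numeric(seed)) %% 2147483647,
                   stats::runif(1))
    keep <- if (lab == 1L) u < sensitivity else u < specificity
    as.character(if (keep) lab else 1L - lab)
  })
}
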