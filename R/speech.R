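#' Dialogue-act label set
#'
#' The eight functional labels assigned to utterances: acknowledgements
#' (`Acks`), disagreement/negative statements (`Neg`), positive feedback
#' (`Pos`), questions (`Ques`), reading task instructions aloud
#' (`Read`), statements of information, action directives and opinions
#' (`Inform`), conventional pleasantries (`Conv`), and uninterpretable
#' fragments (`Out`). `Out` utterances are counted but excluded from
#' downstream analysis.
#'
#' @return Character vector of the eight labels.
#' @export
dialogue_act_labels <- function() {
  c("Acks", "Neg", "Pos", "Ques", "Read", "Inform", "Conv", "Out")
}

#' Segment a timestamped word stream into utterances
#'
#' Mirrors the segmentation behavior of a streaming speech-to-text
#' service: a new utterance starts when the gap since the previous word
#' reaches `silence_gap`, or when appending the word would push the
#' utterance duration past `max_utterance` (default 15 s). Every word
#' belongs to exactly one utterance.
#'
#' @param words Data frame with columns `time` (seconds, sorted) and
#'   `word`; optional `player` and `topic_id` columns are carried
#'   through (an utterance takes the first word's annotations).
#' @param silence_gap Silence that closes an utterance, seconds
#'   (default 1).
#' @param max_utterance Maximum utterance duration, seconds (default 15).
#' @return Data frame of utterances: `player`, `start`, `end`, `text`,
#'   `word_count`, `topic_id`.
#' @export
segment_utterances <- function(words, silence_gap = 1, max_utterance = 15) {
  stopifnot(silence_gap > 0, max_utterance > 0)
  empty <- data.frame(player = character(), start = numeric(), end = numeric(),
                      text = character(), word_count = integer(),
                      topic_id = character(), stringsAsFactors = FALSE)
  if (is.null(words) || nrow(words) == 0) return(empty)
  if (is.unsorted(words$time)) stop("word stream must be sorted by time", call. = FALSE)
  player <- if ("player" %in% names(words)) as.character(words$player) else rep("P1", nrow(words))
  topic <- if ("topic_id" %in% names(words)) as.character(words$topic_id) else rep(NA_character_, nrow(words))
  t <- words$time
  n <- nrow(words)
  seg <- integer(n)
  cur <- 1L
  start_t <- t[1]
  for (i in seq_len(n)) {
    if (i > 1) {
      gap <- t[i] - t[i - 1]
      if (gap >= silence_gap || (t[i] - start_t) > max_utterance ||
          player[i] != player[i - 1]) {
        cur <- cur + 1L
        start_t <- t[i]
      }
    }
    seg[i] <- cur
  }
  rows <- lapply(split(seq_len(n), seg), function(ix) {
    data.frame(player = player[ix[1]], start = t[ix[1]], end = t[ix[length(ix)]],
               text = paste(as.character(words$word[ix]), collapse = " "),
               word_count = length(ix), topic_id = topic[ix[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag and count conversational initiations
#'
#' An utterance is an initiation if it introduces a new topic (when
#' `topic_id` annotations are present) or if it follows at least
#' `silence_threshold` seconds of silence from *either* participant
#' (default 30 s, giving the partner time to respond verbally or
#' nonverbally before speech counts as a fresh start). The session's
#' first utterance is always an initiation. Without topic annotations
#' only the silence rule applies; no lexical topic model is attempted.
#'
#' @param utterances Utterance data frame (both players, sorted by
#'   `start`), as from [segment_utterances()].
#' @param silence_threshold Silence gap in seconds that makes the next
#'   utterance an initiation (default 30).
#' @return The input with a logical `is_initiation` column;
#'   `attr(x, "counts")` holds per-player initiation counts.
#' @export
count_initiations <- function(utterances, silence_threshold = 30) {
  if (is.null(utterances) || nrow(utterances) == 0) {
    out <- cbind(utterances, is_initiation = logical(0))
    attr(out, "counts") <- stats::setNames(integer(0), character(0))
    return(out)
  }
  u <- utterances[order(utterances$start), , drop = FALSE]
  topic <- if ("topic_id" %in% names(u)) as.character(u$topic_id) else rep(NA_character_, nrow(u))
  init <- logical(nrow(u))
  init[1] <- TRUE
  last_topic <- topic[1]
  for (i in seq_len(nrow(u))[-1]) {
    gap <- u$start[i] - u$end[i - 1]
    new_topic <- !is.na(topic[i]) && (is.na(last_topic) || topic[i] != last_topic)
    init[i] <- gap >= silence_threshold || new_topic
    if (!is.na(topic[i])) last_topic <- topic[i]
  }
  u$is_initiation <- init
  counts <- tapply(init, u$player, sum)
  attr(u, "counts") <- stats::setNames(as.integer(counts), names(counts))
  u
}

# --- rule/lexicon dialogue-act classifier ------------------------------------

.da_lexicon <- function() {
  list(
    conv = c("thanks", "thank you", "sorry", "my bad", "you're welcome",
             "no problem", "excuse me"),
    pos = c("well done", "good job", "great job", "nice job", "nice work",
            "good work", "awesome job", "perfect"),
    interrogatives = c("what", "where", "when", "who", "whose", "why", "how",
                       "which", "can", "could", "would", "will", "shall",
                       "should", "do", "does", "did", "is", "are", "was",
                       "were", "am", "have", "has", "may", "might"),
    read_cues = c("mine says", "it says", "it said", "instructions say",
                  "instruction says", "the instructions", "my instructions",
                  "says to", "it reads"),
    neg = c("no", "not", "don't", "dont", "can't", "cant", "won't", "wont",
            "isn't", "isnt", "doesn't", "doesnt", "nope", "never", "confused",
            "wrong", "nah"),
    acks = c("i know", "you're right", "youre right", "okay", "ok", "yeah",
             "yes", "yup", "yep", "cool", "uh-huh", "uh huh", "uhhuh", "right",
             "sure", "alright", "gotcha", "got it", "exactly", "true", "mhm"),
    # common verbs/auxiliaries in task talk; used to judge whether a quoted
    # instruction fragment carries interpretable content
    verbs = c("select", "put", "move", "moving", "try", "take", "place", "attach",
              "turn", "go", "press", "click", "grab", "use", "share", "pick",
              "drop", "hold", "look", "see", "need", "want", "wants", "get",
              "make", "is", "are", "be", "do", "have", "has", "choose", "find",
              "read", "connect", "insert", "rotate", "slide", "push", "pull")
  )
}

.da_tokens <- function(text) {
  x <- tolower(text)
  x <- gsub("[‘’ʼ]", "'", x)          # curly apostrophes
  x <- gsub("[^a-z0-9' -]", " ", x)
  tok <- strsplit(trimws(x), "\\s+")[[1]]
  tok[nzchar(tok)]
}

.da_normalize <- function(text) {
  x <- tolower(trimws(text))
  x <- gsub("[‘’ʼ]", "'", x)
  gsub("\\s+", " ", x)
}

.stopword_fragments <- c("the", "a", "an", "and", "or", "but", "of", "to",
                         "in", "on", "at", "it", "um", "uh", "er", "hmm")

#' Classify an utterance into one of eight dialogue acts
#'
#' A deterministic, transparent rule cascade standing in for a trained
#' sequence classifier. Rules are evaluated in a fixed order on the
#' case- and whitespace-normalized text:
#' \enumerate{
#'   \item `Conv` — conventional pleasantries (thanks/sorry/my bad).
#'   \item `Pos` — praise directed at the partner (well done/good job).
#'   \item `Ques` — ends in `?` or opens with an interrogative or
#'     auxiliary (what/where/can/do/is, ...).
#'   \item `Read`/`Out` — instruction-quoting cues ("mine says",
#'     "it says/said", "instructions say"): `Read` when the quoted
#'     remainder carries interpretable content (a known task verb or a
#'     number), otherwise the quote is transcription noise and is `Out`.
#'   \item `Neg` — negation or confusion within the first three tokens
#'     (no/not/don't/"oh no"/"not sure").
#'   \item `Acks` — short agreement tokens (okay/yeah/yup/uh-huh/
#'     "I know"/"you're right") for utterances of at most four tokens.
#'   \item `Out` — no alphabetic token, or a bare function-word fragment.
#'   \item `Inform` — the residual class: action directives,
#'     descriptions of intent, and statements of opinion.
#' }
#'
#' @param text Character vector of utterance texts (non-empty).
#' @return Character vector of labels from [dialogue_act_labels()].
#' @export
classify_dialogue_act <- function(text) {
  if (length(text) == 0) return(character(0))
  vapply(text, .classify_one, character(1), USE.NAMES = FALSE)
}

.classify_one <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) {
    stop("cannot classify an empty utterance", call. = FALSE)
  }
  lex <- .da_lexicon()
  norm <- .da_normalize(text)
  norm_nopunct <- gsub("[[:punct:]]+$", "", norm)
  tok <- .da_tokens(text)
  phrase_in <- function(phrases) {
    any(vapply(phrases, function(p) {
      grepl(paste0("(^|[^a-z])", gsub("'", "'?", p), "($|[^a-z])"), norm)
    }, logical(1)))
  }

  # 1. conventional pleasantries
  if (phrase_in(lex$conv)) return("Conv")
  # 2. positive feedback
  if (phrase_in(lex$pos)) return("Pos")
  # 3. questions
  if (grepl("\\?\\s*$", trimws(text))) return("Ques")
  if (length(tok) >= 2 && tok[1] %in% lex$interrogatives &&
      !tok[1] %in% c("is", "it")) {
    # auxiliary openers mark polar questions; "do"/"can" etc. include
    # imperative false positives rarely seen in task talk
    if (!(tok[1] %in% c("do", "does", "did") && length(tok) <= 2)) return("Ques")
  }
  # 4. instruction quoting
  if (phrase_in(lex$read_cues)) {
    cue_rx <- paste0("(", paste(gsub("'", "'?", lex$read_cues), collapse = "|"), ")")
    remainder <- sub(paste0("^.*?", cue_rx), "", norm)
    rtok <- .da_tokens(remainder)
    has_content <- any(rtok %in% lex$verbs) || any(grepl("[0-9]", rtok))
    return(if (has_content) "Read" else "Out")
  }
  # 5. negation early in the utterance
  head3 <- tok[seq_len(min(3, length(tok)))]
  if (any(head3 %in% lex$neg) || grepl("^(oh no|not sure|i'?m not)", norm)) return("Neg")
  if (grepl("(^|[^a-z])(don'?t|not|no)([^a-z]|$)", paste(head3, collapse = " "))) return("Neg")
  # 6. short acknowledgements
  if (length(tok) <= 4 &&
      (norm_nopunct %in% lex$acks || phrase_in(lex$acks) && length(tok) <= 2 ||
       norm_nopunct %in% c("i know", "you're right"))) return("Acks")
  # 7. uninterpretable fragments
  alpha <- tok[grepl("[a-z]", tok)]
  if (length(alpha) == 0) return("Out")
  if (length(alpha) == 1 && alpha %in% .stopword_fragments) return("Out")
  # 8. residual: information, directives, opinion
  "Inform"
}

#' Tabulate dialogue-act frequencies per player
#'
#' @param utterances Utterance data frame with a `label` column (and
#'   `player`).
#' @return Data frame: one row per player, one column per dialogue act,
#'   plus `n_utterances`. The `Out` column is reported but flagged via
#'   `attr(x, "excluded")` as excluded from downstream analysis.
#' @export
dialogue_act_frequencies <- function(utterances) {
  labels <- dialogue_act_labels()
  players <- unique(as.character(utterances$player))
  rows <- lapply(players, function(p) {
    lab <- utterances$label[utterances$player == p]
    counts <- vapply(labels, function(l) sum(lab == l), numeric(1))
    cbind(data.frame(player = p, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          data.frame(n_utterances = length(lab)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    cbind(data.frame(player = character(), stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(matrix(numeric(0), 0, length(labels))), labels),
          data.frame(n_utterances = numeric(0)))
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- "Out"
  out
}

#' Extract and segment a session's transcript into labeled utterances
#'
#' Convenience pipeline step: pulls each player's transcribed words from
#' the session log (every non-empty `transcribed_text` record contributes
#' its words at the record timestamp), segments them into utterances,
#' flags initiations across both players, and assigns dialogue acts.
#'
#' @param log A `session_log`.
#' @param silence_gap,max_utterance Passed to [segment_utterances()].
#' @param silence_threshold Passed to [count_initiations()].
#' @return Labeled utterance data frame with `is_initiation` and `label`.
#' @export
session_utterances <- function(log, silence_gap = 1, max_utterance = 15,
                               silence_threshold = 30) {
  rec <- log$records
  sp <- rec[!is.na(rec$transcribed_text) & nzchar(trimws(rec$transcribed_text)), , drop = FALSE]
  utt_list <- lapply(sort(unique(sp$player)), function(p) {
    r <- sp[sp$player == p, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    words <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
      w <- strsplit(trimws(r$transcribed_text[i]), "\\s+")[[1]]
      data.frame(time = r$timestamp[i], word = w, player = p,
                 stringsAsFactors = FALSE)
    }))
    segment_utterances(words, silence_gap = silence_gap, max_utterance = max_utterance)
  })
  utt <- do.call(rbind, Filter(Negate(is.null), utt_list))
  if (is.null(utt) || nrow(utt) == 0) {
    out <- data.frame(player = character(), start = numeric(), end = numeric(),
                      text = character(), word_count = integer(),
                      topic_id = character(), is_initiation = logical(),
                      label = character(), stringsAsFactors = FALSE)
    attr(out, "counts") <- stats::setNames(integer(0), character(0))
    return(out)
  }
  utt <- count_initiations(utt[order(utt$start), , drop = FALSE],
                           silence_threshold = silence_threshold)
  counts <- attr(utt, "counts")
  utt$label <- classify_dialogue_act(utt$text)
  attr(utt, "counts") <- counts
  utt
}
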