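#' @title Time-aligned transcripts
#' @description
#' An aligned transcript is an ordered token table with, per token: the word
#' form, onset and offset in seconds, a coarse part-of-speech tag
#' (`noun`, `verb`, `adjective`, `adverb`, `other`), a syllable count, and a
#' stop-word flag. Content words are exactly the tokens tagged noun, verb,
#' adjective or adverb; a token cannot be both a stop word and a content word.
#' Syllable counts and stop-word status are taken from the transcript file
#' (they are language-dependent and produced upstream).
#' @name aligned_transcript
NULL

POS_TAGS <- c("noun", "verb", "adjective", "adverb", "other")
CONTENT_POS <- c("noun", "verb", "adjective", "adverb")

#' Construct and validate an aligned transcript
#'
#' @param tokens data.frame with columns `token`, `onset_s`, `offset_s`,
#'   `pos`, `syllables`, `is_stop`.
#' @param recording_id identifier string.
#' @param duration optional recording duration (seconds) used to check that
#'   all token times fall inside the recording.
#' @return object of class `aligned_transcript`.
#' @export
aligned_transcript <- function(tokens, recording_id = "recording",
                               duration = NULL) {
  req <- c("token", "onset_s", "offset_s", "pos", "syllables", "is_stop")
  missing_cols <- setdiff(req, names(tokens))
  if (length(missing_cols)) {
    stop("missing transcript column(s): ", paste(missing_cols, collapse = ", "))
  }
  tokens <- as.data.frame(tokens)[req]
  tokens$token <- as.character(tokens$token)
  tokens$onset_s <- as.numeric(tokens$onset_s)
  tokens$offset_s <- as.numeric(tokens$offset_s)
  tokens$pos <- as.character(tokens$pos)
  tokens$syllables <- as.integer(tokens$syllables)
  tokens$is_stop <- as.logical(tokens$is_stop)

  n <- nrow(tokens)
  bad_pos <- which(!tokens$pos %in% POS_TAGS)
  if (length(bad_pos)) {
    stop("unknown POS tag '", tokens$pos[bad_pos[1]], "' in row ", bad_pos[1])
  }
  bad_time <- which(tokens$offset_s <= tokens$onset_s)
  if (length(bad_time)) {
    stop("token offset <= onset in row ", bad_time[1],
         " ('", tokens$token[bad_time[1]], "')")
  }
  if (any(tokens$onset_s < 0)) stop("negative token onset time")
  if (n > 1L && any(diff(tokens$onset_s) < 0)) stop("token onsets not non-decreasing")
  if (!is.null(duration) && n > 0L && any(tokens$offset_s > duration + 1e-9)) {
    stop("token times exceed recording duration")
  }
  if (any(tokens$syllables < 1L, na.rm = TRUE)) stop("syllable counts must be >= 1")
  tokens$is_content <- tokens$pos %in% CONTENT_POS
  clash <- which(tokens$is_stop & tokens$is_content)
  if (length(clash)) {
    stop("token '", tokens$token[clash[1]], "' (row ", clash[1],
         ") flagged as stop word but tagged with a content POS")
  }
  structure(list(tokens = tokens, recording_id = recording_id),
            class = "aligned_transcript")
}

#' @export
print.aligned_transcript <- function(x, ...) {
  cat(sprintf("<aligned_transcript> '%s': %d tokens (%d content, %d stop)\n",
              x$recording_id, nrow(x$tokens), sum(x$tokens$is_content),
              sum(x$tokens$is_stop)))
  invisible(x)
}

#' Strip CHAT markup from a raw transcript
#'
#' Removes the annotation characters used by CHAT-style transcription
#' (`? – ( ) + . ! , : ; " [ ] < > / @ & *` and the ASCII dash when isolated)
#' and collapses whitespace, leaving plain text suitable for tokenization.
#'
#' @param raw character scalar, possibly containing CHAT markup.
#' @return cleaned character scalar (possibly empty).
#' @examples
#' clean_chat_transcript("the boy (is) falling +")  # "the boy is falling"
#' @export
clean_chat_transcript <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  out <- gsub("[?–—()+.!,:;\"\\[\\]<>/@&*=^~_%$#]", " ", raw, perl = TRUE)
  out <- gsub("(^| )-+( |$)", " ", out)
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

#' Read an aligned transcript from TSV or JSON
#'
#' The TSV dialect is UTF-8 with a header line
#' `token onset_s offset_s pos syllables is_stop`; the JSON dialect is an
#' object with `recording_id` and a `tokens` array of records with the same
#' fields. Format is chosen by file extension (`.json` vs anything else).
#'
#' @param path file path.
#' @return an [aligned_transcript()].
#' @export
read_aligned_transcript <- function(path) {
  if (!file.exists(path)) stop("transcript file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    tok <- as.data.frame(obj$tokens)
    rid <- if (!is.null(obj$recording_id)) obj$recording_id else basename(path)
    aligned_transcript(tok, recording_id = rid)
  } else {
    tok <- utils::read.delim(path, stringsAsFactors = FALSE)
    aligned_transcript(tok, recording_id = sub("\\.[^.]*$", "", basename(path)))
  }
}

#' Write an aligned transcript to TSV or JSON
#'
#' @param transcript an [aligned_transcript()].
#' @param path output path; `.json` selects the JSON dialect.
#' @return the path, invisibly.
#' @export
write_aligned_transcript <- function(transcript, path) {
  stopifnot(inherits(transcript, "aligned_transcript"))
  tok <- transcript$tokens[c("token", "onset_s", "offset_s", "pos",
                             "syllables", "is_stop")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(recording_id = transcript$recording_id, tokens = tok),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(tok, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a JSON object with a `participants` array; each participant
#' record carries `id`, `group` (`"patient"` or `"control"`), an optional
#' `mmse` (integer 0-30), a `language` tag, and either an `audio` WAV path or
#' a `segments` TSV path (precomputed speech/pause segmentation) plus a
#' `transcript` path. Paths are resolved relative to the manifest location.
#'
#' @param path manifest JSON path.
#' @return data.frame with one row per participant.
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::fromJSON(path)
  p <- as.data.frame(obj$participants)
  if (is.null(p$id) || anyDuplicated(p$id)) stop("manifest ids missing or duplicated")
  if (is.null(p$group) || !all(p$group %in% c("patient", "control"))) {
    stop("manifest group must be 'patient' or 'control' for every participant")
  }
  base <- dirname(normalizePath(path))
  for (col in c("audio", "transcript", "segments")) {
    if (!is.null(p[[col]])) {
      rel <- !is.na(p[[col]]) & !grepl("^/", p[[col]])
      p[[col]][rel] <- file.path(base, p[[col]][rel])
    }
  }
  if (is.null(p$mmse)) p$mmse <- NA_real_
  if (is.null(p$language)) p$language <- "und"
  p
}
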