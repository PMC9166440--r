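#' Tokenize free text
#'
#' Splits text on any run of non-alphanumeric characters and lower-cases the
#' result, keeping character offsets back into the original string. This
#' mirrors the observable behaviour of a standard full-text analyzer while
#' deliberately keeping negation tokens ("no", "not") intact: there is no
#' stemming and no stop-word removal, because the span queries need those
#' words. Hyphenated words split ("follow-up" -> "follow", "up").
#'
#' @param text a character scalar (NA treated as empty).
#' @return a `token_stream`: data.frame with columns `surface`, `normalized`,
#'   `char_start`, `char_end` (1-based, inclusive). Offsets are strictly
#'   increasing and non-overlapping; empty text gives zero rows.
#' @export
#' @examples
#' tokenize("CT OF THE CHEST.")$normalized
tokenize <- function(text) {
  if (length(text) != 1L) stop("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) {
    return(structure(data.frame(surface = character(),
                                normalized = character(),
                                char_start = integer(),
                                char_end = integer(),
                                stringsAsFactors = FALSE),
                     class = c("token_stream", "data.frame")))
  }
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) {
    return(tokenize(""))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surface <- substring(text, starts, starts + lens - 1L)
  structure(data.frame(surface = surface,
                       normalized = tolower(surface),
                       char_start = starts,
                       char_end = starts + lens - 1L,
                       stringsAsFactors = FALSE),
            class = c("token_stream", "data.frame"))
}
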