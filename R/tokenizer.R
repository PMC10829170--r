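# SMILES tokenization against a fixed 148-token vocabulary: every periodic
# table element symbol, the aromatic lowercase atoms, SMILES punctuation and
# a dedicated pad token. The token list is frozen in a versioned plain-text
# file shipped with the package (inst/extdata/vocabulary.txt, one token per
# line, line number - 1 = index) so encodings are reproducible across
# installations.

#' Build the SMILES token vocabulary
#'
#' Loads the frozen 148-token list: all 118 element symbols, the aromatic
#' atoms b/c/n/o/p/s, ring-closure digits 0-9, brackets, bond and charge
#' symbols (including `@` and `\\`), `%`, and a `<pad>` token at index 0.
#'
#' @param path optional path to an alternative token list (one per line).
#' @return object of class `smiles_vocabulary`: list with `tokens`
#'   (character vector), `pad_index` (0-based integer), and `index_of`
#'   (named integer vector of 0-based indices).
#' @export
build_vocabulary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "vocabulary.txt",
                                package = "contrastDDI", mustWork = TRUE)
  tokens <- readLines(path)
  if (anyDuplicated(tokens)) config_error("vocabulary contains duplicates")
  index_of <- stats::setNames(seq_along(tokens) - 1L, tokens)
  pad <- match("<pad>", tokens)
  if (is.na(pad)) config_error("vocabulary has no <pad> token")
  structure(list(tokens = tokens, pad_index = pad - 1L, index_of = index_of),
            class = "smiles_vocabulary")
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat(sprintf("<smiles_vocabulary: %d tokens, pad_index %d>\n",
              length(x$tokens), x$pad_index))
  invisible(x)
}

# Two-character tokens (element symbols) for the greedy longest-match pass.
two_char_tokens <- function(vocab) vocab$tokens[nchar(vocab$tokens) == 2L]

#' Encode a SMILES string as a fixed-length token-id sequence
#'
#' Greedy longest-match tokenization: at each position a two-character
#' element symbol (Cl, Br, Si, ...) is consumed if it matches, otherwise a
#' single character. The id sequence is padded with the pad token to
#' `max_len`; longer strings are truncated (prefix kept) with a warning.
#'
#' @param smiles a non-empty SMILES string.
#' @param vocab a [build_vocabulary()] object.
#' @param max_len fixed output length (default 250).
#' @return object of class `token_sequence`: list with `ids` (0-based
#'   integer vector of length `max_len`), `length_unpadded`, and
#'   `source_smiles`.
#' @export
encode <- function(smiles, vocab = build_vocabulary(), max_len = 250L) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    value_error("smiles must be a single non-empty string")
  if (max_len < 1L) value_error("max_len must be >= 1")
  two <- two_char_tokens(vocab)
  n <- nchar(smiles)
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    pair <- substr(smiles, i, i + 1L)
    if (i < n && pair %in% two) {
      toks <- c(toks, pair); i <- i + 2L
    } else {
      ch <- substr(smiles, i, i)
      if (is.na(vocab$index_of[ch])) unknown_token_error(ch, smiles)
      toks <- c(toks, ch); i <- i + 1L
    }
  }
  ids <- unname(vocab$index_of[toks])
  if (length(ids) > max_len) {
    warning(sprintf("SMILES of %d tokens truncated to max_len = %d",
                    length(ids), max_len))
    ids <- ids[seq_len(max_len)]
  }
  len <- length(ids)
  ids <- c(ids, rep(vocab$pad_index, max_len - len))
  structure(list(ids = as.integer(ids), length_unpadded = len,
                 source_smiles = smiles),
            class = "token_sequence")
}

#' Decode a token sequence back to its SMILES string
#' @param seq a [encode()] result.
#' @param vocab the vocabulary used to encode it.
#' @return the concatenated token string (equals the input SMILES when no
#'   truncation occurred).
#' @export
decode <- function(seq, vocab = build_vocabulary()) {
  ids <- seq$ids[seq_len(seq$length_unpadded)]
  paste(vocab$tokens[ids + 1L], collapse = "")
}

# Encode many SMILES into an n x max_len integer id matrix (0-based ids).
encode_batch <- function(smiles, vocab, max_len) {
  out <- matrix(vocab$pad_index, nrow = length(smiles), ncol = max_len)
  for (i in seq_along(smiles)) {
    out[i, ] <- encode(smiles[i], vocab, max_len)$ids
  }
  out
}
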