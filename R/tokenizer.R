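# SMILES tokenization and the token vocabulary shared by policy models.
# Multi-character units -- bracket atoms "[...]", two-letter halogens Cl/Br,
# and %nn ring-bond labels -- are single tokens; everything else is one
# character per token.

.TOKEN_RE <- "\\[[^]]*\\]|Cl|Br|%[0-9]{2}|."

.PAD <- "<pad>"
.BOS <- "<bos>"
.EOS <- "<eos>"

#' Tokenize a SMILES string
#'
#' @param s a single SMILES string.
#' @return character vector of tokens; pasting them back yields `s`.
#' @export
smiles_tokenize <- function(s) {
  s <- as.character(s)
  if (length(s) != 1) stop("smiles_tokenize() expects a single string")
  if (!nzchar(s)) stop("cannot tokenize an empty string")
  n_open <- lengths(regmatches(s, gregexpr("\\[", s)))
  n_close <- lengths(regmatches(s, gregexpr("\\]", s)))
  if (n_open != n_close) {
    stop("cannot tokenize '", s, "': unbalanced bracket atom")
  }
  toks <- regmatches(s, gregexpr(.TOKEN_RE, s))[[1]]
  stopifnot(identical(paste(toks, collapse = ""), s))
  toks
}

#' Build a token vocabulary from a corpus
#'
#' The vocabulary covers every token occurring in the corpus plus the
#' padding, begin-of-sequence and end-of-sequence specials, in a
#' deterministic order (specials first, then tokens sorted bytewise).
#'
#' @param corpus character vector of SMILES strings.
#' @return a `clm_vocabulary`: list with `tokens` (character) and special
#'   indices `pad`, `bos`, `eos`.
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0) stop("cannot build a vocabulary from an empty corpus")
  toks <- unique(unlist(lapply(corpus, smiles_tokenize)))
  toks <- sort(toks, method = "radix")
  tokens <- c(.PAD, .BOS, .EOS, toks)
  v <- list(tokens = tokens,
            index = stats::setNames(seq_along(tokens), tokens),
            pad = 1L, bos = 2L, eos = 3L)
  class(v) <- "clm_vocabulary"
  v
}

#' @export
print.clm_vocabulary <- function(x, ...) {
  cat("<clm_vocabulary> ", length(x$tokens), " tokens (3 specials)\n", sep = "")
  invisible(x)
}

#' Encode a SMILES string as a token-index sequence
#'
#' @param s a SMILES string.
#' @param vocab a [build_vocabulary()] vocabulary.
#' @return integer vector of content token indices followed by the EOS
#'   index.
#' @export
tokenize <- function(s, vocab) {
  toks <- smiles_tokenize(s)
  idx <- vocab$index[toks]
  if (anyNA(idx)) {
    stop("out-of-vocabulary token(s): ",
         paste(unique(toks[is.na(idx)]), collapse = ", "))
  }
  as.integer(c(idx, vocab$eos))
}

#' Decode a token-index sequence back to a string
#'
#' @param idx integer vector of token indices (EOS and padding are dropped).
#' @param vocab the vocabulary.
#' @return the decoded string.
#' @export
detokenize <- function(idx, vocab) {
  idx <- idx[idx > 3L]  # strip specials
  paste(vocab$tokens[idx], collapse = "")
}

# pad a list of index vectors into the (B x T) matrix the compiled layer
# expects; rows are sequences, 0 marks padding
.pad_sequences <- function(seqs) {
  lens <- lengths(seqs)
  tmax <- max(lens, 1L)
  mat <- matrix(0L, length(seqs), tmax)
  for (i in seq_along(seqs)) mat[i, seq_len(lens[i])] <- seqs[[i]]
  list(tokens = mat, lengths = as.integer(lens))
}
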