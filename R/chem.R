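# Chemistry primitives: validity, canonicalization, circular fingerprints,
# Tanimoto. All molecule handling goes through Open Babel (ChemmineOB); one
# canonicalization dialect is therefore fixed for a whole session.

.chem <- new.env(parent = emptyenv())
.chem$canon <- new.env(parent = emptyenv(), hash = TRUE)
.chem$fp <- new.env(parent = emptyenv(), hash = TRUE)
.chem$silenced <- FALSE
.chem$fp_handle <- NULL

# Open Babel reports parse warnings on stderr for every invalid SMILES; a
# policy early in training produces thousands of those, so the message
# handler is turned down once per session (global Open Babel state).
.ob_quiet <- function() {
  if (!.chem$silenced) {
    h <- ChemmineOB:::obErrorLog_get()
    ChemmineOB:::OBMessageHandler_SetOutputLevel(h, 0L)
    .chem$silenced <- TRUE
  }
  invisible(NULL)
}

# Open Babel batch conversion stops at the first unparsable record; convert
# a suffix at a time, marking each stopping record invalid, until the whole
# vector is covered.
.canon_uncached <- function(smis) {
  .ob_quiet()
  n <- length(smis)
  out <- rep(NA_character_, n)
  ok <- nzchar(smis) & !grepl("[[:space:]]", smis)
  idx <- which(ok)
  i <- 1L
  while (i <= length(idx)) {
    sub <- idx[i:length(idx)]
    input <- paste0(paste(smis[sub], "x"), collapse = "\n")
    res <- ChemmineOB::convertFormat("SMI", "CAN", paste0(input, "\n"))
    lines <- if (nzchar(res)) strsplit(res, "\n", fixed = TRUE)[[1]] else character()
    k <- length(lines)
    if (k > 0) out[sub[seq_len(k)]] <- sub("\t.*$", "", lines)
    # record k+1 (if any) is the one conversion choked on
    i <- i + k + 1L
  }
  out
}

#' Validate and canonicalize SMILES strings
#'
#' Parses each string with Open Babel and returns its canonical SMILES, or
#' `NA` for strings that do not describe a molecule. Invalidity is a value,
#' not an error, because generated strings are routinely malformed.
#' Canonicalization is idempotent and maps equal molecules to equal text
#' within a session.
#'
#' @param smiles character vector of SMILES strings.
#' @param cache reuse previously computed canonical forms (session-level
#'   cache; generated molecules repeat heavily during optimization).
#' @return character vector, canonical SMILES or `NA` per element.
#' @examples
#' \dontrun{
#' validate_and_canonicalize(c("OCC", "C(C)O", "C1CC"))
#' }
#' @export
validate_and_canonicalize <- function(smiles, cache = TRUE) {
  if (length(smiles) == 0) return(character())
  smiles <- as.character(smiles)
  if (!cache) return(.canon_uncached(smiles))
  out <- rep(NA_character_, length(smiles))
  key <- smiles
  key[!nzchar(key)] <- "\x01empty"
  hit <- vapply(key, function(k) exists(k, envir = .chem$canon, inherits = FALSE),
                logical(1), USE.NAMES = FALSE)
  if (any(hit)) {
    out[hit] <- vapply(key[hit], function(k) get(k, envir = .chem$canon),
                       character(1), USE.NAMES = FALSE)
  }
  miss <- which(!hit)
  if (length(miss)) {
    um <- !duplicated(key[miss])
    fresh <- .canon_uncached(smiles[miss][um])
    fk <- key[miss][um]
    for (j in seq_along(fk)) assign(fk[j], fresh[j], envir = .chem$canon)
    out[miss] <- vapply(key[miss], function(k) get(k, envir = .chem$canon),
                        character(1), USE.NAMES = FALSE)
  }
  out
}

#' Test whether SMILES strings are valid
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
smiles_is_valid <- function(smiles) {
  !is.na(validate_and_canonicalize(smiles))
}

.fp_handle <- function() {
  if (is.null(.chem$fp_handle)) {
    .chem$fp_handle <- ChemmineOB:::OBFingerprint_FindFingerprint("ECFP4")
  }
  .chem$fp_handle
}

.fp_one <- function(smiles, nbits) {
  key <- paste0(nbits, "|", smiles)
  if (exists(key, envir = .chem$fp, inherits = FALSE)) {
    return(get(key, envir = .chem$fp))
  }
  .ob_quiet()
  refs <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), identity)
  words <- ChemmineOB:::OBFingerprint_GetFingerprint(.fp_handle(), refs[[1]],
                                                     numeric(1))[[2]]
  bits <- which(as.logical(intToBits(as.integer(words))))
  native <- length(words) * 32L
  if (nbits < native) {
    bits <- sort(unique((bits - 1L) %% as.integer(nbits) + 1L))  # fold
  }
  fp <- structure(as.integer(bits), nbits = as.integer(nbits),
                  class = "molexplore_fp")
  assign(key, fp, envir = .chem$fp)
  fp
}

#' ECFP4 circular fingerprints
#'
#' Radius-2 circular (Morgan-style) substructure fingerprints computed by
#' Open Babel, folded to `nbits` bits. Returned as sorted vectors of on-bit
#' positions, which keeps Tanimoto arithmetic fast for sparse fingerprints.
#'
#' @param smiles character vector of valid SMILES.
#' @param nbits fingerprint length after folding (default 2048).
#' @return list of `molexplore_fp` objects (integer bit positions with an
#'   `nbits` attribute), one per input.
#' @export
ecfp4 <- function(smiles, nbits = 2048L) {
  if (length(smiles) == 0) return(list())
  if (anyNA(smiles)) stop("ecfp4() requires valid SMILES; got NA input")
  bad <- !smiles_is_valid(smiles)
  if (any(bad)) {
    stop("ecfp4() requires valid SMILES; invalid: ",
         paste(utils::head(smiles[bad], 3), collapse = ", "))
  }
  lapply(as.character(smiles), .fp_one, nbits = nbits)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a intersect b| / |a union b|` on on-bit sets. Two empty fingerprints
#' have similarity 0 by convention (unreachable for valid molecules).
#'
#' @param a,b fingerprints from [ecfp4()] (integer vectors of bit positions).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 && nb == 0) return(0)
  ni <- length(intersect(a, b))
  ni / (na + nb - ni)
}

# Cross matrix of Tanimoto similarities; rows = fps_a, cols = fps_b.
.tanimoto_cross <- function(fps_a, fps_b) {
  out <- matrix(0, length(fps_a), length(fps_b))
  for (j in seq_along(fps_b)) {
    b <- fps_b[[j]]
    out[, j] <- vapply(fps_a, tanimoto, numeric(1), b = b)
  }
  out
}
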