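# Shared low-level helpers: alphabets, encodings, dot-bracket parsing.

SEQ_LEVELS <- c("A", "C", "G", "U")
STRUCT_LEVELS <- c("(", ".", ")")

# fixed 10-nt exonic flanks added around the 70-nt variable exon; these
# stand in for the constant reporter context on each side of the window
FLANK_5 <- "AGACUUACCU"
FLANK_3 <- "GUCAUACGAC"

#' Normalize nucleotide strings to the RNA alphabet
#'
#' Uppercases and converts T to U. Errors if any other letter remains.
#'
#' @param x Character vector of DNA or RNA strings.
#' @param allow_n Keep `N` letters instead of erroring (default `FALSE`).
#' @return Character vector over `A,C,G,U`.
#' @export
rna_normalize <- function(x, allow_n = FALSE) {
  out <- chartr("tT", "uU", x)
  out <- toupper(out)
  pat <- if (allow_n) "[^ACGUN]" else "[^ACGU]"
  bad <- grepl(pat, out)
  if (any(bad)) {
    abort(sprintf("invalid nucleotide letters in %d sequence(s), e.g. '%s'",
                  sum(bad), substr(out[which(bad)[1]], 1, 20)))
  }
  out
}

reverse_complement <- function(x) {
  x <- rna_normalize(x)
  vapply(x, function(s) {
    chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

seq_to_int <- function(x) {
  # 0-based codes A=0, C=1, G=2, U=3; x: character vector of equal-length
  # strings -> integer matrix (n x d)
  chars <- strsplit(x, "")
  d <- unique(lengths(chars))
  if (length(d) != 1L) abort("sequences must share one length")
  m <- matrix(match(unlist(chars), SEQ_LEVELS) - 1L, nrow = length(x),
              ncol = d, byrow = TRUE)
  if (anyNA(m)) abort("invalid sequence letter (expected A/C/G/U)")
  m
}

struct_to_int <- function(x) {
  chars <- strsplit(x, "")
  d <- unique(lengths(chars))
  if (length(d) != 1L) abort("structures must share one length")
  m <- matrix(match(unlist(chars), STRUCT_LEVELS) - 1L, nrow = length(x),
              ncol = d, byrow = TRUE)
  if (anyNA(m)) abort("invalid structure character (expected '(', '.', ')')")
  m
}

wobble_to_int <- function(x) {
  # accepts "0"/"1" strings
  chars <- strsplit(x, "")
  d <- unique(lengths(chars))
  if (length(d) != 1L) abort("wobble strings must share one length")
  v <- match(unlist(chars), c("0", "1")) - 1L
  if (anyNA(v)) abort("wobble indicator must be a string of 0s and 1s")
  matrix(v, nrow = length(x), ncol = d, byrow = TRUE)
}

#' Pair table of a dot-bracket structure
#'
#' Matches brackets and returns, for each position, the index of its
#' partner (`NA` for unpaired positions). 1-based.
#'
#' @param structure A single dot-bracket string.
#' @return Integer vector of partner indices.
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  if (!all(chars %in% STRUCT_LEVELS)) {
    abort("invalid structure character (expected '(', '.', ')')")
  }
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) abort("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0L) abort("unbalanced dot-bracket structure")
  partner
}

helix_run_list <- function(partner, min_len = 1L) {
  # maximal stacks of nested pairs; each run reported by its 5' arm positions
  opens <- which(!is.na(partner) & seq_along(partner) < partner)
  if (length(opens) == 0L) return(list())
  runs <- list()
  start <- 1L
  for (i in seq_along(opens)[-1]) {
    contiguous <- opens[i] == opens[i - 1] + 1L &&
      partner[opens[i]] == partner[opens[i - 1]] - 1L
    if (!contiguous) {
      runs[[length(runs) + 1L]] <- opens[start:(i - 1L)]
      start <- i
    }
  }
  runs[[length(runs) + 1L]] <- opens[start:length(opens)]
  runs[lengths(runs) >= min_len]
}

softplus <- function(t) {
  ifelse(t > 30, t, log1p(exp(pmin(t, 30))))
}

sigmoid <- function(t) {
  1 / (1 + exp(-t))
}

#' Fixed flanking sequences of the reporter window
#'
#' The 70-nt variable exon is embedded in a 90-nt window between two fixed
#' 10-nt exonic flanks. These constants define the default reporter context
#' used by the synthetic assay generator and window assembly.
#'
#' @return Named character vector with elements `flank5` and `flank3`.
#' @export
splice_flanks <- function() {
  c(flank5 = FLANK_5, flank3 = FLANK_3)
}

round_half_up <- function(x) {
  floor(x + 0.5)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be in [0, 1]", name))
  }
}
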